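as_labels <- function(l) {
  class(l) <- "SpotLabels"
  l
}

test_that("spots with identical label sets share a group, order-independently", {
  labels <- as_labels(list(s1 = "A", s2 = "A", s3 = c("A", "B"), s4 = character()))
  g <- group_spots(labels)
  expect_setequal(g[["A"]], c("s1", "s2"))
  expect_identical(g[["A;B"]], "s3")
  expect_identical(g[[which(names(g) == "")]], "s4")
  # label order within a spot does not matter
  g2 <- group_spots(as_labels(list(s1 = "A", s2 = "A", s3 = c("B", "A"),
                                   s4 = character())))
  expect_identical(g2, g)
  # spot order does not change group contents
  g3 <- group_spots(as_labels(list(s3 = c("A", "B"), s1 = "A",
                                   s4 = character(), s2 = "A")))
  expect_true(setequal(g3[["A"]], g[["A"]]))
})

test_that("random labellings match a dictionary oracle and partition the spots", {
  set.seed(31)
  pool <- c("A", "B", "C", "D")
  labels <- lapply(seq_len(500), function(i) {
    sample(pool, min(rpois(1, 1.2), 4), replace = FALSE)
  })
  names(labels) <- sprintf("s%03d", seq_len(500))
  g <- group_spots(as_labels(labels))
  # oracle: build the mapping with a plain loop
  oracle <- list()
  for (id in names(labels)) {
    # "k_" prefix keeps the empty combination addressable by name
    key <- paste0("k_", paste(sort(labels[[id]]), collapse = ";"))
    oracle[[key]] <- c(oracle[[key]], id)
  }
  expect_setequal(paste0("k_", names(g)), names(oracle))
  for (key in names(oracle)) {
    expect_setequal(g[[which(paste0("k_", names(g)) == key)]], oracle[[key]])
  }
  # partition: every spot in exactly one group
  expect_equal(sum(lengths(g)), 500L)
  expect_false(anyDuplicated(unlist(g)) > 0)
})

make_group_tables <- function(counts_by_dataset) {
  lapply(counts_by_dataset, function(counts) {
    tab <- list()
    i <- 0
    for (cb in names(counts)) {
      tab[[cb]] <- sprintf("s%05d", seq(i + 1, i + counts[[cb]]))
      i <- i + counts[[cb]]
    }
    class(tab) <- "SpotGroupTable"
    tab
  })
}

test_that("recurrence requires strictly more than the floor in every dataset", {
  tables <- make_group_tables(replicate(8, c("A" = 101, "A;B" = 150), simplify = FALSE))
  names(tables) <- sprintf("d%d", 1:8)
  expect_setequal(recurrent_groups(tables), c("A", "A;B"))

  tables2 <- tables
  tables2[[3]] <- make_group_tables(list(c("A" = 100, "A;B" = 150)))[[1]]
  expect_identical(recurrent_groups(tables2), "A;B")

  expect_error(recurrent_groups(tables[1:7]), "expected 8")
  expect_identical(recurrent_groups(tables[1:5], n_expected = 5),
                   c("A", "A;B"))
})

test_that("flag proportions count flagged members per group and dataset", {
  tables <- make_group_tables(list(d1 = c("A" = 10, "B" = 4)))
  flags <- list(d1 = stats::setNames(rep(c(TRUE, FALSE), c(5, 9)),
                                     sprintf("s%05d", 1:14)))
  gs <- group_flag_proportions(tables, flags)
  expect_equal(gs$proportion[gs$combination == "A"], 0.5)
  expect_equal(gs$proportion[gs$combination == "B"], 0)

  # random instance vs a direct counting oracle
  set.seed(17)
  tables2 <- make_group_tables(list(d1 = c("A" = 30, "B" = 20, "C" = 25)))
  fl <- stats::setNames(runif(75) < 0.4, sprintf("s%05d", 1:75))
  gs2 <- group_flag_proportions(tables2, list(d1 = fl))
  for (cb in c("A", "B", "C")) {
    members <- tables2$d1[[cb]]
    expect_equal(gs2$proportion[gs2$combination == cb],
                 sum(fl[members]) / length(members))
  }
})

make_stats <- function(ref_props, cmp_props, cmp = "B") {
  n <- length(ref_props)
  data.frame(
    combination = rep(c("Astro-2;Micro-2;Vas-1", cmp), each = n),
    dataset_id = rep(sprintf("d%d", seq_len(n)), 2),
    n_spots = 100L, n_flagged = 0L,
    proportion = c(ref_props, cmp_props), stringsAsFactors = FALSE)
}

test_that("paired one-tailed tests behave at the boundaries and planted offsets", {
  equal <- make_stats(rep(0.3, 8), rep(0.3, 8))
  res <- compare_reference_group(equal)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0.5)

  const <- make_stats(seq(0.4, 0.75, by = 0.05),
                      seq(0.1, 0.45, by = 0.05))  # constant +0.3 offset
  res2 <- compare_reference_group(const)
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 0)

  set.seed(5)
  noisy <- make_stats(0.6 + rnorm(8, 0, 0.03), 0.2 + rnorm(8, 0, 0.03))
  res3 <- compare_reference_group(noisy)
  expect_false(res3$degenerate)
  expect_lt(res3$p_value, 0.001)

  expect_error(compare_reference_group(make_stats(0.5, 0.1)), "fewer than 2")
})

test_that("swapping reference and comparator maps p to 1 - p in the continuous case", {
  set.seed(6)
  a <- 0.5 + rnorm(8, 0, 0.05)
  b <- 0.4 + rnorm(8, 0, 0.05)
  fwd <- compare_reference_group(make_stats(a, b))$p_value
  rev <- compare_reference_group(make_stats(b, a))$p_value
  expect_equal(fwd + rev, 1, tolerance = 1e-12)
})
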