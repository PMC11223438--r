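test_that("a pair at the null floor has activity 0 and a dominant pair is capped", {
  # geneA and geneB share their whole top set; all other genes are noise, so
  # no null pair can reach the observed score and freq hits the 1/n floor
  n <- 1000
  set.seed(10)
  counts <- cbind(matrix(0L, n, 2),
                  matrix(rnbinom(n * 300, mu = 5, size = 2), n, 300))
  counts[1:60, 1:2] <- 50L
  expr <- expression_matrix(counts, sprintf("s%04d", 1:n),
                            c("lig", "rec", sprintf("g%03d", 1:300)),
                            unit = "raw")
  ds <- spatial_dataset(expr, data.frame(spot_id = row_ids(expr),
                                         x = seq_len(n), y = 0))
  null <- null_params(n_random_pairs = 500L, rng_seed = 7)
  act <- lr_activity(ds, lr_catalog("lig", "rec"), coloc_params(), null)
  expect_equal(act$score, 1)
  expect_equal(act$freq, 1 / 500)
  expect_equal(act$activity, log2(500))
  expect_true(act$active)

  # a pair whose score ties the bulk of the null: freq 1, activity exactly 0
  act0 <- lr_activity(ds, lr_catalog("g001", "g002"), coloc_params(), null)
  expect_equal(act0$score, 0)
  expect_equal(act0$freq, 1)
  expect_equal(act0$activity, 0)
  expect_false(act0$active)
})

test_that("activity is bit-for-bit reproducible under a fixed seed", {
  ds <- random_dataset(20, n_spots = 400, n_genes = 40, mu = 6)
  pairs <- lr_catalog(c("g001", "g003"), c("g002", "g004"))
  null <- null_params(n_random_pairs = 300L, rng_seed = 5)
  a <- lr_activity(ds, pairs, coloc_params(min_overlap = 5L), null)
  b <- lr_activity(ds, pairs, coloc_params(min_overlap = 5L), null)
  expect_identical(a, b)
  # a different dataset index derives a different null substream
  s1 <- nichecoloc:::.dataset_seed(null$rng_seed, 1L)
  s2 <- nichecoloc:::.dataset_seed(null$rng_seed, 2L)
  expect_false(s1 == s2)
  expect_false(identical(nichecoloc:::.draw_null_pairs(40, 300, s1),
                         nichecoloc:::.draw_null_pairs(40, 300, s2)))
})

test_that("undetected genes yield missing activity with a warning", {
  ds <- random_dataset(21, n_spots = 100, n_genes = 10)
  pairs <- lr_catalog(c("g001", "ghost"), c("g002", "g003"))
  expect_warning(act <- lr_activity(ds, pairs, coloc_params(),
                                    null_params(n_random_pairs = 100L)),
                 "undetected")
  expect_false(is.na(act$activity[1]))
  expect_true(is.na(act$activity[2]))
  expect_false(act$active[2])
})

test_that("spot flags are the logical AND of nonzero raw counts", {
  counts <- matrix(c(2L, 0L,
                     1L, 1L,
                     0L, 3L), ncol = 2, byrow = TRUE)
  expr <- expression_matrix(counts, c("s1", "s2", "s3"), c("lig", "rec"),
                            unit = "raw")
  ds <- spatial_dataset(expr, data.frame(spot_id = c("s1", "s2", "s3"),
                                         x = 1:3, y = 0))
  expect_equal(as.logical(lr_spot_flags(ds, "lig", "rec")),
               c(FALSE, TRUE, FALSE))

  rnd <- random_dataset(22, n_spots = 150, n_genes = 6, mu = 0.7)
  fl <- lr_spot_flags(rnd, "g001", "g002")
  v <- as.matrix(rnd$expr$values)
  expect_equal(unname(fl), unname(v[, "g001"] > 0 & v[, "g002"] > 0))

  expect_warning(none <- lr_spot_flags(rnd, "g001", "ghost"), "absent")
  expect_false(any(none))
})

test_that("the exact rank-sum p-value matches the classical test without ties", {
  x <- c(3.1, 4.5, 2.2, 5.0)
  y <- c(1.0, 1.5, 2.0, 0.5)
  expect_equal(nichecoloc:::.exact_ranksum_p(x, y),
               stats::wilcox.test(x, y, alternative = "greater",
                                  exact = TRUE)$p.value)
})

make_activity_table <- function(bins_by_tp, genotype = "WT",
                                ligand = "L", receptor = "R") {
  rows <- list()
  for (tp in names(bins_by_tp)) {
    for (i in seq_along(bins_by_tp[[tp]])) {
      act <- if (bins_by_tp[[tp]][i] == 1) 10 else 0
      rows[[length(rows) + 1]] <- data.frame(
        ligand = ligand, receptor = receptor,
        dataset_id = sprintf("%s_%sh_r%d", genotype, tp, i),
        genotype = genotype, timepoint_h = as.integer(tp),
        score = 0.1, freq = 2^-act, activity = act, active = act > 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("responsiveness needs full separation of the binarized sets", {
  sep <- make_activity_table(list(`0` = c(0, 0), `12` = c(1, 1),
                                  `24` = c(1, 1), `72` = c(0, 0)))
  res <- responsive_lrs(sep, "WT")
  expect_true(res$responsive)
  expect_equal(res$p_value, 1 / choose(8, 4), tolerance = 1e-12)

  flat <- make_activity_table(list(`0` = c(1, 1), `12` = c(1, 1),
                                   `24` = c(1, 1), `72` = c(1, 1)))
  expect_false(responsive_lrs(flat, "WT")$responsive)

  partial <- make_activity_table(list(`0` = c(0, 0), `12` = c(1, 1),
                                      `24` = c(1, 0), `72` = c(0, 0)))
  expect_false(responsive_lrs(partial, "WT")$responsive)

  missing_tp <- sep[sep$timepoint_h != 72L, ]
  expect_error(responsive_lrs(missing_tp, "WT"), "four timepoints")
})
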