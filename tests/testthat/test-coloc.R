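test_that("top sets have the stated size and match a full-sort oracle", {
  ds <- random_dataset(1, n_spots = 1000, n_genes = 10)
  params <- coloc_params()
  expect_length(top_spots(ds, "g001", params), 50L)
  for (g in gene_ids(ds)) {
    expect_identical(top_spots(ds, g, params), brute_top_set(ds, g, params))
  }
  expect_error(top_spots(ds, "missing"), "not present")
})

test_that("an unexpressed gene yields the deterministic all-tie top set", {
  ds <- random_dataset(2, n_spots = 200, n_genes = 5)
  v <- as.matrix(ds$expr$values)
  v[, "g001"] <- 0L
  ds$expr <- expression_matrix(v, row_ids(ds), gene_ids(ds), unit = "raw")
  top <- top_spots(ds, "g001")
  # all-zero ties resolve to the lexicographically first spot ids
  expect_identical(sort(top), sort(row_ids(ds))[seq_len(10)])
})

test_that("constructed overlaps give the exact Jaccard values and floor behavior", {
  n <- 2000  # top fraction 0.05 -> sets of exactly 100 spots
  ds_60 <- constructed_pair_dataset(n, setA = 1:100, setB = 41:140)
  expect_equal(coloc_score(ds_60, "geneA", "geneB"), 60 / 140)
  ds_49 <- constructed_pair_dataset(n, setA = 1:100, setB = 52:151)
  expect_equal(coloc_score(ds_49, "geneA", "geneB"), 0)
  ds_eq <- constructed_pair_dataset(n, setA = 1:100, setB = 1:100)
  expect_equal(coloc_score(ds_eq, "geneA", "geneA"), 1)
  expect_equal(coloc_score(ds_eq, "geneA", "geneB"), 1)
})

test_that("the score is symmetric and monotone in the overlap", {
  ds <- random_dataset(3, n_spots = 500, n_genes = 30, mu = 8)
  params <- coloc_params(min_overlap = 2L)
  genes <- gene_ids(ds)
  set.seed(99)
  for (i in 1:50) {
    pair <- sample(genes, 2)
    expect_identical(coloc_score(ds, pair[1], pair[2], params),
                     coloc_score(ds, pair[2], pair[1], params))
  }
  # larger overlap at fixed set size never decreases the score
  scores <- vapply(seq(50, 100, by = 10), function(ov) {
    d <- constructed_pair_dataset(2000, 1:100, (101 - ov):(200 - ov))
    coloc_score(d, "geneA", "geneB")
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("the pairwise matrix equals per-pair recomputation and the brute oracle", {
  ds <- random_dataset(4, n_spots = 400, n_genes = 30, mu = 6)
  params <- coloc_params(min_overlap = 10L)
  cm <- coloc_matrix(ds, gene_ids(ds), params)
  expect_equal(cm$S, t(cm$S))
  expect_true(all(cm$S >= 0 & cm$S <= 1))
  expect_true(all(diag(cm$S) == 1))
  for (i in c(1, 7, 19)) {
    for (j in c(2, 15, 30)) {
      expect_identical(cm$S[i, j],
                       coloc_score(ds, cm$genes[i], cm$genes[j], params))
    }
  }
  expect_equal(cm$S, brute_coloc_matrix(ds, cm$genes, params))
})

test_that("identical genes give an all-ones block and disjoint genes a diagonal", {
  counts <- matrix(0L, nrow = 100, ncol = 3)
  counts[1:40, ] <- 10L  # three identical columns
  expr <- expression_matrix(counts, sprintf("s%03d", 1:100),
                            c("a", "b", "c"), unit = "raw")
  coords <- data.frame(spot_id = row_ids(expr), x = 1:100, y = 0)
  ds <- spatial_dataset(expr, coords)
  cm <- coloc_matrix(ds, c("a", "b", "c"), coloc_params(min_overlap = 5L))
  expect_true(all(cm$S == 1))

  counts2 <- matrix(0L, nrow = 90, ncol = 3)
  counts2[1:10, 1] <- 5L
  counts2[11:20, 2] <- 5L
  counts2[21:30, 3] <- 5L
  expr2 <- expression_matrix(counts2, sprintf("s%03d", 1:90),
                             c("a", "b", "c"), unit = "raw")
  ds2 <- spatial_dataset(expr2, data.frame(spot_id = row_ids(expr2),
                                           x = 1:90, y = 0))
  cm2 <- coloc_matrix(ds2, c("a", "b", "c"),
                      coloc_params(top_fraction = 0.1, min_overlap = 2L,
                                   use_raw = TRUE))
  expect_equal(cm2$S, diag(3), ignore_attr = TRUE)
})

test_that("module detection pulls out a planted block and is order-invariant", {
  genes <- sprintf("m%02d", 1:30)
  S <- matrix(0, 30, 30, dimnames = list(genes, genes))
  S[1:10, 1:10] <- 0.6
  diag(S) <- 1
  cm <- structure(list(S = S, genes = genes, params = coloc_params(),
                       dataset_id = "toy"), class = "ColocMatrix")
  expect_setequal(detect_colocm(cm), genes[1:10])

  perm <- sample(30)
  cm_perm <- structure(list(S = S[perm, perm], genes = genes[perm],
                            params = coloc_params(), dataset_id = "toy"),
                       class = "ColocMatrix")
  expect_identical(detect_colocm(cm_perm), detect_colocm(cm))
})

test_that("a scoreless matrix yields an empty module with a warning", {
  genes <- sprintf("m%02d", 1:12)
  S <- diag(12)
  dimnames(S) <- list(genes, genes)
  cm <- structure(list(S = S, genes = genes, params = coloc_params(),
                       dataset_id = "toy"), class = "ColocMatrix")
  expect_warning(mod <- detect_colocm(cm), "empty module")
  expect_length(mod, 0L)
})

test_that("module scoring matches the signature-score contract on spots", {
  ds <- random_dataset(5, n_spots = 150, n_genes = 12)
  genes <- gene_ids(ds)[1:6]
  ms <- module_score(ds, genes)
  ln <- lognormalize(ds$expr)
  expect_equal(ms$score, signature_score(ln, genes)$score, tolerance = 1e-12)
  expect_identical(attr(ms, "signature_name"), "Co-locM")
})
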