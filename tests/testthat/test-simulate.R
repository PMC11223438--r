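# a reduced configuration for null-control experiments (the default-size
# cohort is exercised by the shared fixture and the acceptance tests)
small_cfg <- function(...) {
  sim_config(n_spots_per_dataset = 2500L, grid_width = 50L,
             grid_height = 50L, niche_radius = 8, vessel_core_radius = 2,
             n_cells_per_type = 60L, ...)
}

test_that("the same seed reproduces the cohort and the reference exactly", {
  a <- simulate_cohort(small_cfg(rng_seed = 11))
  b <- simulate_cohort(small_cfg(rng_seed = 11))
  expect_identical(names(a$datasets), names(b$datasets))
  for (id in c("WT_0h_r1", "KO_24h_r2")) {
    expect_identical(as.matrix(a$datasets[[id]]$expr$values),
                     as.matrix(b$datasets[[id]]$expr$values))
  }
  expect_identical(a$weights, b$weights)

  r1 <- simulate_reference(small_cfg(rng_seed = 11))
  r2 <- simulate_reference(small_cfg(rng_seed = 11))
  expect_identical(as.matrix(r1$expr$values), as.matrix(r2$expr$values))

  c_ <- simulate_cohort(small_cfg(rng_seed = 12))
  expect_false(identical(as.matrix(a$datasets[[1]]$expr$values),
                         as.matrix(c_$datasets[[1]]$expr$values)))
})

test_that("the cohort covers the full design with valid containers", {
  sim <- default_cohort()
  expect_length(sim$datasets, 16L)
  meta <- data.frame(
    genotype = vapply(sim$datasets, function(d) d$genotype, ""),
    tp = vapply(sim$datasets, function(d) d$timepoint_h, 0L))
  expect_equal(unname(table(meta$genotype)), c(8L, 8L), ignore_attr = TRUE)
  expect_equal(sort(unique(meta$tp)), c(0L, 12L, 24L, 72L))
  for (id in c("WT_12h_r1", "KO_0h_r2")) {
    ds <- sim$datasets[[id]]
    expect_identical(ds$expr$unit, "raw")
    expect_false(anyDuplicated(row_ids(ds)) > 0)
    expect_true(all(sim$weights[[id]]$weight >= 0 &
                      sim$weights[[id]]$weight <= 1))
    # weights sum to one within each spot
    sums <- tapply(sim$weights[[id]]$weight, sim$weights[[id]]$spot_id, sum)
    expect_equal(unname(range(sums)), c(1, 1), tolerance = 1e-12)
  }
})

test_that("simulated datasets serialize losslessly through the MTX triplet", {
  sim <- simulate_cohort(small_cfg(rng_seed = 13))
  ds <- sim$datasets[["WT_12h_r1"]]
  dir <- withr::local_tempdir()
  paths <- write_mtx_dataset(ds, dir)
  back <- read_mtx_dataset(paths[["matrix"]], paths[["genes"]],
                           paths[["spots"]], paths[["coords"]],
                           genotype = ds$genotype,
                           timepoint_h = ds$timepoint_h)
  expect_equal(as.matrix(back$expr$values), as.matrix(ds$expr$values))
  expect_equal(back$coords, ds$coords)
})

test_that("the reactive niche carries the planted label combination and decays in KO", {
  sim <- default_cohort()
  truth <- sim$truth
  reactive <- c("WT_12h_r1", "WT_12h_r2", "WT_24h_r1", "WT_24h_r2",
                "KO_12h_r1", "KO_12h_r2", "KO_24h_r1", "KO_24h_r2")
  for (id in reactive) {
    niche <- truth$niche_spots[[id]]
    expect_gt(length(niche), 100)
    labs <- truth$labels[[id]]
    combos <- vapply(unclass(labs)[niche], function(l)
      setequal(l, c("Vas-1", "Astro-2", "Micro-2")), TRUE)
    expect_true(all(combos))
  }
  expect_lt(length(truth$niche_spots[["KO_24h_r1"]]),
            0.5 * length(truth$niche_spots[["WT_24h_r1"]]))
  expect_length(truth$niche_spots[["WT_0h_r1"]], 0L)
})

test_that("turning off the marker effect removes signature recovery (null control)", {
  ref <- simulate_reference(small_cfg(rng_seed = 14, marker_effect = 1))
  # without an effect no gene passes the marker filters: each type keeps
  # its single best gene, with a warning per type
  suppressWarnings(
    sigs <- derive_signatures(lognormalize(ref$expr), ref$cell_labels))
  hits <- vapply(names(ref$markers), function(t)
    sum(ref$markers[[t]] %in% sigs[[t]]), 0)
  # 20 markers among 600 genes: chance-level overlap in a 50-gene signature
  expect_lt(mean(hits), 5)
})

test_that("turning off the niche effect leaves no detectable module (null control)", {
  sim <- simulate_cohort(small_cfg(rng_seed = 15, niche_effect = 1))
  ds <- sim$datasets[["WT_12h_r1"]]
  cm <- coloc_matrix(ds, sim$truth$module_genes, coloc_params())
  expect_warning(mod <- detect_colocm(cm), "empty module")
  expect_length(mod, 0L)
})

test_that("without the knockout decay the genotypes are exchangeable at 24 h", {
  sim <- simulate_cohort(small_cfg(rng_seed = 16, ko_decay_24h = 1))
  n_wt <- length(sim$truth$niche_spots[["WT_24h_r1"]])
  n_ko <- length(sim$truth$niche_spots[["KO_24h_r1"]])
  expect_equal(n_ko / n_wt, 1, tolerance = 0.15)
  # niche-spot module counts from the two genotypes are indistinguishable
  wt <- sim$datasets[["WT_24h_r1"]]
  ko <- sim$datasets[["KO_24h_r1"]]
  mwt <- Matrix::rowSums(wt$expr$values[sim$truth$niche_spots[["WT_24h_r1"]],
                                        sim$truth$module_genes])
  mko <- Matrix::rowSums(ko$expr$values[sim$truth$niche_spots[["KO_24h_r1"]],
                                        sim$truth$module_genes])
  expect_gt(stats::wilcox.test(mwt, mko)$p.value, 0.01)
})

test_that("configuration invariants are validated", {
  expect_error(sim_config(grid_width = 10L), "must equal")
  expect_error(sim_config(niche_radius = 40), "too large")
  expect_error(sim_config(n_genes = 100L), "at least")
})
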