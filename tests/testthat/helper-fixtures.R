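# Shared fixtures and independent oracles.

# iid negative-binomial spatial dataset on a wxh grid
random_dataset <- function(seed, n_spots = 200, n_genes = 20, mu = 5,
                           size = 2, genotype = "WT", timepoint_h = 0L,
                           replicate_id = "r1", dataset_id = NULL,
                           gene_prefix = "g") {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_spots * n_genes, mu = mu, size = size),
                   nrow = n_spots)
  ids <- sprintf("s%05d", seq_len(n_spots))
  genes <- sprintf("%s%03d", gene_prefix, seq_len(n_genes))
  expr <- expression_matrix(counts, row_ids = ids, gene_ids = genes,
                            unit = "raw")
  coords <- data.frame(spot_id = ids,
                       x = (seq_len(n_spots) - 1L) %% 100L,
                       y = (seq_len(n_spots) - 1L) %/% 100L)
  spatial_dataset(expr, coords, genotype = genotype,
                  timepoint_h = timepoint_h, replicate_id = replicate_id,
                  dataset_id = dataset_id)
}

# brute-force co-localization oracle: full sort + explicit set arithmetic,
# independent of the package's indicator-matrix path
brute_top_set <- function(ds, gene, params) {
  v <- if (params$use_raw || ds$expr$unit != "raw") {
    ds$expr
  } else {
    lognormalize(ds$expr)
  }
  x <- as.numeric(v$values[, gene])
  ids <- row_ids(ds)
  tab <- data.frame(id = ids, x = x, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$x, tab$id, method = "radix"), ]
  k <- max(1L, floor(params$top_fraction * nrow(tab)))
  tab$id[seq_len(k)]
}

brute_coloc_matrix <- function(ds, genes, params) {
  n <- length(genes)
  min_ov <- if (!is.null(params$min_overlap_fraction)) {
    floor(params$min_overlap_fraction * nrow(ds$expr$values))
  } else {
    params$min_overlap
  }
  sets <- lapply(genes, brute_top_set, ds = ds, params = params)
  S <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      S[i, j] <- if (ov < min_ov) 0 else ov / length(union(sets[[i]], sets[[j]]))
    }
  }
  S
}

# percentile-cap score oracle: sorts the sums and interpolates by hand
score_oracle <- function(lognorm_mat, genes, q = 0.99) {
  present <- intersect(genes, colnames(lognorm_mat))
  s <- rowSums(lognorm_mat[, present, drop = FALSE])
  srt <- sort(s)
  n <- length(srt)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  x <- srt[lo] + (h - lo) * (srt[min(lo + 1, n)] - srt[lo])
  if (x <= 0) rep(0, n) else pmin(s / x, 1)
}

# a dataset whose top-k sets are fully controlled: target spots get distinct
# high counts of the focal gene; a balance gene equalizes library sizes so
# log-normalized ranking coincides with the construction
constructed_pair_dataset <- function(n_spots, setA, setB, seed = 1) {
  set.seed(seed)
  counts <- matrix(0L, nrow = n_spots, ncol = 3)
  counts[setA, 1] <- 100L
  counts[setB, 2] <- 100L
  counts[, 3] <- 300L - counts[, 1] - counts[, 2]
  ids <- sprintf("s%05d", seq_len(n_spots))
  expr <- expression_matrix(counts, row_ids = ids,
                            gene_ids = c("geneA", "geneB", "balance"),
                            unit = "raw")
  coords <- data.frame(spot_id = ids, x = seq_len(n_spots), y = 0)
  spatial_dataset(expr, coords)
}

# memoised default synthetic cohort (shared by simulator and acceptance tests)
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 1L) {
  key <- paste0("seed", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(sim_config(rng_seed = seed))
  }
  .cohort_cache[[key]]
}

planted_catalog <- function(sim) {
  lr_catalog(c(sim$truth$planted_lrs$ligand, sim$truth$null_lrs$ligand),
             c(sim$truth$planted_lrs$receptor, sim$truth$null_lrs$receptor))
}

# Cell x gene matrix with exact detected-gene counts and mitochondrial
# fractions: each cell detects the mt- gene plus (d - 1) nuclear genes, with
# the totals arranged so the mt fraction is hit exactly.
qc_fixture <- function(detected, mt_fraction, n_genes = 1100) {
  stopifnot(length(detected) == length(mt_fraction))
  counts <- matrix(0L, nrow = length(detected), ncol = n_genes)
  genes <- c("mt-Nd1", sprintf("g%04d", seq_len(n_genes - 1)))
  for (i in seq_along(detected)) {
    d <- detected[i]
    f <- mt_fraction[i]
    if (f == 0) {
      counts[i, seq(2, d + 1)] <- 1L
    } else {
      # smallest total T with f*T integer and enough nuclear mass for
      # (d - 1) detected nuclear genes, so the fraction is hit exactly
      T <- ceiling((d - 1) / (1 - f))
      while (abs(f * T - round(f * T)) > 1e-9) T <- T + 1
      m <- round(f * T)
      nuc <- T - m
      counts[i, 1] <- m
      counts[i, seq(3, d)] <- 1L
      counts[i, 2] <- nuc - (d - 2)
    }
  }
  stopifnot(all(rowSums(counts > 0) == detected))
  expression_matrix(counts, row_ids = sprintf("c%d", seq_along(detected)),
                    gene_ids = genes, unit = "raw")
}
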