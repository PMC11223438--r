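#' Permutation-null parameters for LR activity
#'
#' @param n_random_pairs random gene pairs in the null (default 10,000,
#'   minimum 100).
#' @param alpha significance level for the activity binarization
#'   (default 0.05): a pair is active when activity exceeds `-log2(alpha)`.
#' @param rng_seed root seed; each dataset draws its null pairs from a
#'   deterministic substream derived from this seed and the dataset index
#'   (see Details).
#' @details The per-dataset seed is
#'   `(rng_seed * 7919 + dataset_index) mod (2^31 - 1)`, so cohort-scale
#'   results are reproducible bit-for-bit while datasets remain
#'   independent. Null pairs are drawn once per dataset and shared across
#'   all LR pairs evaluated on it.
#' @return A list of class `NullParams`.
#' @export
null_params <- function(n_random_pairs = 10000L, alpha = 0.05,
                        rng_seed = 1L) {
  stopifnot(n_random_pairs >= 100, alpha > 0, alpha < 1)
  structure(list(n_random_pairs = as.integer(n_random_pairs),
                 alpha = alpha, rng_seed = as.integer(rng_seed)),
            class = "NullParams")
}

#' Internal: per-dataset derived seed
#' @noRd
.dataset_seed <- function(rng_seed, dataset_index) {
  as.integer((as.double(rng_seed) * 7919 + dataset_index) %% (2^31 - 1))
}

#' Internal: draw distinct-gene null pairs (indices into a gene universe)
#' @noRd
.draw_null_pairs <- function(n_genes, n_pairs, seed) {
  if (n_genes < 2) stop("gene universe must hold at least 2 genes")
  set.seed(seed)
  g1 <- sample.int(n_genes, n_pairs, replace = TRUE)
  g2 <- sample.int(n_genes, n_pairs, replace = TRUE)
  clash <- g1 == g2
  while (any(clash)) {
    g2[clash] <- sample.int(n_genes, sum(clash), replace = TRUE)
    clash <- g1 == g2
  }
  cbind(g1, g2)
}

#' Ligand-receptor activity on one dataset
#'
#' The observed statistic is the co-localization score of the ligand and
#' receptor top-expression spot sets. Its null distribution is formed by
#' the co-localization scores of `n_random_pairs` random distinct-gene
#' pairs drawn (seeded) from the genes detected in at least one spot of the
#' dataset. `freq` is the fraction of null scores greater than or equal to
#' the observed score, floored at `1/n_random_pairs` so that the activity
#' `-log2(freq)` stays finite; a pair is "active" when its activity
#' strictly exceeds `-log2(alpha)`.
#'
#' @param ds a `SpatialDataset`.
#' @param pairs an `LRCatalog` (or data.frame with `ligand`, `receptor`).
#' @param params a [coloc_params()] object.
#' @param null a [null_params()] object.
#' @param dataset_index integer used in the per-dataset seed derivation
#'   (default 1; [lr_activity_cohort()] passes each dataset's position).
#' @return A data.frame of class `LRActivityTable` with one row per pair:
#'   `ligand`, `receptor`, `dataset_id`, `genotype`, `timepoint_h`,
#'   `score`, `freq`, `activity`, `active`. Pairs with a gene undetected in
#'   the dataset get `NA` score/freq/activity and `active = FALSE`.
#' @export
lr_activity <- function(ds, pairs, params = coloc_params(),
                        null = null_params(), dataset_index = 1L) {
  stopifnot(inherits(ds, "SpatialDataset"))
  pairs <- as.data.frame(pairs)
  detected <- gene_ids(ds)[Matrix::colSums(ds$expr$values > 0) > 0]
  if (length(detected) < 2) stop("gene universe must hold at least 2 genes")

  n <- nrow(ds$expr$values)
  k <- .top_k(params, n)
  min_ov <- .resolve_min_overlap(params, n)
  seed <- .dataset_seed(null$rng_seed, dataset_index)
  null_idx <- .draw_null_pairs(length(detected), null$n_random_pairs, seed)

  need <- union(detected[unique(as.vector(null_idx))],
                intersect(unique(c(pairs$ligand, pairs$receptor)), detected))
  ind <- .topset_indicator(ds, need, params)
  inter <- as.matrix(Matrix::crossprod(ind))
  pair_score <- function(a, b) {
    ov <- inter[a, b]
    if (ov < min_ov) 0 else ov / (2 * k - ov)
  }
  null_scores <- inter[cbind(detected[null_idx[, 1]], detected[null_idx[, 2]])]
  null_scores <- ifelse(null_scores < min_ov, 0,
                        null_scores / (2 * k - null_scores))

  score <- freq <- activity <- rep(NA_real_, nrow(pairs))
  ok <- pairs$ligand %in% detected & pairs$receptor %in% detected
  if (any(!ok)) {
    warning(sprintf("%d pair(s) with undetected genes; activity undefined",
                    sum(!ok)))
  }
  for (i in which(ok)) {
    s <- pair_score(pairs$ligand[i], pairs$receptor[i])
    f <- max(mean(null_scores >= s), 1 / null$n_random_pairs)
    score[i] <- s
    freq[i] <- f
    activity[i] <- -log2(f)
  }
  out <- data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
                    dataset_id = ds$dataset_id, genotype = ds$genotype,
                    timepoint_h = ds$timepoint_h, score = score, freq = freq,
                    activity = activity,
                    active = !is.na(activity) & activity > -log2(null$alpha),
                    stringsAsFactors = FALSE)
  class(out) <- c("LRActivityTable", "data.frame")
  out
}

#' Ligand-receptor activity across a cohort
#'
#' Runs [lr_activity()] on every dataset, deriving each dataset's null-pair
#' seed from its position in the cohort, and row-binds the results.
#'
#' @param cohort list of `SpatialDataset`s.
#' @param pairs an `LRCatalog`.
#' @param params,null see [lr_activity()].
#' @return An `LRActivityTable` covering all datasets.
#' @export
lr_activity_cohort <- function(cohort, pairs, params = coloc_params(),
                               null = null_params()) {
  tabs <- lapply(seq_along(cohort), function(i) {
    lr_activity(cohort[[i]], pairs, params, null, dataset_index = i)
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("LRActivityTable", "data.frame")
  out
}

#' Internal: exact one-sided rank-sum p-value by enumeration
#'
#' Exact permutation p-value for the Wilcoxon rank-sum statistic of
#' `x` versus `y` (H1: x tends larger), valid under heavy ties (the
#' binarized activities are 0/1). Enumerates all group assignments when
#' feasible, otherwise falls back to the normal approximation.
#' @noRd
.exact_ranksum_p <- function(x, y, max_enum = 50000) {
  nx <- length(x)
  z <- c(x, y)
  r <- rank(z)
  obs <- sum(r[seq_len(nx)])
  if (choose(length(z), nx) <= max_enum) {
    combos <- utils::combn(length(z), nx)
    stats_all <- colSums(matrix(r[combos], nrow = nx))
    mean(stats_all >= obs)
  } else {
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
  }
}

#' Responsive LR pairs within a genotype
#'
#' For each LR pair, activities from the genotype's 12- and 24-hour
#' datasets form Set1 and those from the 0- and 72-hour datasets Set2. Both
#' are binarized (1 when activity exceeds `-log2(alpha)`, else 0) and
#' compared by a one-sided rank-sum test (exact permutation p-value, since
#' each set holds only a few heavily tied values). A pair is responsive
#' when Set1 ranks higher with p < 0.05.
#'
#' @param table an `LRActivityTable` covering all four timepoints for the
#'   genotype.
#' @param genotype `"WT"` or `"KO"`.
#' @param null a [null_params()] object (supplies `alpha`).
#' @param p_cutoff responsiveness cutoff (default 0.05, strict).
#' @return A data.frame with one row per pair: `ligand`, `receptor`,
#'   `genotype`, `p_value`, `responsive`. Pairs with any undefined activity
#'   are dropped.
#' @export
responsive_lrs <- function(table, genotype = c("WT", "KO"),
                           null = null_params(), p_cutoff = 0.05) {
  genotype <- match.arg(genotype)
  tab <- table[table$genotype == genotype & !is.na(table$activity), ]
  if (!all(c(0L, 12L, 24L, 72L) %in% tab$timepoint_h)) {
    stop(sprintf("genotype %s does not cover all four timepoints", genotype))
  }
  cut <- -log2(null$alpha)
  tab$bin <- as.integer(tab$activity > cut)
  key <- paste(tab$ligand, tab$receptor, sep = "\r")
  res <- lapply(split(tab, key), function(d) {
    set1 <- d$bin[d$timepoint_h %in% c(12L, 24L)]
    set2 <- d$bin[d$timepoint_h %in% c(0L, 72L)]
    if (length(set1) == 0 || length(set2) == 0) return(NULL)
    p <- .exact_ranksum_p(set1, set2)
    data.frame(ligand = d$ligand[1], receptor = d$receptor[1],
               genotype = genotype, p_value = p,
               responsive = mean(set1) > mean(set2) && p < p_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$ligand, out$receptor, method = "radix"), , drop = FALSE]
}

#' Per-spot ligand-receptor co-expression flags
#'
#' A spot carries an LR pair when both the ligand and the receptor have a
#' raw count above zero in that spot.
#'
#' @param ds a `SpatialDataset` with `unit = "raw"`.
#' @param ligand,receptor gene symbols.
#' @return Named logical vector over spots. If either gene is absent from
#'   the matrix, all-FALSE with a warning.
#' @export
lr_spot_flags <- function(ds, ligand, receptor) {
  stopifnot(inherits(ds, "SpatialDataset"))
  if (ds$expr$unit != "raw") stop("lr_spot_flags requires unit = 'raw'")
  ids <- row_ids(ds)
  if (!ligand %in% gene_ids(ds) || !receptor %in% gene_ids(ds)) {
    warning("ligand or receptor absent from the matrix; all-FALSE flags")
    return(stats::setNames(rep(FALSE, length(ids)), ids))
  }
  v <- ds$expr$values
  stats::setNames(as.numeric(v[, ligand]) > 0 & as.numeric(v[, receptor]) > 0,
                  ids)
}
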