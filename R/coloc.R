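#' Co-localization scoring parameters
#'
#' The co-localization statistic compares the top-expression spot sets of
#' two genes. Each gene's set holds the `floor(top_fraction * N_spots)`
#' spots with highest expression (at least 1), ties broken deterministically
#' by (expression descending, spot id ascending). The pair score is the
#' Jaccard index of the two sets, floored to 0 when the overlap is below
#' `min_overlap` spots.
#'
#' @param top_fraction fraction of spots in each gene's top set
#'   (default 0.05).
#' @param min_overlap absolute overlap floor in spots (default 50, the
#'   published value calibrated to ~20k-spot chips). For small datasets a
#'   relative floor can be given instead via `min_overlap_fraction`, in
#'   which case `min_overlap = floor(min_overlap_fraction * N_spots)` is
#'   derived per dataset.
#' @param min_overlap_fraction optional relative overlap floor; overrides
#'   `min_overlap` when set.
#' @param use_raw rank spots on raw counts instead of log-normalized values
#'   (default FALSE; log-normalized ranking is consistent with every other
#'   score in the pipeline).
#' @return A list of class `ColocParams`.
#' @export
coloc_params <- function(top_fraction = 0.05, min_overlap = 50L,
                         min_overlap_fraction = NULL, use_raw = FALSE) {
  stopifnot(top_fraction > 0, top_fraction < 1, min_overlap >= 0)
  if (!is.null(min_overlap_fraction)) {
    stopifnot(min_overlap_fraction >= 0, min_overlap_fraction < 1)
  }
  structure(list(top_fraction = top_fraction,
                 min_overlap = as.integer(min_overlap),
                 min_overlap_fraction = min_overlap_fraction,
                 use_raw = use_raw),
            class = "ColocParams")
}

#' Internal: resolve the per-dataset overlap floor
#' @noRd
.resolve_min_overlap <- function(params, n_spots) {
  if (!is.null(params$min_overlap_fraction)) {
    as.integer(floor(params$min_overlap_fraction * n_spots))
  } else {
    params$min_overlap
  }
}

#' Internal: ranking values for top-set extraction
#' @noRd
.ranking_values <- function(ds, params) {
  if (params$use_raw || ds$expr$unit != "raw") {
    ds$expr
  } else {
    lognormalize(ds$expr)
  }
}

#' Internal: top-set size k
#' @noRd
.top_k <- function(params, n_spots) {
  max(1L, as.integer(floor(params$top_fraction * n_spots)))
}

#' Top-expression spot set of a gene
#'
#' @param ds a `SpatialDataset`.
#' @param gene gene symbol (exact match).
#' @param params a [coloc_params()] object.
#' @return Character vector of spot ids (the top set, in rank order).
#' @export
top_spots <- function(ds, gene, params = coloc_params()) {
  stopifnot(inherits(ds, "SpatialDataset"))
  if (!gene %in% gene_ids(ds)) stop(sprintf("gene '%s' not present", gene))
  vals <- .ranking_values(ds, params)
  x <- as.numeric(vals$values[, gene])
  ids <- row_ids(ds)
  k <- .top_k(params, length(ids))
  ord <- order(-x, rank(ids), method = "radix")
  ids[ord[seq_len(k)]]
}

#' Internal: sparse indicator of top sets for many genes at once
#'
#' Returns an n_spots x n_genes 0/1 sparse matrix whose columns mark each
#' gene's top-k spot set (same tie rule as [top_spots()]). Computing all
#' sets in one pass makes cohort-scale scoring cheap.
#' @noRd
.topset_indicator <- function(ds, genes, params) {
  vals <- .ranking_values(ds, params)
  ids <- row_ids(ds)
  n <- length(ids)
  k <- .top_k(params, n)
  v <- vals$values[, genes, drop = FALSE]
  idr <- rank(ids)  # integer tie key: same order as the spot ids themselves
  idx <- matrix(0L, nrow = k, ncol = length(genes))
  for (j in seq_along(genes)) {
    x <- as.numeric(v[, j])
    ord <- order(-x, idr, method = "radix")
    idx[, j] <- ord[seq_len(k)]
  }
  Matrix::sparseMatrix(i = as.vector(idx),
                       j = rep(seq_along(genes), each = k), x = 1,
                       dims = c(n, length(genes)),
                       dimnames = list(ids, genes))
}

#' Internal: pairwise scores from a top-set indicator
#' @noRd
.scores_from_indicator <- function(ind, k, min_overlap) {
  inter <- as.matrix(Matrix::crossprod(ind))
  s <- inter / (2 * k - inter)
  s[inter < min_overlap] <- 0
  s
}

#' Co-localization score of a gene pair
#'
#' With `A` and `B` the two genes' top-expression spot sets: returns 0 when
#' `|A intersect B| < min_overlap`, else the Jaccard index
#' `|A intersect B| / |A union B|`.
#'
#' @param ds a `SpatialDataset`.
#' @param geneA,geneB gene symbols.
#' @param params a [coloc_params()] object.
#' @return A number in `[0, 1]`.
#' @export
coloc_score <- function(ds, geneA, geneB, params = coloc_params()) {
  a <- top_spots(ds, geneA, params)
  b <- top_spots(ds, geneB, params)
  n_ab <- length(intersect(a, b))
  if (n_ab < .resolve_min_overlap(params, nrow(ds$expr$values))) return(0)
  n_ab / length(union(a, b))
}

#' All-pairs co-localization score matrix
#'
#' Computes every pairwise score among `genes` on one dataset, with each
#' gene's top set extracted once. The matrix is symmetric with entries in
#' `[0, 1]`; the diagonal is 1 whenever the top-set size reaches the
#' overlap floor.
#'
#' @param ds a `SpatialDataset`.
#' @param genes character vector (at least 2 genes, all present).
#' @param params a [coloc_params()] object.
#' @return An object of class `ColocMatrix`: a list with `S` (the score
#'   matrix with gene dimnames), `genes`, `params`, and `dataset_id`.
#' @export
coloc_matrix <- function(ds, genes, params = coloc_params()) {
  stopifnot(inherits(ds, "SpatialDataset"))
  genes <- as.character(genes)
  if (length(genes) < 2) stop("coloc_matrix needs at least 2 genes")
  absent <- setdiff(genes, gene_ids(ds))
  if (length(absent)) {
    stop(sprintf("genes not present: %s", paste(absent, collapse = ", ")))
  }
  n <- nrow(ds$expr$values)
  k <- .top_k(params, n)
  ind <- .topset_indicator(ds, genes, params)
  S <- .scores_from_indicator(ind, k, .resolve_min_overlap(params, n))
  structure(list(S = S, genes = genes, params = params,
                 dataset_id = ds$dataset_id),
            class = "ColocMatrix")
}

#' @export
print.ColocMatrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  cat(sprintf("ColocMatrix '%s': %d genes, %.1f%% nonzero pairs, max %.3f\n",
              x$dataset_id, length(x$genes),
              100 * mean(off > 0), if (length(off)) max(off) else NA))
  invisible(x)
}

#' Export a co-localization matrix in long form
#' @param cm a `ColocMatrix`.
#' @param path TSV path, header `geneA  geneB  score  dataset_id`.
#' @return `path`, invisibly.
#' @export
write_coloc_matrix <- function(cm, path) {
  idx <- which(upper.tri(cm$S, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(geneA = cm$genes[idx[, 1]], geneB = cm$genes[idx[, 2]],
                    score = cm$S[idx], dataset_id = cm$dataset_id)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect the co-localization gene module (Co-locM)
#'
#' Hierarchical clustering on the distance `1 - S`. The dendrogram is cut at
#' the merge height that maximizes the size of the largest cluster whose
#' mean intra-cluster score (off-diagonal mean) is at least
#' `mean_score_floor`; among equal-sized qualifying clusters at the optimal
#' height, the one containing the lexicographically smallest gene wins (so
#' the result is invariant to gene input order). The winning cluster is
#' returned when it reaches `min_module_size`, otherwise an empty module
#' with a warning.
#'
#' @param cm a `ColocMatrix`.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param min_module_size minimum genes in a reported module (default 5).
#' @param mean_score_floor minimum mean intra-cluster score (default 0.2).
#' @return Character vector of module genes (sorted; possibly empty).
#' @export
detect_colocm <- function(cm, linkage = "average", min_module_size = 5L,
                          mean_score_floor = 0.2) {
  stopifnot(inherits(cm, "ColocMatrix"))
  ord <- order(cm$genes, method = "radix")
  S <- cm$S[ord, ord]
  genes <- cm$genes[ord]
  n <- length(genes)
  hc <- stats::hclust(stats::as.dist(1 - S), method = linkage)
  heights <- sort(unique(c(0, hc$height)))
  best_genes <- character()
  best_size <- 0L
  for (h in heights) {
    cl <- stats::cutree(hc, h = h)
    for (id in unique(cl)) {
      members <- which(cl == id)
      m <- length(members)
      if (m < 2 || m <= best_size) next
      sub <- S[members, members]
      mean_score <- mean(sub[upper.tri(sub)])
      if (mean_score >= mean_score_floor) {
        best_size <- m
        best_genes <- genes[members]
      }
    }
  }
  if (best_size < min_module_size) {
    warning("no qualifying cluster; empty module")
    return(character())
  }
  sort(best_genes)
}

#' Module score of a gene module across spots
#'
#' Identical contract to [signature_score()], applied to the spots of a
#' spatial dataset: summed log-normalized expression over the module genes,
#' normalized by the 99th percentile and capped at 1.
#'
#' @param ds a `SpatialDataset` (raw data are log-normalized internally).
#' @param module_genes character vector of module genes.
#' @param cap_quantile percentile normalizer (default 0.99).
#' @return A `ScoreVector` data.frame (`row_id`, `score`).
#' @export
module_score <- function(ds, module_genes, cap_quantile = 0.99) {
  stopifnot(inherits(ds, "SpatialDataset"))
  ln <- if (ds$expr$unit == "raw") lognormalize(ds$expr) else ds$expr
  signature_score(ln, module_genes, cap_quantile = cap_quantile,
                  signature_name = "Co-locM")
}
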