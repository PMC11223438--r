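#' QC parameters for cell-level count matrices
#'
#' Single-pass quality filter on detected-gene counts and mitochondrial
#' fraction. A cell is kept when it detects at least `min_genes` genes, at
#' most `max_gene_fraction_of_top * N_express` genes (N_express being the
#' detected-gene count of the most gene-rich cell, computed before any
#' removal), and has a mitochondrial count fraction not exceeding
#' `max_percent_mt`. The mitochondrial fraction is on the [0, 1] scale
#' (0.2 = 20%); mitochondrial genes are identified by symbol prefix,
#' `"mt-"` by mouse convention.
#'
#' @param min_genes detected-gene floor (default 400).
#' @param max_gene_fraction_of_top ceiling as a fraction of N_express
#'   (default 0.9); removal uses strict "more than".
#' @param max_percent_mt mitochondrial-fraction ceiling (default 0.2);
#'   removal uses strict "larger than".
#' @param mt_prefix gene-symbol prefix marking mitochondrial genes.
#' @return A list of class `QCParams`.
#' @export
qc_params <- function(min_genes = 400L, max_gene_fraction_of_top = 0.9,
                      max_percent_mt = 0.2, mt_prefix = "mt-") {
  stopifnot(min_genes >= 0,
            max_gene_fraction_of_top > 0, max_gene_fraction_of_top <= 1,
            max_percent_mt >= 0, max_percent_mt <= 1)
  structure(list(min_genes = as.integer(min_genes),
                 max_gene_fraction_of_top = max_gene_fraction_of_top,
                 max_percent_mt = max_percent_mt,
                 mt_prefix = mt_prefix),
            class = "QCParams")
}

#' Quality-filter a raw count matrix
#'
#' @param expr an `ExpressionMatrix` with `unit = "raw"`, rows = cells.
#' @param params a [qc_params()] object.
#' @param n_express optional externally supplied N_express reference (the
#'   detected-gene count of the most gene-rich cell). By default it is
#'   computed from `expr` itself before filtering; supplying it allows
#'   filtering a subset of cells consistently with its parent matrix.
#' @return A list with elements `expr` (the filtered matrix; values of
#'   surviving cells are untouched) and `report`, a data.frame with one row
#'   per input cell: `cell_id`, `detected_genes`, `mt_fraction`, `kept`, and
#'   `rule_violated` (the first violated rule among `"min_genes"`,
#'   `"max_genes"`, `"percent_mt"`, or `""`).
#' @export
qc_filter <- function(expr, params = qc_params(), n_express = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$unit != "raw") stop("qc_filter requires unit = 'raw'")
  v <- expr$values
  detected <- Matrix::rowSums(v > 0)
  total <- Matrix::rowSums(v)
  mt_genes <- startsWith(gene_ids(expr), params$mt_prefix)
  mt_counts <- if (any(mt_genes)) {
    Matrix::rowSums(v[, mt_genes, drop = FALSE])
  } else {
    rep(0, nrow(v))
  }
  mt_fraction <- ifelse(total > 0, mt_counts / total, 0)
  if (is.null(n_express)) n_express <- max(detected)
  ceiling_genes <- params$max_gene_fraction_of_top * n_express

  rule <- rep("", nrow(v))
  rule[detected < params$min_genes] <- "min_genes"
  rule[rule == "" & detected > ceiling_genes] <- "max_genes"
  rule[rule == "" & mt_fraction > params$max_percent_mt] <- "percent_mt"
  kept <- rule == ""

  report <- data.frame(cell_id = row_ids(expr),
                       detected_genes = as.integer(detected),
                       mt_fraction = as.numeric(mt_fraction),
                       kept = kept, rule_violated = rule,
                       stringsAsFactors = FALSE)
  if (!any(kept)) warning("qc_filter removed all cells")
  out <- expression_matrix(v[kept, , drop = FALSE],
                           row_ids = row_ids(expr)[kept],
                           gene_ids = gene_ids(expr), unit = "raw")
  list(expr = out, report = report)
}

#' Log-normalize a raw count matrix
#'
#' Per-cell depth normalization followed by a log transform:
#' `value' = ln(1 + scale_factor * c / C)` with `C` the cell's total counts.
#' Cells with zero total counts map to all-zero rows.
#'
#' @param expr an `ExpressionMatrix` with `unit = "raw"`.
#' @param scale_factor library-size scale factor (default 10,000).
#' @return An `ExpressionMatrix` with `unit = "lognorm"`.
#' @export
lognormalize <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$unit != "raw") stop("lognormalize requires unit = 'raw'")
  v <- expr$values
  if (nrow(v) == 0) {
    return(expression_matrix(v, character(), gene_ids(expr),
                             unit = "lognorm"))
  }
  total <- Matrix::rowSums(v)
  inv <- ifelse(total > 0, scale_factor / total, 0)
  out <- Matrix::Diagonal(x = inv) %*% v
  out@x <- log1p(out@x)
  out <- methods::as(out, "CsparseMatrix")
  expression_matrix(out, row_ids = row_ids(expr), gene_ids = gene_ids(expr),
                    unit = "lognorm")
}
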