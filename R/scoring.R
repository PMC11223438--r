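#' Derive cell-type signatures from a labelled reference
#'
#' Transparent mean-difference ranking: for each cell type, genes detected
#' in at least `min_detect_fraction` of the type's cells, elevated by at
#' least `min_diff` mean log-normalized units over the other cells, and
#' significant in a Welch t-test at `sig_p` are ranked by the mean
#' difference, and the top `n_genes_per_type` are taken as the signature
#' (fewer when fewer genes qualify). The effect-size and significance
#' floors mirror the standard log-fold-change threshold and test of
#' single-cell marker detection; without them, sampling noise pads the
#' signature with uninformative genes and dilutes the percentile-capped
#' score contrast that the labelling thresholds rely on. A type with no
#' qualifying gene keeps its single best gene, with a warning. Externally
#' curated signature files can be used instead via [read_signatures()].
#'
#' @param ref an `ExpressionMatrix` with `unit = "lognorm"`, rows = cells.
#' @param cell_labels character vector of cell-type labels, one per row of
#'   `ref`; every label must have at least 2 cells.
#' @param n_genes_per_type maximum signature length (default 50).
#' @param min_detect_fraction detection floor within the type (default 0.1).
#' @param min_diff mean log-normalized difference floor (default 0.25).
#' @param sig_p Welch-test p-value ceiling (default 1e-4, i.e. a
#'   Bonferroni-scale cutoff for panels of hundreds of genes).
#' @return A `SignatureTable` with one signature per label.
#' @export
derive_signatures <- function(ref, cell_labels, n_genes_per_type = 50L,
                              min_detect_fraction = 0.1, min_diff = 0.25,
                              sig_p = 1e-4) {
  stopifnot(inherits(ref, "ExpressionMatrix"))
  if (ref$unit != "lognorm") stop("derive_signatures requires unit = 'lognorm'")
  cell_labels <- as.character(cell_labels)
  if (length(cell_labels) != nrow(ref$values)) {
    stop("cell_labels must have one entry per cell")
  }
  counts <- table(cell_labels)
  if (any(counts < 2)) {
    stop(sprintf("cell types with fewer than 2 cells: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  v <- ref$values
  genes <- gene_ids(ref)
  n_all <- nrow(v)
  total_sum <- Matrix::colSums(v)
  total_sq <- Matrix::colSums(v^2)
  sigs <- lapply(sort(names(counts)), function(type) {
    in_type <- cell_labels == type
    n_t <- sum(in_type)
    n_r <- n_all - n_t
    sum_t <- Matrix::colSums(v[in_type, , drop = FALSE])
    sq_t <- Matrix::colSums(v[in_type, , drop = FALSE]^2)
    detect_t <- Matrix::colSums(v[in_type, , drop = FALSE] > 0) / n_t
    mean_t <- sum_t / n_t
    mean_r <- (total_sum - sum_t) / n_r
    var_t <- pmax(0, (sq_t - n_t * mean_t^2) / (n_t - 1))
    var_r <- pmax(0, ((total_sq - sq_t) - n_r * mean_r^2) / (n_r - 1))
    diff <- mean_t - mean_r
    se2 <- var_t / n_t + var_r / n_r
    tstat <- ifelse(se2 > 0, diff / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((var_t / n_t)^2 / (n_t - 1) +
                            (var_r / n_r)^2 / (n_r - 1)),
                 1)
    pval <- stats::pt(tstat, df, lower.tail = FALSE)
    ok <- detect_t >= min_detect_fraction
    ord <- order(-diff, genes, method = "radix")
    ord <- ord[ok[ord]]
    keep <- ord[diff[ord] >= min_diff & pval[ord] < sig_p]
    if (length(keep) == 0) {
      warning(sprintf("no gene qualifies for type '%s'; keeping its best gene",
                      type))
      keep <- ord[1]
    }
    genes[keep[seq_len(min(n_genes_per_type, length(keep)))]]
  })
  names(sigs) <- sort(names(counts))
  signature_table(sigs)
}

#' Percentile-capped signature score
#'
#' For each row (cell or spot), sums the log-normalized expression of the
#' signature genes, divides by the 99th percentile of the summed-value
#' distribution (linear interpolation between order statistics, quantile
#' type 7), and caps at 1. Signature genes absent from the matrix are
#' ignored with a warning; if no signature gene is present this is an error.
#' A degenerate all-zero distribution (99th percentile 0) yields all-zero
#' scores.
#'
#' @param expr an `ExpressionMatrix` with `unit = "lognorm"`.
#' @param genes character vector of signature genes.
#' @param cap_quantile percentile used as the normalizer (default 0.99).
#' @param signature_name label stored on the result.
#' @return A data.frame of class `ScoreVector` with columns `row_id`,
#'   `score` (in `[0, 1]`), and attribute `signature_name`.
#' @export
signature_score <- function(expr, genes, cap_quantile = 0.99,
                            signature_name = "signature") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$unit != "lognorm") stop("signature_score requires unit = 'lognorm'")
  present <- intersect(genes, gene_ids(expr))
  if (length(present) == 0) stop("no signature gene present in the matrix")
  if (length(present) < length(genes)) {
    warning(sprintf("%d of %d signature genes absent; ignored",
                    length(genes) - length(present), length(genes)))
  }
  s <- Matrix::rowSums(expr$values[, present, drop = FALSE])
  x <- stats::quantile(s, cap_quantile, names = FALSE, type = 7)
  score <- if (x <= 0) rep(0, length(s)) else pmin(s / x, 1)
  out <- data.frame(row_id = row_ids(expr), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "signature_name") <- signature_name
  class(out) <- c("ScoreVector", "data.frame")
  out
}

#' Cell-type labelling thresholds
#'
#' Per-type score/weight thresholds for spot labelling; comparisons are
#' strict (label assigned when the value surpasses the threshold). Module
#' labels have their own thresholds: the Co-locM label at module score
#' above 0.5 and the Cdkn1a+Serpina3n+ OligoD label at signature score
#' above 0.4.
#'
#' @param thresholds named numeric vector mapping cell type to threshold;
#'   defaults to Neuron 0.5, Astro-1 0.25, OligoD 0.2, Vas-1 0.2, Astro-2
#'   0.1, OPC 0.05, Micro-1 0.05, Micro-2 0.05.
#' @param colocm_threshold Co-locM module-score threshold (default 0.5).
#' @param cdkn1a_serpina3n_threshold signature-score threshold for the
#'   Cdkn1a+Serpina3n+ OligoD label (default 0.4).
#' @return A list of class `LabelParams`.
#' @export
label_params <- function(thresholds = c("Neuron" = 0.5, "Astro-1" = 0.25,
                                        "OligoD" = 0.2, "Vas-1" = 0.2,
                                        "Astro-2" = 0.1, "OPC" = 0.05,
                                        "Micro-1" = 0.05, "Micro-2" = 0.05),
                         colocm_threshold = 0.5,
                         cdkn1a_serpina3n_threshold = 0.4) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1),
            colocm_threshold > 0, colocm_threshold <= 1,
            cdkn1a_serpina3n_threshold > 0, cdkn1a_serpina3n_threshold <= 1)
  structure(list(thresholds = thresholds,
                 colocm_threshold = colocm_threshold,
                 cdkn1a_serpina3n_threshold = cdkn1a_serpina3n_threshold),
            class = "LabelParams")
}

#' Internal: name under which the reactive oligodendrocyte module label runs
#' @noRd
.cs_oligod <- "Cdkn1a+Serpina3n+ OligoD"

#' Assign cell-type labels to spots
#'
#' A spot receives a cell-type label when its decomposition weight (used
#' for every thresholded type whenever a weight table is supplied, with
#' absent types counting as weight 0) or, without weights, its signature
#' score strictly exceeds the type's threshold. Label sets may be
#' empty or contain multiple labels. The Cdkn1a+Serpina3n+ OligoD label is
#' always score-based, against its own threshold. When `module_genes` is
#' given, spots whose module score exceeds `colocm_threshold` additionally
#' receive the `"Co-locM"` label.
#'
#' @param ds a `SpatialDataset` (raw or lognorm; raw data are
#'   log-normalized internally for scoring).
#' @param weights optional `WeightTable` of per-spot cell-type weights.
#' @param sigs optional `SignatureTable` of cell-type signatures (required
#'   for any thresholded type without weights).
#' @param params a [label_params()] object.
#' @param module_genes optional character vector: the Co-locM gene module.
#' @return A list of class `SpotLabels`: one character vector of labels per
#'   spot, named by spot id (order follows the dataset).
#' @export
assign_labels <- function(ds, weights = NULL, sigs = NULL,
                          params = label_params(), module_genes = NULL) {
  stopifnot(inherits(ds, "SpatialDataset"))
  spots <- row_ids(ds)
  ln <- if (ds$expr$unit == "raw") lognormalize(ds$expr) else ds$expr

  weight_types <- character()
  wmat <- NULL
  if (!is.null(weights)) {
    weights <- as.data.frame(weights)
    weight_types <- unique(weights$cell_type)
    wmat <- matrix(0, nrow = length(spots), ncol = length(weight_types),
                   dimnames = list(spots, weight_types))
    keep <- weights$spot_id %in% spots
    wmat[cbind(weights$spot_id[keep], weights$cell_type[keep])] <-
      weights$weight[keep]
  }

  types <- names(params$thresholds)
  vals <- matrix(0, nrow = length(spots), ncol = length(types),
                 dimnames = list(spots, types))
  for (type in types) {
    if (!is.null(weights)) {
      # decomposition semantics: a type absent from the table has weight 0
      if (type %in% weight_types) vals[, type] <- wmat[, type]
    } else if (!is.null(sigs) && type %in% names(sigs)) {
      vals[, type] <- signature_score(ln, sigs[[type]],
                                      signature_name = type)$score
    } else {
      stop(sprintf("cell type '%s' has neither weights nor a signature", type))
    }
  }
  exceeds <- sweep(vals, 2, params$thresholds[types], ">")
  labels <- lapply(seq_along(spots), function(i) types[exceeds[i, ]])

  if (!is.null(sigs) && .cs_oligod %in% names(sigs)) {
    cs <- signature_score(ln, sigs[[.cs_oligod]], signature_name = .cs_oligod)
    hit <- cs$score > params$cdkn1a_serpina3n_threshold
    labels <- mapply(function(l, h) if (h) c(l, .cs_oligod) else l,
                     labels, hit, SIMPLIFY = FALSE)
  }
  if (!is.null(module_genes)) {
    ms <- module_score(ds, module_genes)
    hit <- ms$score > params$colocm_threshold
    labels <- mapply(function(l, h) if (h) c(l, "Co-locM") else l,
                     labels, hit, SIMPLIFY = FALSE)
  }
  names(labels) <- spots
  class(labels) <- "SpotLabels"
  labels
}

#' @export
print.SpotLabels <- function(x, ...) {
  n <- lengths(unclass(x))
  cat(sprintf("SpotLabels: %d spots (%d unlabelled, max %d labels/spot)\n",
              length(x), sum(n == 0), max(n)))
  invisible(x)
}
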