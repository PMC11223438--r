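#' Construct an expression matrix
#'
#' The package's core container: a sparse nonnegative matrix with rows as
#' cells or spots and columns as genes, tagged with the unit of its values.
#' Raw matrices hold UMI-style integer counts; \code{lognorm} matrices hold
#' log-normalized values (see [lognormalize()]); \code{rpm} is reserved for
#' reads-per-million pseudo-bulk style scaling.
#'
#' @param values matrix-like, coercible to [Matrix::sparseMatrix()]; rows are
#'   cells/spots, columns genes. Must be nonnegative.
#' @param row_ids character vector of unique cell/spot identifiers. Defaults
#'   to `rownames(values)`.
#' @param gene_ids character vector of unique gene symbols (case-sensitive;
#'   matching everywhere in the package is exact-string). Defaults to
#'   `colnames(values)`.
#' @param unit one of `"raw"`, `"lognorm"`, `"rpm"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (dgCMatrix with dimnames), and `unit`.
#' @export
expression_matrix <- function(values, row_ids = rownames(values),
                              gene_ids = colnames(values),
                              unit = c("raw", "lognorm", "rpm")) {
  unit <- match.arg(unit)
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(row_ids) || is.null(gene_ids)) {
    stop("row_ids and gene_ids are required (or provide dimnames)")
  }
  row_ids <- as.character(row_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(row_ids) || ncol(values) != length(gene_ids)) {
    stop("dimensions of values do not match row_ids/gene_ids")
  }
  if (anyDuplicated(row_ids)) stop("duplicate row_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (length(values@x) && min(values@x) < 0) stop("negative values not allowed")
  if (unit == "raw" && length(values@x) &&
      any(abs(values@x - round(values@x)) > 1e-8)) {
    stop("unit 'raw' requires integer counts")
  }
  dimnames(values) <- list(row_ids, gene_ids)
  structure(list(values = values, unit = unit), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d x %d (%s), %.1f%% nonzero\n",
              nrow(x$values), ncol(x$values), x$unit,
              100 * length(x$values@x) / max(1, prod(dim(x$values)))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Row (cell/spot) identifiers of an expression matrix
#' @param x an `ExpressionMatrix` or `SpatialDataset`.
#' @return character vector.
#' @export
row_ids <- function(x) {
  if (inherits(x, "SpatialDataset")) x <- x$expr
  rownames(x$values)
}

#' Gene symbols of an expression matrix
#' @param x an `ExpressionMatrix` or `SpatialDataset`.
#' @return character vector.
#' @export
gene_ids <- function(x) {
  if (inherits(x, "SpatialDataset")) x <- x$expr
  colnames(x$values)
}

#' Construct a spatial dataset
#'
#' Bundles a spot-by-gene expression matrix with planar spot coordinates and
#' the cohort metadata used throughout the pipeline (genotype, time after
#' challenge, replicate). Coordinates are opaque planar reals; downstream
#' statistics use only spot identity, never distances.
#'
#' @param expr an [expression_matrix()] whose rows are spots.
#' @param coords data.frame with columns `spot_id`, `x`, `y` covering every
#'   spot in `expr` exactly once.
#' @param genotype `"WT"` or `"KO"`.
#' @param timepoint_h integer hours after challenge: 0, 12, 24 or 72.
#' @param replicate_id free-form replicate label.
#' @param dataset_id identifier; defaults to
#'   `"<genotype>_<timepoint_h>h_<replicate_id>"`.
#' @return An object of class `SpatialDataset`.
#' @export
spatial_dataset <- function(expr, coords, genotype = c("WT", "KO"),
                            timepoint_h = 0L, replicate_id = "r1",
                            dataset_id = NULL) {
  genotype <- match.arg(genotype)
  timepoint_h <- as.integer(timepoint_h)
  if (!timepoint_h %in% c(0L, 12L, 24L, 72L)) {
    stop("timepoint_h must be one of 0, 12, 24, 72")
  }
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (nrow(expr$values) < 1) stop("a SpatialDataset needs at least one spot")
  coords <- as.data.frame(coords)
  if (!all(c("spot_id", "x", "y") %in% names(coords))) {
    stop("coords must have columns spot_id, x, y")
  }
  coords$spot_id <- as.character(coords$spot_id)
  if (anyDuplicated(coords$spot_id)) stop("duplicate spot_id in coords")
  ids <- row_ids(expr)
  if (!all(ids %in% coords$spot_id)) {
    stop("every spot in expr must have exactly one coordinate pair")
  }
  coords <- coords[match(ids, coords$spot_id), c("spot_id", "x", "y")]
  rownames(coords) <- NULL
  if (is.null(dataset_id)) {
    dataset_id <- sprintf("%s_%dh_%s", genotype, timepoint_h, replicate_id)
  }
  structure(list(expr = expr, coords = coords, genotype = genotype,
                 timepoint_h = timepoint_h, replicate_id = replicate_id,
                 dataset_id = dataset_id),
            class = "SpatialDataset")
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat(sprintf("SpatialDataset '%s': %d spots x %d genes (%s, %s, %d h)\n",
              x$dataset_id, nrow(x$expr$values), ncol(x$expr$values),
              x$expr$unit, x$genotype, x$timepoint_h))
  invisible(x)
}

#' Construct a signature table
#'
#' A named mapping cell type / module name -> ordered gene list. Gene-module
#' signatures (e.g. the Co-locM module) live here alongside cell-type
#' signatures.
#'
#' @param signatures named list of character vectors; each non-empty, with
#'   unique genes within a signature.
#' @return An object of class `SignatureTable` (the validated named list).
#' @export
signature_table <- function(signatures) {
  if (is.null(names(signatures)) || any(names(signatures) == "")) {
    stop("signatures must be a named list")
  }
  for (nm in names(signatures)) {
    g <- signatures[[nm]]
    if (length(g) == 0) stop(sprintf("signature '%s' is empty", nm))
    if (anyDuplicated(g)) stop(sprintf("duplicate gene in signature '%s'", nm))
    signatures[[nm]] <- as.character(g)
  }
  structure(signatures, class = "SignatureTable")
}

#' @export
print.SignatureTable <- function(x, ...) {
  cat(sprintf("SignatureTable: %d signatures (%s)\n", length(x),
              paste(sprintf("%s:%d", names(x), lengths(x)), collapse = ", ")))
  invisible(x)
}

#' Construct a ligand-receptor catalog
#'
#' @param ligand,receptor character vectors of gene symbols (recycled to the
#'   same length). Self-pairs (ligand == receptor) and duplicate pairs are
#'   rejected, mirroring curated mouse LR catalogs such as CellTalkDB.
#' @return An object of class `LRCatalog`: a data.frame with columns
#'   `ligand`, `receptor`.
#' @export
lr_catalog <- function(ligand, receptor) {
  pairs <- data.frame(ligand = as.character(ligand),
                      receptor = as.character(receptor),
                      stringsAsFactors = FALSE)
  if (any(pairs$ligand == pairs$receptor)) {
    stop("self-pairs (ligand == receptor) are not allowed")
  }
  if (anyDuplicated(pairs)) stop("duplicate ligand-receptor pairs")
  class(pairs) <- c("LRCatalog", "data.frame")
  pairs
}

#' Construct a per-spot cell-type weight table
#'
#' Holds per-spot decomposition weights (e.g. normalized RCTD weights),
#' treated as an input: the decomposition fit itself is out of scope.
#'
#' @param spot_id,cell_type,weight equal-length vectors; weights in `[0, 1]`.
#' @return An object of class `WeightTable`: a data.frame with columns
#'   `spot_id`, `cell_type`, `weight`.
#' @export
weight_table <- function(spot_id, cell_type, weight) {
  w <- data.frame(spot_id = as.character(spot_id),
                  cell_type = as.character(cell_type),
                  weight = as.numeric(weight), stringsAsFactors = FALSE)
  if (any(w$weight < 0 | w$weight > 1)) stop("weights must lie in [0, 1]")
  if (anyDuplicated(w[c("spot_id", "cell_type")])) {
    stop("duplicate (spot_id, cell_type) entries")
  }
  class(w) <- c("WeightTable", "data.frame")
  w
}
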