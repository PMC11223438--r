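#' Read a spatial dataset from a MatrixMarket triplet
#'
#' Reads the on-disk layout used for spot-level expression: a MatrixMarket
#' coordinate file (spots x genes), a gene list (one symbol per line), a spot
#' list (one id per line), and a tab-separated coordinate table with header
#' `spot_id  x  y`. Row and column order is taken from the id files. The MTX
#' file is 1-based per the MatrixMarket standard.
#'
#' @param matrix_path path to the `.mtx` coordinate file.
#' @param genes_path path to the gene list (one symbol per line).
#' @param spots_path path to the spot-id list (one id per line).
#' @param coords_path path to the coordinate TSV.
#' @param genotype,timepoint_h,replicate_id,dataset_id dataset metadata, see
#'   [spatial_dataset()].
#' @return A `SpatialDataset` with `unit = "raw"`.
#' @export
read_mtx_dataset <- function(matrix_path, genes_path, spots_path, coords_path,
                             genotype = "WT", timepoint_h = 0L,
                             replicate_id = "r1", dataset_id = NULL) {
  for (p in c(matrix_path, genes_path, spots_path, coords_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  spots <- readLines(spots_path)
  spots <- spots[nzchar(spots)]
  if (nrow(m) != length(spots)) {
    stop(sprintf("MTX declares %d rows but spot file lists %d ids",
                 nrow(m), length(spots)))
  }
  if (ncol(m) != length(genes)) {
    stop(sprintf("MTX declares %d columns but gene file lists %d symbols",
                 ncol(m), length(genes)))
  }
  coords <- utils::read.delim(coords_path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(coords))) {
    stop("coords file must have header: spot_id, x, y")
  }
  missing <- setdiff(spots, as.character(coords$spot_id))
  if (length(missing)) {
    stop(sprintf("spots missing coordinates: %s%s",
                 paste(utils::head(missing, 3), collapse = ", "),
                 if (length(missing) > 3) ", ..." else ""))
  }
  expr <- expression_matrix(m, row_ids = spots, gene_ids = genes, unit = "raw")
  spatial_dataset(expr, coords, genotype = genotype,
                  timepoint_h = timepoint_h, replicate_id = replicate_id,
                  dataset_id = dataset_id)
}

#' Write a spatial dataset as a MatrixMarket triplet
#'
#' Inverse of [read_mtx_dataset()]; lossless for integer counts up to the
#' ordering of nonzero entries.
#'
#' @param ds a `SpatialDataset`.
#' @param out_dir output directory, created if needed.
#' @param prefix file-name prefix (default the dataset id).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_mtx_dataset <- function(ds, out_dir, prefix = ds$dataset_id) {
  stopifnot(inherits(ds, "SpatialDataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(out_dir, paste0(prefix, ".mtx")),
             genes = file.path(out_dir, paste0(prefix, ".genes.tsv")),
             spots = file.path(out_dir, paste0(prefix, ".spots.tsv")),
             coords = file.path(out_dir, paste0(prefix, ".coords.tsv")))
  Matrix::writeMM(ds$expr$values, paths[["matrix"]])
  writeLines(gene_ids(ds), paths[["genes"]])
  writeLines(row_ids(ds), paths[["spots"]])
  utils::write.table(ds$coords, paths[["coords"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a signature table from TSV
#'
#' Expects a tab-separated file with header `signature  gene`, one gene per
#' line; gene order within a signature is preserved.
#'
#' @param path file path.
#' @return A `SignatureTable`.
#' @export
read_signatures <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("signature", "gene") %in% names(tab))) {
    stop("signature file must have header: signature, gene")
  }
  sigs <- split(as.character(tab$gene), factor(tab$signature,
                                               levels = unique(tab$signature)))
  signature_table(sigs)
}

#' Write a signature table to TSV
#' @param sigs a `SignatureTable`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  tab <- data.frame(signature = rep(names(sigs), lengths(sigs)),
                    gene = unlist(sigs, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor catalog from TSV
#'
#' Expects header `ligand  receptor`, one pair per line, emulating catalog
#' exports such as the mouse CellTalkDB pair list.
#'
#' @param path file path.
#' @return An `LRCatalog`.
#' @export
read_lr_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab))) {
    stop("LR file must have header: ligand, receptor")
  }
  lr_catalog(tab$ligand, tab$receptor)
}

#' Read a per-spot cell-type weight table from TSV
#'
#' Expects header `spot_id  cell_type  weight`.
#'
#' @param path file path.
#' @return A `WeightTable`.
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "cell_type", "weight") %in% names(tab))) {
    stop("weights file must have header: spot_id, cell_type, weight")
  }
  weight_table(tab$spot_id, tab$cell_type, tab$weight)
}

#' Write a per-spot weight table to TSV
#' @param w a `WeightTable`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  utils::write.table(as.data.frame(w), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
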