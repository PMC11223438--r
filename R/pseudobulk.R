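#' Collapse a spatial dataset to a pseudo-bulk RPM profile
#'
#' Sums raw counts over spots per gene and rescales to reads per million:
#' `rpm(g) = 1e6 * sum_spots c(., g) / total counts`. A dataset with zero
#' total counts yields an all-zero profile with a warning.
#'
#' @param ds a `SpatialDataset` with `unit = "raw"`.
#' @return An object of class `PseudoBulkProfile`: a list with `rpm` (named
#'   numeric vector over genes), `total_counts`, and `source` metadata.
#' @export
to_pseudobulk <- function(ds) {
  stopifnot(inherits(ds, "SpatialDataset"))
  if (ds$expr$unit != "raw") stop("to_pseudobulk requires unit = 'raw'")
  sums <- Matrix::colSums(ds$expr$values)
  total <- sum(sums)
  if (total == 0) {
    warning("dataset has zero total counts; all-zero profile")
    rpm <- sums
  } else {
    rpm <- 1e6 * sums / total
  }
  structure(list(rpm = stats::setNames(as.numeric(rpm), gene_ids(ds)),
                 total_counts = total,
                 source = list(dataset_id = ds$dataset_id,
                               genotype = ds$genotype,
                               timepoint_h = ds$timepoint_h,
                               replicate_id = ds$replicate_id)),
            class = "PseudoBulkProfile")
}

#' @export
print.PseudoBulkProfile <- function(x, ...) {
  cat(sprintf("PseudoBulkProfile '%s': %d genes, %.0f counts\n",
              x$source$dataset_id, length(x$rpm), x$total_counts))
  invisible(x)
}

#' Pseudo-bulk differential expression between two groups
#'
#' Per-gene fold change with pseudocount,
#' `FC = (mean_A + eps) / (mean_B + eps)`, and a two-tailed Welch t-test on
#' RPM values when both groups have more than two samples. With two or fewer
#' samples in either group the p-value is undefined (reported `NA`) and the
#' p-criterion is waived: calling is fold-change-only.
#'
#' @param groupA,groupB lists of `PseudoBulkProfile`s; gene universes are
#'   aligned on their intersection (with a warning if they differ).
#' @param fc_cutoff fold-change cutoff for up-regulation (default 2, strict).
#' @param p_cutoff p-value cutoff (default 0.01, strict).
#' @param eps RPM pseudocount guarding against division by zero (default 1).
#' @return A data.frame of class `DEGResult` with columns `gene`,
#'   `mean_rpm_A`, `mean_rpm_B`, `fold_change`, `p_value`, `up_regulated`.
#' @export
pseudobulk_deg <- function(groupA, groupB, fc_cutoff = 2, p_cutoff = 0.01,
                           eps = 1) {
  if (inherits(groupA, "PseudoBulkProfile")) groupA <- list(groupA)
  if (inherits(groupB, "PseudoBulkProfile")) groupB <- list(groupB)
  if (length(groupA) == 0 || length(groupB) == 0) {
    stop("both groups must be non-empty")
  }
  universes <- lapply(c(groupA, groupB), function(p) names(p$rpm))
  genes <- Reduce(intersect, universes)
  if (!all(lengths(universes) == length(genes))) {
    warning("gene universes differ between profiles; aligned on intersection")
  }
  if (length(genes) == 0) stop("no shared genes between profiles")
  A <- vapply(groupA, function(p) p$rpm[genes], numeric(length(genes)))
  B <- vapply(groupB, function(p) p$rpm[genes], numeric(length(genes)))
  A <- matrix(A, nrow = length(genes))
  B <- matrix(B, nrow = length(genes))
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  fc <- (mean_a + eps) / (mean_b + eps)
  run_test <- ncol(A) > 2 && ncol(B) > 2
  pv <- rep(NA_real_, length(genes))
  if (run_test) {
    pv <- vapply(seq_along(genes), function(i) {
      a <- A[i, ]; b <- B[i, ]
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        return(if (mean_a[i] == mean_b[i]) 1 else 0)
      }
      stats::t.test(a, b)$p.value
    }, 0)
  }
  up <- fc > fc_cutoff & (if (run_test) pv < p_cutoff else TRUE)
  out <- data.frame(gene = genes, mean_rpm_A = mean_a, mean_rpm_B = mean_b,
                    fold_change = fc, p_value = pv, up_regulated = up,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("DEGResult", "data.frame")
  out
}

#' Candidate gene set: reactive-phase up-regulation per genotype
#'
#' For each genotype separately, compares pseudo-bulk profiles of the 12-
#' and 24-hour datasets against the 0- and 72-hour datasets and takes the
#' up-regulated genes; the two genotype-level sets are merged (union) into
#' the candidate set screened for co-localization modules.
#'
#' @param cohort list of `SpatialDataset`s covering both genotypes and all
#'   four timepoints.
#' @param fc_cutoff,p_cutoff passed to [pseudobulk_deg()].
#' @return Character vector of candidate genes (sorted).
#' @export
candidate_gene_set <- function(cohort, fc_cutoff = 2, p_cutoff = 0.01) {
  meta <- data.frame(genotype = vapply(cohort, function(d) d$genotype, ""),
                     timepoint = vapply(cohort, function(d) d$timepoint_h, 0L))
  up <- lapply(c("WT", "KO"), function(gt) {
    reactive <- which(meta$genotype == gt & meta$timepoint %in% c(12L, 24L))
    baseline <- which(meta$genotype == gt & meta$timepoint %in% c(0L, 72L))
    if (length(reactive) == 0 || length(baseline) == 0 ||
        !all(c(12L, 24L) %in% meta$timepoint[reactive]) ||
        !all(c(0L, 72L) %in% meta$timepoint[baseline])) {
      stop(sprintf("genotype %s is missing a timepoint group", gt))
    }
    deg <- pseudobulk_deg(lapply(cohort[reactive], to_pseudobulk),
                          lapply(cohort[baseline], to_pseudobulk),
                          fc_cutoff = fc_cutoff, p_cutoff = p_cutoff)
    deg$gene[deg$up_regulated]
  })
  sort(unique(unlist(up)))
}
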