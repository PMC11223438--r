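#' Internal: canonical string form of a label combination
#' @noRd
.combo_key <- function(labels) {
  paste(sort(unique(labels)), collapse = ";")
}

#' Group spots by their exact label combination
#'
#' Spots with identical label sets (exact-set semantics: a
#' `{Astro-2, Vas-1}` spot is not in the `{Astro-2, Micro-2, Vas-1}` group)
#' share a group. Unlabelled spots form their own group with the empty
#' combination `""`, which downstream statistics exclude.
#'
#' @param labels a `SpotLabels` object (see [assign_labels()]) or a named
#'   list of per-spot label vectors.
#' @return An object of class `SpotGroupTable`: a list mapping
#'   combination key (sorted labels joined by `";"`) to a character vector
#'   of member spot ids.
#' @export
group_spots <- function(labels) {
  keys <- vapply(unclass(labels), .combo_key, "")
  groups <- split(names(labels), keys)
  groups <- groups[order(names(groups), method = "radix")]
  class(groups) <- "SpotGroupTable"
  groups
}

#' @export
print.SpotGroupTable <- function(x, ...) {
  cat(sprintf("SpotGroupTable: %d groups over %d spots\n",
              sum(names(x) != ""), sum(lengths(x)[names(x) != ""])))
  invisible(x)
}

#' Label combinations recurring across datasets
#'
#' Keeps the combinations whose spot count strictly exceeds `min_spots` in
#' every one of the supplied per-dataset group tables (the published
#' analysis screens the eight 12/24-hour datasets with a floor of 100
#' spots). The empty combination is never retained.
#'
#' @param tables named list of `SpotGroupTable`s, one per dataset.
#' @param min_spots per-dataset spot floor (default 100, strict
#'   greater-than).
#' @param n_expected if not `NULL` (default 8), error unless exactly this
#'   many tables are supplied.
#' @return Character vector of recurrent combination keys (sorted).
#' @export
recurrent_groups <- function(tables, min_spots = 100L, n_expected = 8L) {
  if (!is.null(n_expected) && length(tables) != n_expected) {
    stop(sprintf("expected %d datasets, got %d", n_expected, length(tables)))
  }
  combos <- Reduce(intersect, lapply(tables, names))
  combos <- setdiff(combos, "")
  keep <- vapply(combos, function(cb) {
    all(vapply(tables, function(tab) length(tab[[cb]]) > min_spots, TRUE))
  }, TRUE)
  sort(combos[keep])
}

#' Per-group flagged-spot proportions
#'
#' For each (combination, dataset), the proportion of the group's member
#' spots that carry a flag (e.g. the Co-locM label or an LR co-expression
#' flag). Empty groups are excluded.
#'
#' @param tables named list of `SpotGroupTable`s, one per dataset.
#' @param flags named list (parallel to `tables`) of named logical vectors
#'   over spots.
#' @param combinations combinations to report (default: all non-empty
#'   combinations appearing in any dataset).
#' @return A data.frame of class `GroupStatTable` with columns
#'   `combination`, `dataset_id`, `n_spots`, `n_flagged`, `proportion`.
#' @export
group_flag_proportions <- function(tables, flags, combinations = NULL) {
  stopifnot(length(tables) == length(flags))
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  if (is.null(combinations)) {
    combinations <- setdiff(sort(unique(unlist(lapply(tables, names)))), "")
  }
  rows <- list()
  for (d in names(tables)) {
    tab <- tables[[d]]
    fl <- flags[[d]]
    for (cb in combinations) {
      members <- tab[[cb]]
      if (is.null(members) || length(members) == 0) next
      nf <- sum(fl[members], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        combination = cb, dataset_id = d, n_spots = length(members),
        n_flagged = nf, proportion = nf / length(members),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("GroupStatTable", "data.frame")
  out
}

#' Paired one-tailed comparison against a reference spot group
#'
#' For each comparator combination, a one-tailed paired t-test of H1:
#' reference proportion > comparator proportion, paired by dataset.
#' Degenerate cases (zero variance of the paired differences) are reported
#' as p = 0 or p = 1 by the sign of the common difference (p = 0.5 when
#' the differences are identically zero) with `degenerate = TRUE` rather
#' than `NaN`.
#'
#' @param stats a `GroupStatTable` (see [group_flag_proportions()]).
#' @param reference reference combination key (default the perivascular
#'   `"Astro-2;Micro-2;Vas-1"` niche).
#' @param comparators combination keys to test against (default: all other
#'   combinations present).
#' @return A data.frame with columns `reference`, `comparator`, `n_pairs`,
#'   `p_value`, `degenerate`.
#' @export
compare_reference_group <- function(stats, reference = "Astro-2;Micro-2;Vas-1",
                                    comparators = NULL) {
  stats <- as.data.frame(stats)
  if (!reference %in% stats$combination) {
    stop(sprintf("reference combination '%s' not in stats", reference))
  }
  if (is.null(comparators)) {
    comparators <- setdiff(unique(stats$combination), reference)
  }
  ref <- stats[stats$combination == reference, ]
  rows <- lapply(comparators, function(cb) {
    cmp <- stats[stats$combination == cb, ]
    shared <- intersect(ref$dataset_id, cmp$dataset_id)
    if (length(shared) < 2) {
      stop(sprintf("fewer than 2 paired datasets for '%s'", cb))
    }
    d <- ref$proportion[match(shared, ref$dataset_id)] -
      cmp$proportion[match(shared, cmp$dataset_id)]
    degenerate <- stats::sd(d) <= 1e-12
    p <- if (degenerate) {
      if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    } else {
      stats::t.test(d, alternative = "greater")$p.value
    }
    data.frame(reference = reference, comparator = cb,
               n_pairs = length(shared), p_value = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
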