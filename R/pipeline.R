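#' Pipeline configuration
#'
#' Bundles all stage parameters for [run_pipeline()]. Exactly one input
#' mode must be chosen: a simulation configuration (`sim`), or a cohort
#' manifest (`manifest`) pointing at on-disk MatrixMarket datasets.
#'
#' @param sim a [sim_config()] object, or `NULL` when reading from disk.
#' @param manifest path to a tab-separated cohort manifest with columns
#'   `dataset_id`, `matrix`, `genes`, `spots`, `coords`, `genotype`,
#'   `timepoint_h`, `replicate_id`, and optionally `weights`; or `NULL`
#'   when simulating.
#' @param signatures optional path to a signature TSV (required in
#'   manifest mode; in simulation mode signatures are derived from the
#'   simulated reference).
#' @param lr_catalog optional path to an LR-pair TSV (required in manifest
#'   mode; in simulation mode the planted and null pairs are used).
#' @param reference_dataset_id dataset used for module detection
#'   (default `"WT_12h_r1"`).
#' @param qc,labels,coloc,null parameter objects ([qc_params()],
#'   [label_params()], [coloc_params()], [null_params()]).
#' @param fc_cutoff,p_cutoff pseudo-bulk DEG cutoffs (defaults 2 and 0.01).
#' @param min_group_spots recurrence floor for spot groups (default 100).
#' @param min_module_size,mean_score_floor module-detection knobs, see
#'   [detect_colocm()].
#' @param outdir output directory for tables and `summary.json`.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(sim = sim_config(), manifest = NULL,
                            signatures = NULL, lr_catalog = NULL,
                            reference_dataset_id = "WT_12h_r1",
                            qc = qc_params(), labels = label_params(),
                            coloc = coloc_params(), null = null_params(),
                            fc_cutoff = 2, p_cutoff = 0.01,
                            min_group_spots = 100L,
                            min_module_size = 5L, mean_score_floor = 0.2,
                            outdir = tempfile("nichecoloc_run_")) {
  if (is.null(sim) == is.null(manifest)) {
    stop("provide exactly one of 'sim' or 'manifest'")
  }
  if (!is.null(manifest) && (is.null(signatures) || is.null(lr_catalog))) {
    stop("manifest mode requires 'signatures' and 'lr_catalog' paths")
  }
  structure(list(sim = sim, manifest = manifest, signatures = signatures,
                 lr_catalog = lr_catalog,
                 reference_dataset_id = reference_dataset_id,
                 qc = qc, labels = labels, coloc = coloc, null = null,
                 fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                 min_group_spots = as.integer(min_group_spots),
                 min_module_size = as.integer(min_module_size),
                 mean_score_floor = mean_score_floor,
                 outdir = outdir),
            class = "PipelineConfig")
}

#' Internal: read a cohort from a manifest file
#' @noRd
.read_cohort <- function(manifest) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("dataset_id", "matrix", "genes", "spots", "coords",
            "genotype", "timepoint_h", "replicate_id")
  if (!all(need %in% names(man))) {
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  }
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  datasets <- list()
  weights <- list()
  for (i in seq_len(nrow(man))) {
    ds <- read_mtx_dataset(resolve(man$matrix[i]), resolve(man$genes[i]),
                           resolve(man$spots[i]), resolve(man$coords[i]),
                           genotype = man$genotype[i],
                           timepoint_h = man$timepoint_h[i],
                           replicate_id = man$replicate_id[i],
                           dataset_id = man$dataset_id[i])
    datasets[[man$dataset_id[i]]] <- ds
    if ("weights" %in% names(man) && nzchar(man$weights[i])) {
      weights[[man$dataset_id[i]]] <- read_weights(resolve(man$weights[i]))
    }
  }
  list(datasets = datasets, weights = weights)
}

#' Run the full co-localization pipeline
#'
#' Executes the stages end to end: simulate or ingest the cohort; derive
#' or load signatures; label spots; screen the reactive-phase candidate
#' gene set by pseudo-bulk differential expression; compute the
#' co-localization matrix on the designated reference dataset and extract
#' the Co-locM module; score the module and label Co-locM spots; group
#' spots by label combination, filter to recurrent groups, and compare
#' Co-locM spot proportions against the perivascular reference group;
#' compute permutation-null LR activities across the cohort and call
#' responsive pairs per genotype. Every stage writes its table under
#' `cfg$outdir`, and a deterministic `summary.json` captures the headline
#' results.
#'
#' @param cfg a [pipeline_config()] object.
#' @param quiet suppress progress messages (default FALSE).
#' @return Invisibly, a list with all intermediate results (`cohort`,
#'   `signatures`, `labels`, `candidates`, `coloc`, `module_genes`,
#'   `module_scores`, `groups`, `recurrent`, `group_stats`, `group_tests`,
#'   `lr_table`, `responsive`, `summary`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  ## --- cohort ---------------------------------------------------------
  if (!is.null(cfg$sim)) {
    say("simulating cohort (seed %d)", cfg$sim$rng_seed)
    sim <- simulate_cohort(cfg$sim)
    cohort <- sim$datasets
    weights <- sim$weights
    say("deriving signatures from simulated reference")
    ref <- simulate_reference(cfg$sim)
    qc <- qc_filter(ref$expr, cfg$qc)
    sigs <- derive_signatures(lognormalize(qc$expr),
                              ref$cell_labels[match(row_ids(qc$expr),
                                                    row_ids(ref$expr))])
    catalog <- lr_catalog(c(sim$truth$planted_lrs$ligand,
                            sim$truth$null_lrs$ligand),
                          c(sim$truth$planted_lrs$receptor,
                            sim$truth$null_lrs$receptor))
    utils::write.table(qc$report, file.path(cfg$outdir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    say("reading cohort from %s", cfg$manifest)
    loaded <- .read_cohort(cfg$manifest)
    cohort <- loaded$datasets
    weights <- loaded$weights
    sigs <- read_signatures(cfg$signatures)
    catalog <- read_lr_catalog(cfg$lr_catalog)
  }
  say("cohort: %d datasets, %d genes", length(cohort),
      length(gene_ids(cohort[[1]])))
  write_signatures(sigs, file.path(cfg$outdir, "signatures.tsv"))

  ## --- candidate genes (pseudo-bulk screen) ---------------------------
  say("screening candidate genes by pseudo-bulk DEG")
  candidates <- candidate_gene_set(cohort, cfg$fc_cutoff, cfg$p_cutoff)
  say("candidate set: %d genes", length(candidates))
  writeLines(candidates, file.path(cfg$outdir, "candidate_genes.txt"))

  ## --- co-localization module on the reference dataset ----------------
  if (!cfg$reference_dataset_id %in% names(cohort)) {
    stop(sprintf("reference dataset '%s' not in cohort",
                 cfg$reference_dataset_id))
  }
  ref_ds <- cohort[[cfg$reference_dataset_id]]
  module_genes <- character()
  cm <- NULL
  if (length(candidates) >= 2) {
    say("co-localization matrix on %s (%d genes)",
        cfg$reference_dataset_id, length(candidates))
    cm <- coloc_matrix(ref_ds, candidates, cfg$coloc)
    write_coloc_matrix(cm, file.path(cfg$outdir, "coloc_matrix.tsv"))
    module_genes <- detect_colocm(cm, min_module_size = cfg$min_module_size,
                                  mean_score_floor = cfg$mean_score_floor)
  } else {
    warning("fewer than 2 candidate genes; no module detection")
  }
  say("Co-locM module: %d genes", length(module_genes))
  writeLines(module_genes, file.path(cfg$outdir, "colocm_genes.txt"))

  ## --- labels, module scores, spot groups -----------------------------
  say("labelling spots and scoring the module")
  labels <- list()
  module_scores <- list()
  flags <- list()
  for (id in names(cohort)) {
    labels[[id]] <- assign_labels(cohort[[id]], weights = weights[[id]],
                                  sigs = sigs, params = cfg$labels)
    if (length(module_genes)) {
      ms <- module_score(cohort[[id]], module_genes)
      module_scores[[id]] <- ms
      flags[[id]] <- stats::setNames(ms$score > cfg$labels$colocm_threshold,
                                     ms$row_id)
    } else {
      flags[[id]] <- stats::setNames(rep(FALSE, length(row_ids(cohort[[id]]))),
                                     row_ids(cohort[[id]]))
    }
  }
  label_tab <- do.call(rbind, lapply(names(labels), function(id) {
    data.frame(dataset_id = id, spot_id = names(labels[[id]]),
               labels = vapply(unclass(labels[[id]]), paste,
                               collapse = ";", ""),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(label_tab, file.path(cfg$outdir, "spot_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- lapply(labels, group_spots)
  reactive_ids <- names(cohort)[vapply(cohort, function(d)
    d$timepoint_h %in% c(12L, 24L), TRUE)]
  recurrent <- recurrent_groups(groups[reactive_ids],
                                min_spots = cfg$min_group_spots,
                                n_expected = length(reactive_ids))
  say("%d recurrent spot groups across %d reactive datasets",
      length(recurrent), length(reactive_ids))
  group_tab <- do.call(rbind, lapply(names(groups), function(id) {
    g <- groups[[id]]
    data.frame(dataset_id = id, combination = names(g),
               spot_count = lengths(g), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  utils::write.table(group_tab, file.path(cfg$outdir, "spot_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- niche enrichment ------------------------------------------------
  group_stats <- group_flag_proportions(groups[reactive_ids],
                                        flags[reactive_ids],
                                        combinations = recurrent)
  utils::write.table(group_stats, file.path(cfg$outdir, "group_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reference_combo <- "Astro-2;Micro-2;Vas-1"
  group_tests <- NULL
  top_group <- NA_character_
  if (nrow(group_stats) && length(recurrent)) {
    means <- tapply(group_stats$proportion, group_stats$combination, mean)
    top_group <- names(which.max(means))
    if (reference_combo %in% group_stats$combination &&
        length(recurrent) > 1) {
      group_tests <- compare_reference_group(group_stats, reference_combo)
      utils::write.table(group_tests,
                         file.path(cfg$outdir, "group_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## --- LR activity and responsiveness ---------------------------------
  say("LR activity: %d pairs x %d datasets (null %d pairs)",
      nrow(catalog), length(cohort), cfg$null$n_random_pairs)
  lr_table <- lr_activity_cohort(cohort, catalog, cfg$coloc, cfg$null)
  utils::write.table(lr_table, file.path(cfg$outdir, "lr_activity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  responsive <- do.call(rbind, lapply(c("WT", "KO"), function(gt) {
    responsive_lrs(lr_table, gt, cfg$null)
  }))
  utils::write.table(responsive, file.path(cfg$outdir, "responsive_lrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- summary ---------------------------------------------------------
  resp_by_gt <- lapply(split(responsive, responsive$genotype), function(d) {
    sort(paste(d$ligand[d$responsive], d$receptor[d$responsive], sep = "-"))
  })
  summary <- list(
    n_datasets = length(cohort),
    n_candidate_genes = length(candidates),
    module_genes = module_genes,
    n_recurrent_groups = length(recurrent),
    recurrent_groups = recurrent,
    top_colocm_group = top_group,
    responsive_lrs = resp_by_gt,
    parameters = list(top_fraction = cfg$coloc$top_fraction,
                      min_overlap = cfg$coloc$min_overlap,
                      fc_cutoff = cfg$fc_cutoff, p_cutoff = cfg$p_cutoff,
                      n_random_pairs = cfg$null$n_random_pairs,
                      alpha = cfg$null$alpha,
                      min_group_spots = cfg$min_group_spots))
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  say("done; outputs in %s", cfg$outdir)
  invisible(list(cohort = cohort, signatures = sigs, labels = labels,
                 candidates = candidates, coloc = cm,
                 module_genes = module_genes,
                 module_scores = module_scores, groups = groups,
                 recurrent = recurrent, group_stats = group_stats,
                 group_tests = group_tests, lr_table = lr_table,
                 responsive = responsive, summary = summary))
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads a flat YAML key-value file mirroring the [pipeline_config()]
#' arguments; nested blocks `sim`, `qc`, `coloc`, `lr_null` are passed to
#' their respective constructors (the permutation-null block is named
#' `lr_null` because bare `null` is a YAML literal). Keys not present keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$manifest)) {
    args$sim <- NULL
    args$manifest <- y$manifest
  } else if (!is.null(y$sim)) {
    args$sim <- do.call(sim_config, y$sim)
  }
  for (k in c("signatures", "lr_catalog", "reference_dataset_id",
              "fc_cutoff", "p_cutoff", "min_group_spots",
              "min_module_size", "mean_score_floor", "outdir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$qc)) args$qc <- do.call(qc_params, y$qc)
  if (!is.null(y$coloc)) args$coloc <- do.call(coloc_params, y$coloc)
  if (!is.null(y$lr_null)) args$null <- do.call(null_params, y$lr_null)
  if (!is.null(y$labels)) args$labels <- do.call(label_params, y$labels)
  if (is.null(args$sim) && is.null(args$manifest)) args["sim"] <- list(NULL)
  do.call(pipeline_config, args)
}
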