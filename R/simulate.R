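#' Simulation configuration for the synthetic LPS cohort
#'
#' Defines a fully specified 16-dataset cohort (2 genotypes x 4 timepoints
#' x 2 replicates) of negative-binomial spot counts on a rectangular grid,
#' with planted structure at every level the pipeline measures: cell-type
#' territories, vessel-like loci ringed by reactive astrocyte/microglia
#' labels at 12/24 h (shrinking in the knockout at 24 h), a perivascular
#' gene module whose expression tapers with distance from the vessel
#' centers, globally induced (but spatially diffuse) genes, and planted
#' ligand-receptor pairs whose genes co-occur at the loci.
#'
#' @param rng_seed root seed; every stochastic draw flows from per-dataset
#'   substreams derived from it.
#' @param n_spots_per_dataset spots per dataset (default 5000, laid out on
#'   `grid_width x grid_height`).
#' @param grid_width,grid_height grid extent in spot units (default
#'   100 x 50; must multiply to `n_spots_per_dataset`).
#' @param n_genes gene panel size (default 600).
#' @param n_markers_per_type markers per cell type (default 20).
#' @param module_size planted co-localization module size (default 30).
#' @param n_vessel_loci vessel-like loci per dataset (default 6).
#' @param niche_radius perivascular niche radius in spot units
#'   (default 11).
#' @param vessel_core_radius radius of the Vas-1-dominant center, also the
#'   vessel extent at baseline timepoints (default 3).
#' @param nb_mean_base negative-binomial base mean per gene per spot
#'   (default 1).
#' @param nb_dispersion negative-binomial size parameter (default 10,
#'   i.e. the moderate overdispersion typical of binned pseudo-spot UMI
#'   counts).
#' @param marker_effect fold elevation of a type's markers at mixture
#'   weight 1, relative to their off-type background (default 8).
#' @param marker_low off-type background mean multiplier of marker genes
#'   (default 0.2): markers are lowly but not silently expressed outside
#'   their own population, as real cell-type markers are.
#' @param niche_effect average fold of module genes across the niche at
#'   12/24 h (default 4); the radial profile tapers quadratically from the
#'   locus center (peak fold `1 + 6 * (niche_effect - 1)`) to baseline at
#'   the niche edge, so the disk average equals `niche_effect`.
#' @param lr_niche_effect average in-niche fold of planted LR genes
#'   (default 3, same tapered profile).
#' @param diffuse_effect fold of the spatially diffuse induced genes at
#'   12/24 h, applied uniformly over all spots (default 3).
#' @param n_diffuse_induced number of diffuse induced genes (default 10).
#' @param ko_decay_24h multiplier on the niche area in KO at 24 h
#'   (default 0.3; the effective radius scales by its square root).
#' @param n_planted_lrs number of planted niche-restricted LR pairs
#'   (default 3).
#' @param n_null_lrs number of null LR pairs at base expression
#'   (default 20).
#' @param n_cells_per_type cells per type in the simulated labelled
#'   reference (default 150).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(rng_seed = 1L, n_spots_per_dataset = 5000L,
                       grid_width = 100L, grid_height = 50L,
                       n_genes = 600L, n_markers_per_type = 20L,
                       module_size = 30L, n_vessel_loci = 6L,
                       niche_radius = 11, vessel_core_radius = 3,
                       nb_mean_base = 1, nb_dispersion = 10,
                       marker_effect = 8, marker_low = 0.2, niche_effect = 4,
                       lr_niche_effect = 3, diffuse_effect = 3,
                       n_diffuse_induced = 10L, ko_decay_24h = 0.3,
                       n_planted_lrs = 3L, n_null_lrs = 20L,
                       n_cells_per_type = 150L) {
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_spots_per_dataset = as.integer(n_spots_per_dataset),
              grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              n_genes = as.integer(n_genes),
              n_markers_per_type = as.integer(n_markers_per_type),
              module_size = as.integer(module_size),
              n_vessel_loci = as.integer(n_vessel_loci),
              niche_radius = niche_radius,
              vessel_core_radius = vessel_core_radius,
              nb_mean_base = nb_mean_base, nb_dispersion = nb_dispersion,
              marker_effect = marker_effect, marker_low = marker_low,
              niche_effect = niche_effect,
              lr_niche_effect = lr_niche_effect,
              diffuse_effect = diffuse_effect,
              n_diffuse_induced = as.integer(n_diffuse_induced),
              ko_decay_24h = ko_decay_24h,
              n_planted_lrs = as.integer(n_planted_lrs),
              n_null_lrs = as.integer(n_null_lrs),
              n_cells_per_type = as.integer(n_cells_per_type))
  if (cfg$grid_width * cfg$grid_height != cfg$n_spots_per_dataset) {
    stop("grid_width * grid_height must equal n_spots_per_dataset")
  }
  if (cfg$niche_radius >= min(cfg$grid_width, cfg$grid_height) / 2) {
    stop("niche_radius too large for the grid")
  }
  stopifnot(cfg$module_size >= 1, cfg$n_markers_per_type >= 1,
            cfg$nb_mean_base > 0, cfg$nb_dispersion > 0,
            cfg$ko_decay_24h > 0, cfg$ko_decay_24h <= 1)
  panel_need <- 9L * cfg$n_markers_per_type + cfg$module_size +
    cfg$n_diffuse_induced + 2L * cfg$n_planted_lrs + 2L * cfg$n_null_lrs
  if (cfg$n_genes < panel_need + 10L) {
    stop(sprintf("n_genes must be at least %d for this panel", panel_need + 10L))
  }
  class(cfg) <- "SimConfig"
  cfg
}

#' Internal: the nine simulated cell types
#' @noRd
.sim_cell_types <- function() {
  c("Neuron", "Astro-1", "Astro-2", "Micro-1", "Micro-2",
    "OligoD", "OPC", "Vas-1", .cs_oligod)
}

#' Internal: gene panel with disjoint index ranges per role
#' @noRd
.gene_panel <- function(cfg) {
  types <- .sim_cell_types()
  markers <- lapply(types, function(t) {
    sprintf("%s.mk%02d", gsub("[^A-Za-z0-9]", "", t),
            seq_len(cfg$n_markers_per_type))
  })
  names(markers) <- types
  module <- sprintf("Mod%03d", seq_len(cfg$module_size))
  diffuse <- sprintf("Ind%02d", seq_len(cfg$n_diffuse_induced))
  lr_pairs <- data.frame(
    ligand = sprintf("Lig%02d", seq_len(cfg$n_planted_lrs)),
    receptor = sprintf("Rec%02d", seq_len(cfg$n_planted_lrs)),
    niche_restricted = TRUE, stringsAsFactors = FALSE)
  null_lrs <- data.frame(
    ligand = sprintf("Nlig%02d", seq_len(cfg$n_null_lrs)),
    receptor = sprintf("Nrec%02d", seq_len(cfg$n_null_lrs)),
    niche_restricted = FALSE, stringsAsFactors = FALSE)
  used <- c(unlist(markers, use.names = FALSE), module, diffuse,
            lr_pairs$ligand, lr_pairs$receptor,
            null_lrs$ligand, null_lrs$receptor)
  filler <- sprintf("Gene%04d", seq_len(cfg$n_genes - length(used)))
  list(markers = markers, module = module, diffuse = diffuse,
       lr_pairs = lr_pairs, null_lrs = null_lrs, filler = filler,
       genes = c(used, filler))
}

#' Simulate a labelled single-cell reference
#'
#' Cells of the nine types with each type's markers elevated
#' `marker_effect`-fold; counts are negative-binomial with the configured
#' mean and dispersion at nucleus-scale depth (1.5x the spot base mean).
#' A small fraction of cells is planted at aberrant depth — 3% shallow
#' (0.3x, low-quality nuclei) and 3% deep (4x, doublet-like) — so the
#' detected-gene QC floor and ceiling both have genuine work to do.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with `expr` (raw `ExpressionMatrix`, cells x genes),
#'   `cell_labels` (character vector), and `markers` (the planted marker
#'   lists per type).
#' @export
simulate_reference <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  panel <- .gene_panel(cfg)
  types <- .sim_cell_types()
  n_cells <- cfg$n_cells_per_type * length(types)
  labels <- rep(types, each = cfg$n_cells_per_type)
  mult <- matrix(1, nrow = n_cells, ncol = cfg$n_genes,
                 dimnames = list(NULL, panel$genes))
  mult[, panel$filler] <- 2
  mult[, unlist(panel$markers, use.names = FALSE)] <- cfg$marker_low
  for (t in types) {
    mult[labels == t, panel$markers[[t]]] <- cfg$marker_low * cfg$marker_effect
  }
  set.seed(.dataset_seed(cfg$rng_seed, 0L))
  depth <- sample(c(0.3, 1, 4), n_cells, replace = TRUE,
                  prob = c(0.03, 0.94, 0.03))
  counts <- matrix(stats::rnbinom(n_cells * cfg$n_genes,
                                  mu = 1.5 * cfg$nb_mean_base * depth * mult,
                                  size = cfg$nb_dispersion),
                   nrow = n_cells, ncol = cfg$n_genes)
  expr <- expression_matrix(counts,
                            row_ids = sprintf("cell-%04d", seq_len(n_cells)),
                            gene_ids = panel$genes, unit = "raw")
  list(expr = expr, cell_labels = labels, markers = panel$markers)
}

#' Internal: distance of every grid spot to its nearest locus
#' @noRd
.locus_distance <- function(cfg, loci) {
  x <- rep(seq_len(cfg$grid_width) - 1L, times = cfg$grid_height)
  y <- rep(seq_len(cfg$grid_height) - 1L, each = cfg$grid_width)
  d2 <- outer(x, loci[, 1], "-")^2 + outer(y, loci[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Internal: per-spot cell-type mixture weights for one dataset
#'
#' Background territories are horizontal bands (an oligodendrocyte band
#' with a reactive Cdkn1a+Serpina3n+ patch at 12/24 h, an astrocyte zone,
#' a microglia-tinged zone, and a neuron-dominant remainder). At reactive
#' timepoints, spots within the effective niche radius of a vessel locus
#' are overwritten with the perivascular Vas-1/Astro-2/Micro-2 mixture;
#' at baseline timepoints only the vessel core carries Vas-1. Weights sum
#' to 1 in every spot.
#' @noRd
.spot_weights <- function(cfg, dist, reactive, r_eff) {
  n <- cfg$n_spots_per_dataset
  types <- .sim_cell_types()
  x <- rep(seq_len(cfg$grid_width) - 1L, times = cfg$grid_height)
  y <- rep(seq_len(cfg$grid_height) - 1L, each = cfg$grid_width)
  w <- matrix(0, nrow = n, ncol = length(types),
              dimnames = list(NULL, types))
  set_w <- function(idx, ...) {
    vals <- c(...)
    w[idx, ] <<- 0
    w[cbind(rep(which(idx), length(vals)),
            rep(match(names(vals), types), each = sum(idx)))] <<-
      rep(vals, each = sum(idx))
  }
  oligo <- y < 10
  astro <- y >= 10 & y < 18
  micro <- y >= 18 & y < 24
  neuron <- y >= 24
  set_w(neuron, "Neuron" = 0.7, "Astro-1" = 0.15, "OligoD" = 0.1,
        "Micro-1" = 0.05)
  set_w(micro, "Neuron" = 0.6, "Micro-1" = 0.08, "Astro-1" = 0.12,
        "OligoD" = 0.2)
  set_w(astro, "Astro-1" = 0.35, "Neuron" = 0.4, "Micro-1" = 0.1,
        "OligoD" = 0.15)
  set_w(oligo, "OligoD" = 0.55, "Neuron" = 0.25, "OPC" = 0.1,
        "Astro-1" = 0.1)
  if (reactive) {
    patch <- oligo & x < cfg$grid_width / 2
    set_w(patch, "Cdkn1a+Serpina3n+ OligoD" = 1)
    core <- dist < cfg$vessel_core_radius
    ring <- dist >= cfg$vessel_core_radius & dist < r_eff
    set_w(ring, "Vas-1" = 0.25, "Astro-2" = 0.3, "Micro-2" = 0.2,
          "Neuron" = 0.25)
    set_w(core, "Vas-1" = 0.35, "Astro-2" = 0.3, "Micro-2" = 0.2,
          "Neuron" = 0.15)
  } else {
    vessel <- dist < cfg$vessel_core_radius
    set_w(vessel, "Vas-1" = 0.6, "Neuron" = 0.25, "Astro-1" = 0.15)
  }
  w
}

#' Internal: simulate one spatial dataset of the cohort
#' @noRd
.simulate_dataset <- function(cfg, panel, genotype, timepoint_h,
                              replicate_id, dataset_index) {
  set.seed(.dataset_seed(cfg$rng_seed, dataset_index))
  n <- cfg$n_spots_per_dataset
  ## vessel loci: jittered 3 x 2 template, keeping loci well separated and
  ## inside the grid for any jitter draw
  tx <- round(cfg$grid_width * c(0.17, 0.50, 0.83))
  ty <- round(cfg$grid_height * c(0.28, 0.72))
  template <- cbind(rep(tx, times = 2), rep(ty, each = 3))
  template <- template[seq_len(min(cfg$n_vessel_loci, nrow(template))), ,
                       drop = FALSE]
  extra <- cfg$n_vessel_loci - nrow(template)
  if (extra > 0) {
    template <- rbind(template,
                      cbind(sample.int(cfg$grid_width, extra) - 1L,
                            sample.int(cfg$grid_height, extra) - 1L))
  }
  loci <- template + matrix(sample(-3:3, 2 * nrow(template), replace = TRUE),
                            ncol = 2)
  dist <- .locus_distance(cfg, loci)

  reactive <- timepoint_h %in% c(12L, 24L)
  r_eff <- if (!reactive) 0 else if (genotype == "KO" && timepoint_h == 24L) {
    cfg$niche_radius * sqrt(cfg$ko_decay_24h)
  } else {
    cfg$niche_radius
  }
  w <- .spot_weights(cfg, dist, reactive, r_eff)

  mult <- matrix(1, nrow = n, ncol = cfg$n_genes,
                 dimnames = list(NULL, panel$genes))
  mult[, panel$filler] <- 2  # stable housekeeping-scale background genes
  for (t in colnames(w)) {
    mult[, panel$markers[[t]]] <-
      cfg$marker_low * (1 + (cfg$marker_effect - 1) * w[, t])
  }
  if (reactive) {
    ## quadratic radial taper: disk average of (1-d/R)^2 is 1/6, so the
    ## per-spot fold averages to the configured effect across the niche
    ## while peaking sharply at the vessel center
    taper <- pmax(0, 1 - dist / r_eff)^2
    mult[, panel$module] <- 1 + 6 * (cfg$niche_effect - 1) * taper
    lr_genes <- c(panel$lr_pairs$ligand, panel$lr_pairs$receptor)
    mult[, lr_genes] <- 1 + 6 * (cfg$lr_niche_effect - 1) * taper
    mult[, panel$diffuse] <- cfg$diffuse_effect
  }
  counts <- matrix(stats::rnbinom(n * cfg$n_genes,
                                  mu = cfg$nb_mean_base * mult,
                                  size = cfg$nb_dispersion),
                   nrow = n, ncol = cfg$n_genes)
  spot_ids <- sprintf("s%05d", seq_len(n))
  coords <- data.frame(spot_id = spot_ids,
                       x = rep(seq_len(cfg$grid_width) - 1L,
                               times = cfg$grid_height),
                       y = rep(seq_len(cfg$grid_height) - 1L,
                               each = cfg$grid_width))
  expr <- expression_matrix(counts, row_ids = spot_ids,
                            gene_ids = panel$genes, unit = "raw")
  ds <- spatial_dataset(expr, coords, genotype = genotype,
                        timepoint_h = timepoint_h,
                        replicate_id = replicate_id)
  rownames(w) <- spot_ids
  list(ds = ds, weights = w, niche_spots = spot_ids[dist < r_eff])
}

#' Internal: true label sets from mixture weights and thresholds
#' @noRd
.truth_labels <- function(w, params = label_params()) {
  types <- names(params$thresholds)
  exceeds <- sweep(w[, types, drop = FALSE], 2, params$thresholds[types], ">")
  cs <- w[, .cs_oligod] > params$cdkn1a_serpina3n_threshold
  labels <- lapply(seq_len(nrow(w)), function(i) {
    l <- types[exceeds[i, ]]
    if (cs[i]) c(l, .cs_oligod) else l
  })
  names(labels) <- rownames(w)
  class(labels) <- "SpotLabels"
  labels
}

#' Simulate the 16-dataset synthetic cohort
#'
#' Generates two genotypes (WT, KO) x four timepoints (0, 12, 24, 72 h) x
#' two replicates, each with its own jittered vessel loci and seeded
#' negative-binomial counts, plus per-dataset decomposition-style weight
#' tables (the true mixtures) and a ground-truth record.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with:
#'   \describe{
#'     \item{datasets}{named list of 16 `SpatialDataset`s.}
#'     \item{weights}{named list of `WeightTable`s (true mixtures).}
#'     \item{truth}{ground truth: `module_genes`, `diffuse_genes`,
#'       `candidate_genes` (genes planted to pass the reactive-phase
#'       screen), `null_genes` (genes with no planted induction),
#'       `bystander_genes` (markers of the reactive types, induced through
#'       composition shifts rather than planting), `planted_lrs`,
#'       `null_lrs`, `markers`, per-dataset `labels` and `niche_spots`.}
#'   }
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  panel <- .gene_panel(cfg)
  grid <- expand.grid(replicate_id = c("r1", "r2"),
                      timepoint_h = c(0L, 12L, 24L, 72L),
                      genotype = c("WT", "KO"),
                      stringsAsFactors = FALSE)
  datasets <- list()
  weights <- list()
  labels <- list()
  niche_spots <- list()
  for (i in seq_len(nrow(grid))) {
    sim <- .simulate_dataset(cfg, panel, grid$genotype[i],
                             grid$timepoint_h[i], grid$replicate_id[i],
                             dataset_index = i)
    id <- sim$ds$dataset_id
    datasets[[id]] <- sim$ds
    nz <- which(sim$weights > 0, arr.ind = TRUE)
    weights[[id]] <- weight_table(rownames(sim$weights)[nz[, 1]],
                                  colnames(sim$weights)[nz[, 2]],
                                  sim$weights[nz])
    labels[[id]] <- .truth_labels(sim$weights)
    niche_spots[[id]] <- sim$niche_spots
  }
  reactive_markers <- unlist(panel$markers[c("Vas-1", "Astro-2", "Micro-2",
                                             .cs_oligod)],
                             use.names = FALSE)
  truth <- list(
    module_genes = panel$module,
    diffuse_genes = panel$diffuse,
    candidate_genes = sort(c(panel$module, panel$diffuse)),
    bystander_genes = sort(reactive_markers),
    null_genes = sort(setdiff(panel$genes,
                              c(panel$module, panel$diffuse,
                                reactive_markers,
                                panel$lr_pairs$ligand,
                                panel$lr_pairs$receptor))),
    planted_lrs = panel$lr_pairs,
    null_lrs = panel$null_lrs,
    markers = panel$markers,
    labels = labels,
    niche_spots = niche_spots)
  list(datasets = datasets, weights = weights, truth = truth)
}
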