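# nichecoloc

Spatial co-localization and perivascular niche analysis for spot-based
transcriptomics.

Systemic inflammation (e.g. an LPS challenge) triggers a transient,
spatially organized response in the mouse brain: reactive astrocytes
(Astro-2) and reactive microglia (Micro-2) gather around vascular cells
(Vas-1), and a coherent module of inflammation-response genes is induced in
exactly those perivascular zones. `nichecoloc` implements the analysis
machinery for detecting this structure in spot-based spatial
transcriptomics, for researchers working with binned/pseudo-spot expression
matrices (Stereo-seq, Visium-style data) plus cell-type decomposition
weights:

* **Gene co-localization score** — for genes *A*, *B* with top-5%
  expression spot sets *T(A)*, *T(B)* on a dataset of *N* spots,

  *S(A,B) = |T(A) ∩ T(B)| / |T(A) ∪ T(B)|*, floored to 0 when
  *|T(A) ∩ T(B)| < 50* spots

  (deterministic tie rule; floor and top fraction configurable).
* **Co-locM module detection** — pseudo-bulk screen of reactive-phase
  up-regulation (RPM fold change > 2, Welch p < 0.01; 12/24 h vs 0/72 h
  per genotype, sets merged), then hierarchical clustering of the pairwise
  score matrix (average linkage on 1 − S, largest cluster with mean
  intra-cluster score ≥ 0.2).
* **Percentile-capped signature/module scores** — per-spot sums of
  log-normalized signature expression, normalized by the 99th percentile
  and capped at 1; threshold labelling of spots (strict `>`), including
  the Co-locM label at score > 0.5.
* **Ligand–receptor activity** — a permutation-null tail statistic,
  activity = −log2(freq), where freq is the fraction of 10,000 random
  distinct-gene pairs whose co-localization score reaches the pair's
  observed score; "responsive" pairs are those whose binarized activity is
  higher at 12/24 h than at 0/72 h (exact one-sided rank-sum, p < 0.05).
* **Niche analysis** — spot groups by exact cell-type label combination,
  recurrence filtering (> 100 spots in all eight reactive datasets),
  per-group flagged-spot proportions, and paired one-tailed t-tests
  against the perivascular {Astro-2, Micro-2, Vas-1} reference group.
* **Synthetic cohort with planted truth** — a 16-dataset negative-binomial
  generator (2 genotypes × 4 timepoints × 2 replicates) that plants the
  perivascular niche, a 30-gene co-localized module, diffuse induced
  genes, and niche-restricted ligand–receptor pairs, with a knockout whose
  niche decays at 24 h. Every pipeline stage can be validated against the
  generator's ground truth.

snRNA-seq-style QC (400-gene floor, 0.9 × N_express ceiling,
mitochondrial fraction ≤ 0.2) and scale-factor-10,000 log-normalization
are included for deriving cell-type signatures from a labelled reference.

## Worked example

```r
library(nichecoloc)

sim <- simulate_cohort(sim_config(rng_seed = 1))
ds  <- sim$datasets[["WT_12h_r1"]]
ds
#> SpatialDataset 'WT_12h_r1': 5000 spots x 600 genes (raw, WT, 12 h)

# two planted module genes co-localize; a background gene does not
coloc_score(ds, "Mod001", "Mod002")
#> [1] 0.2315271
coloc_score(ds, "Mod001", "Gene0100")
#> [1] 0

# reactive-phase candidate screen, then module detection on the
# designated reference dataset
cand <- candidate_gene_set(sim$datasets)
length(cand)
#> [1] 40
module <- detect_colocm(coloc_matrix(ds, cand))
head(module, 5)
#> [1] "Mod001" "Mod002" "Mod003" "Mod004" "Mod005"

# permutation-null ligand-receptor activity on one dataset
lr_activity(ds, lr_catalog("Lig01", "Rec01"),
            null = null_params(rng_seed = 1))[
  , c("score", "freq", "activity", "active")]
#>       score   freq activity active
#> 1 0.2077295 0.0033 8.243318   TRUE
```

The first score (0.23) means the two module genes share 94 of their
250-spot top sets (Jaccard 94/406) — both concentrate at the planted
vessel loci —
while the background pair's overlap falls below the 50-spot floor and is
zeroed. The LR activity 8.24 = −log2(0.0033) says only 33 of 10,000 random
gene pairs co-localize as strongly as the planted ligand–receptor pair;
this exceeds −log2(0.05) ≈ 4.32, so the pair is called active on this
dataset.

`run_pipeline(pipeline_config(sim = sim_config(rng_seed = 1)))` executes
the whole analysis (QC → signatures → labels → candidate screen → Co-locM →
module scores → spot groups → group tests → LR activity → responsiveness)
and writes every intermediate table plus a deterministic `summary.json`.

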