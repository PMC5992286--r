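# mlfcg

Multilayer functional connectivity graphs from electrophysiological time
series, and connectome-based classification built on them.

## The problem

Resting-state MEG/EEG source activity couples across brain regions in two
distinct ways: *within* a frequency band (phase locking, co-varying
amplitude envelopes) and *across* bands (the phase of a slow rhythm
modulating the envelope of a fast one). A complete functional description
of N regions under a B-band decomposition is therefore not one
connectivity matrix but a stack of B intra-band and B(B−1)/2
cross-band graphs — 28 layers with the canonical seven bands
δ (0.5–4 Hz), θ (4–8), α₁ (8–10), α₂ (10–13), β₁ (13–20), β₂ (20–30),
γ₁ (30–45 Hz). `mlfcg` builds that stack, filters it down to its
topologically informative core, summarizes it, and turns it into a
classifier — for example to separate patients with mild cognitive
impairment from controls using their connectome alone.

## What it computes

**Connectivity estimators.** For phase series φ_X, φ_Y obtained by
zero-phase 3rd-order Butterworth filtering and the Hilbert transform
(z(t) = A(t)·e^{iφ(t)}):

- PLV = |T⁻¹ Σ_t e^{i(φ_X(t) − φ_Y(t))}|, and its imaginary part
  iPLV = |Im T⁻¹ Σ_t e^{i(φ_X − φ_Y)}|, which ignores zero-lag
  (volume-conduction-like) coupling; for a constant lag Δ, iPLV = |sin Δ|.
- CorrEnv: absolute Pearson correlation of amplitude envelopes, within or
  across bands (non-orthogonalized).
- Phase–amplitude coupling: the envelope A_HF of the fast band is
  band-pass filtered within the slow band and Hilbert-transformed; iPLV
  between its phase and the slow rhythm's phase quantifies how strongly
  the slow phase modulates the fast amplitude.

Each estimate is computed per epoch and averaged across epochs.

**Topological filtering (OMST).** Successive edge-disjoint ("orthogonal")
minimum spanning trees are extracted on distances 1/w and accumulated;
the aggregate maximizing J = GE − Cost is kept, where GE is weighted
global efficiency and Cost the retained fraction of total edge weight.

**Multilayer summaries.** The 28 layers flatten into a (7N × 7N)
supra-adjacency matrix (630 × 630 at N = 90). The multilayer
participation coefficient MPC_i = M/(M−1)·(1 − Σ_λ (k_i[λ]/o_i)²)
scores how evenly node i's retained connections spread over the M
layers; comodulograms tabulate the fraction of OMST-retained connections
per coupling mode.

**Classification.** SVM (RBF kernel) under leave-one-out or stratified
5-fold CV, with every data-dependent step fitted inside the training
fold: the edge route ranks single connections by max-relevance
min-redundancy mutual information (top 15 per fold, 15-of-a-kind
consensus across folds); the tensor route learns a supervised tensor
subspace analysis projection (6 × 6 = 36 bilinear features per graph);
an MPC route classifies the per-node participation profile.

**Synthetic cohorts with known truth.** A generator plants
phase-coupled, phase–amplitude-coupled and shared-envelope edges with
controllable strength, lag and group differences on a 1/f background, so
every stage of the pipeline can be validated against ground truth.

## Worked example

Plant three α₁ phase-coupled edges whose strength rises by 0.5 in
group 2, build per-subject iPLV graphs, and classify with in-fold
feature selection:

```r
library(mlfcg)

edges <- tibble::tibble(
  roi_i = c(1, 3, 5), roi_j = c(2, 4, 6),
  kind = "intra", band_a = "alpha1", band_b = "alpha1",
  strength = 0.2, phase_lag = pi / 2, delta_strength = 0.5)
plan <- coupling_plan(n_rois = 10, edges = edges, seed = 42)
cohort <- generate_cohort(plan, n_subjects_per_group = 8,
                          epochs = 10, epoch_len_s = 4, fs = 250)

md <- dplyr::filter(coupling_modes(), mode == "alpha1")
graphs <- lapply(cohort$recordings, build_sl_fcgs,
                 estimator = "iPLV", modes = md)
graphs[[1]]$alpha1
#> <sl_fcg> iPLV / alpha1 (intra): 10 x 10, mean weight 0.245

X <- edge_feature_matrix(graphs)
y <- factor(vapply(cohort$recordings, function(r) r$group, integer(1)))
cv <- crossvalidate(X, y, scheme = "loocv", route = "edge",
                    k_rank = 5, m_consensus = 5)
cv
#> <cv_result> loocv / edge route
#>   accuracy 1.000, sensitivity 1.000, specificity 1.000
head(cv$consensus_features, 5)
#> # A tibble: 5 × 3
#>   feature     freq mean_rank
#>   <chr>      <int>     <dbl>
#> 1 alpha1|3|4    16      2.75
#> 2 alpha1|1|2    14      1.43
#> 3 alpha1|5|8    11      3.36
#> 4 alpha1|1|4    10      3.5
#> 5 alpha1|5|6    10      3.9
```

Every subject is classified correctly, and the consensus features are
dominated by the three planted edges (1–2, 3–4, 5–6): the biomarker the
classifier found is the structure that was planted. `fcg_edges()`,
`tidy()`, `glance()` and `autoplot()` expose every result as a tibble or
ggplot; `run_pipeline()` chains simulate → connect → OMST → MPC →
comodulogram → classify from a YAML config and writes per-stage CSV/TSV
artifacts.

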