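---
title: "Multilayer functional connectomics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer functional connectomics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlfcg)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, what the
synthetic cohorts emulate (and what they do not), and the numerical and
design choices made where more than one defensible option existed.

## 1. From time series to a multilayer connectome

The object of study is a set of N regional (source-level) time series
recorded in epochs at sampling rate `fs`. Each channel is decomposed by
a filterbank of seven bands — δ (0.5–4 Hz), θ (4–8), α₁ (8–10),
α₂ (10–13), β₁ (13–20), β₂ (20–30), γ₁ (30–45 Hz) — using a zero-phase
(forward–backward) 3rd-order Butterworth filter, and the Hilbert
transform supplies each narrowband signal's instantaneous phase φ(t)
and amplitude envelope A(t).

Coupling is then estimated in all 7 intra-band modes and all 21 ordered
low→high band pairs, giving 28 single-layer graphs per subject
(`coupling_modes()` fixes the layer order). Stacked, these form the
multilayer connectome; flattened, a (7N × 7N) supra-adjacency matrix
with intra-band graphs on the diagonal blocks and cross-band graphs off
it (630 × 630 at the atlas scale N = 90).

### Estimators

* **PLV / iPLV** — phase-locking value and its imaginary part. iPLV
  discards zero-lag phase consistency and is therefore the default in
  source space, where instantaneous field spread produces spurious
  zero-lag coupling. For a constant lag Δ, PLV = 1 and iPLV = |sin Δ|;
  0 ≤ iPLV ≤ PLV ≤ 1 always.
* **CorrEnv** — absolute Pearson correlation of amplitude envelopes,
  within or across bands, non-orthogonalized.
* **PAC (phase–amplitude coupling)** — the envelope of the fast band is
  band-pass filtered *within the slow band*, Hilbert-transformed, and
  the phase synchronization (iPLV by default, PLV optionally) between
  that derived phase and the slow rhythm's phase is reported.

All estimates are computed per epoch and averaged across epochs (the
field's standard convention); an epoch therefore has to be long enough
for its band-limited phases to decorrelate, which bounds the estimator
noise floors discussed in §4.

**Assumptions.** Phase is only meaningful for narrowband signals, so the
caller-facing `analytic()` presumes filtered input. Envelope
correlations are rectified (absolute value): downstream topological
filtering and the participation coefficient require non-negative
weights, and the sign of an envelope correlation is not interpretable
after rectified averaging across epochs anyway. This is a documented
convention, not a claim that anti-correlation is absent.

**Direction and symmetrization.** Cross-frequency estimators are
directional (the slow phase of one node against the fast envelope of the
other). The undirected graph entry is the maximum over the two direction
assignments by default — preserving the stronger modulation — with the
mean available via `cfc_symmetrize = "mean"`.

## 2. Topological filtering, participation, comodulograms

Dense weighted graphs mix signal with estimator noise floor. The OMST
scheme (`omst_filter()`) extracts successive *edge-disjoint* minimum
spanning trees on distances 1/w: round r takes the MST of the graph
without the edges already selected, so each round adds the strongest
spanning backbone not yet used. After each round the aggregate is scored
by J = GE − Cost, where GE is weighted global efficiency (mean inverse
shortest-path length, distances 1/w) and Cost the retained fraction of
the graph's total weight. The aggregate at the first maximum of J is
returned.

Choices the method itself leaves open, fixed here:

* **Distance transform** 1/w rather than 1 − w, matching GE's own path
  convention (the two disagree on heterogeneous weight scales).
* **Cost normalization**: retained weight over total weight of the input
  graph, the convention of the OMST literature.
* **Stopping rule**: extraction stops when the remaining graph no longer
  spans all nodes or when J has declined for 5 consecutive rounds; the
  J-curve is concave in practice and the patience rule only guards
  against sampling noise near the peak.
* **MST tie-breaks**: Kruskal with ties broken by (smaller distance,
  then smaller node-index pair), making results order-independent and
  reproducible. Ties have measure zero for continuous weights but occur
  in constructed test graphs.

The **multilayer participation coefficient** (`mpc()`) uses binary
degrees of OMST-filtered layers: MPC_i = M/(M−1)(1 − Σ_λ (k_i[λ]/o_i)²),
0 for a node whose retained edges sit in one layer, 1 for perfectly even
spread. Binary degree is the primary definition (the filtered layers
carry the topology; weights would re-import estimator scale differences
between, say, PLV and CorrEnv layers); a weighted variant sits behind
`weighted = TRUE`. Isolated nodes are assigned 0 rather than NaN.

**Comodulograms** (`comodulogram()`) run OMST once on the flattened
multilayer matrix and count retained connections per coupling-mode
layer, normalized to sum to 1. Flattening follows the
{band × ROI} × {band × ROI} layout; no artificial inter-layer links
between homologous ROIs are added, so the multilayer graph is exactly
the union of its 28 layers.

## 3. Classification routes

All routes use an SVM with RBF kernel under leave-one-out or stratified
seeded 5-fold CV. The hyperparameters are deliberately plain — C = 1,
γ = 1/(n_features · mean feature variance), i.e. γ ≈ 1/n_features after
the in-fold z-scoring — because the scientific claim being tested is
about the features, not about tuning. Every data-dependent step
(z-scoring, feature ranking, TSA fitting) is fitted inside each training
fold; the test suite asserts this by corrupting held-out labels and
checking bitwise-identical fold artifacts.

* **Edge route**: each graph is vectorized to its N(N−1)/2 upper-triangle
  weights. Per fold, features are ranked by greedy
  max-relevance-min-redundancy mutual information (first pick maximizes
  MI(f; y); later picks maximize MI(f; y) minus mean MI with the already
  picked), with MI estimated on 8-bin quantile-discretized features; the
  top 15 enter the SVM, and the 15 most frequently selected features
  across folds are reported as the consensus biomarker. Eight quantile
  bins keep ≥ 4 observations per bin at desk-scale cohort sizes;
  constant features get MI 0 and sort last rather than erroring.
* **Tensor route**: graphs are treated as second-order tensors. Tensor
  subspace analysis learns row/column bases (N × 6 each) by an
  alternating generalized eigenproblem with a supervised affinity
  (within-class pairs 1, between-class 0), minimizing within-class
  scatter of the bilinear projections UᵀWV; the 36 projected entries are
  the feature vector. The bases are orthonormalized after each solve:
  this stabilizes the generalized eigenproblem (a small ridge,
  1e-8 × mean diagonal, guards rank deficiency) and makes the full-rank
  case an exact rotation. Five alternations suffice; the objective
  changes negligibly afterwards on all tested inputs. The tensor route
  operates on OMST-filtered graphs, while the edge route uses the
  fully-weighted graphs — sparse matrices suit a low-rank bilinear
  projection, single informative edges do not survive it.
* **MPC route**: the N per-node participation coefficients as features,
  unselected.

LOOCV metrics come from the pooled confusion matrix (each fold has one
subject); 5-fold metrics are reported as mean ± sd across folds. The
positive class is the second factor level (the patient group by the
package's convention). 5-fold splits are stratified and seeded — the
alternative (unstratified) risks class-free training folds at small n,
which the code treats as an error rather than silently resampling.

## 4. The synthetic cohort generator

Real source-space MEG cannot ship with a package; planted-truth
synthesis can, and it is what makes every pipeline stage testable. The
generator emulates:

* a 1/f^1 broadband background (spectrally shaped white noise),
  independent per channel;
* narrowband carriers whose *phase* is a smooth stochastic oscillation —
  instantaneous frequency wanders inside the band (Gaussian deviation,
  sd bw/8, rate bw/3) under an independent slow positive envelope
  (rate bw/6);
* planted coupling of three kinds, per edge: **intra** (a cosine
  injection of the source's phase at a fixed lag, mixed with an
  independent realization at weight 1 − strength, riding its own slow
  envelope), **pac** (target's fast carrier multiplied by
  1 + m·cos(φ_LF − lag)) and **env** (two tone carriers sharing a slow
  envelope component with variance weight ρ);
* per-subject strength jitter (truncated normal, sd 0.05) and additive
  group-2 strength shifts (`delta_strength`) — the ground truth for
  recovery and classification experiments;
* voxel clusters around a true regional source (distance-decaying gain,
  per-voxel SNR, one voxel exactly at the coordinate centroid) for
  testing the two ROI representations: first principal component
  (`roi_pca()`, sign-aligned to the mean voxel series so results are
  seed-independent) versus the centroid voxel (`roi_centroid()`,
  unweighted coordinate mean, ties to the lowest index).

Why a smooth-phase oscillation rather than the more common
filtered-noise carrier: the phase of filtered noise slips by ±π wherever
its envelope touches zero. Those slips broaden the spectrum exactly
where the envelope dips, so a planted constant lag survives re-filtering
only approximately (locked-pair PLV saturates near 0.95), and the slip
bursts leak into envelope correlation between phase-coupled channels.
With a slip-free phase the planted lag is exact (locked-pair PLV > 0.99
in every band) while envelopes still fluctuate. The *independent*
mixture component remains filtered noise, whose fast phase
decorrelation keeps the strength-0 null at the analytic floor. For
envelope edges the carriers are tones at the band centers: a noise
carrier's own envelope fluctuation would multiply onto the planted one
and dilute the planted correlation, breaking the clean ρ → CorrEnv
mapping.

PAC edges that share a source ROI share that ROI's low-frequency driver
(one oscillator per region and band, per epoch). Independent drivers
per edge would sum in the source channel and destroy its phase, making
any one-to-many modulation structure unrecoverable by construction —
the shared driver is also the physiologically sensible reading of "a
region's slow rhythm modulates several targets".

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: field spread / source leakage (the very
artifact iPLV exists for: planted couplings here are leakage-free),
realistic head geometry and beamformer residuals, heteroscedastic and
artifact-laden noise, non-stationarity across epochs, and realistic
anatomical covariance between regions. Results on synthetic cohorts
validate the *implementation* (estimators respond to what was planted,
selection is leakage-free, filtering finds planted topology), not
clinical effect sizes.

### Default conditions

Two groups of 25 subjects, 20 epochs of 4 s at 250 Hz, N = 20 ROIs,
SNR 1 (planted signal amplitude : background amplitude), noise exponent
1. These are desk-scale stand-ins for the acquisition they emulate
(~30 vs ~24 subjects, 20–44 epochs of 4–6 s at 1 kHz, N = 90): with all
bands below 45 Hz, 250 Hz sampling is spectrally sufficient, and N = 20
keeps a full 28-layer build per subject in seconds. Epoch length is a
parameter (4 s default, 6 s used where cross-frequency floors matter,
matching the two trial lengths in use for such recordings); the
full-scale geometry is available through the same configuration
interface.

## 5. Numerical choices and degenerate inputs

* **Edge transients**: 0.5 s is trimmed from each epoch end after
  filtering and Hilbert transform, generously covering filtfilt and FFT
  edge effects at the default bands; epochs must exceed 1 s.
* **Band edges at Nyquist** are rejected with an error naming fs/2. A
  band-edge tone, it is worth knowing, passes a 3rd-order zero-phase
  Butterworth at only ~25% power (−3 dB applied twice): "in band" means
  mid-band for power arguments.
* **Constant input to `analytic()`** errors (phase undefined).
* **Degenerate PAC**: if the LF-refiltered fast envelope shows < 2.5%
  relative modulation, `pac_iplv()` errors rather than reporting the
  phase of numerical ripple; a filtered pure tone shows ~1.8% ripple,
  genuine modulation at depth 0.05 about 4%, so the threshold separates
  artifact from weak signal with margin on both sides.
* **Zero-variance envelopes** error in `corr_env()` (correlation
  undefined), as does an all-zero voxel cluster in `roi_pca()`.
* **Estimator noise floors**: per-epoch averaged |Im ⟨e^{iΔφ}⟩| does not
  shrink with the number of epochs (it averages magnitudes), only with
  epoch length; narrow bands (α₁ at 2 Hz) have few phase degrees of
  freedom per epoch and correspondingly high floors. This is a property
  of the estimators, not of the implementation, and it is why
  cross-frequency comodulogram structure needs widespread planted
  coupling to dominate finite-epoch floors.
* **Exact file round trips**: cohort CSVs and edge-list TSVs are written
  with 17 significant digits and parsed by strtod, reproducing doubles
  bit-exactly.

## 6. Problem sizes used by the test suite

Unit tests run on 4–6 ROI cohorts with 2–5 epochs of 2–4 s. The
end-to-end recovery experiments use the default cohort above (N = 20,
25 + 25 subjects; single-band graphs for classification), 20-seed
Monte-Carlo nulls and strength grids at 20–60 s of signal per run, 100
five-node instances for the OMST brute-force comparison, and a
four-subject 6-s-epoch cohort with a 40-edge planted δ→γ₁ structure for
comodulogram recovery. The full suite runs in well under ten minutes on
one CPU; the same experiments scale to the full-size geometry by
configuration only.

## 7. Known limitations

* Surrogate-based statistical edge pruning is not implemented (only the
  topological OMST filter); orthogonalized envelope correlation and
  corrected iPLV variants are out of scope.
* The mutual-information ranking uses a fixed 8-bin quantile
  discretization; very small training folds (< 16 subjects) make MI
  estimates coarse.
* TSA's supervised affinity is the simple class-indicator; neighborhood
  weighting is not exposed.
* The MPC route and tensor route are sensitive to the OMST filter's
  output density; comparisons across estimators should fix the
  estimator before interpreting MPC differences.
* Group comodulograms average subject-level probability tables; they do
  not propagate subject-level edge-count uncertainty.
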