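---
title: "Models and methods behind sockeica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sockeica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the parameters that matter, what the phantom
generator does and does not emulate, and where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The signal model and the pipeline

The package treats a 4D fMRI series as a voxel-by-time grid with a
repetition time TR (seconds). All event times are seconds relative to the
acquisition of the first volume, voxel indices are 0-based, and the time
axis is the fourth array axis — one convention used by every module.

The pipeline has two ICA stages with different jobs:

1. **Full-series spatial ICA + artifact screening.** The whole series is
   decomposed into spatially independent maps with time courses; a
   rule-based classifier labels each component *artifact* or *unlikely
   artifact*; artifact time courses are regressed out of every voxel.
2. **Event-related ICA (eICA).** The denoised series is deconvolved against
   the event train with a shape-free FIR model, and the per-voxel peri-event
   responses (not the raw series) are decomposed by ICA into a handful of
   maps that are all, by construction, time-locked to the events.

The rationale for denoising first is that the FIR deconvolution is a
least-squares estimator: structured noise inflates the variance of its
estimates and the spatial heterogeneity of the responses, which then
degrades the second ICA. The acceptance suite measures exactly this
(criterion 6): peri-event response RMSE against ground truth with and
without the denoising stage.

## 2. Spatial ICA (`decompose`)

Let $X$ be the $t \times v$ masked series. The decomposition

* removes the voxelwise temporal mean (`mean_map`),
* removes the spatial-mean time course (`global_tc`),
* reduces to $k$ principal components and whitens,
* runs FastICA with the tanh (log-cosh) contrast and symmetric
  decorrelation, up to 500 iterations at tolerance $10^{-5}$, restarting
  `n_restarts` times from derived seeds and keeping the best final
  contrast.

**Why the explicit `global_tc` term.** Spatial maps are z-scaled (zero mean,
unit variance over mask voxels). A linear combination of zero-spatial-mean
maps can never represent the spatially constant part of the signal, so the
global time course is removed first and stored explicitly; the
reconstruction identity is then
`mean_map + global_tc ⊗ 1 + time_courses %*% spatial_maps`, and its residual
variance fraction is bounded by the PCA loss exactly. This mirrors
MELODIC-style centering while keeping the container self-inverting.

**Model order.** The Laplace-approximation order estimation used by MELODIC
is deliberately not reproduced; it is opaque and data-dependent. The default
rule retains the smallest order reaching 99.5% of variance
(`order_variance(0.995)`), with `order_fixed(k)` as an override, and the
choice is exposed in the pipeline config. Tests and acceptance batteries use
`order_fixed(10)` on phantoms with six injected structures so that each
battery exercises a known regime.

**Determinism.** Components are ordered by descending explained variance
(the variance of their time courses, since maps are unit variance), signs
are fixed so each map has non-negative skewness, and all randomness flows
from one integer seed through a splittable derivation
(`derive_seed`). Identical calls are bitwise identical.

## 3. Artifact features and classification (`sock_*`)

Four feature families per component:

| family | scalar | default floor | what it captures |
|---|---|---|---|
| smoothness | high/low 2D spatial-spectral power ratio (radial cutoff 0.25 of spatial Nyquist), averaged over axial slices with ≥ 32 in-mask voxels | 1.0 | spatially rough, noise-like maps |
| (same family) | fraction of suprathreshold voxels in 26-connected clusters < 5 voxels | 0.5 | "spotty" scattered activity |
| edge | fraction of suprathreshold voxels in the edge mask (brain minus 6-connected erosion) | 0.4 | motion/edge ringing |
| csf | fraction in the CSF mask | 0.35 | ventricular pulsation |
| tfn | time-course periodogram power above 0.08 Hz (0 Hz bin excluded) | 0.5 | machine/physiological high-frequency noise |

Suprathreshold means $|z| \ge 2.3$ on the z-scaled map — the conventional
level for component maps; the source publications leave the level to the
thresholded maps of the upstream tool. Per family the scalar is robust-z
scored (median/MAD, falling back to SD when the MAD degenerates) and split
by 2-means (seed-fixed, 10 restarts, `stats::kmeans` Lloyd). The higher-mean
cluster is called artifact-prone **only** when its mean exceeds the family
floor: without the floors, k-means on homogeneous features would
manufacture an artifact class. A component is an artifact iff flagged in at
least one family; with fewer than three components carrying defined
features, the floors alone decide. These aggregation rules — one-family
sufficiency, thresholded maps for the region fractions, per-family 1-D
clustering — are this package's explicit instantiation of decisions the
source method delegates to its reference implementation.

Components with no suprathreshold voxels have all spatial fractions defined
as 0 and are flagged `empty`; an undefined smoothness (no qualifying slice)
excludes that component from that family only.

## 4. Aggressive regression filtering (`regression_filter`)

Per voxel, the demeaned signal is regressed on the demeaned artifact time
courses alone and replaced by residual plus temporal mean. This is an
orthogonal projection: idempotent, variance non-increasing, mean-preserving,
with residuals orthogonal to every artifact time course — all asserted in
tests at $10^{-8}$–$10^{-10}$. Only this "aggressive" semantics is
implemented; partial (non-aggressive) filtering is out of scope because the
published pipeline used the aggressive option exclusively. Drift is *not*
handled here — it belongs to the deconvolution GLM (separation of
concerns).

## 5. FIR deconvolution (`build_fir_design`, `deconvolve`)

The design has one indicator column per peri-event bin over a −30…+30 s
window (21 bins at TR = 3 s, `n_bins = (w_post − w_pre)/TR + 1`), plus an
intercept and Legendre drift columns (default order 1). Decisions the
source material leaves open, fixed here and configurable:

* **event-to-volume assignment**: nearest volume (`round`), unbiased at
  sub-TR offsets;
* **overlapping windows**: the default `cap` policy keeps cells at 0/1 (an
  indicator-regressor deconvolution); `accumulate` sums hits and is what
  the phantom uses to synthesize exactly-linear overlapping responses;
* **boundary events**: partial windows are used with missing bins dropped
  from the design (equivalently zero-filled), `drop_partial = TRUE` to
  exclude them.

Estimation is per-voxel least squares through the Moore-Penrose
pseudo-inverse; rank-deficient designs (e.g. bins that no event maps into
the series) yield the minimum-norm solution with exactly-zero coefficients
on unidentifiable bins rather than failing. On noiseless data whose
responses lie in the FIR span the estimator is exact to machine precision —
the acceptance suite asserts a relative error below $10^{-8}$ and measures
$\sim 10^{-13}$.

## 6. Event-related ICA with stability clustering (`eica_decompose`)

The $n_\text{bins} \times v$ response matrix (or the concatenation of
per-subject matrices for groups) is centered, whitened to the requested
order, and decomposed by `n_runs` FastICA runs from derived seeds. All runs'
components are pooled and clustered by average linkage on
$1 - |\text{spatial correlation}|$, cut at the model order; each cluster is
represented by its **centrotype** (the member with maximal summed
within-cluster similarity) and scored by a **stability index**: mean
within-cluster minus mean between-cluster absolute correlation, clipped to
[0, 1]. This is the ICASSO construction; the number of runs (default 10)
and the clustering cut are explicit substitutes for settings the source
material does not state.

Model order defaults to 10 for single subjects and is user-set; published
single-subject analyses of this kind yield roughly 1–10 components, and the
order is intentionally exposed rather than estimated. Group stacks scale
each subject's response matrix to unit Frobenius norm first so no
high-variance subject dominates — one simple choice among several
defensible normalizations, made configurable at the stacking call.

**z-maps.** Each spatial map is standardized against the null component of
a two-component Gaussian mixture fitted by EM: deterministic initialization
at the robust location/scale with an offset second component (median,
MAD·1.4826 scale; second mean at +3 scales), ≤ 200 iterations, tolerance
$10^{-8}$ on the log-likelihood; the larger-weight component is the null and
$z = (s - \mu_0)/\sigma_0$. The transform is affine, hence monotone — voxel
ranking within a component is preserved, which is the property downstream
thresholding relies on. A degenerate fit (vanishing scale) falls back to a
flagged median/MAD z. A two-Gaussian family (rather than Gaussian + gamma
tails) is the simplest family satisfying the monotonicity contract; this is
a deliberate simplification, noted as such.

**Thresholding.** Two-sided Gaussian p-values, optionally Benjamini-Hochberg
FDR across in-mask voxels; survivors keep their signed z.

## 7. The phantom: what it emulates, what it does not

`generate_phantom` is a pure function of its spec (seed included) producing
baseline-1000 data with percent-scale signals:

* **event-locked sources**: unit-max Gaussian blobs times FIR-sampled
  response shapes — `canonical_like` (difference of gammas peaking ~5 s
  post onset, zero before), `early_onset` (begins 6 s before the event,
  emulating BOLD changes that precede the electrographic discharge), and
  `undershoot_dominant` (undershoot exactly twice the positive peak);
  default amplitudes 1.0–1.2% of baseline;
* **artifacts**: an edge-confined ring driven by high-pass (> 0.08 Hz)
  noise; CSF-confined 0.10–0.15 Hz pulsation; global stripes at 90% of
  Nyquist; ~60 isolated "spotty" voxels with white time courses; optional
  smooth quadratic drift; default amplitudes 1.5–2%;
* **white measurement noise**, default SD 2 (0.2% of baseline — generous
  relative to raw scanners but representative of spatially smoothed data,
  which is what the pipeline expects);
* geometry: an ellipsoid brain (~38% of the grid), a central CSF ellipsoid
  (~3% of the brain), and a width-1 edge shell — the minimal geometry that
  exercises every mask-dependent feature.

Event trains are renewal processes: a 12 s minimum gap plus an
exponential extra gap of mean 9 s (mean interval ~21 s), or a caller-given
train. Default grid 32×32×16 voxels of 3 mm, 400 volumes at TR 3 s.

The phantom does **not** emulate k-space physics, motion interpolation
artifacts, spatial autocorrelation of thermal noise, or EEG waveforms. A
green phantom test therefore establishes the *algorithmic* contracts
(recovery, classification, projection identities) — not clinical
performance on patient data, which would require the original EEG-fMRI
cohort and is explicitly out of scope.

## 8. Numerical choices and degenerate inputs

* FastICA: tanh contrast, symmetric decorrelation via the inverse matrix
  square root, tolerance $10^{-5}$ on $\max_i |1 - |w_i^\top w_i'||$,
  restart-best by the log-cosh negentropy proxy.
* Whitening uses the SVD; requested orders beyond the achievable rank fail
  with the achievable rank named.
* Constant-in-time series, all-zero brain masks, empty event trains, event
  trains past the series end, cutoffs at or above Nyquist, and rank-deficient
  artifact sets (collinear pairs listed) are all distinct, tested errors.
* Periodograms are one-sided with Parseval normalization (sum = population
  variance of the demeaned series, within $10^{-6}$ relative).
* All k-means, ICA and phantom randomness is seed-derived; library code
  saves and restores the caller's RNG state.

## 9. Known limitations

* The spatial-ICA model order rule is variance-based, not an evidence
  approximation; component counts are not comparable to MELODIC's.
* The classifier's floors are fixed defaults, not learned; on data whose
  artifact profile differs strongly from the four families they should be
  reviewed (they are config keys).
* Two-Gaussian z-maps understate heavy activation tails compared to
  Gaussian-gamma mixtures; ranking (and hence thresholding topology) is
  unaffected.
* Group analysis assumes subjects share one registered voxel grid; no
  registration is performed here (preprocessing is upstream of this
  package).
* Small grids inflate the TFN of genuine event-locked components (less
  spatial noise averaging in their time courses); the classification
  batteries therefore run at the generator's default size.
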