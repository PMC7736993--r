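---
title: "Dynamic functional connectivity as a random walk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity as a random walk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstream)
```

## The model

`dfcstream` treats time-resolved functional connectivity as a smooth
stochastic reconfiguration process rather than a sequence of discrete
states. An N-region recording `TS_i(t)` (rows = samples, columns = regions)
is converted into a *dFC stream*: FC frames

    FC_ij(t_k) = Corr[TS_i(t), TS_j(t)],   t_k <= t < t_k + W,

with frame starts `t_k` separated by the slide step Δτ (default Δτ = W,
non-overlapping). Window slices are half-open in sample units, and trailing
windows that would be trimmed are dropped, so the frame count is exactly
`F = floor((T − W)/Δτ) + 1`. Each frame is a point in the L-dimensional
space of link weights (L = N(N−1)/2); over time that point traces a random
walk, and the package's statistics are descriptors of this walk:

- the **recurrence (dFC) matrix** `dFC(t1, t2)`, the Pearson similarity of
  frames, whose block/stripe texture exposes transient stabilization
  ("knots") and fast reconfiguration ("leaps");
- the **dFC speed** `V = 1 − dFC(t, t + W)`, the flight length per window
  step, summarized by its distribution and *typical* (median or modal)
  value;
- the **DFA exponent** of the instantaneous increments
  `v = 1 − dFC(t, t + δt)` on a maximally smooth stream (Δτ = δt = 1
  sample), separating memoryless (α = 0.5), persistent (α > 0.5) and
  anti-persistent (α < 0.5) walks;
- **meta-connectivity** `MC = Corr[FC_ij(t), FC_kl(t)]`, the static
  coordination structure of the link fluctuations, with its dFC modules,
  trimer meta-strengths and meta-hubs;
- **surrogate nulls** that isolate which aspect of the empirical walk is
  non-trivial (stationarity-preserving phase randomization; sequence-
  destroying frame shuffling).

All correlation estimates use the sample (n−1) normalization, and no
entry is ever thresholded or masked by significance: FC, MC and eFC
entries are treated as features whose predictive value is assessed
downstream.

### Assumptions

The framework assumes real-valued, finite, non-constant signals and enough
samples per window to estimate correlations (zero-variance windows are
hard errors, not NaNs, because a silent NaN frame would poison every
downstream correlation). It does not assume stationarity — that is what
the surrogate comparisons test — nor any hemodynamic or spectral model.
Preprocessing (filtering, global regression, motion handling) is out of
scope and must happen upstream; its choices materially affect dFC results.

## Parameters that matter

- **Window `W` (samples).** Controls the bias/variance trade-off of every
  frame: short windows give noisy frames but many of them. For speed
  distributions a non-overlapping stream (Δτ = W) is standard; for DFA and
  MC a smooth stream (Δτ = 1) with a *short* window is preferable because
  the loss of per-frame precision is repaid by many more frames. There is
  no universal optimum: results should be shown robust over a range of W,
  and speed samples from nearby W can be pooled ([pool_speeds()]) — a
  pragmatic smoothing device to be cross-checked against single-window
  analyses.
- **Frame offset Δf.** Speeds compare frame a with frame a + Δf. With
  Δτ = W use Δf = 1; with Δτ = 1 use Δf = W so each frame is compared to
  the first non-overlapping one (window oversampling). Oversampled speeds
  are flagged `oversampled`: they are not independent samples and no
  effective-sample-size correction is applied — they serve to denoise the
  instantaneous estimate, not to inflate n.
- **Histogram bins.** Default 20 equal-width bins over [0, 2], the full
  admissible speed range (speeds are 1 minus a correlation). Bin-wise
  Agresti–Coull intervals use the stated closed form; values outside the
  range go to flagged overflow bins with a warning rather than being
  silently dropped.
- **DFA scales.** Default 12 log-spaced integer segment lengths from 8 to
  K/4 (deduplicated), each scale requiring at least 4 segments. Log
  spacing equalizes leverage in the log–log fit.
- **MC window defaults.** The `mc` pipeline command defaults to Δτ = 1;
  choose W around 20 s worth of samples for fMRI-like data.
- **Louvain resolution and seed.** Signed modularity with resolution 1 by
  default; the seed fixes the sweep orders, making the partition
  deterministic and reproducible.
- **Surrogate ensemble size.** 1000 instances recommended for final
  5th/95th percentile bands; tests and quick exploration use fewer.

## Numerical and design choices

**Canonical link order.** Vector-format objects enumerate links row-major
over pairs (i, j), i < j — in R, exactly `m[lower.tri(m)]`. One documented
bijection ([link_of_index()], [index_of_link()], and the directed variants
for the redundant MC view) is used everywhere, preventing silent
misalignment between streams, MC rows and module labels. Because FC
matrices are symmetric, correlating "upper" or "lower" triangular parts is
equivalent; the package fixes one order and never mixes conventions.

**DFA centering.** The increment series is mean-centered before cumulative
integration. dFC increments have a strongly positive mean (speeds are
nonnegative), and integrating without centering adds a deterministic ramp
that biases the exponent; centering is the standard Peng-style convention
and is applied here deliberately.

**DFA detrending and fit.** Per-segment detrending is linear (order 1)
only; the trailing remainder of the profile is discarded rather than also
scanned from the reverse end (the simplest reading of M = K/k). The fit
uses the RMS fluctuation per scale. A Bayesian model comparison of
power-law validity is out of scope; instead the fit's R² is reported and
results with R² < 0.95 are flagged `is_scaling = FALSE` — such values must
not be interpreted as scaling exponents. Note that increments of
overlapping-window streams are autocorrelated up to lag ≈ W by
construction, which inflates apparent persistence at small scales even for
stationary inputs; α is a descriptor of the chosen estimator's walk, and
comparisons are only meaningful at fixed W.

**Typical speed.** Default is the median (binning-free, robust, the
natural choice for pooled lists); the histogram mode is available as an
option, with ties broken toward the lowest bin. The similarity metric is
fixed to Pearson correlation throughout; other network similarity metrics
(e.g. Jaccard) would slot into the same recurrence machinery but are not
implemented.

**Trimer-pair convention.** `MC(i)` sums over unordered pairs of distinct
links incident on region i, each pair once, diagonal excluded, so an
all-ones compact MC gives MC(i) = (N−1)(N−2)/2. Other conventions
(ordered pairs, diagonal included) only rescale the values; one convention
is fixed so results are comparable and testable.

**Compact vs redundant MC.** The compact L × L matrix is canonical
storage; the redundant M × M view (M = N(N−1)) exists because it lets
standard graph algorithms treat MC as an adjacency matrix, but it grows
with N⁴ (9900 × 9900 already at N = 100) and is therefore materialized
only on demand behind a memory cap (default 4 GB) with an error that
directs users back to compact-mode operations.

**Signed Louvain.** Community detection on MC must handle negative
weights, which the classic modularity null model does not. The package
implements Louvain on the uniform signed modularity (positive and negative
layers with their own configuration-model terms, combined with weights
1/(2w⁺ + 2w⁻)); `signed_modularity()` is exported so partitions from any
other tool can be scored identically. Ties in the greedy sweep prefer
keeping a node in place, and aggregation preserves self-loops, so the
optimization is deterministic given the seed. An MC with no off-diagonal
structure returns the singleton partition flagged `uninformative`.

**Phase randomization.** One uniform angle is drawn per positive frequency
bin and applied to *all* regions at that bin (independent per-region
rotations would destroy the cross-spectra and hence the static
covariance). The description of this construction in the source
literature says "at every time-step"; rotation happens in the Fourier
domain, so the operative reading — the one that actually preserves the
covariance — is per frequency bin, and that is what is implemented. The
DC bin is left alone; for even T the Nyquist bin, whose handling the
construction leaves open, is multiplied by a common random sign (the only
unit-modulus real option that keeps the output real and the rotation
common). Series are de-meaned before the transform and means re-added
after. These choices make the preservation exact to machine precision:
the tests require covariance and periodogram agreement to 1e−10.

**Zero-variance policy.** Constant regions or windows raise errors naming
the offending region and frame. The one exception is a constant *link
time-course* inside MC: that signals an uninformative link, not a broken
input, so its MC row is zeroed with a warning instead.

## The synthetic generators: what they emulate, and what they do not

- `gen_stationary_gaussian()` — the stationarity null: i.i.d.-in-time
  Gaussian draws with a prescribed covariance. Every dFC fluctuation in
  such data is estimator noise.
- `gen_switching_covariance()` — piecewise-stationary alternation between
  covariance regimes: the minimal mechanism producing recurrence-matrix
  "knots" (within-regime similarity blocks) and "leaps" (regime changes).
- `gen_planted_mc_modules()` — a time-varying covariance
  Σ(t) = Σ₀ + Σ_m a_m(t)·B_m whose templates B_m cover the links inside
  disjoint region sets, with slow independent modulations a_m(t)
  (moving-average-smoothed white noise, span 100 samples by default).
  Links inside one set covary — a planted dFC module with known labels;
  links across sets carry no planted structure and therefore no
  ground-truth label (module-recovery scores are computed over the
  labelled links). For 4-region sets, Σ(t) is PSD exactly when
  |a_m(t)| ≤ 1/3; the default amplitude (0.32, clipped just inside the
  ceiling) drives the modulation as hard as PSD allows, the calibration at
  which the planted contrast is reliably recoverable: within-group minus
  between-group MC ≥ 0.2, exact module recovery, and upper-triangle MC
  correlation > 0.8 between independent generator seeds at T = 4000,
  W = 20, Δτ = 1 (the property that justifies group-averaging MC).
- `gen_fgn_increments()` — exact fractional Gaussian noise via
  Davies–Harte circulant embedding, the calibration standard for DFA: the
  true exponent equals the Hurst parameter H.

What these fixtures do **not** emulate: hemodynamics, scanner drift,
motion artifacts, 1/f regional spectra, non-Gaussian marginals, or any
spatial embedding. Passing tests on them demonstrates that the estimators
recover the structure they are defined to measure — not that any
particular empirical dataset contains such structure.

## Problem sizes used by the test suite

The suite is built to be exhaustive at small scale: oracle-equivalence
checks (brute-force double/triple loops for the recurrence matrix, MC,
trimer strengths, DFA fluctuations) run on ≤ 5 regions and ≤ 30 frames at
1e−10 agreement; link-index bijections are exhaustive for N ≤ 12; DFA
calibration uses 20 replicates of length 4096 with H ∈ {0.3, 0.5, 0.8}
(±0.05 on the mean); module recovery uses the planted fixture at T = 4000,
W = 20, Δτ = 1; surrogate chance bands use 200 instances. These sizes were
chosen so the full suite completes in well under a minute of numerical
work while keeping every statistical check adequately powered.

## Known limitations

- Sliding-window correlation is itself an estimator; α and MC depend on W
  and Δτ, and no correction is applied for overlap-induced
  autocorrelation (in speeds, increments, or MC link time-courses).
- The signed-Louvain optimizer is greedy: it guarantees determinism given
  a seed and local optimality, not the global modularity optimum.
- Pooled-window and oversampled statistics are pragmatic smoothing
  devices without rigorous sampling theory; conclusions should be checked
  at single windows.
- Large-N workflows must stay in compact vector format: the stream is
  O(N²·F) and the redundant MC is O(N⁴) memory.
- Streams are exchanged as delimited text plus a JSON sidecar; no binary
  container is provided.
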