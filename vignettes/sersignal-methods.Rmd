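---
title: "Methods: background removal and signal identification for SERS time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background removal and signal identification for SERS time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sersignal)
```

This vignette is the package's account of its statistical machinery: the
model each stage assumes, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical conventions adopted where more than
one was defensible.

## Data model

The input is a matrix `X` of non-negative intensities with `T` rows (time
points, one acquired spectrum each) and `W` columns (frequency channels).
The working decomposition is

```
X[t, j] = c_t * B_t(j) + signal[t, j] + noise[t, j]
```

* `c_t > 0` — the overall background strength at time `t`; allowed to
  change arbitrarily between consecutive spectra (laser power, nanoparticle
  coupling and flow all perturb it).
* `B_t(j)` — the background *shape* along frequency; allowed to fluctuate
  sharply along `j` but assumed to drift only slowly in `t`. This is the
  central assumption: within a window of `w_T` consecutive time points the
  shape is treated as constant.
* `signal` — transient analyte contributions: positive bumps occupying
  limited channel ranges and a few consecutive time points, intensifying
  then fading.
* `noise` — additive, approximately Gaussian, independent across channels.

All intervals the package reports (bump supports, informative sections)
are 1-based and closed, matching how R indexes vectors and how
spectroscopists count channels; the same convention is used internally, so
there is no translation layer to get wrong.

## Background removal

The matrix is tiled into time–frequency blocks. Each axis of length `n`
windowed at `w` yields `floor(n / w)` segments; when `w` does not divide
`n` the remainder joins the final segment (length up to `2w − 1`). A tiny
trailing block would make its median estimate unstable, which is why the
remainder is absorbed rather than split off.

Within a block, spectrum fragments are scaled to unit mean, the
background shape is the per-channel median of the scaled fragments, and
each raw fragment row sheds `Q_i · B`, where `Q_i` is the `q`-th
percentile of the projection profile `P_ij = X*_ij / B_j`. Two exactness
properties pin the implementation down and are enforced in the tests: a
block of the form `X*_ij = c_i B_j` is annihilated identically (any
percentile of a constant profile is that constant), and scaling the input
by `λ > 0` scales the output by exactly `λ`.

Parameter guidance:

* `w_time` (time points) and `w_freq` (channels), default 50/50. The
  faster the background shape drifts, the smaller `w_time` should be;
  overly large windows leave residual background, overly small ones eat
  into signals that persist across many spectra. For long-lasting signals
  a larger time window (the `"long-signal"` preset uses 150) avoids the
  median absorbing the signal itself. `w_freq` bounds the channel span on
  which a single scaling factor `Q_i` must be adequate; it should stay
  comfortably above the width of any single analyte band, since a band
  occupying more than roughly `q`% of a frequency window starts inflating
  its own `Q_i` and is partially subtracted.
* `q`, default 40 (percentile, 0–100 scale). Below the median, so that
  channels elevated by signal — a minority by assumption — do not drag the
  scaling factor up. Percentiles interpolate linearly between closest
  ranks (`stats::quantile` type 7): the estimate is then continuous in the
  data, and the package does not depend on a discontinuous rank rule.

Numerical guards: a fragment row with non-positive mean cannot be scaled
and raises an error naming the time index (a genuinely dark detector row
is a data problem, not something to patch silently); a background shape
entry below `1e-12 ×` its mean likewise errors, naming the channel, rather
than dividing by it. Blocks are processed independently — no blending
across block edges, which would change the estimator — and errors are
re-raised with the block's coordinates attached.

## Signal detection

Per corrected spectrum `Y_i.`:

1. `σ̂_i = median_j |Y_ij| / Φ⁻¹(0.75)`. Under pure Gaussian noise the
   median absolute value sits at the 0.75 quantile, so this is a
   consistent, 50%-breakdown estimate of the noise SD. Note what the
   breakdown point does and does not promise: the estimate stays *bounded*
   under contamination approaching half the channels, but the median's
   sampling quantile moves, so it is unchanged to within ~10% only while
   signal occupies a few percent of channels. With realistic sparse bands
   that is the operating regime.
2. `p_ij = 2 Φ(−Y_ij / σ̂_i)` for positive channels, `p_ij = 1` otherwise
   (signals are positive; negative excursions are evidence of nothing).
   P-values are clamped below at `1e-300` so extreme signals cannot
   underflow to exact zeros. A degenerate all-zero row gets `σ̂_i = 0`,
   every p-value 1, and a warning; it can never be detected.
3. Benjamini–Hochberg conversion to per-channel FDR, applied within the
   spectrum across its `W` channels. The row-wise structure of the
   procedure makes per-spectrum adjustment the natural scope; pooling all
   `T × W` p-values would couple unrelated time points through their
   multiplicity correction.
4. Bumps: maximal runs of channels with `Y_ij > α σ̂_i` and `FDR < β`; a
   spectrum is signal-positive when some bump reaches length `γ`.

`α` (default 3) is expressed in noise-SD units: a practical-significance
floor that transfers across datasets with different intensity scales. An
absolute-intensity reading is available via `alpha_absolute = TRUE` for
instruments with calibrated units. `β` (default 0.05) is the per-channel
FDR level. `γ` (default 3 channels) encodes that genuine Raman bands are
several channels wide, whereas cosmic-ray artifacts hit a single channel:
a length cutoff of 3 removes them without any shape fitting. Raising `α`
or `γ`, or lowering `β`, can only shrink the detected set — a monotonicity
the tests assert directly.

## Merging consecutive detections

One analyte event spans several consecutive detections of a common shape
at varying strength. Detections are walked in time order; a detection
extends the current event when it is the immediate successor
(`t_k = t_{k−1} + 1`) *and* its full-spectrum Pearson correlation with its
predecessor exceeds `φ` (default 0.9 — deliberately high, so two distinct
co-eluting analytes are not fused). Within an event, the surviving
signature is updated whenever a spectrum is stronger than its immediate
predecessor, ties keeping the earlier time; for intensify-then-fade
profiles this retains the maximum-strength spectrum. The comparison is
strictly with the immediate predecessor (chain semantics), not with the
current survivor: for monotone rise–fall events the two coincide, and the
chain rule is the simpler contract.

Strength is the median |Y| over the spectrum's bump support — over all
channels it would be a noise statistic, not a signal one. A zero-variance
spectrum cannot be correlated; it is treated as dissimilar (correlation
0) with a warning rather than propagating `NA`.

## Cross-experiment similarity

Wavenumber miscalibration between experiments translates a signal by a
small integer number of channels — typically under ten — which can destroy
a naive correlation. The metric translates the second signal by every
integer `s` in `[−max_shift, max_shift]` (default 10; an unbounded search
invites spurious maxima), forms the *informative section* — the union of
the first support and the translated second support, coalescing
overlapping or adjacent intervals and clipping to the channel range — and
takes the largest correlation over the section's channels. Positive `s`
moves the second signal toward higher channels, so a replicate recorded
`d` channels too high matches at `s = −d`.

Conventions worth stating exactly:

* The section is *recomputed at every shift* from the translated support:
  "where the signals occupy" moves with the shift. The alternative (a
  section frozen in the first signal's frame) under-covers the moving
  signal at large shifts.
* Supports are the detector's bump intervals padded by `support_pad`
  channels (default 5, about one peak half-width) on each side.
  Thresholded bumps capture only the supra-threshold crest of a band,
  and over the crest alone two matching peaks are flat plateaus whose
  correlation is noise; the flanks, where intensity falls to baseline,
  carry the shape contrast the metric needs. Padding is the
  operationalization of "occupied frequency range" from thresholded
  output; `support_pad = 0` restores the bare bumps.
* Sections shorter than 3 usable channels at some shift make the
  correlation degenerate; that shift is skipped, and if every shift is
  skipped the pair is reported as having no usable overlap.
* Ties in correlation break toward the smallest |s|, then the smaller s —
  the no-shift hypothesis wins when the data cannot distinguish.
* Correlation is invariant to positive affine rescaling of either signal,
  so no intensity normalisation is needed before matching.

`match_signatures` scores all pairs and reports those reaching
`min_similarity` (default 0.5), best first.

## The synthetic-data generator

`simulate_spectra` emulates exactly the structure the method assumes —
and nothing more:

* background: two fixed smooth positive profiles mixed by a weight moving
  linearly over the run (`drift`, default 15% relative amplitude, lowering
  the low-frequency end and raising the high-frequency end; `drift_speed`
  scales how much of the transition the run traverses), multiplied by
  i.i.d. lognormal per-time strengths (`strength_sdlog = 0.4`);
* signals: sharp Gaussian bands (widths 3–5 channels) spaced tens of
  channels apart — the sparse-band structure of Raman fingerprints, and
  the sparsity the `q = 40` percentile relies on — with triangular
  three-point rise–fall time profiles and amplitudes in noise-SD units
  (default 6, i.e. barely comfortable for a 3σ detector);
* noise: additive i.i.d. Gaussian (`noise_sd = 1` detector unit; the
  default background mean is 80, so background dominates noise as in real
  SERS);
* cosmic rays: Poisson-many (default rate 2 per matrix) single-channel
  spikes of 20–50 σ.

Identical configurations (including the seed) generate bit-identical
matrices, and the generator restores the caller's RNG state. Ground truth
records each signal's time window, channel support (where its shape
exceeds 5% of maximum), exact shape, the noiseless background matrix and
the cosmic-ray positions. `shifted_replicate` regenerates the same
configuration with background profiles and band centers translated by an
integer channel shift (edge values extended) and fresh noise — a
technical replicate with a miscalibrated wavenumber axis.

What the generator does *not* emulate: Poisson/shot noise, correlated
noise, photodegradation trends, sub-channel (fractional) calibration
shifts, overlapping co-eluting analytes, or any physical model of
plasmonic enhancement. Tests passing on this generator therefore certify
the statistical contract of each stage — not performance on every real
instrument's artifacts.

## Observed operating limits

Two noise-floor effects are worth knowing when interpreting output near
the detection threshold; both follow from the model and are visible in
the test suite's measurements:

* A single corrected spectrum of a signal at amplitude `A` noise-SDs
  correlates with the true band shape at about
  `SNR / sqrt(1 + SNR²)` where `SNR = A · sd(g)` for a unit-peak shape
  `g` (`sd(g)` ≈ 0.3–0.4 over a band's support). At `A = 6` this caps the
  signature-vs-truth correlation near 0.9 — not an implementation defect,
  a noise floor.
* The shift-search argmax inherits the same noise: threshold-level
  signals recover a true inter-replicate shift to within ±1 channel,
  while strong signals (e.g. 20 σ) recover it exactly across the full
  ±10 range.

## Problem sizes used in the tests

The suite exercises full-scale behaviour once — a 5,000 × 1,600 pipeline
run, the size of a long chromatographic acquisition — and otherwise works
at 600 × 400 (the simulator default) or smaller, with Monte-Carlo checks
at 50–100 replicates; these sizes make the statistical assertions stable
while keeping the whole suite fast enough to run habitually.

## Known limitations

* No sub-channel shift estimation or wavenumber recalibration model; the
  shift search is integer-valued.
* No deconvolution of overlapping analyte events within one time window:
  co-eluting analytes whose spectra correlate above `φ` merge into one
  signature.
* Block-independent background estimation can leave small discontinuities
  at block edges; these stay below the noise when the drift-per-window is
  small, but very fast shape drift calls for smaller `w_time` rather than
  post-hoc smoothing.
* The Gaussian tail model for p-values is a convenience; heavy-tailed
  detector noise will inflate the effective false-positive rate at fixed
  `β`, which the magnitude and length cutoffs partially absorb.
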