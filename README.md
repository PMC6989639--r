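# sersignal

Background removal and signal identification for time series of
surface-enhanced Raman scattering (SERS) spectra.

## The problem

SERS amplifies Raman scattering with plasmonic nanostructures, but the
enhancement comes with a large continuum background (substrate, solvent,
plasmonic emission) that dwarfs the analyte signals. In time-resolved
acquisitions — e.g. chromatography coupled to SERS, where a detector
records a spectrum of `W` frequency channels at each of `T` time points —
this background has two awkward properties: its overall strength changes
arbitrarily from one spectrum to the next, and its *shape* along the
frequency axis drifts slowly over the run. Classical baseline-correction
methods either smooth each spectrum independently (and fail on a
background that fluctuates sharply along frequency) or assume one fixed
background shape for the whole run (and fail when the shape drifts).
Analyte signals, meanwhile, are transient: a molecule's bumps appear on a
few consecutive spectra, intensify, fade, and vanish.

`sersignal` is for analysts of such `T x W` intensity matrices who want an
automated, statistically controlled route from raw spectra to a table of
analyte signature spectra matched across experiments.

## The method

Four stages, each exposed as an ordinary R function:

1. **Background removal** (`remove_background`). The matrix
   `X = (X_ij)_{T x W}` is tiled into time–frequency blocks (window sizes
   `w_T`, `w_F`; default 50 × 50). Within a block, each spectrum fragment
   `X*_i.` is scaled by its mean, `X'_i. = X*_i. / mean(X*_i.)`, and the
   block's background shape is the per-channel median
   `B_j = median_i X'_ij` — no smoothing along frequency, and the median
   ignores signals present in a minority of rows. Each row's projection
   profile `P_ij = X*_ij / B_j` is summarized by its `q`-th percentile
   `Q_i` (default `q = 40`), and the background is removed at original
   scale: `Y_i. = X*_i. − Q_i · B`.
2. **Signal detection** (`detect_signals`). Per corrected spectrum, the
   noise SD is the scaled median absolute value
   `σ̂_i = median_j |Y_ij| / Φ⁻¹(0.75)`; positive channels get Gaussian
   tail p-values `2Φ(−Y_ij/σ̂_i)`, converted to per-channel false
   discovery rates (Benjamini–Hochberg within the spectrum). A *bump* is a
   maximal run of channels with `Y_ij > α·σ̂_i` and `FDR < β`; a spectrum
   carries signal when some bump has length ≥ `γ` (defaults `α = 3`,
   `β = 0.05`, `γ = 3`; the length cutoff rejects single-channel cosmic
   rays).
3. **Merging** (`merge_signals`). Consecutive detections whose full
   spectra correlate above `φ` (default 0.9) belong to one analyte event;
   only the strongest spectrum (median |Y| over its bump support) survives
   as the event's *signature signal*.
4. **Cross-experiment matching** (`shifted_similarity`,
   `match_signatures`). Wavenumber miscalibration shifts signals by a few
   channels between experiments. The similarity of two signatures is the
   largest Pearson correlation over integer shifts in
   `[-max_shift, max_shift]` (default 10), computed on the *informative
   section* — the union of the two signals' occupied frequency ranges —
   rather than the full spectrum.

A seeded simulator (`simulate_spectra`, `shifted_replicate`) generates
SERS-like matrices with known ground truth, and `run_pipeline` plus the
`exec/sersignal` command-line interface orchestrate the whole workflow.

## Worked example

```r
library(sersignal)

# a 600 x 400 synthetic run: drifting background, lognormal per-spectrum
# strengths, three transient analytes at 6 noise-SDs, cosmic rays
sim <- simulate_spectra(simulation_config(seed = 3))

cs  <- remove_background(sim$spectra, w_time = 50, w_freq = 50, q = 40)
det <- detect_signals(cs, alpha = 3, beta = 0.05, gamma = 3)
det$detected_times
#> [1] 151 301 451

sigs <- merge_signals(cs, det, phi = 0.9)
as.data.frame(sigs)
#>   time_index                                                 support strength
#> 1        151           85-92;123-123;125-130;132-132;134-134;190-190 4.882439
#> 2        301 183-183;185-192;225-231;233-233;258-258;262-267;269-270 5.015293
#> 3        451                         138-138;185-185;309-317;355-365 5.221383
```

The three injected events (peaking at times 150–152, 300–302, 450–452)
are each recovered as one signature at the event's strongest time point;
the supports are the detected bump intervals (1-based closed channel
ranges) and the strength is the median corrected intensity over them.

Matching against a replicate of the same sample whose wavenumber axis is
miscalibrated by +5 channels:

```r
rep2  <- shifted_replicate(sim, shift = +5, seed = 11)
cs2   <- remove_background(rep2$spectra)
sigs2 <- merge_signals(cs2, detect_signals(cs2))
match_signatures(sigs, sigs2, max_shift = 10, min_similarity = 0.5)
#>   a_time b_time best_shift best_correlation correlation_at_zero   section
#> 1    301    301         -4            0.847               0.281  178-197;220-238;253-275
#> 2    151    151         -4            0.811               0.359  78-98;118-139;185-195
#> 3    451    451         -5            0.755               0.370  133-143;180-190;303-322;350-370
```

Every analyte is paired with its counterpart, the shift-searched
correlations (0.75–0.85) far exceed the naive unshifted ones (~0.3), and
the estimated shift is the applied −5 to within one channel — for signals
this close to the detection threshold the correlation argmax carries ±1
channel of noise jitter; stronger signals recover the shift exactly (see
the test suite).

Command-line equivalent:

```sh
sersignal simulate --output-prefix run1 --seed 3
sersignal remove-background --input run1_spectra.tsv --output run1_corr.tsv
sersignal detect --input run1_corr.tsv --output run1_det.tsv
sersignal merge --corrected run1_corr.tsv --detections run1_det.tsv --output run1_sigs.tsv
sersignal compare --signatures-a run1_sigs.tsv --signatures-b run2_sigs.tsv --output matches.tsv
```

## Documentation

The methods vignette (`vignettes/sersignal-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the simulator does and does not emulate, numerical edge
cases, and known limitations.
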