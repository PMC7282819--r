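---
title: "Optical quantal analysis with gluquant: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical quantal analysis with gluquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gluquant)
```

## The measurement problem

Surface-displayed glutamate sensors (iGluSnFR) turn single release events at
presynaptic boutons into brief, localized fluorescence transients. Two
acquisition designs cover the two release modes:

* **Evoked**: 150 frames at 10 ms/frame (100 Hz); a single field stimulus
  500 ms after the first frame. The question is *when* each release site's
  ΔF/F₀ peaks relative to the stimulus: peaks within 10 ms are counted as
  synchronous release, later peaks as asynchronous. The 10 ms boundary is
  closed (exactly 10 ms is synchronous) and — with 10 ms frames — equivalent
  to "the first post-stimulus frame holds the trace maximum".
* **Spontaneous**: 300 frames at 200 ms/frame (60 s) in TTX, where only
  action-potential-independent miniature glutamate transients (mGTs) remain.
  The question is the event *rate*.

Around the imaging pipeline sit an exponential-kinetics module (protein
cleavage/turnover curves, `value(t) = C + (A − C)e^{−t/τ}`, half-life
`τ·ln 2`), ordinary least squares for relating synchronous to spontaneous
release across conditions, and Costes-thresholded Pearson colocalization of
two-channel images.

## Evoked segmentation and classification

`detect_rois()` implements the projection-difference workflow: the average
of the 45 pre-stimulus frames (450 ms of baseline, a 50 ms guard before the
stimulus) is subtracted from the per-pixel maximum over all 150 frames;
the result is band-passed by subtracting a radius-10 circular mean filter
(edge-replicated); the band-passed image is thresholded; a binary watershed
(Euclidean distance transform, basins from its regional maxima, cut lines
between basins) splits touching sites; and 8-connected particles of at
least 10 px not touching the border become ROIs, with interior holes
filled. Three conventions are fixed deliberately:

* the *size* rule is `area ≥ 10 px` (at least, not strictly greater);
* the band-pass is a plain circular **mean** filter, not a rolling-ball
  background estimator — the mean filter is what the normative workflow
  executes;
* thresholding defaults to the deterministic **isodata** (iterative
  intermeans on a 256-bin histogram) rule rather than an interactive
  adjustment, with `method = "manual"` as the override. Because an
  intermeans threshold lands mid-distribution on a structureless (no-release)
  image, the automatic threshold is clamped from below at a robust noise
  floor, `median + 3·MAD` of the band-passed image (`noise_floor_mads`,
  settable to 0). On signal-bearing movies the isodata threshold sits well
  above this floor and the clamp is inert; on pure-noise movies it is what
  keeps the particle count at zero.

`extract_traces()` takes per-ROI mean intensities; `normalize_dff()` uses
the per-ROI mean of the 45 baseline frames as F₀ (no separate dark-region
background ROI — the workflow being reproduced measures only ROI means);
`detect_peaks()` takes one peak per ROI (the global trace maximum, ties to
the earliest frame) and classifies it by the 10 ms rule. Peak times are
frame-center times, so latencies are quantized to the frame grid.
Pre-stimulus peaks are reported but flagged, and excluded from the
synchronous fraction's denominator. `compare_groups()` wraps the
tie-corrected Kruskal–Wallis H with Dunn's mean-rank z statistics;
p values are Bonferroni-multiplied by default (`p_adjust = "holm"`
available).

## Spontaneous detection

`walking_average_subtract()` subtracts a trailing 4-frame running mean
(window inferred from the three leading frames the normative workflow
deletes; configurable), so a 300-frame movie yields 297 difference frames
and any static or spatially uniform background cancels exactly.

`detect_mgt_events()` replaces manual event counting. Candidates are
strict spatiotemporal local maxima (3×3×3) of the lightly smoothed
difference movie (Gaussian, σ = `spot_sigma_px`/1.5, at least 0.8 px).
An event's `peak_df` is the smoothed — spot-averaged — ΔF at the
candidate; its noise reference is the robust per-pixel temporal sd
(median over the local neighbourhood of per-pixel MADs of the *unsmoothed*
difference traces, frames around the candidate excluded); retention
requires `peak_df ≥ 4 × noise`. The asymmetry is the point: spot-averaging
suppresses pixel noise in the statistic while the reference preserves the
per-pixel noise scale, so under the null the statistic essentially never
reaches 4× the reference, and the detector's false-positive calibration
(< 0.5 events per FOV-minute) holds at the default threshold without
per-dataset tuning — while a true event with per-pixel SNR ≳ 8 clears it
comfortably. `background_roi_validation()` repeats each event's
measurement at an off-center position with the identical noise rule, which
is why a zero offset reproduces the event values exactly; the separation
statistic (minimum event SNR − maximum background SNR) is the detector's
validation criterion. Rates (`event_rate()`) are scaled to the *analyzed*
duration — the difference movie's 59.4 s, not the nominal 60 s — keeping
the Poisson rate estimator unbiased despite the deleted leading frames.

## What the simulator emulates

`sim_config()`/`simulate_evoked_movie()`/`simulate_spontaneous_movie()`
generate movies with known ground truth. Release sites are Gaussian spots
(σ = 2 px by default, roughly a 1 µm bouton imaged at ~0.1 µm/px) placed
by rejection sampling at ≥ 4σ separation with an edge margin. Evoked
latencies mix a truncated Gaussian synchronous component (mean 1.5 ms,
sd 0.5 ms — physiological action-potential-to-fusion delays) with an
exponential asynchronous component (mean 100 ms, resampled to peak inside
the recording) at probability `sync_fraction`; ground-truth labels always
re-apply the 10 ms rule to the *realized* latency, so a slow "synchronous"
draw is labelled asynchronous, exactly as the analysis would see it.

Three modelling choices deserve explanation:

* **Transient kinetics.** The optical impulse response is
  `(1 − e^{−t/rise})e^{−t/decay}`, normalized to unit peak, with defaults
  rise 1 ms, decay 15 ms. These are *effective, ROI-level* constants chosen
  so that frame-quantized peak times track release mode: with a decay much
  longer than the 10 ms exposure, the maximum frame would land one frame
  after stimulus regardless of latency and peak-timing classification
  could not reproduce the first-bin concentration of synchronous release
  that motivates the 10 ms rule. They are recorded in the config and
  carried through every analysis default, never hard-coded.
* **Amplitude convention.** `transient_amplitude_dff` is defined as the
  net *peak-frame* ΔF/F₀: the kernel is integrated over each exposure
  window and the per-event frame profile rescaled so its best frame equals
  the configured amplitude. This makes amplitude recovery exact by
  construction for an ideal ROI (the rescaling does not move the argmax
  frame, so timing statistics are unaffected) and makes the parameter
  directly comparable between the 10 ms and 200 ms protocols. The evoked
  default is 0.8; the spontaneous default is 0.05, which is what a
  ~15 ms transient amounts to after integration over a 200 ms exposure.
* **Noise.** Gaussian read noise of fixed sd (20 counts), independent of
  intensity — a read-noise-dominated camera; an intensity-scaled variant
  (`noise_model = "scaled"`) approximates shot noise. Baseline counts
  scale with the exposure (200 counts per 10 ms frame, 4000 per 200 ms
  frame: the same photon flux), so the evoked defaults give a per-pixel
  peak SNR of 8 and the spontaneous defaults an mGT SNR of 10.

What the simulator does **not** emulate: focal drift, axial structure,
photobleaching heterogeneity (a global mono-exponential bleach is
optional), vesicle-pool depletion, correlated (structured) noise, and
amplitude variability between events. Passing recovery tests therefore
demonstrates the pipeline's correctness under its stated model, not
robustness to every artifact of real recordings.

## Kinetics

`fit_single_exponential()` fits `C + (A − C)e^{−t/τ}` by
Levenberg–Marquardt least squares with a log-linear τ initialization, a
coarse multi-start grid (so single bad noise draws cannot strand the
optimizer), a direct-SSE fallback, and τ constrained positive;
convergence tolerance is 1e-8 on parameters. The plateau floats by
default — turnover curves of long-lived proteins genuinely asymptote above
zero — with `fix_plateau_to_zero = TRUE` for cleavage curves that run to
completion; fixing the plateau when it is truly zero roughly halves the
median τ error on short noisy series. Increasing series are refused
unless `allow_increasing = TRUE`, flat series are rejected as
non-identifiable, and `t_half` is `τ·ln 2` by identity (the reporting
helper rounds minutes to the integer, matching how half-lives are usually
printed; raw values are always retained). For slow turnover sampled over a
finite window (τ ≈ 4 days observed for ~11 days), a single noisy curve
constrains the plateau poorly; the tests fit the mean of three replicate
curves — as the emulated experiments do — under which the fitted plateau
stays clearly positive in ≥ 95% of replicates.

## Colocalization

`costes_threshold()` regresses channel 2 on channel 1 by orthogonal
(major-axis) regression and scans 256 candidate levels downward from the
channel-1 maximum; the threshold is the largest level at which the
below-threshold pixels (in both channels, under the regression line) are
uncorrelated or anticorrelated. Perfectly correlated noiseless channels
never decorrelate below threshold, so the thresholds fall to the channel
minima with a warning. `pcc_costes()` reports the global Pearson
coefficient and the coefficient over pixels above threshold in *either*
channel (an AND variant behind `rule = "both"`); results with fewer than
10 above-threshold pixels are flagged unreliable. Note that major-axis
regression is not equivariant under affine rescaling of a single channel,
so the thresholded coefficient is only approximately invariant to one-sided
gain changes (the global coefficient is exactly invariant).
`coloc_rectangles()` mirrors the practice of measuring a handful of
randomly placed rectangular regions: a seeded sampler with per-rectangle
and pooled results.

## Rendering and pipeline

`time_projection()` maps each pixel's time-of-maximum (background
subtracted) linearly onto an HSV hue ramp from red (window start) to
purple (hue 0.8, window end), scales brightness by the maximum's amplitude
and blacks out pixels below a noise floor (default 4× the MAD of the
windowed data). Presets: evoked renderings use ΔF/F₀ over 100 ms
post-stimulus; spontaneous renderings the full 60 s of ΔF.
`run_pipeline()` exposes the subcommands (`simulate`, `detect-evoked`,
`detect-spontaneous`, `fit-kinetics`, `coloc`, `render`); every run
writes its outputs, a JSON run log, and a flat key/value echo of the full
effective configuration, so any output directory is reproducible from the
embedded config and seed. Movies travel as 16-bit multi-page TIFF
(intensities rounded to integer counts, which is what makes write-then-read
round trips exact for count-valued data).

## Numerical choices and degenerate inputs

* Frame times are frame centers; the first frame covers `[0, dt)`.
* Isodata runs on a 256-bin histogram; the fixed point is compared against
  a direct value-iteration oracle in the tests (agreement within a bin).
* The watershed cut removes foreground pixels adjacent (8-neighbourhood)
  to a basin with a smaller label, which guarantees split basins are not
  8-connected while leaving single-maximum objects untouched.
* Labeling is 8-connected (diagonal-merged 4-connected components),
  ids assigned in storage (column-major) raster order of first pixel.
* Peak ties break toward the earliest frame; histogram bins are half-open
  `[edge, edge + 10)`.
* Empty inputs (no ROIs, no events, empty masks) propagate as empty
  results, not errors; undefined statistics (synchronous fraction with no
  post-stimulus peaks, correlation of a constant channel) return `NA` with
  a warning.

## Validation surface and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) runs: ROI precision/recall on a default
128×128/64-bouton movie; synchronous-fraction recovery pooled over ~18
movies (≥ 1000 events, `sync_fraction = 0.8`), compared with the realized
ground-truth fraction; τ = 41 min recovery over 200 noisy 8-point curves;
Poisson rate recovery at 0.2, 1 and 5 events/bouton/min (50, 50 and 12
movies; the high-rate arm uses few sites because two events at one site
within one 200 ms frame are physically one blob — an irreducible ~4%
pile-up loss at 5/min that the sampling error must dominate); a 2.4-fold
two-condition contrast at 15 movies/condition; 100 pure-noise movies for
the false-positive calibration; 1000 null Kruskal–Wallis simulations; the
small-instance oracle equivalences (flood-fill labeling, direct
neighbourhood sums, isodata fixed point, exhaustive Costes scan, rank-sum
H); and the colocalization monotonicity sweep. These sizes were chosen to
keep each statistical check's known systematic bias at or below half its
sampling error.

## Known limitations

* One peak per ROI per trial: multi-vesicular or train-stimulus responses
  are out of scope.
* The latency quantization means sub-frame latency structure is invisible;
  classification fidelity depends on the transient decaying on the frame
  timescale.
* The mGT detector reports spot-averaged ΔF, which understates the true
  center-pixel amplitude by the smoothing attenuation (~30% at the
  defaults); comparisons between conditions are unaffected.
* Costes thresholds on nearly-uncorrelated channels are poorly determined
  (a warning fires below r² = 0.1).
* Rates assume detection operates far from its threshold; near SNR 4 the
  estimator inherits the detector's miss rate.
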