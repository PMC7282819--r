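# gluquant

Optical quantal analysis of glutamate release from fluorescence time-lapse
imaging.

`gluquant` is an R toolkit for analysing recordings made with
surface-displayed fluorescent glutamate sensors (iGluSnFR) in dissociated
neuronal cultures, where single release events appear as brief, localized
fluorescence transients. It targets the two standard acquisition designs:

- **Evoked recordings** — 150 frames at 10 ms/frame with a single field
  stimulus 500 ms after the first frame. The pipeline segments putative
  release sites (ROIs), extracts ΔF/F₀ traces, finds each ROI's peak, and
  classifies release as *synchronous* (peak ≤ 10 ms after the stimulus) or
  *asynchronous* (peak > 10 ms), with 10 ms latency histograms and
  Kruskal–Wallis/Dunn group comparisons.
- **Spontaneous (TTX) recordings** — 300 frames at 200 ms/frame. A
  walking-average difference movie isolates miniature glutamate transients
  (mGTs); an SNR-thresholded detector replaces manual counting and is
  validated by off-center background ROIs (amplitude-vs-SNR separation).

Around these sit three supporting analyses: single-exponential-with-plateau
fits of protein cleavage/turnover time courses
(`value(t) = C + (A − C)·e^(−t/τ)`, with `t½ = τ·ln 2`), ordinary linear
regression for relating synchronous to spontaneous release, and
Costes-thresholded Pearson colocalization of two-channel images. A
synthetic-data generator produces movies, decay tables and channel pairs
with known ground truth (bouton positions, event times and classes,
amplitudes, noise), so every stage is validated by parameter recovery.

## ROI segmentation in one line

The evoked segmentation follows the classic projection-difference recipe:
maximum projection minus pre-stimulus average projection, band-passed by a
radius-10 circular mean filter, auto-thresholded (isodata), split by a
binary watershed, and filtered to interior particles of ≥ 10 px.

## Worked example

```r
library(gluquant)

# simulate a default evoked experiment: 128x128 px, 64 boutons,
# single stimulus at 500 ms, peak dF/F0 0.8, read noise 20 counts
sim  <- simulate_evoked_movie(sim_config("evoked", seed = 7))
rois <- detect_rois(sim$movie)
rois
#> <glu_rois> 61 ROIs in a 128 x 128 label image
#>   threshold 27.97 (isodata)

traces <- normalize_dff(extract_traces(sim$movie, rois), baseline_frame_count = 45)
peaks  <- detect_peaks(traces)
synchronous_fraction(peaks)
#> [1] 0.9344262
# ground truth for comparison:
mean(subset(sim$events, event_time_ms >= 500)$latency_class == "synchronous")
#> [1] 0.9344262

fit <- fit_single_exponential(
  simulate_decay_series(41, 1, 0, seq(0, 280, 40), noise_sd = 0.02, seed = 1))
fit
#> Single-exponential decay fit
#>   amplitude A = 0.988, plateau C = 0.00694
#>   tau = 40.82, t1/2 = 28.29 (tau * ln 2)
#>   R^2 = 0.9979 on 8 points
```

The printed numbers mean: 61 of the 64 simulated boutons released and were
segmented (the threshold chosen by the isodata rule is echoed for the run
log); 93.4% of detected ΔF/F₀ peaks fell within 10 ms of the stimulus,
matching the simulated ground truth exactly; and a noisy τ = 41 min decay
is recovered with τ̂ = 40.8 min, i.e. a half-life of ~28 min.

A command-line wrapper over the same functions is installed at
`inst/scripts/gluquant-cli.R`
(`Rscript gluquant-cli.R simulate --out dir --seed 7`, then
`detect-evoked`, `detect-spontaneous`, `fit-kinetics`, `coloc`, `render`).

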