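# coralrhythm

`coralrhythm` extracts behavioral activity rhythms of a sessile deep-sea
coral colony from time-lapse imagery and analyses them jointly with
oceanographic records. It is aimed at observatory ecologists and
biological-imaging engineers who have (a) a fixed camera producing hourly
frames of one colony and (b) co-located sensor readings, and who want
per-frame surface-coverage percentages of the colony's activity statuses —
**bloated** (polyps extruded, the filter-feeding posture), **semi-bloated**
and **non-bloated** — plus the chronobiological and multivariate statistics
that turn those series into biology.

## What it computes

**Imaging → coverage series.** Frames are enhanced with CLAHE applied to
the CIELAB luminance only (hue is preserved because color carries the
segmentation signal), the coral foreground is extracted with an HSV red-hue
mask refined by a 3×3 binary median filter, and a patch classifier labels
every 30×30 window of the frame on a stride-10 grid. The classifier is a
six-convolution CNN (3×3 kernels; blocks of 32-32, 64-64, 128-128 channels
with 2×2 max-pooling and dropout; dense 512; 4-way softmax over the three
statuses plus background), trained with Adam (lr 1e-4, β₁ 0.9, β₂ 0.999,
batch 256) on 30×30 patches centered on labeled pixels — 120 foreground and
40 background pixels sampled per tagged rectangular section. Overlapping
windows are combined per grid cell by averaging softmax vectors; coverage
percentages are taken over coral cells, so bloated + semi + non = 100.

**Chronobiology.** The coverage series are scanned with a floating-mean
Lomb–Scargle periodogram over the 600–1620 min band (power as % variance
explained, Baluev false-alarm significance at α = 0.05), and folded into
24-h waveforms whose MESOR (the re-average of the hourly means) defines the
rhythm's phase as the contiguous above-MESOR hours.

**Multivariate model.** Bloated coverage binarized at 50% is modeled from
seven predictors (time of day, chlorophyll, temperature, depth, turbidity,
salinity, and a binary field-of-view dummy) expanded into all unique
monomials of degree ≤ 3 (119 for seven columns), with the feature count
chosen by cross-validated RMS error, a Kennard–Stone Euclidean 70/30
partition, and a 9-node sigmoid/softmax network trained with
Bayesian-regularized backpropagation. Post-hoc, feature importance is the
column-max of |hidden weights| and sigmoid activation profiles correlate
each covariate with the sorted coverage curve.

Raw observatory imagery of this kind is not publicly deposited, so the
package includes a ground-truthed synthetic-fixture generator (coral-like
scenes whose textures differ by status, and rhythmic multiparametric series
with a dusk-peaking 24-h rhythm, a 745-min tidal depth cycle, noise and
sensor gaps) against which every stage is tested.

## Worked example

```r
library(coralrhythm)

# 1. a ground-truthed synthetic scene
spec <- sceneSpec(160, 160, regions = list(
  list(rect = c(11, 11, 80, 80),  status = "bloated"),
  list(rect = c(90, 11, 150, 70), status = "non_bloated"),
  list(rect = c(11, 95, 70, 150), status = "semi_bloated")), seed = 3)
scene <- generateColonyImage(spec)

# 2. segmentation mask quality against the ground truth
mask <- medianFilterMask(hsvRedMask(scene$image))
fg <- statusGrid(scene$truth) > 0
sum(mask == 1 & fg) / sum(fg)
#> mask recall on true foreground: 0.999

# 3. a rhythmic series and its periodogram + waveform
series <- generateActivitySeries(seriesSpec(nHours = 720, rhythmAmplitude = 15,
                                            noiseSd = 5, seed = 11))
d <- seriesData(series)
lombScargle(d$timestamp, d$bloated_pct)
#> PeriodogramResult: 1021 periods in [600, 1620] min, n = 720
#>   top significant peak: 1441 min (82.0% variance, p = 0)
wf <- waveformAnalysis(d$timestamp, d$bloated_pct)
wf
#> WaveformResult: 24 bins of 60 min, MESOR 50.179
#>   above-MESOR hours: 0 1 2 3 16 17 18 19 20 21 22 23
phaseIntervals(wf)
#>   start_hour end_hour n_hours singleton
#> 1         16        3      12     FALSE
```

The injected 24-h rhythm (period 1440 min, dusk peak at 21:30) is recovered
as the top significant peak at 1441 min explaining 82% of the variance, and
the waveform phase is a single contiguous block wrapping midnight
(16:00–03:00) around the dusk peak — the daily signature of filter-feeding
behavior this pipeline is built to detect.

The full image-to-series chain (simulate → enhance → tag-sample →
build-patches → train → evaluate → map → compile → periodogram → waveform →
mlfn) runs behind one entry point:

```r
cfg <- readPipelineConfig()          # defaults; YAML file optional
cfg$paths$output_dir <- "out"
runStage("simulate", cfg); runStage("enhance", cfg)  # ... and so on
```

or from a shell via the installed script:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/coralrhythm", package="coralrhythm"))') simulate --seed 7
```

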