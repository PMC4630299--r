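# mitomotion

Automated quantification of fast mitochondrial transport in time-lapse
fluorescence movies of neurons.

Mitochondria in MitoTracker-labeled neurites are almost all stationary;
a small fraction (~0.3–2%) is carried by microtubule motors at roughly
0.1–1.5 μm/s. Measuring that minority motion across the dozens of movies
produced by a high-content imaging screen is impractical by hand.
`mitomotion` implements a fully automated analysis chain for this problem,
together with a seeded synthetic-movie simulator with known ground truth so
every stage can be validated end to end without microscope data.

## What it computes

Two independent motion estimators run on the same pre-conditioned movies
(spatial binning ×4, rigid-body registration, quintic B-spline temporal
stretching ×2):

**Dense Lucas–Kanade optical flow.** For every pixel, gradients
(I_x, I_y, I_t) are taken with separable Gaussian-derivative filters
(Σ_s = Σ_t = 2), and the window-weighted structure tensor

    G = Σ w² [ I_x²  I_xI_y ;  I_xI_y  I_y² ],   b = −Σ w² [ I_xI_t ; I_yI_t ]

is accumulated over a Gaussian window (Σ_w = 0.3). Where the smaller
eigenvalue of G reaches the noise gate τ = 0.02 the flow v = G⁻¹b (px/frame)
is emitted; everywhere else the pixel reports no flow. Speeds |v| are
log-transformed and binned (140 natural-log bins over −10..4, i.e.
0.000045–54.6 px/frame ≙ up to 13.5 μm/s at 0.432 μm/px and 1.75 s/frame)
into per-time-point histograms — the *velocity histogram montage*. After
per-time normalization, a running standard deviation over three adjacent
time points flags and removes frames corrupted by illumination flicker or
residual stage drift. The headline statistic per movie is the *flow ratio*:
the fraction of above-gate measurements faster than 0.25 μm/s.

**Difference tracker.** A temporal difference filter (minimum difference 20,
frame offset 4 on 8-bit movies; implied speed floor 0.06 μm/s) isolates
moving pixels and tallies static/moving intensity and object counts. A mass
particle tracker then links bright features (≥ 2 px, ≥ 20 total intensity)
into tracks by greedy, priority-ordered nearest-neighbor assignment with a
constant-velocity prediction, and reports track counts, durations and
speeds.

Screen-level inference pools control wells and compares every treated well
against them with Dunnett's many-to-one simultaneous 95% confidence
intervals (one-way ANOVA residual variance), plus Welch t-tests for paired
comparisons.

## Worked example

```r
library(mitomotion)

# a synthetic neurite field: 100 stationary puncta, 2 movers (0.3 and 0.5 um/s)
sc  <- make_scene_movie(scene_config(image_size = c(160, 160), n_frames = 50,
                                     n_stationary = 100, n_moving = 2, seed = 9))
cfg <- screen_config(bin_factor = 1, register = FALSE)  # scene is already at the binned scale
pre <- preprocess_movie(sc$movie, cfg)                  # stretch x2 -> 100 frames
fl  <- analyze_flow(pre, cfg, "demo")                   # LK flow -> montage -> mask -> ratios
tr  <- analyze_tracks(pre, cfg)                         # difference filter -> tracks

100 * mean(fl$ratios, na.rm = TRUE)       # 0.848  : % of flow faster than 0.25 um/s
sum(fl$mask)                              # 87 (of 88 time points retained by the artifact mask)
tr$report$total_track_count               # 12     : tracks (movers split at pauses, plus
                                          #          short jitter tracks, as on real data)
tr$report$intensity_percentage_moving     # 2.15   : % of intensity classified moving
tr$report$average_speed_per_track         # 0.50   : um/s
```

The flow ratio (~0.85%) and the tracker's moving percentage (~2%) are the
two per-well statistics a screen aggregates: `run_screen()` maps them over
a plate manifest and `pooled_dunnett()` flags treated wells whose ratio
drops significantly below the pooled controls. A ready-to-use command line
sits in `inst/cli/mitomotion.R` (subcommands `simulate`, `preprocess`,
`flow`, `track`, `run-screen`).

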