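---
title: "Measuring fast mitochondrial transport: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fast mitochondrial transport: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitomotion` quantifies microtubule-motor-driven ("fast") transport of
mitochondria in single-channel time-lapse fluorescence movies. This
vignette explains the underlying models, why the defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design decisions taken where more than one reasonable implementation
exists.

## The measurement problem

In MitoTracker-labeled neurites, 95–99% of mitochondria are essentially
stationary; the transported minority moves at roughly 0.1–1.5 μm/s in runs
interrupted by pauses. In a movie of 50 frames at 3.5-s intervals a single
transported mitochondrion changes the intensity of only a few dozen pixels
per frame out of tens of thousands. The package therefore measures motion
two independent ways — a dense optical-flow estimator that sees *all*
motion, and a particle tracker that only accepts *persistent* motion — and
aggregates both into per-well statistics for screen-level inference.

## Movie pre-conditioning

All analysis operates on movies conditioned as follows (all steps are
`Movie -> Movie` operations that append to a replayable history):

1. **Spatial binning ×4** (block average). At the 0.108 μm/px camera scale
   a mitochondrion is only ~10 px across but moves many pixels per frame;
   binning to 0.432 μm/px brings frame-to-frame displacements into the
   sub-pixel-to-few-pixel regime where differential flow estimation works,
   and averages read noise down fourfold.
2. **Rigid-body registration** to frame 1. Translation is initialized by
   FFT cross-correlation and (dx, dy, θ) are refined by Nelder–Mead on the
   mean-squared intensity difference over a 10%-margin central region,
   with bilinear resampling. The registration model is global and rigid:
   it removes stage motion, not biological motion. Recovery on synthetic
   drift is ≤ 0.25 px and ≤ 0.2° (test suite).
3. **Temporal stretching ×2** by quintic B-spline interpolation, so a
   mover at 0.4 μm/s advances ~1.6 px per (stretched) frame. Output frame
   j samples input time 1 + (j−1)/2 (edge-clamped), giving 2T frames with
   originals at odd indices. Spline coefficients solve the banded
   interpolation system with linear-extrapolation boundary conditions, so
   constants and linear trends are reproduced exactly everywhere and
   degree-≤5 polynomials in the interior; no installed package provides
   degree-5 series interpolation, so this primitive is implemented here
   and validated against closed forms.
4. For the tracker branch only: centered crop and stack-wide conversion to
   8-bit (percentile stretch saturating 5% of pixels). See "contrast
   enhancement" below.

Calibration bookkeeping is centralized: `velocity_umps()` converts px/frame
to μm/s through `pixel_size × bin_factor` and `interval / time_stretch`
only, so a mover simulated in μm/s round-trips through any combination of
binning and stretching.

## Dense Lucas–Kanade flow and the noise gate

Gradients are separable Gaussian derivatives with Σ_s = Σ_t = 2 (px,
frames); kernels truncate at ceil(3σ). Equal spatial and temporal scales
matter: with Σ_s ≠ Σ_t the flow-field intensity is no longer linearly
related to velocity, and `lk_params()` warns accordingly. Frames within
ceil(3Σ_t) = 6 of either end have no full kernel support and produce no
flow field, which is why a 100-frame stretched movie yields 88 usable time
points.

Per pixel, the structure tensor `G = Σ w²[Ix², IxIy; IxIy, Iy²]` and
`b = −Σ w²[IxIt; IyIt]` are accumulated over a squared-Gaussian window of
scale Σ_w = 0.3 px on an odd square of half-width max(1, ceil(3Σ_w))
(3×3 at the default). If the smaller eigenvalue of G (closed-form 2×2
eigendecomposition; no iterative solver) is at least τ = 0.02, the flow is
the closed-form solution of Gv = b; otherwise the pixel reports zero flow
and is marked invalid. A "normal flow" branch for pixels where only the
larger eigenvalue passes exists behind `lk_params(normal_flow = TRUE)` but
is off by default: empty regions should produce *no* output.

Two consequences of this gate are worth stating explicitly:

* **τ is an intensity-squared quantity.** Eigenvalues of G scale with the
  square of the image gradients, so τ = 0.02 is only meaningful relative
  to an intensity scale. The package's operating point is calibrated for
  camera-count-scale data (hundreds to thousands of counts): there,
  smoothed background noise yields eigenvalues orders of magnitude below
  0.02 (noise-only movies produce exactly zero valid pixels, a property
  test), while structured objects pass easily.
* **The calibration procedure is automated.** `parameter_sweep()` scans
  Σ_w over 0.1–1 and τ over 20 consecutive doublings from 10⁻⁵ (largest
  value 5.24) on a small movie with user-nominated foreground and
  background ROIs; `select_parameters()` picks the smallest Σ_w that
  produces foreground flow and then the largest τ that fully suppresses
  the background while retaining it. On synthetic scenes this lands on
  (0.3, ~0.02–0.04), bracketing the default operating point.

Known bias: as a differential method, LK underestimates larger
displacements. On movers at ~1–1.5 px/frame the recovered run-mean is
~0.82–0.9 of truth while the histogram mode is nearly unbiased; both are
checked in the acceptance suite.

## Velocity histograms, the artifact mask and flow tables

Above-gate speeds are natural-log transformed (zeros are treated as
missing, never binned) and histogrammed into 140 uniform bins over −10..4;
the bin width is 0.1 and the bounds correspond to 0.000045–54.6 px/frame.
Natural log is used because those printed speed bounds equal e⁻¹⁰ and e⁴.
Row t of the *velocity histogram montage* is the histogram of frame t;
before normalization each row sums to that frame's above-gate pixel count
(a conservation test).

Normalizing each row by its own mean factors out the total mitochondrial
content, leaving the velocity *profile*. Because acquisition is fast
(1.75 s effective) relative to biology, adjacent profiles should be nearly
identical; a sudden global change means the illumination flickered or the
stage moved. The artifact score of time point t is the binwise population
SD over rows {t−1, t, t+1} summed over bins (2-point windows at the ends).
The retention rule rejects scores above median + 3×MAD (SD-consistent
MAD), with a 40% rejection cap — beyond the cap the sample is flagged
failed rather than silently truncated, since a mask that removes half a
movie is evidence of a broken acquisition, not of artifacts.

The per-time *flow ratio* is the fraction of above-gate measurements at or
above 0.25 μm/s; the threshold maps to the nearest histogram bin edge not
below it so the statistic is reproducible across calibrations. Gated
(zero-flow) pixels are excluded from the denominator entirely, consistent
with zeros-as-missing; this choice is recorded here because the
alternative (counting them) would shrink all ratios by a constant scene-
dependent factor without changing treated/control contrasts. Flow tables
assemble the ratio series of many wells column-wise with NA at masked
rows.

## The difference tracker

The difference filter classifies pixel (t, y, x) as moving when the
absolute difference to the frame 4 earlier *or* later (max over the
offsets that exist; one-sided at the ends) is ≥ 20 on the 8-bit scale —
an implied floor of one pixel per 7 s, 0.06 μm/s. Moving pixels keep
their intensity; everything else is zeroed. Static/moving object counts
are 8-connected components of pixels at or above the tracked-intensity
floor within each partition (the published table does not define these
counts precisely; component counting is our documented interpretation,
recorded in the report metadata). Connected-component labeling is a
vectorized min-label propagation validated against a flood-fill oracle.

The mass particle tracker then links features (8-connected components,
area ≥ 2 px, total intensity ≥ 20, intensity-weighted centroids) greedily:
longer tracks claim features first (ties: lower id), an established track
searches within 5 px of its constant-velocity prediction (velocity = last
step only), a 1-frame-old track within 10 px of its seed; each feature
joins at most one track, unclaimed features seed tracks, empty-handed
tracks terminate, and tracks shorter than 4 frames are discarded. Greedy
priority linking is the published rule — on well-separated movers it
coincides with the exhaustive optimal assignment (tested); the id
tie-break is ours, for determinism. Speeds convert to μm/s through the
movie's effective calibration, including the temporal stretch.

### Contrast enhancement and why the tracker branch skips equalization

`enhance_contrast_8bit()` implements the full published chain: stack-wide
percentile stretch plus histogram equalization (with √-count damping, as
ImageJ's equalizer uses) and 8-bit conversion. Percentiles and the
equalization map are computed over the whole stack, not per frame, so
global flicker is preserved for the artifact mask to catch rather than
silently normalized away. However, the default tracker branch
(`analyze_tracks()`) applies the stretch *without* equalization: on
spots-on-plain-background scenes the background mode dominates the
histogram, and equalization spreads it across the 8-bit range, pushing
pure background noise over the minimum-difference threshold (three
quarters of all pixels classify as moving). On real neurite images, whose
histograms are broad, equalization is harmless; on the synthetic scenes
this package must run on, it is not. The op remains available and tested.

## Screen statistics

The published analysis pools control wells and compares each treated well
against the pool with Dunnett's many-to-one test. `pooled_dunnett()` fits
a one-way ANOVA over (pooled control, treated₁, …, treatedₖ) with the
retained per-time-point flow ratios as observations within each well, and
computes two-sided simultaneous 95% CIs via the equicorrelated
multivariate-t machinery (`multcomp::glht`); a well is significant iff its
CI excludes 0. Observations within a well are time points — this is the
published design and the only one that yields per-treated-well intervals;
time points are never pooled *across* treated wells as independent
replicates. The multivariate-t quantile is evaluated by quasi-Monte-Carlo,
so the RNG is pinned locally to make identical inputs give identical
intervals. Calibration is verified by simulation: under the global null
the family-wise error over 1000 seeded replicates sits in [0.03, 0.07].
Paired pre/post comparisons use the Welch t-test (the published variant is
unstated; unequal variances are the safe default).

## The synthetic-movie generator

`scene_config()`/`make_scene_movie()` emulate the binned acquisition scale
directly: 0.432 μm/px, 3.5-s frames, isotropic Gaussian puncta of σ 1.5 px
(~0.65 μm, matching the feature size the trackers are tuned to), peak
amplitude 3000 counts over a 400-count background. Movers follow
piecewise-constant-velocity run/pause schedules (default: runs over
frames 1–30% and 50–80% of the movie — run lengths of tens of seconds);
stationary puncta wobble with per-frame sub-pixel jitter. Noise is shot
noise (Poisson, scale 1/16 — 4×4 binning averages 16 camera pixels) plus
Gaussian read noise (sd 8 counts). Defaults were fixed once against the
stated study conditions: with them, empty background produces exactly zero
above-gate flow at τ = 0.02, and stationary puncta are "essentially
stationary" to the difference filter (jitter sd 0.03 px ≈ 13 nm; larger
wobble makes the stationary population visibly "move" to a 0.06 μm/s-floor
detector, contradicting the 95–99%-stationary regime being modeled).
Determinism is part of the contract: identical (config, seed) gives
byte-identical stacks.

What the generator does *not* emulate — and what passing tests therefore
do not show — matters for interpretation. Real neurites are dense,
elongated, partially out-of-focus structures with heterogeneous
brightness; the simulator renders isolated round puncta on a flat
background. Two consequences:

* Absolute statistics differ from real data. Most importantly, a bright
  isolated Gaussian punctum passes the eigenvalue gate over essentially
  its whole footprint (~70–80 px; the gate radius depends only
  logarithmically on amplitude), whereas a dim extended mitochondrion in
  real images passes over only ~6–10 px. The flow-ratio denominator per
  stationary object is therefore ~8× larger on synthetic scenes, and the
  flow-based percent-moving (~1.3% here) sits *below* the tracker's
  moving percentage (~4%) — the reverse of the real-data ordering (~2.1%
  vs ~0.4%, a 5× gap). The ratio of the two estimators is a geometry
  property, not an implementation one; relative treated/control effects,
  which is what screens measure, are unaffected (both estimators recover
  the simulated 50% mover reduction at 44–54%).
* Photobleaching, focus drift and 3-D motion are out of scope; the
  artifact model covers global flicker, rigid drift and transient
  defocus only.

## Numerical choices and degenerate inputs

* Convolution boundaries are replicate (clamp-to-edge) everywhere;
  drift injection uses replicate fill so no dark seams masquerade as
  motion.
* Binning of non-divisible sizes trims trailing rows/columns first;
  centered crops with odd remainders remove the extra pixel from the
  right/bottom. Coordinates are 1-based (row = y down, col = x right),
  matching R matrix indexing.
* Singular structure tensors above τ (numerically zero determinant) are
  treated as gated, not inverted.
* Constant movies: contrast enhancement returns mid-gray with a warning;
  registration refuses all-zero frames with an error naming the frame.
* Plateau maxima count once in `count_maxima()`; a candidate is subsumed
  when its tolerance flood reaches higher ground, a previously claimed
  region, or when its prominence over the image floor is below tolerance.
* Zero control denominators in ratio reports give NA with a warning, not
  an exception.

## Problem sizes

The shipped tests and the acceptance script use scenes of 128–192 px and
30–60 frames, screens of 8 wells, and 1000 Monte-Carlo replicates for the
Dunnett calibration; these sizes make the full validation run in minutes
on a single CPU while every quantity they check is scale-free (ratios,
rates, error fractions). The pipeline itself has no size assumptions
beyond memory; `run_screen()` processes movies at roughly one frame per
second per branch, writes all intermediates, isolates per-movie failures,
and reproduces its CSV outputs bit-identically for a fixed manifest,
configuration and seed.
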