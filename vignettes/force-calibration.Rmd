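---
title: "Trajectory-based femtonewton force calibration for magnetic nanoparticle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-based femtonewton force calibration for magnetic nanoparticle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmnptrack)
```

## The measurement problem

Fluorescent magnetic nanoparticles (FMNPs) bound to membrane molecules serve
a double purpose: they are bright single-particle-tracking (SPT) labels, and
they are force handles. When a magnetized needle is brought near the sample,
each particle acquires a small directed velocity towards the tip on top of
its Brownian motion in the membrane. The forces involved are in the
femtonewton range — far below what an optical trap resolves, and far below
the piconewton scale that would rupture biomolecular bonds — so the force
cannot be measured by any static deflection. It can, however, be read out of
the trajectory itself.

A membrane-bound particle is overdamped: its velocity response to a constant
force is `v = F / gamma`, with `gamma` the drag coefficient. The Einstein
relation `D = kB*T / gamma` eliminates the unmeasurable drag and leaves

```
F = kB * T * v_x / D
```

where `v_x` is the drift velocity in the pull direction and `D` the
diffusion coefficient of the same particle. Both are observable in a single
trajectory: `v_x` from the directed displacement towards the tip, and `D`
from the fluctuations **perpendicular** to the pull, which the force does
not contaminate. With `v_x` in um/s and `D` in um^2/s, `kB*T` is
conveniently `~4.11 fN um` at 298 K (see `kBT_fN_um()`), so a particle
drifting at `0.1 um/s` while diffusing at `0.1 um^2/s` experiences ~4 fN.

The package implements this estimator together with everything needed to
validate it end to end without experimental data: a drift–diffusion
simulator with a configurable needle force field, a synthetic camera,
sub-pixel localization and linking, MSD-based diffusion analysis with the
standard mobility filters, log-normal diffusion statistics, and
fiducial-based similarity registration.

## The force estimator

`trackset_forces()` cuts each trajectory into sliding windows (default 50
frames advanced by 25, i.e. 50% overlap; both configurable and recorded in
all outputs). For each window, `needle_frame()` rotates coordinates so that
+x points from the window centroid towards the tip, and `window_force()`
computes

* `v_x`: the ordinary-least-squares slope of the tip-directed coordinate
  against time;
* `D_perp`: the lag-1 perpendicular mean squared step over `2*dt`;
* `F_x = kB*T*v_x / D_perp`, in fN, positive towards the tip.

Each window also carries `d_x`, its mean Euclidean distance to the tip, so
that `force_distance_profile()` can bin forces by distance.
`per_track_force()` averages a track's windows (unweighted), and
`ensemble_force_stats()` gives the mean ± s.d. across tracks.

Design choices that were genuinely open, and how they were resolved:

* **Which D enters the force?** The per-window perpendicular estimate is
  used by default: it is local in time, uses the same data as `v_x`, and is
  immune to the drift itself. A per-track D can be substituted by the caller
  (all functions take plain columns), but is not the default.
* **Tip direction per window.** The pull axis is recomputed for each window
  from its centroid. Far from the tip this is effectively a constant
  direction; near the tip it follows the curvature of converging pulls.
* **`d_x`.** The full Euclidean distance to the tip, averaged over the
  window. The projection onto the pull axis differs only at second order
  for the nearly straight magnet-on tracks the profile is built from.
* **Localization-noise correction.** Camera noise inflates `D_perp` by
  `sigma_loc^2/dt`. The correction is implemented (`sigma_loc` argument of
  `window_force()`) but **off by default**, because the standard analysis
  applies none and at 10 nm noise and 0.1 s frames it shifts `D` by under
  1%.

### Known estimator bias

`F_x` divides by an estimated diffusion coefficient. With `n` perpendicular
steps per window, `E[1/D_hat] = n/(n-2) / D`, so a 50-frame window carries
a known `+4%` multiplicative bias, partly offset by the (uncorrected)
localization-noise inflation of `D_hat`. The per-window force distribution
is correspondingly heavy-tailed; per-track averaging of overlapping windows
tames most of it. The consistency tests in the suite bound the total bias
well below 10% at forces of 5–30 fN; users needing unbiased absolute forces
at the percent level should enlarge the window or pool `D` across windows.

## The simulator defines the validation conditions

`simulate_tracks()` integrates the overdamped Langevin equation with
Euler–Maruyama steps at the frame interval:

```
r(t+dt) = r(t) + F(r) * D_drift/(kB*T) * dt + sqrt(2*D*dt) * xi
```

with `xi` standard bivariate normal, the force evaluated at the step start
(the field varies slowly over a single step at these scales), and
independent `N(0, sigma_loc^2)` noise added per axis to the **reported**
positions only — the camera observes the path, it does not perturb it.
Tracks that leave the arena are truncated, not reflected, mimicking
particles leaving the field of view.

Defaults are the membrane-diffusion regime the package targets: `D = 0.13
um^2/s` (lipid-bound particles on a supported bilayer), 50 Hz frames,
`sigma_loc = 10 nm`, and room temperature (298 K). Force-calibration
simulations in the tests use 0.1 s frames and 500-frame tracks, matching
the slower acquisition used for calibration experiments, with ensembles of
100 pulled tracks and 178 null tracks — sizes chosen to match the scale of
a realistic calibration data set while keeping the whole suite fast.

The needle field is `F(d) = F0 * (d0/d)^p` pointing at the tip
(`force_field()`). No quantitative field map exists for a magnetized
needle tip at these distances; any monotone decay exercises the estimator,
so the exponent is configurable. `p = 0` gives a spatially constant force —
the cleanest ground truth for calibrating the estimator — and `p = 1` a
1/d decay for testing the force–distance profile's monotonicity.

One deliberate decoupling: the drift mobility uses `D_drift`, defaulting to
`D_true`. Setting `D_true = 0` with `D_drift > 0` turns off the Brownian
term while keeping a finite drift response, giving the deterministic limit
in which each step is exactly `v*dt` — useful as a noise-free oracle even
though a particle with zero diffusivity could not physically respond to
force.

What the generator does **not** emulate: photoblinking and bleaching,
membrane barriers or picket-fence compartments, 3D motion and defocus,
anisotropic or anomalous diffusion, and particle–particle aggregation.
Passing tests therefore demonstrate correctness of the estimators on clean
drift–diffusion data, not robustness to every artifact of live-cell
recordings.

## Imaging, localization and linking

`render_frames()` draws each emitter as a pixel-integrated 2D Gaussian
(error-function integral per pixel, so the photon budget is conserved to
edge truncation), adds constant background, Poisson shot noise and Gaussian
read noise. The two pixel-size presets, 99 and 217 nm/px, correspond to
typical unbinned and 2x2-binned sCMOS configurations.

`localize_spots()` detects candidates as 3x3 local maxima on a
difference-of-Gaussians band-pass (1x and 2x the PSF sigma) thresholded in
robust (MAD) standard deviations above the median, then refines each by
Levenberg–Marquardt least squares of a 2D Gaussian with free width (fixed
width is available; free is the default because ~160 nm hydrodynamic-radius
particles broaden spots slightly beyond the nominal PSF). Failed fits are
flagged, never silently dropped. `link_localizations()` is deliberately
minimal: mutual nearest neighbours between consecutive frames, a hard
`max_disp` gate, no gap closing; ties break by distance, then by lower
track id. This matches the low-density regime the method operates in and
keeps linking deterministic.

`localization_precision()` is the sample standard deviation (n−1
denominator) of repeated localizations of an immobile particle, the
empirical precision definition; immobility is asserted by the caller,
mirroring the deliberate use of stuck particles for this measurement.

## Diffusion analysis and statistics

`compute_msd()` is the time-averaged MSD over all start points;
`fit_diffusion()` fits the first 4 lags by OLS with a **free intercept**
(the intercept absorbs the `4*sigma_loc^2` static-noise offset; few lags
limit the bias from correlated MSD points). Negative fitted slopes are
reported and flagged rather than censored, so that downstream log
statistics can count them explicitly.

The filter presets encode the two standard rule sets: SPT analysis keeps
tracks with at least 50 frames and `D >= 0.005 um^2/s`; force calibration
keeps tracks with at least 200 frames, `D >= 0.01 um^2/s` and a net
start-to-end displacement of at least 10 um. "Displacement" is read as net
displacement (not path length): magnet-pulled tracks are nearly straight,
so the two nearly coincide, and net displacement is the conventional
meaning.

Diffusion coefficients of membrane particles are approximately log-normal,
so `summarize_D()` reports moments of `ln D` alongside the arithmetic mean
and median, excluding non-positive estimates with an explicit count, and
`paired_logD_test()` runs the two-tailed paired Student's t-test on
`ln(before) - ln(after)`. The natural log is used throughout; the t
statistic is base-invariant. Degenerate input (all paired differences
identical) is resolved by the limit values (`t = 0, p = 1` when they
vanish) instead of the `0/0` a naive implementation returns.

## Registration

`fit_similarity()` is the closed-form least-squares nonreflective
similarity fit (uniform scale, rotation, translation): with points as
complex numbers, the scale–rotation is the complex regression coefficient
of the centred destination on the centred source. Its modulus is positive
for any non-degenerate input, so the fitted map can never reflect — the
constraint is structural, not a post-hoc sign flip. The fit is exact at
n = 2 and needs no iteration. Correspondence is by input order; fiducials
are paired manually upstream, so no automatic matching is attempted.

## Numerical conventions and degenerate inputs

* Lengths in um everywhere; pixel conversion only at image I/O, using the
  configured pixel size. Forces in fN, time in s, precision in nm.
* Image convention: x rightward along columns, y downward along rows,
  pixel (0,0) centred at (0,0) um; frames are 0-based.
* `window_force()` errors on `D_perp <= 0` (a noise-free straight line has
  no defined force) rather than returning infinity.
* `force_field()` errors at the tip singularity; `needle_frame()` errors
  when the tip coincides with the window centroid.
* Track CSVs are written with fixed 6-decimal um precision and
  deterministic ordering, so identical track sets produce byte-identical
  files.
* All generators take explicit integer seeds and are bit-reproducible.

## Problem sizes used for validation

The test suite and the acceptance script validate on: ensembles of 100–178
tracks of 500 frames for force recovery and nulls; 100 tracks of 500 frames
at 50 Hz for diffusion recovery; 3000 localizations for the precision
estimate; 8–100 fiducials for registration; 1000 random point sets for the
no-reflection property. These sizes give Monte-Carlo standard errors
comfortably inside the tested tolerances while the full suite runs in a few
minutes on one core.

## Limitations

* The estimator assumes constant force and free diffusion within each
  window; barriers, tethering or strong field gradients within a window
  violate this and bias `v_x` low.
* Linking has no gap closing, so blinking labels fragment tracks.
* The simulator's force field is a stand-in with a configurable power-law
  decay; it reproduces the qualitative distance dependence, not any
  measured field map.
* No drift correction of the microscope stage and no 3D localization are
  provided.
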