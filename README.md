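# fmnptrack

Single-particle tracking (SPT) analysis and femtonewton force calibration
for experiments in which fluorescent magnetic nanoparticles (FMNPs) bound
to membrane molecules are pulled laterally across a membrane by a
magnetized needle.

The package is for membrane biophysicists who combine SPT with magnetic
manipulation: it estimates the tiny (fN-scale) pulling forces directly from
trajectories, quantifies diffusion and localization precision, applies the
standard track-filtering rules, and registers trajectories onto a second
imaging modality via fiducial markers. Because experiments of this kind
rarely ship with public raw data, the package also contains a full
synthetic pipeline — a drift–diffusion simulator with a configurable needle
force field and a camera model — so every estimator is validated against
known ground truth.

## The estimator at its core

A membrane-bound particle is overdamped, so a constant force produces a
drift velocity `v = F/gamma`, and the Einstein relation `D = kB*T/gamma`
removes the unknown drag:

```
F_x = kB * T * v_x / D
```

`v_x` is extracted as the linear (OLS) drift of the trajectory component
directed at the needle tip, and `D` from the fluctuations perpendicular to
the pull, which the force leaves untouched. Forces are computed in sliding
windows along each trajectory, averaged per track, and binned against
distance to the tip to give a force–distance profile. With `v_x` in um/s
and `D` in um^2/s, `kB*T ~ 4.11 fN um` at 298 K sets the scale: drift and
diffusion of similar magnitude means the force does work of order `kB*T`
per diffusion length — strong enough to steer a molecule, too weak to break
its interactions.

## Worked example

Simulate a calibration experiment — 100 particles diffusing at
`D = 0.13 um^2/s` on a supported bilayer, pulled by a constant 13.4 fN
towards a needle tip 1 mm to the east, imaged at 10 Hz with 10 nm
localization noise — then recover the force from the trajectories alone:

```r
library(fmnptrack)

phys   <- physical_params(298)                 # room temperature
needle <- needle_geometry(tip = c(1000, 0),    # tip 1 mm east, in-plane
                          F0 = 13.4, d0 = 50, p = 0)
cfg <- sim_config(D_true = 0.13, dt = 0.1, n_frames = 500, n_tracks = 100,
                  sigma_loc = 0.01, arena = c(-80, 80, -80, 80),
                  start_box = c(-30, 30, -30, 30), seed = 1)
ts <- simulate_tracks(cfg, needle, phys)
ts
#> <track_set> 100 tracks, 50000 localizations, dt = 0.1 s

est <- trackset_forces(ts, needle, window_len = 50, step = 25, phys = phys)
head(est[, c("track_id", "w_start", "F_x", "v_x", "D_perp", "d_x")], 3)
#>   track_id w_start       F_x       v_x    D_perp      d_x
#> 1        1       0 12.746813 0.3975038 0.1283037 1013.274
#> 2        1      25 25.445173 0.6186579 0.1000333 1011.967
#> 3        1      50  4.543501 0.1150142 0.1041503 1011.071

stats <- ensemble_force_stats(per_track_forces(est))
sprintf("apparent force: %.1f +/- %.1f fN (mean +/- s.d., %d tracks)",
        stats$mean_fN, stats$sd_fN, stats$n)
#> "apparent force: 13.9 +/- 2.4 fN (mean +/- s.d., 100 tracks)"
```

Individual windows scatter widely (12.7, 25.4, 4.5 fN above — the window
estimate divides by a 49-step diffusion estimate and is heavy-tailed), but
the ensemble mean recovers the injected 13.4 fN to within a few percent.
The per-window table also carries `v_x` (um/s), the perpendicular `D_perp`
(um^2/s) and the mean tip distance `d_x` (um) feeding
`force_distance_profile()`.

Diffusion analysis of the same tracks:

```r
Dtab <- track_diffusion(ts)        # 4-lag MSD fit, free intercept
s <- summarize_D(Dtab$D)
sprintf("D: mean %.3f / median %.3f um^2/s (%d tracks)", s$mean, s$median, s$n)
#> "D: mean 0.153 / median 0.153 um^2/s (100 tracks)"
```

Note the MSD-fitted `D` of pulled tracks is inflated above the true
0.13 um^2/s by the ballistic `v^2 tau^2` term — exactly why the force
estimator takes `D` from the perpendicular fluctuations instead.

Other entry points: `render_frames()`/`localize_stack()`/
`link_localizations()` for the image pipeline, `localization_precision()`
for immobile-particle precision, `apply_filters()` with
`filter_spec_spt()`/`filter_spec_force()` for the standard track filters,
`paired_logD_test()` for before/after comparisons, `fit_similarity()` /
`apply_transform()` for fiducial registration, and `run_pipeline()` plus
the thin CLI in `inst/cli/fmnptrack.R` (subcommands `simulate`, `track`,
`diffuse`, `force`, `register`, `report`) for scripted use.

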