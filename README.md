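# peptrecon

An *in-silico* workbench for reconstructing pulsatile arterial velocity
profiles from sparse tracer-particle data, as acquired by positron emission
particle tracking (PEPT). PEPT follows positron-emitting tracers through
opaque media — in principle, blood in a coronary artery — but only a
handful of tracers cross any given cross-section per cardiac cycle. The
question this package exists to study is: **how well can the time-resolved
velocity profile downstream of a stenosis be reconstructed from those few
crossings, and with what uncertainty?**

It is aimed at people designing PEPT flow experiments (tracer counts,
seeding rates, tolerable localization noise) and at developers of
sparse-data flow-reconstruction methods who need a controlled testbed with
known ground truth.

## What's inside

* **Ground-truth flow fields** — parametric stenosed tubes (cosine-bell
  occlusion of the diameter) and idealized coronary bifurcations (Murray's
  law radii, 35°/40° branch angles), carrying a pulsatile
  parabolic-by-continuity velocity field with period `T_c = 0.96 s`, peak
  flow at `t = 0.582 s`, and an optional near-wall recirculation zone
  producing retrograde velocities downstream of the throat.
* **A lumped-parameter (Windkessel) outlet model** — the second-order
  pressure–flow ODE with coefficients built from two compliances and three
  resistances, a time-domain solver, an exact spectral periodic solver,
  and least-squares calibration to a target pressure curve.
* **Tracer physics and tracking** — Stokes-number fidelity analysis
  (`tau_p = rho_p d_p^2 / 18 mu_f`), batch seeding, a ballistic
  second-order tracker, plane-of-interest (POI) crossing extraction with
  cycle-time folding, and bounded localization-noise injection.
* **Direct sampling** of the field at the POI — the idealized arm used to
  establish required point counts and as the particle arm's upper bound.
* **Space–time universal kriging** (`ukrige()`) — drift basis
  `{1, X, Y, t}`, anisotropic exponential semivariogram estimated from
  drift residuals and fitted by weighted least squares, no-slip boundary
  augmentation, exact interpolation at zero nugget, and kriging-variance
  uncertainty maps. A classed model object with `predict`, `summary`,
  `coef`, `plot`, `residuals` and `simulate` methods.
* **Error metrics and experiment drivers** — normalized RMS surface error
  `e_RMS = sqrt(∫e² dA / A) / |v̄|`, peak-velocity error `e_max(v)`,
  area-averaged curve errors (particle-vs-truth, sampling-vs-truth),
  clustering `C_d`, stenosis localization from per-particle maximum
  velocities, convergence and noise sweeps.

The methods vignette
(`vignettes/pept-velocity-reconstruction.Rmd`) documents the model,
its assumptions, the numerical choices, and what the synthetic fields do
and do not emulate.

## Worked example

Six hundred tracers (15 batches of 40, one batch every 64 ms), tracked
through a 50%-occluded tube with recirculation; the profile is
reconstructed at the plane 10 mm downstream of the minimum lumen area:

```r
library(peptrecon)
set.seed(42)

field <- flow_field(stenosed_tube(occlusion = 0.5), coronary_waveform(),
                    recirculation = recirculation())
plane <- poi_plane(field$geometry)            # z = 35 mm, r = 1.75 mm

starts <- seed_particles(seeding_plan(), field)
tracks <- track(field, starts)
cross  <- group_by_cycle_time(detect_poi_crossings(tracks, plane, field), 0.96)
nrow(cross)
#> [1] 374

localize_stenosis(max_velocity_record(tracks))$z   # true throat at 25 mm
#> [1] 25.24

train <- augment_no_slip(training_set(cross, plane, source = "particles"),
                         instants = (0:14) * 0.064)
fit <- ukrige(data = train)
fit
#> Space-time universal kriging model
#>   drift: v_n ~ X + Y + t_c
#>   914 observations (after deduplication)
#> Exponential semivariogram: nugget = 0, sill = 0.0398 (m/s)^2, range = 0.675 mm (time scaling 10.9 mm/s)

predict(fit, data.frame(X = 0, Y = 0, t_c = 0.582), se.fit = TRUE)
#> $fit      0.721       # m/s at the centerline, peak flow
#> $se.fit   0.131       # kriging standard error (truth: 0.728)
```

The zero fitted nugget makes the model an exact interpolator at the
crossings; the standard error quantifies how far the query sits from data.
Scoring both measurement arms against the truth:

```r
rep <- run_particle_experiment(field, plane, n_trials = 5,
                               sampling_arm = sampling_plan(n_trials = 5),
                               seed = 42)
rep
#> PEPT reconstruction error report
#>   particle arm: 5 trials, 352-380 crossings per trial (mean 367)
#>   e_par-truth (curve)        : 15.4% +/- 0.4%
#>   mean e_RMS over cycle      : 26.8% +/- 1.0%
#>   mean e_max(v) over cycle   : 4.4% +/- 1.0%
#>   clustering C_d             : 0.29 +/- 0.02 mm
#>   sampling arm e_sam-truth   : 11.4% +/- 0.9%  (C_d 0.33 mm)
```

Read: with retrograde near-wall flow present, particle crossings (which
ride the forward core — note the smaller clustering statistic) reconstruct
the full profile worse than matched random sampling (15.4% vs 11.4% curve
error; 26.8% mean surface error), **but the cross-sectional peak velocity
is still recovered to under 5%** — the workbench's central finding, and
the reason tracer-kriging peak-velocity estimates are the trustworthy
output of such an experiment.

A thin command-line front end over the same functions is installed at
`inst/cli/peptrecon.R` (subcommands `field-export`, `sample`, `track`,
`full`, `sweep-convergence`, `sweep-noise`, driven by a YAML/JSON config).

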