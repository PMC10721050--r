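---
title: "Reconstructing post-stenotic velocity profiles from sparse tracer data"
author: "peptrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing post-stenotic velocity profiles from sparse tracer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptrecon)
```

## The problem

Positron emission particle tracking (PEPT) locates positron-emitting tracer
particles from coincident gamma detections, which makes it one of the few
techniques that can follow flow inside an opaque medium — including, in
principle, blood flow in a coronary artery. A tracer small enough to follow
the flow faithfully (Stokes number far below one) turns each recorded
trajectory into a set of Lagrangian velocity samples. The clinical quantity
of interest is the cross-sectional velocity profile just downstream of a
stenosis: from it one can derive peak jet velocity, flow rate, and pressure
gradients used to grade lesion severity.

The difficulty is sparsity. A handful of tracers crossing a measurement
plane at scattered positions and phases of the cardiac cycle must be turned
into a full space–time velocity field, with an honest statement of
uncertainty where no tracer passed. `peptrecon` is an *in-silico* workbench
for that reconstruction problem: it generates a known pulsatile stenotic
flow field, simulates both idealized random sampling and actual particle
transits through a plane of interest (POI), reconstructs the normal
velocity by space–time universal kriging, and scores the reconstruction
against the known truth.

Because everything is synthetic, the workbench can answer design questions
that are expensive to answer experimentally: how many tracers are needed,
at what seeding rate per cardiac cycle, how localization noise propagates,
and where the reconstruction breaks down (retrograde near-wall flow).

## The ground-truth flow field

The field stands in for a computational fluid dynamics solution, with the
features that matter to the reconstruction problem built in analytically:

* **Geometry.** An axisymmetric tube of baseline radius $r_0$ (default
  1.75 mm) whose lumen narrows over a cosine bell of one full period:
  $R(z) = r_0 - r_0\,o\,\tfrac12[1+\cos(2\pi(z-z_c)/L_s)]$ inside the bell
  support and $r_0$ outside, with occlusion fraction $o$ the *diameter*
  reduction at the throat. The bell makes $R(z)$ continuously
  differentiable and puts the minimum lumen area (MLA) exactly at $z_c$.
  An idealized coronary bifurcation (Murray's law radii, 35°/40° branch
  angles for the LAD and LCx) is available for geometry studies.
* **Waveform.** A strictly periodic flow factor with period
  $T_c = 0.96$ s: a baseline plus two Gaussian pulses, a small systolic
  pulse and the dominant diastolic pulse peaking at $t = 0.582$ s. This is
  a parametric surrogate for a measured left-coronary inflow curve; it
  preserves the features the reconstruction is sensitive to (pulsatility,
  one dominant peak, strictly forward mean flow) without tracing any
  particular patient's trace. The default flow amplitude of 3.5 mL/s gives
  a peak mean velocity of about 0.36 m/s in the parent tube, i.e. a
  Reynolds number of roughly 370 — laminar, as assumed.
* **Velocity.** A quasi-steady parabolic profile modulated by continuity:
  $v_z = 2\bar V(z,t)\,[1-(\rho/R)^2]$ with
  $\bar V = Q(t)/\pi R(z)^2$, and the radial component obtained in closed
  form from axisymmetric incompressibility. Flow rate is exactly
  independent of $z$ and the no-slip condition holds identically on the
  wall. Quasi-steadiness ignores the Womersley phase lag of real pulsatile
  profiles; that is acceptable here because the workbench evaluates
  *reconstruction of a given field*, not hemodynamic fidelity.
* **Recirculation (optional).** A kinematic additive axial term
  $-A\,\bar V\,g(z)\,h(\rho/R)$ with $h$ concentrated near the wall
  ($h(1)=0$, preserving no-slip) and $g$ a Gaussian envelope peaking a few
  millimetres downstream of the throat. It produces the negative near-wall
  normal velocities seen distal to a stenosis in pulsatile flow — the
  regime in which tracer-based reconstruction degrades — at the price of
  exact mass conservation. Amplitude maps qualitatively to occlusion
  severity.

What the generator does **not** emulate: Womersley profiles, turbulence or
transitional jets, wall compliance, non-Newtonian rheology, junction flow
details at the bifurcation, and detector physics (positron range, line-of-
response reconstruction, particle pairing). Conclusions drawn from passing
tests are therefore about the *reconstruction pipeline*, not about blood.

## The measurement models

**Sampling arm.** At each of the cycle instants $t_c \in \{0, \Delta t_c,
\dots\}$, $n$ positions are drawn uniformly over the central disk of 0.8
lumen radii and the true normal velocity is recorded. This idealized arm
establishes how many observations the reconstruction needs and serves as
its accuracy upper bound. The 0.8 confinement reflects that tracers rarely
visit the near-wall region; it is configurable and never applied to the
particle arm.

**Particle arm.** Tracers are released in batches at the inlet (default 15
batches of 40, one batch every $\Delta t_c = 64$ ms, spanning one cycle of
release phases), seeded uniformly over the inlet disk area. The tracker
advances all particles with the ballistic update
$x_{k+1} = x_k + v\,\Delta t_{PT} + \tfrac12 a\,\Delta t_{PT}^2$, reading
$v$ from the ground-truth field at the particle's position and estimating
$a$ by a backward difference of the particle's own velocity history (zero
for the first two steps after release, when no history exists). The
tracking step $\Delta t_{PT}$ defaults to 1 ms, chosen so the update error
is far below the kriging error; halving it reduces the deviation from an
adaptive ODE integration about fourfold (the scheme is second-order). A
particle terminates on leaving the lumen. Forward transits of the POI are
detected by sign change of the signed plane distance and linearly
interpolated in time; each crossing record carries the local plane
coordinates $(X, Y)$, the absolute time folded into the cycle
($t_c = t \bmod T_c$), and the true normal velocity at the interpolated
point. Localization noise is modeled by standard-normal 3-vectors rescaled
so every component lies in $[-L_n r, L_n r]$ and added to crossing
*positions* only (times and velocities untouched), then re-projected onto
the plane.

## The reconstruction model

The normal velocity over the POI is treated as a random field over
$(X, Y, t_c)$ and estimated by **universal kriging**:

* **Drift.** The mean is a linear combination of $\{1, X, Y, t_c\}$ —
  the minimal basis that does not assume a constant mean for pulsatile
  data. The basis is configurable.
* **Covariance.** An anisotropic exponential semivariogram
  $\gamma(h) = \text{nugget} + \text{sill}\,(1 - e^{-h/\text{range}})$ in
  the scaled lag
  $h = \sqrt{\Delta X^2 + \Delta Y^2 + (s_t\,\Delta t)^2}$. The time-axis
  scaling $s_t$ (mm/s) encodes the anisotropy; by default one cardiac
  cycle of temporal separation decorrelates like **six lumen radii** of
  spatial separation, i.e. spatial correlation carries more weight than
  temporal correlation. (Stretching time less — e.g. one cycle per three
  radii — makes adjacent cycle instants effectively closer than adjacent
  spatial samples, and cross-instant smoothing then dominates the error;
  at the study configuration this roughly doubles the reconstruction
  error, which is why the stronger default was adopted.) Optionally the
  scaling is selected among $\{0.5, 1, 2, 4\}\times$ the prior by a
  deterministic hold-out cross-validation; weighted variogram residuals
  are not comparable across scalings and are not used for this choice.
* **Variogram estimation.** Method-of-moments semivariances of the
  ordinary-least-squares drift residuals, binned in scaled lag, fitted by
  weighted least squares (weights = pair counts, nugget constrained
  non-negative, multi-start). Only the rising limb (lags up to 0.45 of
  the maximum) enters the fit: on a bounded lumen disk the sample
  semivariogram bends back down at long lags — a hole effect, because
  profile center and no-slip edge anticorrelate — and fitting the full
  curve collapses to a pure-nugget model. On the noiseless synthetic
  fields the fitted nugget is zero and kriging interpolates the data
  exactly, with zero kriging variance at the data sites.
* **No-slip augmentation.** Before fitting, the training set is augmented
  with a ring of boundary points (default 36) carrying zero velocity at
  each cycle instant. For sampled data the instants are those present in
  the data; particle crossings carry continuous interpolated times, so
  the ring is placed on the $\Delta t_c$ cycle grid instead (a ring per
  unique crossing time would inflate the kriging system roughly
  fifteen-fold for no information gain).
* **Prediction.** Means use the dual-kriging weights — one linear solve
  per fitted model, $O(n)$ per query — which keeps 30-trial sweeps cheap;
  kriging variances solve the primal saddle-point system per query and
  are computed only when requested. Numerical safeguards: space–time
  duplicates averaged (tolerance $10^{-9}$), the drift block of the
  saddle-point system equilibrated column-wise, cross-distances computed
  per dimension (the $|a|^2+|b|^2-2ab$ expansion loses half the digits to
  cancellation near zero separation), one step of iterative refinement on
  every solve, and a logged diagonal jitter of $10^{-10}\,\text{sill}$
  only if the system is numerically singular.

`ukrige()` returns a classed model with `print`, `summary`, `coef`
(generalized-least-squares drift coefficients), `predict` (mean and
kriging standard error), `residuals` (drift residuals), `plot` (empirical
vs fitted semivariogram) and `simulate` (marginal predictive draws)
methods; `reconstruct_profile()` wraps it over a lattice masked to the
lumen disk.

## Error metrics

With truth in hand, reconstructions are scored by: the per-instant RMS
surface error $e_{RMS} = \sqrt{\int e^2 dA / A}$ normalized by the
area-averaged true velocity at the same instant (in percent); the relative
error of the cross-sectional maximum, $e_{\max(v)}$; the cycle-level
normalized RMS error between area-averaged velocity curves (the
particle-vs-truth and sampling-vs-truth variants); and the clustering
statistic $C_d$, the standard deviation of distances from the data points
to their centroid. Disk integrals use a Gauss–Legendre-in-radius,
trapezoid-in-angle quadrature, validated against a $10^6$-point
Monte-Carlo oracle to 0.1%. Cycle summaries report the max, mean and min
over instants; repeated trials are aggregated as mean ± sample standard
deviation. The stenosis is localized as the median axial position of the
top speed-quartile of per-particle maximum-velocity records, flagged
low-confidence when those records are not axially concentrated
(interquartile range above 5 mm) — in pulsatile flow per-particle maximum
*speeds* spread widely even without a stenosis, so spatial concentration,
not speed spread, is the discriminator.

## The 0D outlet model

The coronary outlet is a lumped resistance–compliance circuit relating
outlet pressure and flow,
$a\ddot P + b\dot P + P = d\ddot Q + e\dot Q + fQ + g(t)$, with the
coefficients given products of the two compliances ($C_{im}$, $C_a$) and
three resistances ($R_a$, $R_v$, $R_{a\text{-}m}$), and
$g = R_v C_{im}\,\dot P_{LV}$ the ventricular forcing. Units are mmHg, s
and cm³ throughout. The equation is integrated in time with `deSolve`
(`solve_pressure`); because it is linear and time-invariant its periodic
regime also has an exact Fourier solution (`periodic_pressure`), used as
the fast inner solver during calibration. Calibration fits the five
scalars to a target pressure curve by Levenberg–Marquardt on
log-parameters (positivity by construction) with a handful of jittered
restarts: the loss surface has shallow side basins in the weakly
identified $R_v$/$C_{im}$ directions (those two parameters enter mostly
through their product). Default parameter values are order-of-magnitude
physiological placeholders; calibration against a measured curve is the
supported path, with a flag for target means outside the 70–140 mmHg
physiological band.

## Numerical and design choices

* Lengths are mm, times s, velocities m/s, flows mL/s; conversions happen
  only at module boundaries (the tracker converts m/s to mm/s
  internally).
* MLA of an unoccluded tube: reported at the nominal stenosis center
  (documented tie-break).
* Seeding is uniform over the inlet disk area ($r = R\sqrt u$); the exact
  distribution of a real injection is unknown.
* Noise rescaling divides the batch by its maximum absolute component —
  a min–max reading of "scaled to the interval".
* The acceleration in the ballistic update is the trajectory backward
  difference (the most literal reading of a tracker that only has its own
  velocity history); a field material-derivative variant was considered
  and rejected as less faithful to post-processing reality.
* Degenerate variogram inputs (constant data) fall back to flagged
  defaults; near-zero error normalizers return the unnormalized RMS with
  a flag.

## Problem sizes and what the tests show

The shipped experiments run at desk scale on one CPU: convergence sweeps
use 30 trials per cell over $n \in \{10, 20, 40, 60, 80, 100\}$ points and
$\Delta t_c \in \{96, 64, 48\}$ ms (a few minutes); particle experiments
use 600 tracers (15 × 40) tracked at 1 ms over six cardiac cycles, 10
trials; scoring uses a 160-node disk quadrature at the 15 cycle instants.
At the study configuration (50% occlusion, no recirculation) the median
sampling-arm cycle error at $n = 40$, $\Delta t_c = 64$ ms is about 6%,
comfortably below the 10% design bound, and error decreases monotonically
with density. Dense noiseless sampling converges to the analytic profile
to about 2% RMS of peak (worst single lattice node ~10% — the exponential
kernel is not smooth, and the no-data annulus near the wall is hardest).
With recirculation enabled, the particle arm's cycle-mean profile error
roughly quadruples relative to the matched sampling arm — tracers ride the
forward core and never sample the retrograde annulus — while the
cross-sectional *peak* velocity remains much better recovered than the
full profile. That asymmetry, peak recovery surviving profile failure, is
the workbench's central qualitative finding, and motivates treating
tracer-kriging estimates of peak post-stenotic velocity as more
trustworthy than reconstructed flow rates.

## Limitations

The ground truth is kinematic, not dynamic; absolute error magnitudes on
real arteries will differ. The recirculation term breaks exact continuity.
Only one vessel is reconstructed at a time (no junction-plane handling).
Kriging variance quantifies interpolation uncertainty under the fitted
stationary covariance of drift residuals — it is not a physical error bar,
and the residual field is not truly stationary (its amplitude follows the
waveform). Detector physics is out of scope entirely.
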