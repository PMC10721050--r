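#' Tracer particle specification and fidelity numbers
#'
#' PEPT tracers must follow the flow faithfully; this is quantified by the
#' particle relaxation time
#' \deqn{\tau_p = \frac{\rho_p d_p^2}{18 \mu_f}}
#' and the Stokes number \eqn{St = \tau_p / \tau_f}, the ratio of the
#' relaxation time to the characteristic flow time. For blood-density
#' tracers of 1-100 micrometers in coronary flow, `St` is far below 1 and
#' the tracer velocity can be identified with the local fluid velocity.
#'
#' @param diameter particle diameter `d_p` (m).
#' @param density particle material density `rho_p` (kg/m^3).
#' @param viscosity surrounding-fluid dynamic viscosity `mu_f` (Pa·s).
#' @return For `tracer_spec`, an object of class `"tracer_spec"`.
#' @examples
#' relaxation_time(tracer_spec(1e-6))   # ~1.62e-8 s
#' stokes_number(relaxation_time(tracer_spec(1e-4)), tau_f = 1)
#' @export
tracer_spec <- function(diameter, density = 1050, viscosity = 0.0036) {
  stopifnot(diameter > 0, density > 0, viscosity > 0)
  if (diameter < 1e-7 || diameter > 1e-3)
    warning("particle diameter outside the plausible PEPT range [1e-7, 1e-3] m")
  structure(list(diameter = diameter, density = density,
                 viscosity = viscosity), class = "tracer_spec")
}

#' @rdname tracer_spec
#' @param spec a `"tracer_spec"` object.
#' @return For `relaxation_time`, the relaxation time `tau_p` (s).
#' @export
relaxation_time <- function(spec) {
  spec$density * spec$diameter^2 / (18 * spec$viscosity)
}

#' @rdname tracer_spec
#' @param tau_p particle relaxation time (s).
#' @param tau_f characteristic flow time scale (s), positive.
#' @return For `stokes_number`, the dimensionless Stokes number.
#' @export
stokes_number <- function(tau_p, tau_f) {
  if (any(tau_f <= 0)) stop("`tau_f` must be positive", call. = FALSE)
  tau_p / tau_f
}

#' Particle seeding plan
#'
#' Particles are released in batches at the inlet cross-section, one batch
#' every `delta_tc` seconds, so the batches sample distinct phases of the
#' cardiac cycle. The default plan (15 batches of 40 at 64 ms) releases 600
#' particles covering one full cycle.
#'
#' @param particles_per_batch particles released per batch.
#' @param n_batches number of release instants.
#' @param delta_tc interval between releases (s); `n_batches * delta_tc`
#'   must not exceed the cycle length `T_c`.
#' @param release_z axial release station (mm), upstream of the stenosis.
#' @param T_c cardiac cycle length (s), used to validate the plan.
#' @return An object of class `"seeding_plan"`.
#' @export
seeding_plan <- function(particles_per_batch = 40, n_batches = 15,
                         delta_tc = 0.064, release_z = 5, T_c = 0.96) {
  stopifnot(particles_per_batch >= 1, n_batches >= 1, delta_tc > 0)
  if (n_batches * delta_tc > T_c + 1e-12)
    stop("batches must span at most one cardiac cycle of release phases",
         call. = FALSE)
  structure(list(particles_per_batch = particles_per_batch,
                 n_batches = n_batches, delta_tc = delta_tc,
                 release_z = release_z, T_c = T_c,
                 n_total = particles_per_batch * n_batches),
            class = "seeding_plan")
}

#' Seed particles at the inlet
#'
#' Draws initial particle positions independently and uniformly over the
#' inlet disk area (radius equal to the lumen radius at the release
#' station), batch `b` being released at time `b * delta_tc` for
#' `b = 0, ..., n_batches - 1`.
#'
#' @param plan a [seeding_plan()].
#' @param geometry a [stenosed_tube()] (or a `"flow_field"`, whose geometry
#'   is used).
#' @return A data frame with columns `id`, `batch`, `release_t`, `x`, `y`,
#'   `z` (mm). Draws come from R's RNG stream; set the seed for
#'   reproducibility.
#' @export
seed_particles <- function(plan, geometry) {
  if (inherits(geometry, "flow_field")) geometry <- geometry$geometry
  if (plan$release_z >= geometry$stenosis_center -
      geometry$stenosis_length / 2)
    stop("release station must be upstream of the stenosis", call. = FALSE)
  n <- plan$n_total
  R <- lumen_radius(geometry, plan$release_z)
  # uniform over area: radius = R * sqrt(u)
  r <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  batch <- rep(seq_len(plan$n_batches) - 1L, each = plan$particles_per_batch)
  data.frame(id = seq_len(n), batch = batch,
             release_t = batch * plan$delta_tc,
             x = r * cos(th), y = r * sin(th), z = plan$release_z)
}

#' Ballistic particle position update
#'
#' One step of the tracker's update rule,
#' \deqn{x_{k+1} = x_k + v\,\Delta t_{PT} + \tfrac{1}{2} a\,\Delta t_{PT}^2.}
#' Unit-agnostic: positions, velocities and accelerations must share a
#' consistent unit system.
#'
#' @param x,v,a position, velocity and acceleration (vectors or conformable
#'   matrices).
#' @param dt time step.
#' @return The updated position.
#' @export
step_particle <- function(x, v, a, dt) {
  x + v * dt + 0.5 * a * dt^2
}

#' Track particles through the flow field
#'
#' Advances all particles with the ballistic update at a uniform tracking
#' step, reading the ground-truth velocity at each particle's position and
#' time. The acceleration is estimated as the backward difference of the
#' particle's own velocity history, and is taken as zero for the first two
#' steps after release, when no history exists. A particle terminates when
#' it leaves the lumen (including through the outlet); tracking stops when
#' no particle remains active or the end time is reached.
#'
#' @param field a `"flow_field"`.
#' @param seeds a data frame from [seed_particles()].
#' @param dt_pt tracking time step (s). The 1 ms default makes the ballistic
#'   update error negligible next to the reconstruction error.
#' @param t_end end of tracking (s); defaults to six cardiac cycles, enough
#'   for all but the slowest near-wall particles to clear the domain.
#' @return An object of class `"pept_tracks"`: the step times `t` and
#'   step-by-particle matrices `x`, `y`, `z` (mm) and `vx`, `vy`, `vz`
#'   (m/s), `NA` before release and after exit, plus the seed table.
#' @export
track <- function(field, seeds, dt_pt = 0.001,
                  t_end = 6 * field$waveform$period) {
  n <- nrow(seeds)
  times <- seq(0, t_end, by = dt_pt)
  ns <- length(times)
  X <- matrix(NA_real_, ns, n); Y <- matrix(NA_real_, ns, n)
  Z <- matrix(NA_real_, ns, n)
  VX <- matrix(NA_real_, ns, n); VY <- matrix(NA_real_, ns, n)
  VZ <- matrix(NA_real_, ns, n)
  pos <- cbind(seeds$x, seeds$y, seeds$z)
  released <- rep(FALSE, n)
  active <- rep(FALSE, n)
  age <- integer(n)                  # steps since release
  v_prev <- matrix(0, n, 3)          # previous-step velocity (m/s)
  for (k in seq_len(ns)) {
    t <- times[k]
    newly <- !released & seeds$release_t <= t + 1e-12
    if (any(newly)) {
      released[newly] <- TRUE
      active[newly] <- TRUE
      age[newly] <- 0L
    }
    if (!any(active)) {
      if (all(released)) break else next
    }
    i <- which(active)
    v <- eval_velocity(field, pos[i, , drop = FALSE], t)
    inside <- attr(v, "inside")
    if (any(!inside)) {
      active[i[!inside]] <- FALSE
      i <- i[inside]
      if (length(i) == 0) next
      v <- v[inside, , drop = FALSE]
    }
    X[k, i] <- pos[i, 1]; Y[k, i] <- pos[i, 2]; Z[k, i] <- pos[i, 3]
    VX[k, i] <- v[, 1]; VY[k, i] <- v[, 2]; VZ[k, i] <- v[, 3]
    a <- matrix(0, length(i), 3)
    old <- age[i] >= 2L              # acceleration zero for k = 0, 1
    if (any(old))
      a[old, ] <- (v[old, , drop = FALSE] -
                     v_prev[i[old], , drop = FALSE]) / dt_pt
    # positions in mm, velocities in m/s: 1 m/s = 1000 mm/s
    pos[i, ] <- step_particle(pos[i, , drop = FALSE],
                              1000 * v, 1000 * a, dt_pt)
    v_prev[i, ] <- v
    age[i] <- age[i] + 1L
  }
  structure(list(t = times, x = X, y = Y, z = Z, vx = VX, vy = VY, vz = VZ,
                 seeds = seeds, dt_pt = dt_pt),
            class = "pept_tracks")
}

#' @export
print.pept_tracks <- function(x, ...) {
  n_rec <- colSums(!is.na(x$z))
  cat(sprintf("Tracked %d particles, dt = %g s, %d steps; %d recorded at least one in-domain step\n",
              ncol(x$z), x$dt_pt, length(x$t), sum(n_rec > 0)))
  invisible(x)
}

#' Extract plane-of-interest crossings
#'
#' Finds every step pair of every trajectory that straddles the plane in the
#' forward (normal) direction, linearly interpolates the crossing time and
#' position, evaluates the ground-truth normal velocity at the interpolated
#' point and time, and expresses the crossing in local plane coordinates.
#' A particle carried back upstream by recirculation and re-entering
#' produces one record per forward crossing.
#'
#' @param tracks a `"pept_tracks"` object.
#' @param plane a [poi_plane()].
#' @param field the `"flow_field"` the particles were tracked in.
#' @return A data frame with columns `id`, `batch`, `t` (s), `x`, `y`, `z`
#'   (mm), `X`, `Y` (local plane coordinates, mm) and `v_n` (m/s).
#' @export
detect_poi_crossings <- function(tracks, plane, field) {
  S <- tracks$z - plane$z            # signed distance (normal along +z)
  ns <- nrow(S)
  fwd <- !is.na(S[-ns, , drop = FALSE]) & !is.na(S[-1, , drop = FALSE]) &
    S[-ns, , drop = FALSE] < 0 & S[-1, , drop = FALSE] >= 0
  idx <- which(fwd, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(id = integer(), batch = integer(), t = numeric(),
                      x = numeric(), y = numeric(), z = numeric(),
                      X = numeric(), Y = numeric(), v_n = numeric()))
  k <- idx[, 1]; j <- idx[, 2]
  s0 <- S[cbind(k, j)]; s1 <- S[cbind(k + 1, j)]
  frac <- ifelse(s1 - s0 > 0, s0 / (s0 - s1), 0)
  tc <- tracks$t[k] + frac * tracks$dt_pt
  px <- tracks$x[cbind(k, j)] +
    frac * (tracks$x[cbind(k + 1, j)] - tracks$x[cbind(k, j)])
  py <- tracks$y[cbind(k, j)] +
    frac * (tracks$y[cbind(k + 1, j)] - tracks$y[cbind(k, j)])
  pz <- plane$z
  v <- eval_velocity(field, cbind(px, py, pz), tc)
  vn <- as.numeric(v %*% plane$normal)
  loc <- to_local_coords(cbind(px, py, pz), plane)
  out <- data.frame(id = tracks$seeds$id[j], batch = tracks$seeds$batch[j],
                    t = tc, x = px, y = py, z = pz,
                    X = loc[, 1], Y = loc[, 2], v_n = vn)
  out[order(out$t), , drop = FALSE]
}

#' Assign cycle times to crossings
#'
#' Folds absolute crossing times into the cardiac cycle, `t_c = t mod T_c`.
#' Records released in different cycles but at the same phase therefore
#' share a cycle time, which is the pooling the space-time kriging relies
#' on; the release batch is kept as the grouping key.
#'
#' @param crossings a data frame from [detect_poi_crossings()].
#' @param T_c cardiac cycle length (s).
#' @return The input with a `t_c` column added.
#' @export
group_by_cycle_time <- function(crossings, T_c) {
  stopifnot(T_c > 0)
  crossings$t_c <- crossings$t %% T_c
  crossings
}

#' Add localization noise to crossing positions
#'
#' Emulates finite PEPT localization accuracy: a standard-normal 3-vector is
#' drawn per record, the whole batch is rescaled linearly so every component
#' lies in `[-L_n r, L_n r]` (`r` the lumen radius at the plane of
#' interest), and the perturbations are added to the 3D crossing positions,
#' which are then re-projected onto the plane. Velocities and times are
#' unchanged: noise degrades where a velocity sample is believed to lie, not
#' the sample itself.
#'
#' @param crossings a data frame from [detect_poi_crossings()].
#' @param L_n noise level (dimensionless fraction of the lumen radius).
#' @param plane a [poi_plane()]; supplies `r` and the projection basis.
#' @return The crossings with perturbed `x`, `y`, `z`, `X`, `Y`.
#' @export
add_noise <- function(crossings, L_n, plane) {
  stopifnot(L_n >= 0)
  n <- nrow(crossings)
  if (n == 0 || L_n == 0) return(crossings)
  noise <- matrix(stats::rnorm(3 * n), n, 3)
  noise <- noise / max(abs(noise)) * (L_n * plane$radius)
  pos <- as.matrix(crossings[, c("x", "y", "z")]) + noise
  loc <- to_local_coords(pos, plane)
  crossings$x <- pos[, 1]; crossings$y <- pos[, 2]; crossings$z <- pos[, 3]
  crossings$X <- loc[, 1]; crossings$Y <- loc[, 2]
  crossings
}

#' Per-particle maximum-velocity records
#'
#' For each particle with at least one recorded in-domain step, the maximum
#' speed along its trajectory and the position at which it occurred (the
#' first such position in case of ties). Used for stenosis localization:
#' particles reach their peak speed in the stenotic jet.
#'
#' @param tracks a `"pept_tracks"` object.
#' @return A data frame with columns `id`, `speed` (m/s), `x`, `y`, `z`
#'   (mm).
#' @export
max_velocity_record <- function(tracks) {
  sp2 <- tracks$vx^2 + tracks$vy^2 + tracks$vz^2
  has <- colSums(!is.na(sp2)) > 0
  j <- which(has)
  k <- vapply(j, function(jj) which.max(sp2[, jj]), integer(1))
  data.frame(id = tracks$seeds$id[j],
             speed = sqrt(sp2[cbind(k, j)]),
             x = tracks$x[cbind(k, j)],
             y = tracks$y[cbind(k, j)],
             z = tracks$z[cbind(k, j)])
}
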