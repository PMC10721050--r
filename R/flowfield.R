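#' Recirculation descriptor for a flow field
#'
#' Parameterizes a kinematic near-wall recirculation zone downstream of the
#' stenosis: an additive axial velocity term
#' \deqn{-A\, \frac{Q(t)}{\pi R(z)^2}\, g(z)\, h(\rho/R)}
#' where `h` is concentrated near the wall with `h(1) = 0` (no-slip
#' preserved) and `g` is a non-negative axial envelope peaking just
#' downstream of the throat and decaying over `decay_length`. This emulates
#' the negative near-wall normal velocities seen distal to a stenosis in
#' pulsatile flow; it is a kinematic construct, not a Navier-Stokes
#' solution, and deliberately trades exact mass conservation for a
#' controllable retrograde-flow feature.
#'
#' @param amplitude dimensionless fraction of the local mean axial velocity;
#'   larger values give stronger retrograde flow.
#' @param peak_offset axial distance (mm) downstream of the stenosis center
#'   at which the recirculation envelope peaks.
#' @param decay_length axial e-folding scale of the envelope (mm).
#' @param wall_exponent exponent concentrating `h` toward the wall;
#'   `h(u) = u^p (1 - u^2)` normalized to unit maximum.
#' @return An object of class `"recirculation"`.
#' @export
recirculation <- function(amplitude = 0.8, peak_offset = 5,
                          decay_length = 8, wall_exponent = 6) {
  stopifnot(amplitude >= 0, decay_length > 0, wall_exponent > 0)
  structure(list(amplitude = amplitude, peak_offset = peak_offset,
                 decay_length = decay_length, wall_exponent = wall_exponent),
            class = "recirculation")
}

#' Analytic pulsatile flow field on a stenosed tube
#'
#' The ground-truth velocity field used in place of a computational fluid
#' dynamics solution. The axial component is a quasi-steady parabolic
#' (Poiseuille) profile modulated by continuity through the varying lumen:
#' \deqn{v_z(\rho, z, t) = 2\,\bar V(z,t)\,\bigl[1 - (\rho/R(z))^2\bigr],
#'   \qquad \bar V(z,t) = \frac{Q(t)}{\pi R(z)^2},}
#' so the flow rate \eqn{Q(t) = Q_{amp}\, w(t)} is independent of `z`. The
#' radial component follows from axisymmetric incompressibility in closed
#' form,
#' \deqn{v_\rho = \frac{2 Q(t) R'(z) \rho}{\pi R(z)^3}
#'   \bigl[1 - (\rho/R)^2\bigr],}
#' which vanishes on the axis and at the wall. An optional additive
#' [recirculation()] term produces negative near-wall axial velocities
#' downstream of the throat.
#'
#' Positions are in mm, times in s and velocities in m/s.
#'
#' @param geometry a [stenosed_tube()].
#' @param waveform a [coronary_waveform()] or [waveform_from_table()] object.
#' @param flow_amplitude peak flow rate `Q_amp` (mL/s). The default, with the
#'   default geometry, keeps the tube Reynolds number below 500 (laminar).
#' @param recirculation a [recirculation()] descriptor, or `NULL` for a
#'   strictly forward, mass-conserving field.
#' @return An object of class `"flow_field"`.
#' @examples
#' field <- flow_field(stenosed_tube(), coronary_waveform())
#' eval_velocity(field, c(0, 0, 10), t = 0.582)
#' @export
flow_field <- function(geometry, waveform = coronary_waveform(),
                       flow_amplitude = 3.5, recirculation = NULL) {
  stopifnot(inherits(geometry, "stenosed_tube"), inherits(waveform, "waveform"),
            flow_amplitude > 0)
  if (!is.null(recirculation) && !inherits(recirculation, "recirculation"))
    stop("`recirculation` must be a recirculation() descriptor or NULL",
         call. = FALSE)
  structure(list(geometry = geometry, waveform = waveform,
                 flow_amplitude = flow_amplitude,
                 recirculation = recirculation),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Analytic pulsatile stenotic flow field\n")
  print(x$geometry)
  print(x$waveform)
  cat(sprintf("  peak flow rate %.3g mL/s; recirculation %s\n",
              x$flow_amplitude,
              if (is.null(x$recirculation)) "absent" else
                sprintf("amplitude %.2g", x$recirculation$amplitude)))
  invisible(x)
}

#' Instantaneous flow rate
#'
#' @param field a `"flow_field"`.
#' @param t times (s).
#' @return Flow rate `Q(t)` in mL/s.
#' @export
flow_rate <- function(field, t) {
  field$flow_amplitude * eval_waveform(field$waveform, t)
}

# normalized wall-concentrated radial shape of the recirculation term,
# h(u) = u^p (1 - u^2) scaled to unit maximum; h(1) = 0 preserves no-slip.
recirc_radial_shape <- function(u, p) {
  umax2 <- p / (p + 2)
  hmax <- umax2^(p / 2) * (1 - umax2)
  u^p * (1 - u^2) / hmax
}

recirc_axial_envelope <- function(rec, geometry, z) {
  zp <- geometry$stenosis_center + rec$peak_offset
  exp(-((z - zp) / rec$decay_length)^2)
}

#' Evaluate the ground-truth velocity
#'
#' @param field a `"flow_field"`.
#' @param x positions: a length-3 vector or an `n x 3` matrix `(x, y, z)` in
#'   mm.
#' @param t a single time (s), or a vector of length `n`.
#' @return An `n x 3` matrix of velocity components (m/s). Rows for
#'   positions outside the lumen are `NA` and flagged by the logical
#'   attribute `"inside"`, which callers (the particle tracker) use to
#'   detect particles leaving the domain.
#' @export
eval_velocity <- function(field, x, t) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  geom <- field$geometry
  z <- x[, 3]
  rho <- sqrt(x[, 1]^2 + x[, 2]^2)
  inz <- z >= 0 & z <= geom$tube_length
  R <- rep(NA_real_, nrow(x))
  R[inz] <- lumen_radius(geom, z[inz])
  # points on the wall itself count as inside (no-slip evaluates to zero)
  inside <- inz & !is.na(R) & rho <= R * (1 + 1e-12)
  Q <- flow_rate(field, t) * 1000          # mL/s -> mm^3/s
  if (length(Q) == 1) Q <- rep(Q, nrow(x))
  v <- matrix(NA_real_, nrow(x), 3)
  if (any(inside)) {
    i <- which(inside)
    Ri <- R[i]; rhoi <- rho[i]; zi <- z[i]; Qi <- Q[i]
    u2 <- (rhoi / Ri)^2
    vbar <- Qi / (pi * Ri^2)               # mm/s
    vz <- 2 * vbar * (1 - u2)
    dR <- lumen_radius_deriv(geom, zi)
    vrho <- 2 * Qi * dR * rhoi / (pi * Ri^3) * (1 - u2)
    if (!is.null(field$recirculation)) {
      rec <- field$recirculation
      vz <- vz - rec$amplitude * vbar *
        recirc_axial_envelope(rec, geom, zi) *
        recirc_radial_shape(sqrt(u2), rec$wall_exponent)
    }
    # radial direction in the xy-plane (zero on the axis)
    ex <- ifelse(rhoi > 0, x[i, 1] / rhoi, 0)
    ey <- ifelse(rhoi > 0, x[i, 2] / rhoi, 0)
    v[i, 1] <- vrho * ex / 1000            # mm/s -> m/s
    v[i, 2] <- vrho * ey / 1000
    v[i, 3] <- vz / 1000
  }
  attr(v, "inside") <- inside
  v
}

#' Normal velocity on a cross-sectional plane
#'
#' Ground-truth velocity component along the plane normal, evaluated at
#' local in-plane coordinates. This is the quantity the kriging model
#' reconstructs.
#'
#' @param field a `"flow_field"`.
#' @param plane a [poi_plane()].
#' @param X,Y local in-plane coordinates (mm); vectorized.
#' @param t a single time or a vector matching `X` (s).
#' @return Normal velocity `v_n` (m/s); `NA` outside the lumen.
#' @export
truth_vn <- function(field, plane, X, Y, t) {
  pts <- cbind(plane$origin[1] + X * plane$e1[1] + Y * plane$e2[1],
               plane$origin[2] + X * plane$e1[2] + Y * plane$e2[2],
               plane$origin[3] + X * plane$e1[3] + Y * plane$e2[3])
  v <- eval_velocity(field, pts, t)
  v %*% plane$normal
}

#' Area-averaged and maximum normal velocity from the ground truth
#'
#' @param field a `"flow_field"`.
#' @param plane a [poi_plane()].
#' @param t times (s).
#' @param quad a disk quadrature from [disk_quadrature()]; defaults to a
#'   12 x 24 Gauss-Legendre/trapezoid rule on the lumen disk.
#' @return For `truth_mean_vn`, the area-averaged normal velocity (m/s) per
#'   time; for `truth_max_vn`, the maximum over the disk per time.
#' @export
truth_mean_vn <- function(field, plane, t, quad = disk_quadrature(plane$radius)) {
  vapply(t, function(ti) {
    vn <- truth_vn(field, plane, quad$X, quad$Y, ti)
    sum(quad$w * vn) / sum(quad$w)
  }, numeric(1))
}

#' @rdname truth_mean_vn
#' @export
truth_max_vn <- function(field, plane, t, quad = disk_quadrature(plane$radius)) {
  vapply(t, function(ti) {
    max(truth_vn(field, plane, quad$X, quad$Y, ti))
  }, numeric(1))
}
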