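#' Quadrature nodes on a disk
#'
#' Gauss-Legendre nodes in radius combined with a uniform (trapezoidal, exact
#' for trigonometric polynomials) rule in angle, with the radial area weight
#' included. Integrates smooth functions over the lumen disk to high
#' accuracy with a few hundred nodes.
#'
#' @param radius disk radius (mm).
#' @param n_r number of radial Gauss-Legendre nodes.
#' @param n_theta number of equally spaced angular nodes.
#' @return A list with node coordinates `X`, `Y` (mm) and weights `w`
#'   (mm^2); `sum(w)` equals the disk area.
#' @export
disk_quadrature <- function(radius, n_r = 12, n_theta = 24) {
  gl <- pracma::gaussLegendre(n_r, 0, radius)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rho <- rep(gl$x, times = n_theta)
  th <- rep(theta, each = n_r)
  w <- rep(gl$w * gl$x, times = n_theta) * (2 * pi / n_theta)
  list(X = rho * cos(th), Y = rho * sin(th), w = w, radius = radius)
}

#' Area-averaged normal velocity of a profile function
#'
#' @param f a function `f(X, Y)` returning the normal velocity (m/s) at
#'   in-plane coordinates (mm), or a numeric vector of values already
#'   evaluated at the quadrature nodes.
#' @param quad a [disk_quadrature()].
#' @return The area average (m/s).
#' @export
area_averaged_velocity <- function(f, quad) {
  v <- if (is.function(f)) f(quad$X, quad$Y) else f
  sum(quad$w * v) / sum(quad$w)
}

#' Normalized RMS profile error
#'
#' Root-mean-square difference between a reconstructed and a true velocity
#' profile over the cross-section,
#' \deqn{e_{RMS} = \sqrt{\frac{\int e^2\, dA}{A}},}
#' normalized by the magnitude of the area-averaged true velocity at the
#' same instant and expressed in percent.
#'
#' @param recon,truth functions `f(X, Y)` (m/s) or value vectors on the
#'   quadrature nodes.
#' @param quad a [disk_quadrature()].
#' @param normalize divide by the area-averaged truth (default). If the
#'   normalizer is degenerate (see `tol_frac`), the unnormalized RMS (m/s)
#'   is returned with attribute `"normalized" = FALSE`.
#' @param tol_frac the normalizer is considered degenerate when its
#'   magnitude is below `tol_frac` times the peak true velocity.
#' @return Percent error (or m/s when unnormalized; see `normalize`).
#' @export
e_rms <- function(recon, truth, quad, normalize = TRUE, tol_frac = 1e-6) {
  vr <- if (is.function(recon)) recon(quad$X, quad$Y) else recon
  vt <- if (is.function(truth)) truth(quad$X, quad$Y) else truth
  A <- sum(quad$w)
  rms <- sqrt(sum(quad$w * (vr - vt)^2) / A)
  if (!normalize) return(rms)
  vbar <- sum(quad$w * vt) / A
  if (abs(vbar) < tol_frac * max(abs(vt))) {
    out <- rms
    attr(out, "normalized") <- FALSE
    return(out)
  }
  100 * rms / abs(vbar)
}

#' Relative error of the cross-sectional maximum velocity
#'
#' \deqn{e_{max(v)} = \frac{|\max(v_R) - \max(v_{truth})|}{\max(v_{truth})}
#'   \times 100}
#' with both maxima taken over the cross-section at the same instant.
#'
#' @inheritParams e_rms
#' @return Percent error; `NA` when the true maximum is not positive.
#' @export
e_max_v <- function(recon, truth, quad) {
  vr <- if (is.function(recon)) recon(quad$X, quad$Y) else recon
  vt <- if (is.function(truth)) truth(quad$X, quad$Y) else truth
  mt <- max(vt)
  if (mt <= 0) return(NA_real_)
  100 * abs(max(vr) - mt) / mt
}

#' Normalized RMS error between two velocity curves
#'
#' RMS of the pointwise difference between two time curves over one cycle,
#' normalized by the time mean of the reference curve and expressed in
#' percent. Instantiates the cycle-level particle-vs-truth and
#' sampling-vs-truth curve errors by argument choice.
#'
#' @param curve,reference numeric vectors on a common time grid (reference
#'   is the ground-truth curve used for normalization).
#' @param t,t_ref optional time grids for `curve` and `reference`; when both
#'   are supplied and differ, `curve` is linearly interpolated onto the
#'   reference grid.
#' @return Percent error.
#' @export
curve_rms_error <- function(curve, reference, t = NULL, t_ref = NULL) {
  if (!is.null(t) && !is.null(t_ref) &&
      (length(t) != length(t_ref) || any(t != t_ref))) {
    curve <- stats::approx(t, curve, xout = t_ref, rule = 2)$y
  }
  stopifnot(length(curve) == length(reference))
  100 * sqrt(mean((curve - reference)^2)) / abs(mean(reference))
}

#' Spatial clustering statistic
#'
#' Standard deviation of the distances between a set of points and their
#' centroid, `C_d = SD(d)`. Small values indicate points concentrated at a
#' common radius from the centroid (e.g. tracer particles clustered near the
#' vessel center), larger values a more uniform spread.
#'
#' @param points an `n x d` matrix or data frame of coordinates (mm).
#' @return `C_d` in the coordinate units; `NA` for fewer than 2 points.
#' @export
clustering_cd <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2) return(NA_real_)
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  stats::sd(d)
}

#' Stenosis localization from per-particle maximum velocities
#'
#' Estimates the axial position of a stenosis from the locations at which
#' tracked particles attained their maximum speed: particles accelerate
#' through the throat, so records with elevated maximum velocity accumulate
#' near the minimum lumen area. The estimator takes the records in the top
#' quartile of maximum speed and reports the median of their axial
#' coordinates (robust to recirculation-trapped outliers), together with
#' their 3D centroid.
#'
#' A stenotic jet concentrates the high-speed records in a short axial
#' span; in its absence the top-quartile records scatter along the vessel
#' (in pulsatile flow each particle simply peaks wherever it happens to be
#' at peak flow). The confidence flag therefore requires the top-quartile
#' axial positions to be concentrated (interquartile range below
#' `z_iqr_threshold`).
#'
#' @param records a data frame from [max_velocity_record()] with columns
#'   `speed`, `x`, `y`, `z`.
#' @param z_iqr_threshold axial interquartile range (mm) of the top-quartile
#'   records above which no distinct stenotic jet is present and the
#'   estimate is flagged low-confidence.
#' @return A list: `z` (estimated axial position, mm), `centroid`
#'   (3-vector), `confident` (logical), `n_used`.
#' @export
localize_stenosis <- function(records, z_iqr_threshold = 5) {
  stopifnot(nrow(records) >= 10)
  q3 <- stats::quantile(records$speed, 0.75, names = FALSE)
  top <- records[records$speed >= q3, , drop = FALSE]
  z_iqr <- diff(stats::quantile(top$z, c(0.25, 0.75), names = FALSE))
  list(z = stats::median(top$z),
       centroid = c(mean(top$x), mean(top$y), mean(top$z)),
       confident = z_iqr <= z_iqr_threshold,
       n_used = nrow(top))
}

#' Aggregate repeated trials of an error metric
#'
#' @param values per-trial metric values (numeric), or a long data frame
#'   with columns `metric` and `value`.
#' @return For a numeric vector, a list with `mean`, `sd` (sample SD) and
#'   `n`; for a data frame, one row per metric.
#' @export
aggregate_trials <- function(values) {
  if (is.data.frame(values)) {
    sp <- split(values$value, values$metric)
    out <- data.frame(metric = names(sp),
                      mean = vapply(sp, mean, numeric(1)),
                      sd = vapply(sp, stats::sd, numeric(1)),
                      n = vapply(sp, length, integer(1)),
                      row.names = NULL)
    return(out)
  }
  stopifnot(length(values) >= 2)
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}
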