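#' Direct sampling plan for the plane of interest
#'
#' The sampling arm of the workbench: the ground-truth field is probed at
#' random in-plane locations at regularly spaced cycle times, establishing
#' how many observations a reconstruction needs and serving as the accuracy
#' upper bound for the particle arm. Points are confined to a central disk
#' of `radius_fraction` times the lumen radius (0.8 by default), away from
#' the vanishing near-wall velocities.
#'
#' @param n_points observations per time instant (the study grid is 10, 20,
#'   40, 60, 80, 100).
#' @param delta_tc cycle-time spacing of the instants (s); the study values
#'   96, 64 and 48 ms sample 10, 15 and 20 times per cycle.
#' @param radius_fraction fraction of the lumen radius enclosing the sample
#'   points, in `(0, 1]`.
#' @param n_trials number of repeated random draws used when aggregating.
#' @param T_c cardiac cycle length (s).
#' @return An object of class `"sampling_plan"`.
#' @export
sampling_plan <- function(n_points = 40, delta_tc = 0.064,
                          radius_fraction = 0.8, n_trials = 30, T_c = 0.96) {
  stopifnot(n_points >= 1, delta_tc > 0, n_trials >= 1)
  if (radius_fraction <= 0 || radius_fraction > 1)
    stop("`radius_fraction` must lie in (0, 1]", call. = FALSE)
  structure(list(n_points = n_points, delta_tc = delta_tc,
                 radius_fraction = radius_fraction, n_trials = n_trials,
                 T_c = T_c,
                 instants = round(T_c / delta_tc)),
            class = "sampling_plan")
}

#' Cycle-time spacing for a number of instants per cycle
#'
#' @param instants_per_cycle number of sampling instants in one cycle.
#' @param T_c cycle length (s).
#' @return `delta_tc = T_c / instants_per_cycle` (s).
#' @examples
#' delta_tc_for(15)        # 64 ms
#' @export
delta_tc_for <- function(instants_per_cycle, T_c = 0.96) {
  if (instants_per_cycle < 1) stop("need at least one instant", call. = FALSE)
  T_c / instants_per_cycle
}

#' Sample the ground-truth field at the plane of interest
#'
#' For each cycle instant `t_c` in `0, delta_tc, 2 delta_tc, ...` within one
#' cycle, draws `n_points` positions independently and uniformly over the
#' central disk (area-uniform: radius `R sqrt(u)`, angle uniform) and
#' records the true normal velocity there.
#'
#' @param field a `"flow_field"`.
#' @param plane a [poi_plane()].
#' @param plan a [sampling_plan()].
#' @return A data frame with columns `X`, `Y` (mm), `t_c` (s), `v_n` (m/s).
#'   Draws come from R's RNG stream; set the seed for reproducibility.
#' @export
sample_poi <- function(field, plane, plan) {
  t_inst <- (seq_len(plan$instants) - 1) * plan$delta_tc
  Rmax <- plan$radius_fraction * plane$radius
  out <- lapply(t_inst, function(tc) {
    r <- Rmax * sqrt(stats::runif(plan$n_points))
    th <- stats::runif(plan$n_points, 0, 2 * pi)
    X <- r * cos(th); Y <- r * sin(th)
    data.frame(X = X, Y = Y, t_c = tc,
               v_n = as.numeric(truth_vn(field, plane, X, Y, tc)))
  })
  do.call(rbind, out)
}
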