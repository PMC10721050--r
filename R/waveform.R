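#' Parametric coronary inlet waveform
#'
#' A strictly periodic, non-negative flow-factor waveform emulating the
#' characteristic left-coronary inflow pattern: a small systolic pulse
#' followed by the dominant diastolic pulse, with the global maximum at
#' `peak_time` within the cycle. The waveform is a baseline plus a sum of
#' Gaussian pulses, made exactly periodic by summing contributions from the
#' adjacent cycles.
#'
#' The waveform is dimensionless; the flow field scales it by a flow-rate
#' amplitude (mL/s). With the defaults the global maximum equals 1 at
#' `t = 0.582` s, so the amplitude is the peak flow rate.
#'
#' @param period cardiac cycle length `T_c` (s).
#' @param amplitudes pulse heights (dimensionless).
#' @param centers pulse centers within the cycle (s). The last (dominant)
#'   pulse center is the peak-flow time.
#' @param widths Gaussian pulse widths (s).
#' @param baseline constant forward-flow offset (dimensionless).
#' @return An object of class `"waveform"`.
#' @examples
#' wf <- coronary_waveform()
#' eval_waveform(wf, c(0, 0.582, 0.96))
#' @export
coronary_waveform <- function(period = 0.96,
                              amplitudes = c(0.35, 0.88),
                              centers = c(0.15, 0.582),
                              widths = c(0.07, 0.17),
                              baseline = 0.12) {
  stopifnot(period > 0, length(amplitudes) == length(centers),
            length(centers) == length(widths), all(widths > 0),
            baseline >= 0, all(amplitudes >= 0))
  structure(
    list(type = "gaussian", period = period, amplitudes = amplitudes,
         centers = centers, widths = widths, baseline = baseline,
         peak_time = centers[which.max(amplitudes)]),
    class = "waveform")
}

#' Waveform from a tabulated curve
#'
#' Builds a periodic waveform from a two-column table `(t, w)` covering one
#' cycle, interpolated with a periodic cubic spline.
#'
#' @param table a data frame or matrix with columns time (s) and value, or a
#'   path to a delimited text file with those two columns.
#' @param period cycle length (s); defaults to the table's time span.
#' @return An object of class `"waveform"`.
#' @export
waveform_from_table <- function(table, period = NULL) {
  if (is.character(table))
    table <- utils::read.table(table, header = FALSE,
                               col.names = c("t", "w"))
  tab <- as.data.frame(table)[, 1:2]
  names(tab) <- c("t", "w")
  tab <- tab[order(tab$t), ]
  if (is.null(period)) period <- max(tab$t) - min(tab$t)
  stopifnot(period > 0, nrow(tab) >= 4)
  fun <- stats::splinefun(tab$t - min(tab$t), tab$w, method = "periodic")
  grid <- seq(0, period, length.out = 2048)
  structure(
    list(type = "table", period = period, fun = fun,
         peak_time = grid[which.max(fun(grid))]),
    class = "waveform")
}

#' Evaluate a waveform
#'
#' @param waveform a `"waveform"` object.
#' @param t times (s); any real values, evaluated periodically.
#' @param deriv derivative order 0, 1 or 2 (time derivatives are needed by
#'   the lumped-parameter pressure model).
#' @return Waveform values (or derivatives), same length as `t`.
#' @export
eval_waveform <- function(waveform, t, deriv = 0) {
  Tc <- waveform$period
  tc <- t %% Tc
  if (waveform$type == "table") {
    return(waveform$fun(tc, deriv = deriv))
  }
  out <- if (deriv == 0) rep(waveform$baseline, length(tc)) else
    numeric(length(tc))
  for (i in seq_along(waveform$amplitudes)) {
    a <- waveform$amplitudes[i]; c0 <- waveform$centers[i]
    s <- waveform$widths[i]
    # wrap neighbouring cycles so the sum is exactly periodic and smooth
    for (k in -1:1) {
      u <- tc - c0 - k * Tc
      g <- a * exp(-(u / s)^2)
      out <- out + switch(as.character(deriv),
                          "0" = g,
                          "1" = g * (-2 * u / s^2),
                          "2" = g * (4 * u^2 / s^4 - 2 / s^2),
                          stop("deriv must be 0, 1 or 2"))
    }
  }
  out
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Periodic %s waveform, T_c = %.3g s, peak at t = %.3g s\n",
              x$type, x$period, x$peak_time))
  invisible(x)
}
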