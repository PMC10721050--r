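#' Run configuration
#'
#' Bundles every parameter of an end-to-end experiment — geometry, waveform,
#' seeding and sampling plans, kriging and metric settings, and the master
#' random seed — into one serializable list. The master seed
#' deterministically derives the per-stage seeds, so a configuration (or its
#' saved manifest) replays bit-identically.
#'
#' @param geometry list of [stenosed_tube()] arguments.
#' @param waveform list of [coronary_waveform()] arguments.
#' @param flow_amplitude peak flow rate (mL/s).
#' @param recirculation list of [recirculation()] arguments, or `NULL`.
#' @param poi_offset plane-of-interest offset downstream of the minimum
#'   lumen area (mm).
#' @param seeding list of [seeding_plan()] arguments.
#' @param sampling list of [sampling_plan()] arguments.
#' @param kriging list of kriging settings (`n_ring`, `grid_n`).
#' @param seed master RNG seed (integer).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(geometry = list(), waveform = list(),
                       flow_amplitude = 3.5, recirculation = NULL,
                       poi_offset = 10, seeding = list(), sampling = list(),
                       kriging = list(n_ring = 36, grid_n = 64),
                       seed = 1L) {
  structure(list(geometry = geometry, waveform = waveform,
                 flow_amplitude = flow_amplitude,
                 recirculation = recirculation, poi_offset = poi_offset,
                 seeding = seeding, sampling = sampling, kriging = kriging,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read or write a run configuration
#'
#' Configurations serialize losslessly to YAML or JSON (chosen by file
#' extension).
#'
#' @param config a [run_config()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_run_config` returns the `"run_config"`;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(run_config, x)
}

# instantiate the field and plane described by a config
build_field <- function(config) {
  geom <- do.call(stenosed_tube, config$geometry)
  wf <- do.call(coronary_waveform, config$waveform)
  rec <- if (is.null(config$recirculation)) NULL else
    do.call(recirculation, config$recirculation)
  field <- flow_field(geom, wf, flow_amplitude = config$flow_amplitude,
                      recirculation = rec)
  list(field = field, plane = poi_plane(geom, offset = config$poi_offset))
}

#' Derive per-stage seeds from a master seed
#'
#' @param master master seed (integer).
#' @param n number of stage seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max, n)
}

# area-averaged reconstruction curve at the given instants, via the disk
# quadrature nodes and the dual kriging means
recon_mean_curve <- function(fit, instants, quad) {
  vapply(instants, function(tc) {
    nd <- data.frame(X = quad$X, Y = quad$Y, t_c = tc)
    sum(quad$w * predict(fit, nd)) / sum(quad$w)
  }, numeric(1))
}

#' Sampling-convergence sweep
#'
#' Repeats the sampling-arm reconstruction over a grid of observation
#' counts and cycle-time spacings, scoring each trial by the normalized RMS
#' error between the area-averaged reconstructed and true velocity curves
#' over one cycle (normalized by the cycle-mean true velocity). Reports the
#' median and standard deviation across trials per cell.
#'
#' @param field a `"flow_field"`.
#' @param plane a [poi_plane()].
#' @param n_points vector of points-per-instant values.
#' @param delta_tc vector of cycle-time spacings (s).
#' @param n_trials random repetitions per cell.
#' @param seed master seed; each (cell, trial) gets a derived seed.
#' @param radius_fraction sampling confinement radius fraction.
#' @param n_ring no-slip augmentation points.
#' @param quad disk quadrature for the area averages.
#' @return A data frame of class `"convergence_sweep"` with one row per
#'   cell: `n_points`, `delta_tc`, `median_error`, `sd_error`, `n_trials`.
#' @export
run_convergence_sweep <- function(field, plane,
                                  n_points = c(10, 20, 40, 60, 80, 100),
                                  delta_tc = c(0.096, 0.064, 0.048),
                                  n_trials = 30, seed = 1,
                                  radius_fraction = 0.8, n_ring = 36,
                                  quad = disk_quadrature(plane$radius, 8, 12)) {
  Tc <- field$waveform$period
  cells <- expand.grid(n_points = n_points, delta_tc = delta_tc)
  seeds <- derive_seeds(seed, nrow(cells) * n_trials)
  dim(seeds) <- c(nrow(cells), n_trials)
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    plan <- sampling_plan(n_points = cells$n_points[ci],
                          delta_tc = cells$delta_tc[ci],
                          radius_fraction = radius_fraction, T_c = Tc)
    instants <- (seq_len(plan$instants) - 1) * plan$delta_tc
    truth <- truth_mean_vn(field, plane, instants, quad)
    errs <- vapply(seq_len(n_trials), function(tr) {
      set.seed(seeds[ci, tr])
      obs <- sample_poi(field, plane, plan)
      train <- augment_no_slip(training_set(obs, plane), n_ring = n_ring)
      fit <- ukrige(data = train)
      curve_rms_error(recon_mean_curve(fit, instants, quad), truth)
    }, numeric(1))
    data.frame(n_points = cells$n_points[ci], delta_tc = cells$delta_tc[ci],
               median_error = stats::median(errs), sd_error = stats::sd(errs),
               n_trials = n_trials)
  })
  structure(do.call(rbind, res),
            class = c("convergence_sweep", "data.frame"))
}

# score one reconstruction (a fitted ukrige model) against the truth:
# per-instant normalized RMS and peak-velocity errors, the cycle-level
# curve error, and cycle summaries
score_reconstruction <- function(fit, field, plane, instants, quad) {
  truth_curve <- truth_mean_vn(field, plane, instants, quad)
  e_rms_t <- numeric(length(instants))
  e_max_t <- numeric(length(instants))
  recon_curve <- numeric(length(instants))
  for (i in seq_along(instants)) {
    tc <- instants[i]
    vt <- as.numeric(truth_vn(field, plane, quad$X, quad$Y, tc))
    nd <- data.frame(X = quad$X, Y = quad$Y, t_c = tc)
    vr <- predict(fit, nd)
    e_rms_t[i] <- e_rms(vr, vt, quad)
    e_max_t[i] <- e_max_v(vr, vt, quad)
    recon_curve[i] <- sum(quad$w * vr) / sum(quad$w)
  }
  list(instants = instants,
       e_rms_t = e_rms_t, e_max_t = e_max_t,
       recon_curve = recon_curve, truth_curve = truth_curve,
       curve_error = curve_rms_error(recon_curve, truth_curve),
       e_rms_mean = mean(e_rms_t), e_rms_max = max(e_rms_t),
       e_rms_min = min(e_rms_t),
       e_max_mean = mean(e_max_t), e_max_max = max(e_max_t),
       e_max_min = min(e_max_t))
}

#' Full particle-tracking experiment
#'
#' Runs the particle arm end to end — seed, track, extract plane-of-interest
#' crossings, pool by cycle time, reconstruct by universal kriging with
#' no-slip augmentation, score against the ground truth — over repeated
#' random trials, and (optionally) the matched sampling arm on the same
#' field for comparison.
#'
#' @param field a `"flow_field"`.
#' @param plane a [poi_plane()].
#' @param seed_plan a [seeding_plan()].
#' @param n_trials tracking repetitions (the area-averaged comparisons
#'   stabilize within about 10).
#' @param sampling_arm `NULL`, or a [sampling_plan()] for the matched
#'   direct-sampling arm (scored over its own `n_trials`).
#' @param noise_level localization noise level `L_n` applied to crossings
#'   (0 for perfect tracking).
#' @param seed master seed.
#' @param n_ring no-slip augmentation points.
#' @param quad disk quadrature used for scoring.
#' @param dt_pt,t_end tracker step and horizon (s).
#' @return An object of class `"error_report"`: per-trial scores for the
#'   particle arm (and sampling arm), aggregated means and standard
#'   deviations of the cycle summaries, clustering statistics, and the
#'   configuration echo.
#' @export
run_particle_experiment <- function(field, plane, seed_plan = seeding_plan(),
                                    n_trials = 10, sampling_arm = NULL,
                                    noise_level = 0, seed = 1, n_ring = 36,
                                    quad = disk_quadrature(plane$radius, 10, 16),
                                    dt_pt = 0.001,
                                    t_end = 6 * field$waveform$period) {
  Tc <- field$waveform$period
  instants <- (seq_len(round(Tc / seed_plan$delta_tc)) - 1) *
    seed_plan$delta_tc
  seeds <- derive_seeds(seed, n_trials + 1000)
  par_trials <- vector("list", n_trials)
  cd_par <- numeric(n_trials)
  n_crossings <- integer(n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(seeds[tr])
    starts <- seed_particles(seed_plan, field)
    tracks <- track(field, starts, dt_pt = dt_pt, t_end = t_end)
    cross <- detect_poi_crossings(tracks, plane, field)
    cross <- group_by_cycle_time(cross, Tc)
    if (noise_level > 0) cross <- add_noise(cross, noise_level, plane)
    n_crossings[tr] <- nrow(cross)
    cd_par[tr] <- clustering_cd(cross[, c("X", "Y")])
    train <- augment_no_slip(training_set(cross, plane,
                                          source = "particles"),
                             n_ring = n_ring, instants = instants)
    fit <- ukrige(data = train)
    par_trials[[tr]] <- score_reconstruction(fit, field, plane, instants,
                                             quad)
  }
  sam_trials <- NULL; cd_sam <- NULL
  if (!is.null(sampling_arm)) {
    ns <- sampling_arm$n_trials
    sseeds <- derive_seeds(seeds[n_trials + 1], ns)
    sam_trials <- vector("list", ns)
    cd_sam <- numeric(ns)
    for (tr in seq_len(ns)) {
      set.seed(sseeds[tr])
      obs <- sample_poi(field, plane, sampling_arm)
      cd_sam[tr] <- clustering_cd(obs[, c("X", "Y")])
      train <- augment_no_slip(training_set(obs, plane), n_ring = n_ring)
      fit <- ukrige(data = train)
      sam_trials[[tr]] <- score_reconstruction(fit, field, plane, instants,
                                               quad)
    }
  }
  agg <- function(trials, what) {
    v <- vapply(trials, function(x) x[[what]], numeric(1))
    c(mean = mean(v), sd = stats::sd(v))
  }
  summarize_arm <- function(trials) {
    if (is.null(trials)) return(NULL)
    sapply(c("curve_error", "e_rms_mean", "e_rms_max", "e_rms_min",
             "e_max_mean", "e_max_max", "e_max_min"),
           function(w) agg(trials, w))
  }
  structure(
    list(instants = instants,
         particle = par_trials, sampling = sam_trials,
         particle_summary = summarize_arm(par_trials),
         sampling_summary = summarize_arm(sam_trials),
         cd_particle = c(mean = mean(cd_par), sd = stats::sd(cd_par)),
         cd_sampling = if (!is.null(cd_sam))
           c(mean = mean(cd_sam), sd = stats::sd(cd_sam)) else NULL,
         n_crossings = n_crossings,
         noise_level = noise_level, seed = seed,
         seed_plan = seed_plan, sampling_arm = sampling_arm),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("PEPT reconstruction error report\n")
  cat(sprintf("  particle arm: %d trials, %s crossings per trial (mean %.0f)\n",
              length(x$particle),
              paste(range(x$n_crossings), collapse = "-"),
              mean(x$n_crossings)))
  ps <- x$particle_summary
  cat(sprintf("  e_par-truth (curve)        : %.1f%% +/- %.1f%%\n",
              ps["mean", "curve_error"], ps["sd", "curve_error"]))
  cat(sprintf("  mean e_RMS over cycle      : %.1f%% +/- %.1f%%\n",
              ps["mean", "e_rms_mean"], ps["sd", "e_rms_mean"]))
  cat(sprintf("  mean e_max(v) over cycle   : %.1f%% +/- %.1f%%\n",
              ps["mean", "e_max_mean"], ps["sd", "e_max_mean"]))
  cat(sprintf("  clustering C_d             : %.2f +/- %.2f mm\n",
              x$cd_particle["mean"], x$cd_particle["sd"]))
  if (!is.null(x$sampling_summary)) {
    ss <- x$sampling_summary
    cat(sprintf("  sampling arm e_sam-truth   : %.1f%% +/- %.1f%%  (C_d %.2f mm)\n",
                ss["mean", "curve_error"], ss["sd", "curve_error"],
                x$cd_sampling["mean"]))
  }
  if (x$noise_level > 0)
    cat(sprintf("  localization noise L_n     : %.3g\n", x$noise_level))
  invisible(x)
}

#' Noise sweep
#'
#' Repeats the particle experiment at increasing localization-noise levels
#' and reports the cycle-level curve error per level. The `L_n = 0` row is
#' the noiseless experiment.
#'
#' @inheritParams run_particle_experiment
#' @param L_n vector of noise levels (fractions of the lumen radius at the
#'   plane of interest).
#' @return A data frame with columns `L_n`, `max_noise_mm`
#'   (`L_n * radius`), `curve_error_mean`, `curve_error_sd`.
#' @export
run_noise_sweep <- function(field, plane, L_n = c(0, 0.05, 0.1, 0.2),
                            seed_plan = seeding_plan(), n_trials = 5,
                            seed = 1, ...) {
  rows <- lapply(L_n, function(ln) {
    rep <- run_particle_experiment(field, plane, seed_plan = seed_plan,
                                   n_trials = n_trials, noise_level = ln,
                                   seed = seed, ...)
    data.frame(L_n = ln, max_noise_mm = ln * plane$radius,
               curve_error_mean = rep$particle_summary["mean", "curve_error"],
               curve_error_sd = rep$particle_summary["sd", "curve_error"])
  })
  do.call(rbind, rows)
}

#' Write a run manifest
#'
#' Emits a JSON manifest — configuration, master seed, derived stage seeds
#' and package version — sufficient to replay a run bit-identically.
#'
#' @param config a [run_config()].
#' @param path output path (`.json`).
#' @param extra optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  m <- c(list(config = unclass(config),
              package_version =
                as.character(utils::packageVersion("peptrecon")),
              r_version = R.version.string),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
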