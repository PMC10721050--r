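#' Export trajectories and crossings as CSV
#'
#' Trajectories are written in long format (`id, t, x, y, z`), crossings
#' and training observations with their full columns.
#'
#' @param tracks a `"pept_tracks"` object.
#' @param path output file.
#' @param every keep every `every`-th time step (thinning for large runs).
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path, every = 1) {
  keep <- seq(1, length(tracks$t), by = every)
  long <- do.call(rbind, lapply(seq_len(ncol(tracks$z)), function(j) {
    ok <- keep[!is.na(tracks$z[keep, j])]
    if (length(ok) == 0) return(NULL)
    data.frame(id = tracks$seeds$id[j], t = tracks$t[ok],
               x = tracks$x[ok, j], y = tracks$y[ok, j],
               z = tracks$z[ok, j])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param crossings a data frame of plane-of-interest crossings or sampled
#'   observations.
#' @export
write_crossings_csv <- function(crossings, path) {
  utils::write.csv(crossings, path, row.names = FALSE)
  invisible(path)
}

#' Export a field snapshot on a voxel grid
#'
#' Evaluates the ground-truth velocity on a regular voxel grid spanning the
#' vessel bounding box at one instant and writes it as legacy-ASCII VTK
#' structured points (readable by ParaView) or as CSV
#' (`x, y, z, t, vx, vy, vz`). Out-of-lumen voxels carry zero velocity in
#' VTK output and are dropped from CSV output.
#'
#' @param field a `"flow_field"`.
#' @param t snapshot time (s).
#' @param path output file.
#' @param spacing voxel spacing (mm).
#' @param format `"vtk"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
export_field_snapshot <- function(field, t, path, spacing = 0.25,
                                  format = c("auto", "vtk", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vtk$", path)) "vtk" else "csv"
  geom <- field$geometry
  R <- geom$baseline_radius
  xs <- seq(-R, R, by = spacing)
  zs <- seq(0, geom$tube_length, by = spacing)
  gg <- expand.grid(x = xs, y = xs, z = zs)
  v <- eval_velocity(field, as.matrix(gg), t)
  inside <- attr(v, "inside")
  if (format == "csv") {
    out <- cbind(gg[inside, ], t = t, vx = v[inside, 1], vy = v[inside, 2],
                 vz = v[inside, 3])
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }
  v[!inside, ] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("velocity snapshot t = %g s", t),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", length(xs), length(xs),
                       length(zs)),
               sprintf("ORIGIN %g %g %g", -R, -R, 0),
               sprintf("SPACING %g %g %g", spacing, spacing, spacing),
               sprintf("POINT_DATA %d", nrow(gg)),
               "VECTORS velocity double"), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fitted variogram as JSON
#'
#' @param vgm a `"variogram_model"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variogram_json <- function(vgm, path) {
  jsonlite::write_json(unclass(vgm)[c("nugget", "sill", "range",
                                      "time_scaling", "degenerate")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
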