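#' Stenosed straight-tube geometry
#'
#' Describes an axisymmetric straight vessel (axis along global `z`) whose
#' lumen narrows over a finite axial support with a sinusoidal (cosine-bell)
#' occlusion profile. The occlusion fraction `occlusion` is the fractional
#' reduction of the cross-sectional *diameter* at the throat, so a 50%
#' occlusion halves the lumen radius at the stenosis center.
#'
#' The lumen radius is
#' \deqn{R(z) = r_0 - r_0\,o\,\tfrac{1}{2}\left[1 + \cos\!\left(
#'   \frac{2\pi (z - z_c)}{L_s}\right)\right]}
#' for \eqn{|z - z_c| \le L_s/2} and \eqn{R(z) = r_0} outside the bell, so
#' the narrowing blends smoothly (C1) into the parent vessel and the minimum
#' lumen radius \eqn{r_0(1-o)} is attained exactly at `z = stenosis_center`.
#'
#' @param baseline_radius vessel radius away from the stenosis (mm).
#' @param occlusion diameter-reduction fraction in `[0, 1)`; 0 means no
#'   stenosis.
#' @param stenosis_center axial position of the minimum lumen area (mm).
#' @param stenosis_length axial support of the occlusion bell (mm).
#' @param tube_length total axial extent of the vessel, from `z = 0` (mm).
#' @return An object of class `"stenosed_tube"`.
#' @examples
#' geom <- stenosed_tube(occlusion = 0.5)
#' lumen_radius(geom, geom$stenosis_center)   # half the baseline radius
#' @export
stenosed_tube <- function(baseline_radius = 1.75, occlusion = 0.5,
                          stenosis_center = 25, stenosis_length = 10,
                          tube_length = 60) {
  stopifnot(baseline_radius > 0, stenosis_length > 0, tube_length > 0)
  if (occlusion < 0 || occlusion >= 1)
    stop("`occlusion` must lie in [0, 1)", call. = FALSE)
  if (stenosis_center < 0 || stenosis_center > tube_length)
    stop("`stenosis_center` must lie inside the tube", call. = FALSE)
  structure(
    list(baseline_radius = baseline_radius, occlusion = occlusion,
         stenosis_center = stenosis_center, stenosis_length = stenosis_length,
         tube_length = tube_length),
    class = "stenosed_tube")
}

#' @export
print.stenosed_tube <- function(x, ...) {
  cat(sprintf(
    "Stenosed tube: r0 = %.3g mm, %.0f%% diameter occlusion at z = %.3g mm (L_s = %.3g mm), length %.3g mm\n",
    x$baseline_radius, 100 * x$occlusion, x$stenosis_center,
    x$stenosis_length, x$tube_length))
  invisible(x)
}

#' Lumen radius along the vessel axis
#'
#' Evaluates the cosine-bell occlusion profile of a [stenosed_tube()].
#'
#' @param geometry a `"stenosed_tube"` object.
#' @param z axial positions (mm); vectorized.
#' @return Lumen radii (mm), same length as `z`.
#' @export
lumen_radius <- function(geometry, z) {
  if (any(z < 0 | z > geometry$tube_length))
    stop("axial position outside the tube domain", call. = FALSE)
  r0 <- geometry$baseline_radius
  o  <- geometry$occlusion
  zc <- geometry$stenosis_center
  Ls <- geometry$stenosis_length
  bell <- ifelse(abs(z - zc) <= Ls / 2,
                 0.5 * (1 + cos(2 * pi * (z - zc) / Ls)), 0)
  r0 - r0 * o * bell
}

# dR/dz of the occlusion profile; needed for the continuity-derived radial
# velocity component.
lumen_radius_deriv <- function(geometry, z) {
  r0 <- geometry$baseline_radius
  o  <- geometry$occlusion
  zc <- geometry$stenosis_center
  Ls <- geometry$stenosis_length
  ifelse(abs(z - zc) <= Ls / 2,
         r0 * o * pi / Ls * sin(2 * pi * (z - zc) / Ls), 0)
}

#' Minimum lumen area of a stenosed tube
#'
#' @param geometry a `"stenosed_tube"` object.
#' @return A list with `z` (axial position, mm) and `area` (mm^2). For an
#'   unoccluded vessel the minimum is flat; by convention the stenosis
#'   center is reported.
#' @export
min_lumen_area <- function(geometry) {
  z <- geometry$stenosis_center
  r <- geometry$baseline_radius * (1 - geometry$occlusion)
  list(z = z, area = pi * r^2)
}

#' Daughter radii from Murray's law
#'
#' Murray's law states that at a bifurcation the cube of the parent radius
#' equals the sum of cubes of the daughter radii; with flow split fractions
#' \eqn{f_1 + f_2 = 1} each daughter carries flow in proportion to its cubed
#' radius, giving \eqn{r_i = r_p f_i^{1/3}}.
#'
#' @param parent_radius parent-vessel radius (mm).
#' @param flow_split fraction of the parent flow entering the first daughter,
#'   in `(0, 1)`.
#' @return Numeric vector of two daughter radii (mm).
#' @examples
#' murray_daughter_radii(2, 0.5)  # symmetric: 2 * 2^(-1/3)
#' @export
murray_daughter_radii <- function(parent_radius, flow_split = 0.5) {
  stopifnot(parent_radius > 0)
  if (flow_split <= 0 || flow_split >= 1)
    stop("`flow_split` must lie strictly inside (0, 1)", call. = FALSE)
  parent_radius * c(flow_split, 1 - flow_split)^(1 / 3)
}

#' Idealized coronary bifurcation geometry
#'
#' Assembles an idealized left-main bifurcation: a parent vessel splitting
#' into two daughters (LAD and LCx) whose radii follow Murray's law and whose
#' centerlines leave the parent axis at the given branch angles. Each branch
#' may carry its own stenosis, described by a [stenosed_tube()] along the
#' branch's own centerline coordinate.
#'
#' @param parent_radius radius of the parent (left main) vessel, mm.
#' @param flow_split fraction of parent flow entering the first daughter.
#' @param branch_angles angles (degrees) between each daughter centerline and
#'   the parent axis; defaults 35 (LAD) and 40 (LCx).
#' @param parent_length,branch_length centerline lengths (mm).
#' @param occlusion per-branch diameter occlusion fractions (length 2).
#' @param stenosis_center,stenosis_length stenosis descriptors applied to an
#'   occluded branch (branch-centerline coordinates, mm).
#' @return An object of class `"bifurcation"` with per-branch
#'   `"stenosed_tube"` descriptors and unit direction vectors.
#' @export
bifurcation_geometry <- function(parent_radius = 2, flow_split = 0.5,
                                 branch_angles = c(35, 40),
                                 parent_length = 20, branch_length = 45,
                                 occlusion = c(0, 0.5),
                                 stenosis_center = 15, stenosis_length = 10) {
  stopifnot(length(branch_angles) == 2, length(occlusion) == 2)
  r_d <- murray_daughter_radii(parent_radius, flow_split)
  if (abs(parent_radius^3 - sum(r_d^3)) > 1e-9 * parent_radius^3)
    stop("Murray's law violated in construction", call. = FALSE)
  th <- branch_angles * pi / 180
  branches <- lapply(1:2, function(i) {
    stenosed_tube(baseline_radius = r_d[i], occlusion = occlusion[i],
                  stenosis_center = stenosis_center,
                  stenosis_length = stenosis_length,
                  tube_length = branch_length)
  })
  structure(
    list(parent_radius = parent_radius, daughter_radii = r_d,
         flow_split = c(flow_split, 1 - flow_split),
         branch_angles = branch_angles,
         # unit centerline directions in the bifurcation plane (parent = +z)
         branch_directions = rbind(c(sin(th[1]), 0, cos(th[1])),
                                   c(-sin(th[2]), 0, cos(th[2]))),
         parent_length = parent_length, branches = branches),
    class = "bifurcation")
}

#' @export
print.bifurcation <- function(x, ...) {
  cat(sprintf(
    "Idealized bifurcation: parent r = %.3g mm -> daughters %.4g / %.4g mm (Murray), angles %g / %g deg\n",
    x$parent_radius, x$daughter_radii[1], x$daughter_radii[2],
    x$branch_angles[1], x$branch_angles[2]))
  cat(sprintf("  branch occlusions: %.0f%% / %.0f%%\n",
              100 * x$branches[[1]]$occlusion, 100 * x$branches[[2]]$occlusion))
  invisible(x)
}

#' Plane of interest downstream of the minimum lumen area
#'
#' Constructs the measurement cross-section: a plane perpendicular to the
#' vessel centerline a fixed distance downstream of the minimum lumen area
#' (MLA). The 10 mm default follows standard practice for fractional flow
#' reserve assessment distal to a lesion.
#'
#' @param geometry a `"stenosed_tube"` object.
#' @param offset axial distance downstream of the MLA (mm); may be 0 to place
#'   the plane at the throat.
#' @return An object of class `"poi_plane"`: `origin` (3-vector, mm),
#'   `normal` (unit 3-vector), `e1`, `e2` (orthonormal in-plane basis),
#'   `radius` (lumen radius at the plane, mm) and `z` (axial station, mm).
#' @export
poi_plane <- function(geometry, offset = 10) {
  z <- min_lumen_area(geometry)$z + offset
  if (z < 0 || z > geometry$tube_length)
    stop("plane of interest falls outside the vessel domain", call. = FALSE)
  structure(
    list(origin = c(0, 0, z), normal = c(0, 0, 1),
         e1 = c(1, 0, 0), e2 = c(0, 1, 0),
         radius = lumen_radius(geometry, z), z = z),
    class = "poi_plane")
}

#' @export
print.poi_plane <- function(x, ...) {
  cat(sprintf("Plane of interest at z = %.3g mm, lumen radius %.4g mm\n",
              x$z, x$radius))
  invisible(x)
}
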