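# Nozzle and phantom geometry: energy absorber, brass collimator with a
# rectangular aperture, air gaps and the voxelised water phantom.
#
# Coordinates are right handed with +z along the beam; the origin sits at
# the centre of the water surface, so the isocenter is at z = +3 cm and
# the collimator exit face at z = -6 cm.  All interfaces use cm.  Voxel
# intervals are half open, [i*h, (i+1)*h), with zero-based indices.

#' Rectangular target specification
#'
#' A water-phantom target described by its maximum range `R`, SOBP width
#' `S` and square field size `FS` (side length at the isocenter).  Labels
#' follow the `R<r>_S<s>_FS<f>` convention.
#'
#' @param range_R Target maximum range in cm of water (depth of the distal
#'   edge).
#' @param sobp_S SOBP width in cm; the proximal edge sits at
#'   `range_R - sobp_S`.
#' @param field_FS Side of the square field in cm.
#' @param label Optional label; autogenerated when missing.
#' @return Object of class `target_spec`.
#' @export
target_spec <- function(range_R, sobp_S, field_FS, label = NULL) {
  stopifnot(length(range_R) == 1, length(sobp_S) == 1, length(field_FS) == 1)
  if (range_R <= 0 || sobp_S < 0 || field_FS <= 0) {
    stop("range_R, field_FS must be positive and sobp_S >= 0")
  }
  if (sobp_S > range_R) {
    stop("sobp_S exceeds range_R: proximal edge would lie above the surface")
  }
  if (field_FS > 20) stop("field size exceeds the 20 x 20 cm^2 maximum field")
  if (is.null(label)) {
    fmt <- function(v) sub("\\.?0+$", "", sprintf("%.1f", v))
    label <- sprintf("R%s_S%s_FS%s", fmt(range_R), fmt(sobp_S), fmt(field_FS))
  }
  structure(list(range_R = range_R, sobp_S = sobp_S, field_FS = field_FS,
                 label = label),
            class = "target_spec")
}

#' Collimator thickness rule
#'
#' Targets with maximum range up to and including 10 cm use the 2-cm brass
#' collimator (whose configuration tops out at a 10-cm range); deeper
#' targets use the 4-cm collimator.
#'
#' @param range_R Target maximum range in cm.
#' @return Collimator thickness in cm (2 or 4).
#' @export
collimator_thickness_for <- function(range_R) {
  ifelse(range_R <= 10, 2, 4)
}

#' Applicator (SRA) configuration
#'
#' Placement constants of the short-range applicator: a 4-cm energy
#' absorber and a 2- or 4-cm brass collimator whose exit face sits 9 cm
#' upstream of the isocenter; the water surface lies 6 cm downstream of
#' the collimator and the isocenter 3 cm deep in water.
#'
#' @param collimator_thickness 2 or 4 cm.
#' @param aperture_half_x,aperture_half_y Aperture half-openings in cm.
#' @param absorber_gap Air gap between absorber exit and collimator entry
#'   in cm.
#' @return Object of class `sra_config` with all z stations (cm, beam
#'   coordinates).
#' @export
sra_config <- function(collimator_thickness, aperture_half_x,
                       aperture_half_y = aperture_half_x,
                       absorber_gap = 1) {
  if (!collimator_thickness %in% c(2, 4)) {
    stop("collimator_thickness must be 2 or 4 cm")
  }
  if (aperture_half_x <= 0 || aperture_half_x > 10 ||
      aperture_half_y <= 0 || aperture_half_y > 10) {
    stop("aperture half-widths must lie in (0, 10] cm")
  }
  z_col_exit <- -6
  z_col_entry <- z_col_exit - collimator_thickness
  z_abs_exit <- z_col_entry - absorber_gap
  z_abs_entry <- z_abs_exit - 4
  structure(list(collimator_thickness = collimator_thickness,
                 absorber_thickness = 4,
                 aperture_half_x = aperture_half_x,
                 aperture_half_y = aperture_half_y,
                 collimator_exit_to_isocenter = 9,
                 collimator_exit_to_water_surface = 6,
                 isocenter_depth = 3,
                 z_col_exit = z_col_exit, z_col_entry = z_col_entry,
                 z_abs_exit = z_abs_exit, z_abs_entry = z_abs_entry,
                 z_source = z_abs_entry - 1,
                 z_iso = 3),
            class = "sra_config")
}

#' Voxel grid of the water phantom
#'
#' Grid covering the field plus a lateral margin and the target range plus
#' a distal margin.  z = 0 is the water surface, +z the beam direction;
#' voxel `i` spans the half-open interval `[i*h, (i+1)*h)`.
#'
#' @param target A [target_spec()].
#' @param voxel_mm Isotropic voxel size in mm.
#' @param lateral_margin,distal_margin Margins in cm.
#' @return Object of class `phantom_grid`.
#' @export
phantom_grid <- function(target, voxel_mm = 1, lateral_margin = 3,
                         distal_margin = 1) {
  h <- voxel_mm / 10
  half_xy <- target$field_FS / 2 + lateral_margin
  depth <- target$range_R + distal_margin
  nx <- as.integer(2 * ceiling(half_xy / h))
  nz <- as.integer(ceiling(depth / h))
  structure(list(voxel_cm = h, nx = nx, ny = nx, nz = nz,
                 x0 = -nx * h / 2, y0 = -nx * h / 2, z0 = 0),
            class = "phantom_grid")
}

# voxel centre coordinate vectors
grid_axes <- function(grid) {
  h <- grid$voxel_cm
  list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * h,
       y = grid$y0 + (seq_len(grid$ny) - 0.5) * h,
       z = grid$z0 + (seq_len(grid$nz) - 0.5) * h)
}

#' Build the transport scene
#'
#' Assembles the ordered material slabs (air, absorber, air, collimator,
#' air, water) for a target, choosing the collimator thickness by the
#' range rule and the aperture by back-projection of the field edge
#' through the virtual source (see [aperture_for_target()]).
#'
#' @param target A [target_spec()].
#' @param grid Phantom grid; default [phantom_grid()] at 1 mm voxels.
#' @param source Beam source model, [beam_source_model()]; default is the
#'   model matching the collimator rule.
#' @param aperture Optional `c(half_x, half_y)` override in cm.
#' @param thickness Optional collimator thickness override (2 or 4 cm).
#' @param no_phantom If `TRUE` the phantom volume is filled with air
#'   (collimator-free in-air verification geometry uses this together
#'   with a wide `aperture`).
#' @return Object of class `scene`.
#' @export
build_scene <- function(target, grid = phantom_grid(target), source = NULL,
                        aperture = NULL, thickness = NULL,
                        no_phantom = FALSE) {
  stopifnot(inherits(target, "target_spec"))
  if (is.null(thickness)) thickness <- collimator_thickness_for(target$range_R)
  if (is.null(source)) source <- beam_source_model(thickness)
  if (is.null(aperture)) aperture <- aperture_for_target(target, source)
  sra <- sra_config(thickness, aperture[1], aperture[2])
  stopifnot(sra$collimator_exit_to_isocenter ==
            sra$collimator_exit_to_water_surface + sra$isocenter_depth)
  z_end <- grid$nz * grid$voxel_cm
  structure(list(target = target, sra = sra, grid = grid, source = source,
                 no_phantom = no_phantom, z_end = z_end),
            class = "scene")
}

#' Locate a point in the scene
#'
#' Exhaustive, mutually exclusive region labelling.  Boundary points
#' belong to the downstream region (half-open slabs along z); the
#' transverse aperture test is `|x| < half_x` and `|y| < half_y`.
#'
#' @param scene A [build_scene()] result.
#' @param point Numeric length-3 vector `c(x, y, z)` in cm.
#' @return One of `"outside"`, `"air"`, `"absorber"`, `"collimator"`,
#'   `"aperture-air"`, `"water"`.
#' @export
locate <- function(scene, point) {
  stopifnot(length(point) == 3)
  x <- point[1]; y <- point[2]; z <- point[3]
  s <- scene$sra
  if (z < s$z_source || z >= scene$z_end) return("outside")
  if (z >= 0) return(if (scene$no_phantom) "air" else "water")
  if (z >= s$z_col_entry && z < s$z_col_exit) {
    inside <- abs(x) < s$aperture_half_x && abs(y) < s$aperture_half_y
    return(if (inside) "aperture-air" else "collimator")
  }
  if (z >= s$z_abs_entry && z < s$z_abs_exit) return("absorber")
  "air"
}

#' Aperture opening for a target
#'
#' Back-projects the field edge at the proximal target plane through the
#' per-axis virtual source (located one scanning-magnet distance upstream
#' of the isocenter) onto the collimator exit face.  For an unperturbed
#' Gaussian penumbra the 50%-dose point lies on this geometric edge ray,
#' so the rule realises "cover the proximal field edge with 50% of the
#' prescribed dose" without iterative dose calibration.
#'
#' @param target A [target_spec()].
#' @param source A [beam_source_model()]; `sad_x`/`sad_y` may be `Inf`
#'   (parallel beam), in which case the aperture equals the field
#'   half-size.
#' @return Numeric `c(half_x, half_y)` in cm.
#' @export
aperture_for_target <- function(target, source = beam_source_model(
                                  collimator_thickness_for(target$range_R))) {
  z_prox <- target$range_R - target$sobp_S    # proximal plane depth, cm
  z_iso <- 3
  z_ce <- -6
  half <- target$field_FS / 2
  proj <- function(sad) {
    if (!is.finite(sad)) return(half)
    z_v <- z_iso - sad
    half * (z_ce - z_v) / (z_prox - z_v)
  }
  c(half_x = proj(source$sad_x), half_y = proj(source$sad_y))
}

# Scene serialised for the C++ kernel.  Region codes:
# 0 air(source gap) | 1 absorber | 2 air | 3 collimator slab | 4 air |
# 5 phantom.  Material ids follow physics_for_engine ordering.
scene_for_engine <- function(scene, physics = default_physics()) {
  s <- scene$sra
  g <- scene$grid
  # Highland log-correction factor per region, evaluated on the full slab
  # thickness (air gaps, absorber, collimator, phantom depth)
  mat <- physics$materials
  x0cm <- function(name) {
    m <- mat[mat$name == name, ]
    m$x0_g_cm2 / m$density
  }
  corr <- function(t_cm, name) max(1 + log10(t_cm / x0cm(name)) / 9, 0.25)
  list(z_bounds = c(s$z_source, s$z_abs_entry, s$z_abs_exit,
                    s$z_col_entry, s$z_col_exit, 0, scene$z_end),
       ap_x = s$aperture_half_x, ap_y = s$aperture_half_y,
       phantom_is_air = as.integer(scene$no_phantom),
       # per-region material id (1 air, 2 abs, 3 brass aperture handled in
       # kernel, 4 water): regions air/abs/air/collimator/air/phantom
       region_mat = as.integer(c(1, 2, 1, 3, 1,
                                 if (scene$no_phantom) 1 else 4)),
       region_corr = c(corr(s$z_abs_entry - s$z_source, "air"),
                       corr(4, "abs_plastic"),
                       corr(s$z_col_entry - s$z_abs_exit, "air"),
                       corr(s$collimator_thickness, "brass"),
                       corr(6, "air"),
                       if (scene$no_phantom) corr(scene$z_end + 6, "air")
                       else corr(scene$z_end, "water")),
       # air correction reused for aperture air
       aperture_corr = corr(s$collimator_thickness, "air"),
       nx = g$nx, ny = g$ny, nz = g$nz,
       h = g$voxel_cm, x0 = g$x0, y0 = g$y0,
       max_step = c(0.5, 0.2, 0.1, 0.1),   # air, abs, brass, water (cm)
       r_kill = max(abs(g$x0), abs(g$y0)) + 5)
}
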