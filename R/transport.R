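# R-side interface to the condensed-history transport kernel.

default_engine_opts <- function(source, scene, overrides = list()) {
  opts <- list(no_scatter = FALSE, no_straggle = FALSE, no_nuclear = FALSE,
               do_tally = TRUE, do_log = FALSE, do_ledger = FALSE,
               do_zprof = FALSE, plane_z = NA_real_,
               sad_x = source$sad_x, sad_y = source$sad_y,
               z_src = scene$sra$z_source,
               dispersion = source$energy_dispersion)
  opts[names(overrides)] <- overrides
  opts
}

# low-level call: spots must carry x_iso, y_iso, energy, sigma_pos,
# sigma_ang, n_primaries
run_engine <- function(scene, physics, spots, seed, weight, nbatch,
                       source = scene$source, opts = list()) {
  stopifnot(inherits(scene, "scene"))
  eng_opts <- default_engine_opts(source, scene, opts)
  scn <- scene_for_engine(scene, physics)
  if (!is.null(opts$max_step)) scn$max_step <- opts$max_step
  .mc_engine(physics_for_engine(physics), scn,
             spots, as.double(seed), as.double(weight), as.integer(nbatch),
             eng_opts)
}

# largest-remainder apportionment of n primaries over spot weights
apportion_primaries <- function(weights, n) {
  q <- weights / sum(weights) * n
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Transport a planned field
#'
#' Samples primaries across the plan's spots proportionally to their
#' weights, transports them through absorber, collimator and phantom, and
#' accumulates the per-voxel, per-channel (collimator-scattered vs
#' unscattered), per-batch energy-deposit tallies.  Results are fully
#' reproducible given `(seed, n_primaries, batches)`: every primary owns
#' a counter-based random stream keyed by its index.
#'
#' @param plan A [build_plan()] result.
#' @param scene Transport scene; defaults to the plan's geometry at the
#'   given voxel size.
#' @param n_primaries Number of simulated histories (statistical weights
#'   scale tallies to the plan's total protons).
#' @param seed Integer seed.
#' @param batches Number of statistical batches (>= 2).
#' @param voxel_mm Voxel size used when `scene` is not supplied.
#' @param physics Physics bundle.
#' @param opts Named list of kernel option overrides (e.g.
#'   `no_straggle = TRUE`).
#' @return Object of class `tally_grid`.
#' @export
run_field <- function(plan, scene = NULL, n_primaries = 2e5, seed = 1,
                      batches = 4, voxel_mm = 2,
                      physics = default_physics(), opts = list()) {
  stopifnot(inherits(plan, "proton_plan"))
  if (nrow(plan$spots) == 0 || plan$total_protons <= 0) {
    stop("empty plan: no weighted spots to deliver")
  }
  if (n_primaries < batches || batches < 2) {
    stop("need n_primaries >= batches >= 2")
  }
  if (is.null(scene)) {
    scene <- build_scene(plan$target,
                         grid = phantom_grid(plan$target, voxel_mm),
                         source = plan$source, aperture = plan$aperture,
                         thickness = plan$collimator_thickness)
  }
  spots <- plan$spots
  spots$n_primaries <- apportion_primaries(spots$weight, n_primaries)
  spots <- spots[spots$n_primaries > 0, ]
  weight <- plan$total_protons / n_primaries
  res <- run_engine(scene, physics, spots, seed, weight, batches,
                    source = plan$source, opts = opts)
  structure(list(eps = res$eps, epsL = res$epsL,
                 grid = scene$grid, scene = scene, nbatch = batches,
                 n_primaries = res$n_primaries, seed = seed,
                 weight_per_primary = weight,
                 energy_summary = res[c("e_in", "e_dep", "e_escaped",
                                        "e_removed")],
                 step_log = res$step_log, ledger = res$ledger),
            class = "tally_grid")
}

#' Transport a single history with a full step record
#'
#' Runs one (or a few) primaries through the scene and returns the
#' per-step, per-voxel deposition log together with the per-history
#' energy ledger, mainly for bookkeeping checks and teaching plots.
#'
#' @param spots Spot data.frame (`x_iso`, `y_iso`, `energy`, `sigma_pos`,
#'   `sigma_ang`, `n_primaries`).
#' @param scene A [build_scene()] result.
#' @param seed Integer seed.
#' @param weight Statistical weight per primary.
#' @param physics Physics bundle.
#' @param opts Kernel option overrides.
#' @return List with `step_log`, `ledger`, `eps`, `epsL` and the energy
#'   summary.
#' @export
transport_history <- function(spots, scene, seed = 1, weight = 1,
                              physics = default_physics(), opts = list()) {
  run_engine(scene, physics, spots, seed, weight, 2,
             opts = utils::modifyList(list(do_log = TRUE, do_ledger = TRUE),
                                      opts))
}

#' Trace primaries to a transverse plane
#'
#' Transports primaries and records position and energy where each one
#' first crosses `z = plane_z` (used for in-air spot-size verification at
#' the isocenter plane).
#'
#' @inheritParams transport_history
#' @param plane_z Plane position in cm (isocenter is +3).
#' @return `data.frame` with `x`, `y`, `energy`, `scattered`.
#' @export
trace_to_plane <- function(spots, scene, plane_z = 3, seed = 1,
                           physics = default_physics(), opts = list()) {
  res <- run_engine(scene, physics, spots, seed, 1, 2,
                    opts = utils::modifyList(
                      list(do_tally = FALSE, plane_z = plane_z), opts))
  res$plane
}
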