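# Shared fixtures, memoised so expensive Monte Carlo runs happen once per
# test session.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

fix_physics <- function() memo("physics", function() default_physics())

# a mid-sized reference geometry used by several module tests
fix_target <- function() target_spec(10, 5, 8)

fix_plan <- function() memo("plan", function() {
  build_plan(fix_target(), fix_physics(), seed = 3)
})

# one medium-statistics transported field shared across test files
fix_run <- function() memo("run", function() {
  tally <- run_field(fix_plan(), n_primaries = 2e5, seed = 42, batches = 4,
                     voxel_mm = 2, physics = fix_physics())
  finalize_tallies(tally, fix_plan())
})

# a tiny collimated run with the full step log, for scoring oracles
fix_logged_run <- function() memo("logged_run", function() {
  plan <- fix_plan()
  scene <- build_scene(plan$target, grid = phantom_grid(plan$target, 2),
                       source = plan$source, aperture = plan$aperture,
                       thickness = plan$collimator_thickness)
  run_field(plan, scene = scene, n_primaries = 100, seed = 9, batches = 2,
            physics = fix_physics(),
            opts = list(do_log = TRUE, do_ledger = TRUE))
})

# the full acceptance sweep (built once; used by test-acceptance)
fix_sweep <- function() memo("sweep", function() {
  run_study(study_config(base_seed = 1), physics = fix_physics(),
            verbose = FALSE)
})

# dedicated higher-statistics mirror-pooled run for voxel-level LET
# analyses of the reference geometry R15_S5_FS8
fix_fig_run <- function() memo("fig_run", function() {
  tg <- target_spec(15, 5, 8)
  plan <- build_plan(tg, fix_physics(), seed = 1015)
  tally <- run_field(plan, n_primaries = 1e6, seed = 1015, batches = 4,
                     voxel_mm = 2, physics = fix_physics())
  finalize_tallies(symmetrize_tally(tally), plan)
})

# pencil-beam spot table helper
pencil_spots <- function(energy, n, sigma_pos = 1e-6, sigma_ang = 1e-6) {
  data.frame(x_iso = 0, y_iso = 0, energy = energy,
             sigma_pos = sigma_pos, sigma_ang = sigma_ang,
             n_primaries = as.integer(n))
}

# open scene (collimator effectively removed) for a target
open_scene <- function(target, voxel_mm = 1, no_phantom = FALSE) {
  build_scene(target, grid = phantom_grid(target, voxel_mm),
              aperture = c(9.99, 9.99), no_phantom = no_phantom)
}
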