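# Condensed-history transport: ranges, bookkeeping, the scattered tag and
# statistical behaviour.

test_that("with fluctuations disabled transport reduces to the CSDA
          depth", {
  phys <- fix_physics()
  t <- fix_target()
  scene <- open_scene(t)
  tl <- transport_history(pencil_spots(142.5, 20), scene, seed = 4,
                          physics = phys,
                          opts = list(no_scatter = TRUE, no_straggle = TRUE,
                                      no_nuclear = TRUE, dispersion = 0,
                                      do_tally = FALSE))
  z_stop <- tl$ledger$z
  expect_lt(max(abs(z_stop - mean(z_stop))), 1e-6)   # deterministic
  expect_equal(mean(z_stop), residual_range_water(142.5, physics = phys),
               tolerance = 0.05 / 10)                # < 0.5 mm
})

test_that("energy is conserved per history to 1e-6 relative", {
  run <- fix_logged_run()
  led <- run$ledger
  bal <- led$e_dep + led$e_escaped + led$e_removed
  expect_lt(max(abs(bal / led$e_in - 1)), 1e-6)
})

test_that("protons aimed into brass far from the edge die inside the
          collimator", {
  phys <- fix_physics()
  t <- fix_target()                        # R10 -> 2 cm brass
  scene <- build_scene(t, grid = phantom_grid(t, 2))
  ap <- scene$sra$aperture_half_x
  # pencil aimed 1 cm outside the aperture edge at the lowest energies
  spots <- data.frame(x_iso = ap + 1.2, y_iso = 0, energy = 95,
                      sigma_pos = 1e-6, sigma_ang = 1e-6,
                      n_primaries = 50L)
  tl <- transport_history(spots, scene, seed = 6, physics = phys,
                          opts = list(do_tally = FALSE))
  led <- tl$ledger
  expect_true(all(led$scattered == 1))
  expect_true(all(led$z < scene$sra$z_col_exit + 0.1))   # died in brass
  expect_true(all(led$energy == 0))
})

test_that("a grazing proton survives with the scattered tag and reduced
          energy", {
  phys <- fix_physics()
  t <- fix_target()
  scene <- build_scene(t, grid = phantom_grid(t, 2))
  ap <- scene$sra$aperture_half_x
  # beam centred on the aperture edge: some protons graze the wall
  spots <- data.frame(x_iso = ap, y_iso = 0, energy = 140,
                      sigma_pos = 0.3, sigma_ang = 1e-6,
                      n_primaries = 400L)
  tl <- transport_history(spots, scene, seed = 8, physics = phys,
                          opts = list(do_tally = FALSE))
  led <- tl$ledger
  surv <- led[led$z > 0, ]                # reached the phantom
  expect_gt(sum(surv$scattered == 1), 5)
  expect_gt(sum(surv$scattered == 0), 5)
  # scattered survivors carry less energy than unscattered peers at exit
  exit_e <- function(s) {
    out <- led[led$scattered == s & led$z >= scene$z_end - 1e-6, ]
    out$energy
  }
  us <- exit_e(0)
  sc <- exit_e(1)
  if (length(us) > 5 && length(sc) > 5) {
    expect_lt(median(sc), median(us))
  }
  # the pass-through side never touches brass
  inner <- data.frame(x_iso = 0, y_iso = 0, energy = 140,
                      sigma_pos = 1e-6, sigma_ang = 1e-6,
                      n_primaries = 30L)
  tli <- transport_history(inner, scene, seed = 8, physics = phys,
                           opts = list(do_tally = FALSE))
  expect_true(all(tli$ledger$scattered == 0))
})

test_that("a collimated pencil Bragg curve peaks at the nominal residual
          range", {
  phys <- fix_physics()
  t <- fix_target()
  scene <- open_scene(t, voxel_mm = 1)
  res <- pbscatter:::run_engine(scene, phys, pencil_spots(142.5, 15000),
                                seed = 21, weight = 1, nbatch = 2,
                                opts = list(do_tally = FALSE,
                                            do_zprof = TRUE))
  z <- (seq_len(scene$grid$nz) - 0.5) * scene$grid$voxel_cm
  z_peak <- z[which.max(res$zprof_eps)]
  expect_lt(abs(z_peak - 10), 0.2)
})

test_that("target dose is invariant under halving the step size", {
  phys <- fix_physics()
  t <- fix_target()
  scene <- open_scene(t, voxel_mm = 2)
  dose_at_peak <- function(max_step) {
    res <- pbscatter:::run_engine(scene, phys, pencil_spots(142.5, 8e4),
                                  seed = 31, weight = 1, nbatch = 2,
                                  opts = list(do_tally = FALSE,
                                              do_zprof = TRUE,
                                              max_step = max_step))
    z <- (seq_len(scene$grid$nz) - 0.5) * scene$grid$voxel_cm
    sum(res$zprof_eps[z > 5 & z < 9.5])   # plateau region
  }
  d1 <- dose_at_peak(c(0.5, 0.2, 0.1, 0.1))
  d2 <- dose_at_peak(c(0.25, 0.1, 0.05, 0.05))
  expect_lt(abs(d2 / d1 - 1), 0.01)
})

test_that("doubling the statistics leaves the mean dose unchanged within
          batch errors", {
  plan <- fix_plan()
  phys <- fix_physics()
  g1 <- fix_run()
  reg <- pbscatter:::evaluation_regions(g1, plan$target)
  s1 <- pbscatter:::region_stats(g1, reg$centre$ix, reg$centre$iy,
                                 reg$centre$iz)
  t2 <- run_field(plan, n_primaries = 4e5, seed = 43, batches = 4,
                  voxel_mm = 2, physics = phys)
  g2 <- finalize_tallies(t2, plan)
  s2 <- pbscatter:::region_stats(g2, reg$centre$ix, reg$centre$iy,
                                 reg$centre$iz)
  tol <- 3 * sqrt(s1$dose_se[["S+US"]]^2 + s2$dose_se[["S+US"]]^2)
  expect_lt(abs(s1$dose[["S+US"]] - s2$dose[["S+US"]]), tol)
})

test_that("identical seeds reproduce the tally bitwise; the scene kills
          runaway input", {
  plan <- fix_plan()
  phys <- fix_physics()
  a <- run_field(plan, n_primaries = 5000, seed = 99, batches = 2,
                 voxel_mm = 2, physics = phys)
  b <- run_field(plan, n_primaries = 5000, seed = 99, batches = 2,
                 voxel_mm = 2, physics = phys)
  expect_identical(a$eps, b$eps)
  expect_identical(a$epsL, b$epsL)
  expect_error(run_field(plan, n_primaries = 1, seed = 1, batches = 4),
               "n_primaries >= batches")
})

test_that("off-field surface voxels in the collimator shadow receive a
          small fraction of the target dose", {
  g <- fix_run()
  plan <- fix_plan()
  reg <- pbscatter:::evaluation_regions(g, plan$target)
  cen <- pbscatter:::region_stats(g, reg$centre$ix, reg$centre$iy,
                                  reg$centre$iz)
  ax <- g$axes
  far <- which(ax$x > plan$aperture[1] + 2.5)
  iy0 <- which(abs(ax$y) < 0.2)
  off <- pbscatter:::region_stats(g, far, iy0, reg$iz_s)
  expect_lt(off$dose[["S+US"]], 0.01 * cen$dose[["US"]])
})
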