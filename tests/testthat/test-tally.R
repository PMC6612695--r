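# Per-voxel scoring, the dose-averaged LET definition and the grid
# conversions.

test_that("finalized LETd equals a brute-force recomputation from the raw
          step log", {
  run <- fix_logged_run()
  g <- finalize_tallies(run, fix_plan())
  log <- run$step_log
  expect_gt(nrow(log), 100)
  # independent aggregation of the raw records
  key <- paste(log$ix, log$iy, log$iz, log$channel)
  eps_o <- tapply(log$eps, key, sum)
  epsl_o <- tapply(log$eps * log$L, key, sum)
  letd_o <- epsl_o / eps_o
  parts <- do.call(rbind, strsplit(names(letd_o), " "))
  idx <- cbind(as.integer(parts[, 1]) + 1L, as.integer(parts[, 2]) + 1L,
               as.integer(parts[, 3]) + 1L,
               ifelse(parts[, 4] == "0", 1L, 2L))
  expect_equal(unname(g$letd[idx]), unname(as.vector(letd_o)),
               tolerance = 1e-9)
  # and the scored energy matches the engine's own accumulators
  eps_tot <- rowSums(run$eps, dims = 4)
  expect_equal(sum(eps_tot), sum(log$eps), tolerance = 1e-9)
})

test_that("channel additivity and the mixture identity hold on every
          voxel", {
  g <- fix_run()
  expect_equal(g$dose[, , , 3], g$dose[, , , 1] + g$dose[, , , 2],
               tolerance = 1e-12)
  # letd(S+US) (eps_S + eps_US) = letd(S) eps_S + letd(US) eps_US
  both <- !is.na(g$letd[, , , 1]) & !is.na(g$letd[, , , 2])
  lhs <- g$letd[, , , 3][both] * g$dose[, , , 3][both]
  rhs <- g$letd[, , , 1][both] * g$dose[, , , 1][both] +
         g$letd[, , , 2][both] * g$dose[, , , 2][both]
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # the merged channel lies between the pure channels
  lo <- pmin(g$letd[, , , 1][both], g$letd[, , , 2][both])
  hi <- pmax(g$letd[, , , 1][both], g$letd[, , , 2][both])
  expect_true(all(g$letd[, , , 3][both] >= lo - 1e-12))
  expect_true(all(g$letd[, , , 3][both] <= hi + 1e-12))
  # where only one channel deposited, the merge equals it exactly
  us_only <- is.na(g$letd[, , , 1]) & !is.na(g$letd[, , , 2])
  expect_identical(g$letd[, , , 3][us_only], g$letd[, , , 2][us_only])
})

test_that("batch partitions sum exactly to the totals", {
  run <- fix_logged_run()
  tot <- rowSums(run$eps, dims = 4)
  expect_equal(dim(run$eps)[5], run$nbatch, ignore_attr = TRUE)
  expect_equal(sum(abs(tot - (run$eps[, , , , 1] + run$eps[, , , , 2]))), 0)
})

test_that("an axial step split across voxels deposits in proportion to
          path length", {
  phys <- fix_physics()
  t <- fix_target()
  scene <- open_scene(t, voxel_mm = 1)
  run <- transport_history(pencil_spots(142.5, 1), scene, seed = 2,
                           physics = phys,
                           opts = list(no_scatter = TRUE,
                                       no_straggle = TRUE,
                                       no_nuclear = TRUE, dispersion = 0))
  log <- run$step_log
  # an axial pencil crosses voxel boundaries: the per-voxel path of a
  # 1 mm-limited history in 1 mm voxels never exceeds the voxel size
  seg <- tapply(log$eps, paste(log$ix, log$iy, log$iz), sum)
  expect_gt(length(seg), 50)
  # deposits are contiguous along z on the axis
  zs <- sort(unique(log$iz))
  expect_equal(zs, seq(min(zs), max(zs)), ignore_attr = TRUE)
})

test_that("region batch statistics converge at the target centre", {
  g <- fix_run()
  reg <- pbscatter:::evaluation_regions(g, fix_target())
  cen <- pbscatter:::region_stats(g, reg$centre$ix, reg$centre$iy,
                                  reg$centre$iz)
  expect_lt(cen$dose_se[["S+US"]] / cen$dose[["S+US"]], 0.01)
})

test_that("grids round-trip through the text format", {
  phys <- fix_physics()
  t <- target_spec(5, 5, 2)
  plan <- memo("tiny_plan", function() {
    build_plan(t, phys, seed = 2, n_presim = 400)
  })
  tally <- run_field(plan, n_primaries = 2000, seed = 5, batches = 2,
                     voxel_mm = 5, physics = phys)
  g <- finalize_tallies(tally, plan)
  path <- withr::local_tempfile(fileext = ".txt")
  write_grids(g, path)
  back <- read_grids(path)
  expect_equal(back$dose, g$dose, tolerance = 1e-7)
  expect_equal(back$letd, g$letd, tolerance = 1e-7)
  expect_identical(back$grid$nx, g$grid$nx)
  expect_equal(back$axes$z, g$axes$z, tolerance = 1e-9)
})

test_that("profiles extract the requested axis at fixed coordinates", {
  g <- fix_run()
  p <- extract_profile(g, "z", channel = "US", at = list(x = 0, y = 0),
                       band = 0.5)
  expect_identical(nrow(p), g$grid$nz)
  # SOBP plateau: flat region between proximal and distal edges
  plateau <- p$dose[p$coord > 6 & p$coord < 9.5]
  expect_lt((max(plateau) - min(plateau)) / mean(plateau), 0.15)
  # distal falloff
  expect_lt(p$dose[which.min(abs(p$coord - 10.9))],
            0.2 * mean(plateau))
})
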