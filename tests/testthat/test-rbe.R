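# The LQ-based variable RBE model and the point-metric evaluation.

test_that("RBE model coefficients give the published zero-LET limits", {
  p <- rbe_params()
  expect_identical(rbe_max(0, 10, p), 0.99064)
  expect_identical(rbe_min(0, 10, p), 1.1012)
  # hand-evaluated closed form at D = 2 Gy, alpha/beta = 10 Gy, LETd = 0
  expect_equal(rbe_mcnamara(2, 10, 0, p), 1.0236, tolerance = 1e-4)
})

test_that("RBE limits: low dose tends to RBE_max, high dose to RBE_min", {
  p <- rbe_params()
  for (ab in c(3, 10)) {
    for (letd in c(0, 2, 8)) {
      expect_lt(abs(rbe_mcnamara(1e-6, ab, letd, p) - rbe_max(letd, ab, p)),
                1e-4)
      expect_lt(abs(rbe_mcnamara(1e4, ab, letd, p) - rbe_min(letd, ab, p)),
                1e-3)
    }
  }
  expect_error(rbe_mcnamara(0, 10, 1), "dose")
  expect_error(rbe_mcnamara(2, 10, -1), "letd")
})

test_that("RBE increases monotonically with LET at 2 Gy", {
  letd <- seq(0, 15, by = 0.25)
  r <- rbe_mcnamara(2, 10, letd)
  expect_true(all(diff(r) > 0))
  r3 <- rbe_mcnamara(2, 3, letd)
  expect_true(all(diff(r3) > 0))
})

# minimal grids object with a prescribed scattered-dose surface profile
synthetic_grids <- function(profile_x, nx = length(profile_x)) {
  grid <- structure(list(voxel_cm = 0.2, nx = nx, ny = 4, nz = 5,
                         x0 = -nx * 0.1, y0 = -0.4, z0 = 0),
                    class = "phantom_grid")
  dims <- c(nx, 4, 5, 3)
  dose <- array(0, dims)
  for (iy in 1:4) for (iz in 1:5) dose[, iy, iz, 1] <- profile_x
  dose[, , , 2] <- 1
  dose[, , , 3] <- dose[, , , 1] + dose[, , , 2]
  structure(list(dose = dose, letd = dose, channels = c("S", "US", "S+US"),
                 axes = pbscatter:::grid_axes(grid), grid = grid,
                 tally = NULL, plan = NULL),
            class = "proton_grids")
}

test_that("find_xs breaks ties toward the smallest |x| and then negative
          x", {
  prof <- rep(0.1, 10)
  prof[c(2, 9)] <- 1                       # equal maxima at +/- x0
  g <- synthetic_grids(prof)
  x <- g$axes$x
  expect_identical(find_xs(g, z_s = 0.5), x[2])
  expect_lt(find_xs(g, z_s = 0.5), 0)
  # smallest |x| wins over an equal farther peak
  prof2 <- rep(0.1, 10)
  prof2[c(4, 10)] <- 1
  expect_identical(find_xs(synthetic_grids(prof2), z_s = 0.5), x[4])
  expect_error(find_xs(synthetic_grids(rep(0, 10)), z_s = 0.5),
               "identically zero")
})

test_that("metrics record reflects the expected geometry bookkeeping", {
  m <- evaluate_target(fix_run(), fix_target())
  expect_identical(m$z_c, 7.5)
  expect_identical(m$z_s, 0.5)
  expect_gt(m$D_US_center, 0)
  # the scattered channel is ordered: S >= S+US >= US at the surface
  expect_gte(m$letd_S_surface, m$letd_tot_surface)
  expect_gte(m$letd_tot_surface, m$letd_US_surface)
  # surface impact dominates the centre for a deep mid-size target
  expect_gt(m$D_S_surface_frac, m$D_S_center_frac)
})

test_that("swapping the RBE model changes only the RBE fields", {
  g <- fix_run()
  base <- evaluate_target(g, fix_target())
  stub <- evaluate_target(g, fix_target(),
                          rbe_fun = function(dose, ab, letd, params) 1.1)
  rbe_cols <- grep("^rbe_", names(base), value = TRUE)
  keep <- setdiff(names(base), c(rbe_cols, "label"))
  expect_identical(base[keep], stub[keep])
  expect_true(all(unlist(stub[c("rbe_US_surface", "rbe_tot_surface",
                                "rbe_US_center", "rbe_tot_center")]) == 1.1))
  expect_identical(stub$rbe_inc_surface, 0)
})

test_that("a collimator-free field has no scattered channel and equal
          RBE", {
  phys <- fix_physics()
  t <- target_spec(5, 5, 2)
  plan <- memo("tiny_plan", function() {
    build_plan(t, phys, seed = 2, n_presim = 400)
  })
  scene <- open_scene(t, voxel_mm = 2)
  tally <- run_field(plan, scene = scene, n_primaries = 3e4, seed = 12,
                     batches = 2, physics = phys)
  g <- finalize_tallies(tally, plan)
  expect_true(all(g$dose[, , , 1] == 0))
  m <- evaluate_target(g, t)
  expect_identical(m$D_S_surface_frac, 0)
  expect_identical(m$rbe_inc_surface, 0)
  expect_identical(m$rbe_tot_center, m$rbe_US_center)
})

test_that("scatter analysis includes exactly the voxels above threshold
          and bounds the LET increase by the mixture identity", {
  g <- fix_fig_run()
  sa <- scatter_analysis(g, reliable_only = FALSE)
  expect_true(all(sa$points$D_S > 0.01))
  ds <- g$dose[, , , 1]
  n_above <- sum(ds > 0.01)
  expect_identical(nrow(sa$points), as.integer(n_above))
  # dletd <= (eps_S / eps_tot) (letd_S - letd_US) exactly per voxel
  ax <- g$axes
  i <- cbind(match(round(sa$points$x, 6), round(ax$x, 6)),
             match(round(sa$points$y, 6), round(ax$y, 6)),
             match(round(sa$points$z, 6), round(ax$z, 6)))
  f_s <- ds[i] / g$dose[, , , 3][i]
  bound <- f_s * (g$letd[, , , 1][i] - g$letd[, , , 2][i])
  ok <- is.finite(sa$points$dletd) & is.finite(bound)
  expect_true(all(sa$points$dletd[ok] <= bound[ok] + 1e-9))
})
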