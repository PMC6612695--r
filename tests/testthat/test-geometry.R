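# Scene construction, region labelling and the aperture rule.

test_that("collimator thickness follows the range rule", {
  expect_identical(collimator_thickness_for(5), 2)
  expect_identical(collimator_thickness_for(10), 2)   # boundary: 2-cm max
  expect_identical(collimator_thickness_for(10.5), 4)
  scene <- build_scene(target_spec(15, 5, 8))
  expect_identical(scene$sra$collimator_thickness, 4)
  scene2 <- build_scene(target_spec(10, 5, 4))
  expect_identical(scene2$sra$collimator_thickness, 2)
})

test_that("z stations respect the placement constants", {
  scene <- build_scene(target_spec(15, 5, 8))
  s <- scene$sra
  expect_identical(s$z_col_exit, -6)                 # 6 cm above the water
  expect_identical(s$z_col_exit - s$z_col_entry, 4)
  expect_identical(s$collimator_exit_to_isocenter,
                   s$collimator_exit_to_water_surface + s$isocenter_depth)
  expect_identical(s$z_iso, 3)
  expect_identical(s$z_abs_exit - s$z_abs_entry, 4)
})

test_that("target specification validates and labels itself", {
  t <- target_spec(15, 5, 8)
  expect_identical(t$label, "R15_S5_FS8")
  expect_identical(target_spec(2.5, 2.5, 4)$label, "R2.5_S2.5_FS4")
  expect_error(target_spec(5, 10, 4), "proximal")
  expect_error(target_spec(5, 2, 25), "maximum field")
})

test_that("locate matches an independent slab oracle on random points", {
  scene <- build_scene(target_spec(10, 5, 4))
  s <- scene$sra
  oracle <- function(p) {
    x <- p[1]; y <- p[2]; z <- p[3]
    if (z < s$z_source || z >= scene$z_end) return("outside")
    if (z >= 0) return("water")
    if (z >= s$z_col_entry && z < s$z_col_exit) {
      if (abs(x) < s$aperture_half_x && abs(y) < s$aperture_half_y)
        return("aperture-air")
      return("collimator")
    }
    if (z >= s$z_abs_entry && z < s$z_abs_exit) return("absorber")
    "air"
  }
  set.seed(17)
  for (i in 1:2000) {
    p <- c(runif(2, -6, 6), runif(1, -20, 13))
    expect_identical(locate(scene, p), oracle(p))
  }
  # boundary points belong to the downstream region (half-open slabs)
  expect_identical(locate(scene, c(0, 0, s$z_col_exit)), "air")
  expect_identical(locate(scene, c(0, 0, s$z_col_entry)), "aperture-air")
  expect_identical(locate(scene, c(0, 0, 0)), "water")
  expect_identical(locate(scene, c(s$aperture_half_x + 0.1, 0,
                                   (s$z_col_entry + s$z_col_exit) / 2)),
                   "collimator")
})

test_that("aperture back-projection demagnifies toward the source", {
  t <- target_spec(15, 5, 8)
  parallel <- beam_source_model(4, sad_x = Inf, sad_y = 240)
  expect_identical(aperture_for_target(t, parallel)[["half_x"]],
                   t$field_FS / 2)
  finite <- beam_source_model(4)
  ap <- aperture_for_target(t, finite)
  expect_true(all(ap < t$field_FS / 2))
  # similar triangles by hand: a = (FS/2) (z_ce - z_v)/(z_prox - z_v)
  z_v <- 3 - finite$sad_x
  hand <- 4 * (-6 - z_v) / (10 - z_v)
  expect_equal(ap[["half_x"]], hand, tolerance = 1e-12)
  # the two axes differ because the scanning magnets differ
  expect_false(ap[["half_x"]] == ap[["half_y"]])
})

test_that("scene construction is pure", {
  a <- build_scene(target_spec(10, 5, 4))
  b <- build_scene(target_spec(10, 5, 4))
  expect_identical(a, b)
})

test_that("phantom grid covers field and range with margins", {
  t <- target_spec(15, 5, 8)
  g <- phantom_grid(t, voxel_mm = 2)
  expect_gte(g$nx * g$voxel_cm / 2, t$field_FS / 2 + 3)
  expect_gte(g$nz * g$voxel_cm, t$range_R + 1)
  ax <- pbscatter:::grid_axes(g)
  # half-open voxels, zero-based: voxel i spans [i h, (i+1) h)
  expect_equal(ax$z[1], g$voxel_cm / 2)
  expect_equal(ax$x, -rev(ax$x))
})

test_that("delivered 50% isodose at the proximal plane sits on the field
          edge", {
  plan <- fix_plan()                  # R10_S5_FS8
  tally <- run_field(plan, n_primaries = 4e5, seed = 7, batches = 4,
                     voxel_mm = 2, physics = fix_physics())
  g <- finalize_tallies(symmetrize_tally(tally), plan)
  z_prox <- plan$target$range_R - plan$target$sobp_S
  prof <- extract_profile(g, "x", channel = "US",
                          at = list(y = 0, z = z_prox + 0.1), band = 1)
  centre <- mean(prof$dose[abs(prof$coord) < 1])
  right <- which(prof$coord > 1)
  below <- right[prof$dose[right] < centre / 2][1]   # first sub-50% voxel
  x1 <- prof$coord[below - 1]; x2 <- prof$coord[below]
  d1 <- prof$dose[below - 1]; d2 <- prof$dose[below]
  x50 <- x1 + (d1 - centre / 2) / (d1 - d2) * (x2 - x1)
  expect_lt(abs(x50 - plan$target$field_FS / 2), 0.15)
})
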