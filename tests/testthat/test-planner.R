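# Source model calibration, layers, spot maps and SOBP weights.

test_that("layer ranges descend to the proximal edge with clipping at the
          minimum deliverable range", {
  phys <- fix_physics()
  l <- make_layers(target_spec(10, 10, 4), phys)
  expect_equal(l$range[1], 10)
  expect_equal(min(l$range), 0.5)               # 0 clipped to 0.5
  expect_true(all(diff(l$range) < 0))
  expect_true(all(diff(l$energy) < 0))          # strictly decreasing
  expect_false(anyDuplicated(l$range) > 0)
  # each energy solves the residual-range equation
  expect_lt(max(abs(residual_range_water(l$energy, physics = phys) -
                    l$range)), 1e-3)
  # degenerate SOBP width: a single layer is allowed
  l1 <- make_layers(target_spec(10, 0, 4), phys)
  expect_identical(nrow(l1), 1L)
})

test_that("spot maps are square, centred and one spacing beyond the edge", {
  m2 <- make_spot_map(target_spec(5, 5, 2))
  expect_identical(nrow(m2), 49L)               # 7 x 7
  expect_equal(range(m2$x_iso), c(-1.5, 1.5))
  m16 <- make_spot_map(target_spec(20, 5, 16))
  expect_identical(nrow(m16), 35L * 35L)
  # symmetric under x -> -x and y -> -y
  key <- function(d) paste(round(d$x_iso, 6), round(d$y_iso, 6))
  expect_setequal(key(m2), key(transform(m2, x_iso = -x_iso)))
  expect_setequal(key(m2), key(transform(m2, y_iso = -y_iso)))
})

test_that("source calibration reproduces the anchor sigma analytically", {
  phys <- fix_physics()
  for (th in c(2, 4)) {
    src <- beam_source_model(th)
    anchors <- src$sigma_anchor_table
    cal <- calibrate_source(src, anchors$energy, phys)
    sra <- sra_config(th, 1)
    l_iso <- sra$z_iso - sra$z_source
    for (k in seq_len(nrow(anchors))) {
      fe <- pbscatter:::fe_march(anchors$energy[k], th, phys)
      fwd <- sqrt(cal$sigma_pos[k]^2 + cal$sigma_ang[k]^2 * l_iso^2 +
                  fe$var_iso)
      expect_equal(10 * fwd, anchors$sigma_mm[k], tolerance = 1e-6)
    }
    # interpolated sigma is positive and decreasing in energy
    e <- seq(min(anchors$energy), max(anchors$energy), length.out = 20)
    sig <- sigma_at_isocenter(src, e, phys)
    expect_true(all(sig > 0))
    expect_true(all(diff(sig) < 0))
  }
})

test_that("scanning magnets must sit at different distances", {
  expect_error(beam_source_model(2, sad_x = 200, sad_y = 200), "differ")
})

test_that("phase-space sampling honours the deterministic tilt and is
          reproducible", {
  src <- beam_source_model(2)
  spot0 <- list(x_iso = 0, y_iso = 0, energy = 100,
                sigma_pos = 0, sigma_ang = 0)
  ps <- sample_phase_space(spot0, 5, src, seed = 1)
  expect_true(all(ps$dx == 0 & ps$dy == 0))      # mean direction +z exactly
  spot8 <- list(x_iso = 8, y_iso = 0, energy = 100,
                sigma_pos = 0, sigma_ang = 0)
  ps8 <- sample_phase_space(spot8, 5, src, seed = 1)
  expect_equal(unique(ps8$dx / ps8$dz), 8 / src$sad_x, tolerance = 1e-12)
  spot <- list(x_iso = 2, y_iso = -1, energy = 120,
               sigma_pos = 0.5, sigma_ang = 0.01)
  a <- sample_phase_space(spot, 1000, src, seed = 11)
  b <- sample_phase_space(spot, 1000, src, seed = 11)
  expect_identical(a, b)
  expect_error(sample_phase_space(spot, 0, src), "positive")
})

test_that("SOBP weights flatten the plateau and favour the deepest layer", {
  plan <- fix_plan()
  expect_lt(plan$flatness, 0.03)
  w <- plan$layers$weight
  expect_true(all(w >= 0))
  expect_identical(which.max(w), 1L)            # deepest layer dominates
  # broadly decreasing toward proximal layers
  expect_lt(mean(w[-1]), w[1])
  # single layer: weight matches the prescription at the peak
  phys <- fix_physics()
  t1 <- target_spec(10, 0, 4)
  plan1 <- build_plan(t1, phys, seed = 5, n_presim = 1500)
  expect_identical(nrow(plan1$layers), 1L)
  expect_gt(plan1$layers$weight, 0)
})

test_that("degenerate depth-dose matrices are rejected with diagnostics", {
  layers <- data.frame(range = c(10, 9.5), energy = c(140, 137))
  ddm <- list(z = seq(0.1, 10.9, by = 0.2),
              dose = matrix(0, nrow = 55, ncol = 2))
  expect_error(sobp_weights(layers, ddm, target_spec(10, 5, 4)),
               "degenerate")
})

test_that("plans serialise to structured text and back", {
  plan <- fix_plan()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_identical(back$target$label, plan$target$label)
  expect_equal(back$aperture, unname(plan$aperture), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$layers$weight, plan$layers$weight, tolerance = 1e-6)
  expect_equal(back$total_protons, plan$total_protons, tolerance = 1e-6)
  expect_identical(nrow(back$spots), nrow(plan$spots))
})
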