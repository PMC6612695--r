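# Spot-scanning source model and treatment planner: energy layers, spot
# maps and nonnegative least-squares SOBP weights delivering 2 Gy to a
# rectangular water target.

#' Beam source model
#'
#' Printed in-air spot sigmas at the isocenter anchor the source: 11.7 mm
#' at the lowest energy (74.9 MeV) for both applicator configurations,
#' falling to 6.0 mm at 142.5 MeV (2-cm collimator) and 5.3 mm at
#' 192.4 MeV (4-cm collimator).  Sigma is interpolated linearly in energy
#' between the anchors.  The X and Y scanning magnets sit at different
#' distances upstream of the isocenter, so each axis has its own virtual
#' source for the deterministic spot tilt.
#'
#' @param collimator_thickness 2 or 4 (cm); selects the anchor span.
#' @param sad_x,sad_y Scanning-magnet distances upstream of the isocenter
#'   in cm (may be `Inf` for a parallel beam).
#' @param energy_dispersion Relative sigma of the kinetic energy.
#' @param sigma_growth Multiplicative in-air sigma growth between the
#'   collimator exit plane and the isocenter used to split the source
#'   into position and angular spread.
#' @return Object of class `beam_source_model`.
#' @export
beam_source_model <- function(collimator_thickness = 2, sad_x = 200,
                              sad_y = 240, energy_dispersion = 0.006,
                              sigma_growth = 1.2) {
  if (!collimator_thickness %in% c(2, 4)) {
    stop("collimator_thickness must be 2 or 4 cm")
  }
  if (is.finite(sad_x) && is.finite(sad_y) && sad_x == sad_y) {
    stop("sad_x and sad_y must differ (magnets at different positions)")
  }
  anchors <- if (collimator_thickness == 2) {
    data.frame(energy = c(74.9, 142.5), sigma_mm = c(11.7, 6.0))
  } else {
    data.frame(energy = c(74.9, 192.4), sigma_mm = c(11.7, 5.3))
  }
  structure(list(collimator_thickness = collimator_thickness,
                 sigma_anchor_table = anchors,
                 sad_x = sad_x, sad_y = sad_y,
                 energy_dispersion = energy_dispersion,
                 sigma_growth = sigma_growth),
            class = "beam_source_model")
}

#' In-air sigma at a given energy
#'
#' Interpolates the printed in-air isocenter sigma between the anchor
#' energies.  With a physics bundle supplied, the interpolation follows
#' the shape of the absorber multiple-scattering contribution computed by
#' the package's own Fermi-Eyges model,
#' \eqn{\sigma^2(E) = a + c\,M_{iso}(E)}, with `(a, c)` fixed by the two
#' anchors (exact at the anchors, physically convex between them, since
#' the spot size of this nozzle is dominated by absorber scattering).
#' Without a physics bundle the interpolation is linear in energy.
#'
#' @param source A [beam_source_model()].
#' @param energy Kinetic energy in MeV (vectorised).
#' @param physics Optional physics bundle enabling the model-shaped
#'   interpolation.
#' @return One-sigma in-air spot size at the isocenter, in mm.
#' @export
sigma_at_isocenter <- function(source, energy, physics = NULL) {
  a <- source$sigma_anchor_table
  lin <- stats::approx(a$energy, a$sigma_mm, xout = energy, rule = 2)$y
  if (is.null(physics)) return(lin)
  th <- source$collimator_thickness
  m_anchor <- vapply(a$energy, function(e) fe_march(e, th, physics)$var_iso,
                     numeric(1))
  s2 <- (a$sigma_mm / 10)^2                 # cm^2
  cc <- (s2[1] - s2[2]) / (m_anchor[1] - m_anchor[2])
  a0 <- s2[2] - cc * m_anchor[2]
  if (!is.finite(cc) || cc <= 0) return(lin)
  e_cl <- pmin(pmax(energy, min(a$energy)), max(a$energy))
  m_e <- vapply(e_cl, function(e) fe_march(e, th, physics)$var_iso,
                numeric(1))
  10 * sqrt(pmax(a0 + cc * m_e, 1e-4))
}

# Deterministic Fermi-Eyges accumulation of the multiple-scattering
# positional variance from the source plane to two downstream planes,
# marching the on-axis CSDA energy with the same step rule and per-slab
# Highland correction as the Monte Carlo kernel.  Returns variances in
# cm^2 at the collimator exit plane and the isocenter (in air, no
# phantom), plus the exit energy.
fe_march <- function(energy, thickness, physics = default_physics()) {
  key <- sprintf("fe_%.4f_%d_%.5f", energy, thickness, physics$absorber$wet)
  hit <- .pbs_cache[[key]]
  if (!is.null(hit)) return(hit)
  sra <- sra_config(thickness, 1)
  eng <- physics_for_engine(physics)
  # regions: air | absorber | air | aperture air | air to isocenter
  zb <- c(sra$z_source, sra$z_abs_entry, sra$z_abs_exit,
          sra$z_col_entry, sra$z_col_exit, sra$z_iso)
  mats <- c(1, 2, 1, 1, 1)               # engine material ids (1 air, 2 abs)
  scn <- scene_for_engine(build_scene(target_spec(10, 5, 4),
                                      source = beam_source_model(thickness)),
                          physics)
  corr <- c(scn$region_corr[1], scn$region_corr[2], scn$region_corr[3],
            scn$aperture_corr, scn$region_corr[5])
  max_step <- c(0.5, 0.2, 0.1, 0.1)
  z_ce <- sra$z_col_exit
  z_iso <- sra$z_iso
  e <- energy
  var_ce <- 0
  var_iso <- 0
  ang_ce <- 0
  s_of <- function(m, en) exp(stats::approx(eng$log_e, eng$log_s[, m],
                                            xout = log(en), rule = 2)$y)
  r_of <- function(m, en) exp(stats::approx(eng$log_e, eng$log_r[, m],
                                            xout = log(en), rule = 2)$y)
  for (r in seq_along(mats)) {
    z <- zb[r]
    while (z < zb[r + 1] - 1e-9 && e > 1) {
      m <- mats[r]
      rr <- r_of(m, max(e, 0.11))
      l <- min(max_step[m], max(0.05 * rr, 0.01), zb[r + 1] - z)
      emid <- e - 0.5 * s_of(m, e) * l
      if (emid <= 0.15) break
      de <- s_of(m, emid) * l
      th0 <- HIGHLAND_E / proton_pv(emid) * sqrt(l / eng$x0_cm[m]) * corr[r]
      zmid <- z + l / 2
      if (zmid < z_ce) {
        var_ce <- var_ce + th0^2 * (z_ce - zmid)^2
        ang_ce <- ang_ce + th0^2
      }
      var_iso <- var_iso + th0^2 * (z_iso - zmid)^2
      e <- e - de
      z <- z + l
    }
  }
  out <- list(var_ce = var_ce, var_iso = var_iso, ang_ce = ang_ce,
              energy_exit = e)
  .pbs_cache[[key]] <- out
  out
}

#' Calibrate the per-energy source spread
#'
#' For each beam energy, splits the printed in-air isocenter sigma into a
#' Gaussian position sigma at the source plane and a Gaussian angular
#' sigma, after subtracting the multiple-scattering contribution of
#' absorber and air computed deterministically (Fermi-Eyges).  The two
#' free constants are fixed by (i) the isocenter anchor sigma and (ii)
#' the configured sigma growth between collimator exit and isocenter.
#'
#' @param source A [beam_source_model()].
#' @param energies Beam energies in MeV.
#' @param physics Physics bundle.
#' @return `data.frame` with `energy`, `sigma_iso_mm` (anchor),
#'   `sigma_pos` (cm) and `sigma_ang` (rad).
#' @export
calibrate_source <- function(source, energies, physics = default_physics()) {
  th <- source$collimator_thickness
  sra <- sra_config(th, 1)
  l_ce <- sra$z_col_exit - sra$z_source
  l_iso <- sra$z_iso - sra$z_source
  out <- lapply(energies, function(e) {
    fe <- fe_march(e, th, physics)
    s_iso <- sigma_at_isocenter(source, e, physics) / 10   # mm -> cm
    s_ce <- s_iso / source$sigma_growth
    a <- s_ce^2 - fe$var_ce
    b <- s_iso^2 - fe$var_iso
    # when the scattering contribution alone exceeds the growth implied
    # by the configured collimator-exit/isocenter split, drop the angular
    # term: matching the printed isocenter anchor takes priority
    sig_ang2 <- max((b - a) / (l_iso^2 - l_ce^2), 0)
    sig_pos2 <- max(b - sig_ang2 * l_iso^2, 1e-8)
    sig_ang2 <- max(sig_ang2, 1e-10)
    data.frame(energy = e, sigma_iso_mm = s_iso * 10,
               sigma_pos = sqrt(sig_pos2), sigma_ang = sqrt(sig_ang2))
  })
  do.call(rbind, out)
}

#' Energy layers for a target
#'
#' Residual ranges descend from the target range to its proximal edge in
#' steps of the layer spacing; ranges below the minimum deliverable
#' 0.5 cm are clipped to 0.5 cm (duplicates dropped).  Each energy solves
#' `residual_range_water(E, absorber_wet) == range`.
#'
#' Shallow pristine peaks are narrow (little range straggling), so below
#' `fine_below` the spacing is refined to `fine_spacing` to keep the SOBP
#' ripple small.
#'
#' @param target A [target_spec()].
#' @param physics Physics bundle (for the calibrated absorber WET).
#' @param layer_spacing Base layer spacing in cm of water.
#' @param fine_below Residual range (cm) below which the spacing refines.
#' @param fine_spacing Refined spacing in cm.
#' @return `data.frame` with `range` (cm) and `energy` (MeV), deepest
#'   first, energies strictly decreasing.
#' @export
make_layers <- function(target, physics = default_physics(),
                        layer_spacing = 0.5, fine_below = 6,
                        fine_spacing = 0.25) {
  r_min <- max(target$range_R - target$sobp_S, 0.5)
  r <- target$range_R
  while (r[length(r)] > r_min + 1e-9) {
    rc <- r[length(r)]
    # refine near the distal edge (deepest layers dominate the ripple)
    # and at shallow residual ranges (narrow pristine peaks)
    fine <- rc <= fine_below + 1e-9 || target$range_R - rc < 1 - 1e-9
    r <- c(r, max(rc - if (fine) fine_spacing else layer_spacing, r_min))
  }
  r <- unique(pmax(r, 0.5))
  wet <- physics$absorber$wet
  e <- energy_at_range(r + wet, "water", physics)
  data.frame(range = r, energy = e)
}

#' Transverse spot map
#'
#' Square grid of spot positions at the isocenter plane, centred on the
#' axis, extending one spot spacing beyond the field edge on each side;
#' the same map is used for every energy layer.
#'
#' @param target A [target_spec()].
#' @param spacing Spot spacing in cm.
#' @return `data.frame` with `x_iso`, `y_iso` (cm).
#' @export
make_spot_map <- function(target, spacing = 0.5) {
  n <- round((target$field_FS / 2 + spacing) / spacing)
  u <- spacing * seq(-n, n)
  expand.grid(x_iso = u, y_iso = u, KEEP.OUT.ATTRS = FALSE)
}

#' Sample primaries from one spot
#'
#' Draws `n` protons at the source plane: Gaussian transverse position
#' and angle around the deterministic spot ray (tilt `x_iso / sad_x` and
#' analogously in y), Gaussian kinetic energy with the configured
#' relative dispersion.  Mirrors the sampling performed inside the
#' transport kernel.
#'
#' @param spot List or one-row data.frame with `x_iso`, `y_iso` (cm),
#'   `energy` (MeV), `sigma_pos` (cm), `sigma_ang` (rad).
#' @param n Number of primaries.
#' @param source A [beam_source_model()].
#' @param seed RNG seed.
#' @param weight Statistical weight per primary.
#' @return `data.frame` with position (`x`,`y`,`z` cm), direction
#'   (`dx`,`dy`,`dz`, unit), `energy` (MeV) and `weight`.
#' @export
sample_phase_space <- function(spot, n, source, seed = 1, weight = 1) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  sra <- sra_config(source$collimator_thickness, 1)
  z_src <- sra$z_source
  z_iso <- sra$z_iso
  inv_sx <- if (is.finite(source$sad_x)) 1 / source$sad_x else 0
  inv_sy <- if (is.finite(source$sad_y)) 1 / source$sad_y else 0
  fx <- 1 - (z_iso - z_src) * inv_sx
  fy <- 1 - (z_iso - z_src) * inv_sy
  tx <- spot$x_iso * inv_sx + spot$sigma_ang * stats::rnorm(n)
  ty <- spot$y_iso * inv_sy + spot$sigma_ang * stats::rnorm(n)
  x <- spot$x_iso * fx + spot$sigma_pos * stats::rnorm(n)
  y <- spot$y_iso * fy + spot$sigma_pos * stats::rnorm(n)
  nrm <- sqrt(1 + tx^2 + ty^2)
  e <- spot$energy * (1 + source$energy_dispersion * stats::rnorm(n))
  data.frame(x = x, y = y, z = z_src,
             dx = tx / nrm, dy = ty / nrm, dz = 1 / nrm,
             energy = pmin(pmax(e, 2), 295), weight = weight)
}

# Lateral MCS sigma accumulated in water by depth z (cm) for a proton
# entering the surface with the given energy; Fermi-Eyges moments on a
# 1-mm march.
water_mcs_sigma <- function(energy_surface, z_grid, physics) {
  eng <- physics_for_engine(physics)
  m <- 4                                    # water
  zmax <- max(z_grid)
  e <- energy_surface
  corr <- max(1 + log10(zmax / eng$x0_cm[m]) / 9, 0.25)
  z <- 0
  m0 <- m1 <- m2 <- 0
  zs <- numeric(0); c0 <- numeric(0); c1 <- numeric(0); c2 <- numeric(0)
  s_of <- function(en) exp(stats::approx(eng$log_e, eng$log_s[, m],
                                         xout = log(en), rule = 2)$y)
  while (z < zmax && e > 2) {
    l <- 0.1
    emid <- e - 0.5 * s_of(e) * l
    if (emid <= 2) break
    th2 <- (HIGHLAND_E / proton_pv(emid) * sqrt(l / eng$x0_cm[m]) * corr)^2
    zm <- z + l / 2
    m0 <- m0 + th2; m1 <- m1 + th2 * zm; m2 <- m2 + th2 * zm^2
    zs <- c(zs, z + l); c0 <- c(c0, m0); c1 <- c(c1, m1); c2 <- c(c2, m2)
    e <- e - s_of(emid) * l
    z <- z + l
  }
  if (length(zs) == 0) return(rep(0, length(z_grid)))
  f0 <- stats::approx(zs, c0, xout = z_grid, rule = 2, yleft = 0)$y
  f1 <- stats::approx(zs, c1, xout = z_grid, rule = 2, yleft = 0)$y
  f2 <- stats::approx(zs, c2, xout = z_grid, rule = 2, yleft = 0)$y
  sqrt(pmax(f0 * z_grid^2 - 2 * f1 * z_grid + f2, 0))
}

#' Per-layer central-axis depth-dose matrix
#'
#' Fast pre-simulation of each energy layer: a single on-axis spot is
#' transported (collimator wide open) and the laterally integrated
#' dE/dz profile is scored.  The column for layer k is the central-axis
#' dose in Gy per unit spot weight for the target's spot map, including
#' the beam-divergence scaling of the spot density and a coverage factor
#' for the finite map extent and the aperture shadow.
#'
#' @param target A [target_spec()].
#' @param layers Layer table from [make_layers()] with calibration
#'   columns `sigma_pos`, `sigma_ang` joined.
#' @param aperture `c(half_x, half_y)` cm.
#' @param source A [beam_source_model()].
#' @param physics Physics bundle.
#' @param voxel_mm Depth-bin size in mm.
#' @param n_presim Primaries per layer.
#' @param spacing Spot spacing in cm.
#' @param seed RNG seed.
#' @return List with `z` (bin centres, cm), `dose` (matrix, Gy per unit
#'   spot weight, one column per layer).
#' @export
depth_dose_matrix <- function(target, layers, aperture, source,
                              physics = default_physics(), voxel_mm = 2,
                              n_presim = 2000, spacing = 0.5, seed = 1) {
  grid <- phantom_grid(target, voxel_mm = voxel_mm)
  scene <- build_scene(target, grid = grid, source = source,
                       aperture = c(9.99, 9.99),
                       thickness = source$collimator_thickness)
  h <- grid$voxel_cm
  z <- (seq_len(grid$nz) - 0.5) * h
  z_iso <- 3
  m_of <- function(sad, zz) {
    if (!is.finite(sad)) return(rep(1, length(zz)))
    (zz - (z_iso - sad)) / sad
  }
  mx <- m_of(source$sad_x, z)
  my <- m_of(source$sad_y, z)
  z_ce <- -6
  a_proj <- function(sad, ap, zz) {
    if (!is.finite(sad)) return(rep(ap, length(zz)))
    z_v <- z_iso - sad
    ap * (zz - z_v) / (z_ce - z_v)
  }
  l_map <- target$field_FS / 2 + spacing
  # map-extent window per depth (beam-divergence scaled); the aperture is
  # handled separately as a central erosion factor below
  wx <- l_map * mx
  wy <- l_map * my
  ax_proj <- a_proj(source$sad_x, aperture[1], z)
  ay_proj <- a_proj(source$sad_y, aperture[2], z)
  dose <- matrix(0, nrow = grid$nz, ncol = nrow(layers))
  for (k in seq_len(nrow(layers))) {
    res <- run_engine(scene, physics,
                      spots = data.frame(x_iso = 0, y_iso = 0,
                                         energy = layers$energy[k],
                                         sigma_pos = layers$sigma_pos[k],
                                         sigma_ang = layers$sigma_ang[k],
                                         n_primaries = as.integer(n_presim)),
                      seed = seed + k, weight = 1, nbatch = 2,
                      source = source,
                      opts = list(do_tally = FALSE, do_zprof = TRUE,
                                  zprof_wx = wx, zprof_wy = wy))
    # laterally integrated dE/dz within the map window, per proton
    eps_in <- res$zprof_in / n_presim
    # aperture erosion of the central-axis fluence: the collimator clips
    # the field at its exit plane; the clipped edge then migrates toward
    # the axis only through the angular spread (source + absorber MCS)
    # and the in-water scattering accumulated by depth z
    fe <- fe_march(layers$energy[k], source$collimator_thickness, physics)
    ang2 <- fe$ang_ce + layers$sigma_ang[k]^2
    e_surf <- energy_at_range(pmax(layers$range[k], 0.5), "water", physics)
    sig_w <- water_mcs_sigma(e_surf, z, physics)
    sig_mig <- sqrt(ang2 * (z - (-6))^2 + sig_w^2)
    t_ap <- (2 * stats::pnorm(ax_proj / sig_mig) - 1) *
            (2 * stats::pnorm(ay_proj / sig_mig) - 1)
    # MeV/cm per proton -> Gy for one proton per spot on the diverging map
    dose[, k] <- eps_in / h / (spacing^2 * mx * my) * t_ap * 1.602176634e-10
  }
  list(z = z, dose = dose)
}

#' SOBP layer weights
#'
#' Nonnegative least-squares fit of the per-layer depth-dose columns to a
#' flat prescription over the SOBP span (2 mm inside each edge).
#'
#' @param layers Layer table.
#' @param ddm Depth-dose matrix from [depth_dose_matrix()].
#' @param target A [target_spec()].
#' @param prescription Physical dose in Gy.
#' @return List with `weights` (protons per spot, one per layer),
#'   `flatness` ((max-min)/mean of the fit over the SOBP span), `fit_z`,
#'   `fit_dose`.
#' @export
sobp_weights <- function(layers, ddm, target, prescription = 2) {
  # the fit region stays 2-3 mm inside the SOBP edges (the distal bin
  # straddles the falloff) and above the 0.7 cm entrance region that the
  # 0.5-cm minimum deliverable range cannot dose
  z_lo <- max(target$range_R - target$sobp_S + 0.2, 0.7)
  z_hi <- target$range_R - 0.3
  sel <- ddm$z >= z_lo & ddm$z <= z_hi
  if (!any(sel)) {
    sel <- seq_along(ddm$z) == which.min(abs(ddm$z - target$range_R + 0.1))
  }
  a <- ddm$dose[sel, , drop = FALSE]
  if (all(a == 0) || any(!is.finite(a))) {
    stop("degenerate depth-dose matrix for layer ranges: ",
         paste(signif(layers$range, 3), collapse = ", "))
  }
  b <- rep(prescription, sum(sel))
  w <- pracma::lsqnonneg(a, b)$x
  fit <- as.vector(a %*% w)
  list(weights = w, flatness = (max(fit) - min(fit)) / mean(fit),
       fit_z = ddm$z[sel], fit_dose = fit)
}

#' Build a deliverable plan
#'
#' End-to-end planning for a rectangular target: collimator thickness by
#' the range rule, aperture by field-edge back-projection, energy layers,
#' per-energy source calibration, pre-simulated depth-dose matrix and
#' nonnegative SOBP weights normalised to the prescription.
#'
#' @param target A [target_spec()].
#' @param physics Physics bundle.
#' @param source Optional [beam_source_model()] override.
#' @param prescription Physical target dose in Gy.
#' @param spot_spacing,layer_spacing Spacings in cm.
#' @param n_presim Primaries per layer for the depth-dose pre-simulation.
#' @param seed Seed for the pre-simulation.
#' @return Object of class `proton_plan`.
#' @export
build_plan <- function(target, physics = default_physics(), source = NULL,
                       prescription = 2, spot_spacing = 0.5,
                       layer_spacing = 0.5, n_presim = 2000, seed = 1) {
  thickness <- collimator_thickness_for(target$range_R)
  if (is.null(source)) source <- beam_source_model(thickness)
  aperture <- aperture_for_target(target, source)
  layers <- make_layers(target, physics, layer_spacing)
  cal <- calibrate_source(source, layers$energy, physics)
  layers$sigma_iso_mm <- cal$sigma_iso_mm
  layers$sigma_pos <- cal$sigma_pos
  layers$sigma_ang <- cal$sigma_ang
  ddm <- depth_dose_matrix(target, layers, aperture, source, physics,
                           n_presim = n_presim, spacing = spot_spacing,
                           seed = seed)
  fit <- sobp_weights(layers, ddm, target, prescription)
  layers$weight <- fit$weights
  map <- make_spot_map(target, spot_spacing)
  spots <- do.call(rbind, lapply(seq_len(nrow(layers)), function(k) {
    data.frame(x_iso = map$x_iso, y_iso = map$y_iso,
               energy = layers$energy[k],
               sigma_pos = layers$sigma_pos[k],
               sigma_ang = layers$sigma_ang[k],
               weight = layers$weight[k])
  }))
  structure(list(target = target, collimator_thickness = thickness,
                 aperture = aperture, source = source, layers = layers,
                 spot_map = map, spots = spots,
                 total_protons = sum(spots$weight),
                 prescription = prescription,
                 flatness = fit$flatness,
                 fit_z = fit$fit_z, fit_dose = fit$fit_dose),
            class = "proton_plan")
}

#' @export
print.proton_plan <- function(x, ...) {
  cat(sprintf("proton plan for %s: %d layers x %d spots, aperture %.2f x %.2f cm,\n",
              x$target$label, nrow(x$layers), nrow(x$spot_map),
              x$aperture[1], x$aperture[2]))
  cat(sprintf("  %.3g protons for %.3g Gy, SOBP flatness %.2f%%\n",
              x$total_protons, x$prescription, 100 * x$flatness))
  invisible(x)
}

#' Serialise / read a plan as structured text
#'
#' @param plan A `proton_plan`.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  obj <- list(target = unclass(plan$target),
              collimator_thickness = plan$collimator_thickness,
              aperture = as.numeric(plan$aperture),
              prescription = plan$prescription,
              total_protons = plan$total_protons,
              flatness = plan$flatness,
              layers = as.list(plan$layers),
              spot_map = as.list(plan$spot_map),
              source = unclass(plan$source))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- yaml::yaml.load_file(path)
  target <- do.call(target_spec, obj$target[c("range_R", "sobp_S",
                                              "field_FS", "label")])
  source <- do.call(beam_source_model,
                    obj$source[c("collimator_thickness", "sad_x", "sad_y",
                                 "energy_dispersion", "sigma_growth")])
  layers <- as.data.frame(obj$layers)
  map <- as.data.frame(obj$spot_map)
  spots <- do.call(rbind, lapply(seq_len(nrow(layers)), function(k) {
    data.frame(x_iso = map$x_iso, y_iso = map$y_iso,
               energy = layers$energy[k],
               sigma_pos = layers$sigma_pos[k],
               sigma_ang = layers$sigma_ang[k],
               weight = layers$weight[k])
  }))
  structure(list(target = target,
                 collimator_thickness = obj$collimator_thickness,
                 aperture = unlist(obj$aperture), source = source,
                 layers = layers, spot_map = map, spots = spots,
                 total_protons = obj$total_protons,
                 prescription = obj$prescription,
                 flatness = obj$flatness),
            class = "proton_plan")
}
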