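# Material data and single-proton physics: Bethe stopping power, CSDA
# ranges, Highland multiple-Coulomb-scattering angle, Bohr straggling, and
# the water-equivalent-thickness calibration of the nozzle energy absorber.

PROTON_MASS_MEV <- 938.272
ELECTRON_MASS_MEV <- 0.51099895
BETHE_K <- 0.307075           # MeV cm^2 / mol  (4 pi NA re^2 me c^2)
BOHR_K <- 0.1569              # MeV^2 cm^2 / mol, Bohr straggling constant
HIGHLAND_E <- 14.1            # MeV, Highland constant
MEV_TO_J <- 1.602176634e-13

#' Load the material table
#'
#' Reads the structured text file describing the materials of the beamline
#' (water, ABS-like absorber plastic, brass, air): density, mean excitation
#' energy, \eqn{\langle Z/A\rangle}, radiation length, nuclear removal
#' length and water-equivalence ratio.  Users may supply their own file
#' with the same columns to override the shipped data.
#'
#' @param path Path to a tab-separated material file; default is the table
#'   shipped with the package.
#' @return A `data.frame` with one row per material.
#' @export
load_materials <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.tsv", package = "pbscatter")
  }
  m <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "density", "i_ev", "z_over_a",
                  "x0_g_cm2", "lambda_g_cm2", "wer") %in% names(m)))
  if (any(m$density <= 0) || any(m$i_ev <= 0) || any(m$x0_g_cm2 <= 0)) {
    stop("material table: density, i_ev and x0_g_cm2 must be positive")
  }
  if (abs(m$wer[m$name == "water"] - 1) > 0) {
    stop("material table: water must have wer == 1")
  }
  m
}

# Bethe electronic stopping power without shell/density corrections,
# adequate above ~1 MeV.  Vectorised over energy.  Returns MeV/cm.
bethe_stopping <- function(energy, density, i_ev, z_over_a) {
  gamma <- 1 + energy / PROTON_MASS_MEV
  beta2 <- 1 - 1 / gamma^2
  arg <- 2 * ELECTRON_MASS_MEV * 1e6 * beta2 * gamma^2 / i_ev
  # keep the logarithm positive where the formula leaves its validity
  # domain (far below the 1 MeV transport cut-off)
  bracket <- pmax(log(pmax(arg, 1.2)) - beta2, 0.05)
  BETHE_K * density * z_over_a / beta2 * bracket
}

#' Build stopping-power and CSDA-range tables
#'
#' Tabulates the electronic stopping power and the cumulative CSDA range
#' \eqn{R(E)=\int_0^E dE'/S(E')} for every material on a logarithmic
#' energy grid.  Interpolation between grid points is log-log linear.
#'
#' @param materials Material table from [load_materials()].
#' @param n_energy Number of grid points.
#' @param e_min,e_max Grid limits in MeV.
#' @return An object of class `stopping_table`.
#' @export
stopping_table <- function(materials, n_energy = 400, e_min = 0.1, e_max = 300) {
  e <- exp(seq(log(e_min), log(e_max), length.out = n_energy))
  s <- sapply(seq_len(nrow(materials)), function(i) {
    bethe_stopping(e, materials$density[i], materials$i_ev[i],
                   materials$z_over_a[i])
  })
  colnames(s) <- materials$name
  # cumulative trapezoid of 1/S, anchored with the residual range below
  # the grid floor approximated as E_min / S(E_min)
  r <- apply(s, 2, function(sc) {
    inv <- 1 / sc
    cumul <- c(0, cumsum(diff(e) * (inv[-1] + inv[-length(inv)]) / 2))
    cumul + e[1] * inv[1]
  })
  structure(list(energies = e, log_e = log(e),
                 stopping = s, log_s = log(s),
                 csda = r, log_r = log(r),
                 materials = materials),
            class = "stopping_table")
}

tbl_col <- function(table, material) {
  j <- match(material, colnames(table$stopping))
  if (is.na(j)) stop("unknown material: ", material)
  j
}

check_energy_range <- function(energy, table, allow_zero = FALSE) {
  lo <- table$energies[1]
  hi <- table$energies[length(table$energies)]
  bad <- if (allow_zero) energy < 0 | energy > hi else energy < lo | energy > hi
  if (any(bad)) {
    stop(sprintf("energy %.4g MeV outside table range [%.4g, %.4g] MeV",
                 energy[which(bad)[1]], lo, hi))
  }
}

#' Electronic stopping power
#'
#' Unrestricted electronic stopping power \eqn{S(E)} of a proton, from the
#' tabulated Bethe formula with log-log interpolation.
#'
#' @param energy Kinetic energy in MeV (vectorised).
#' @param material Material name.
#' @param physics A physics bundle from [proton_physics()], or a raw
#'   `stopping_table`.
#' @return Stopping power in MeV/cm.
#' @export
electronic_stopping_power <- function(energy, material = "water",
                                      physics = default_physics()) {
  table <- as_stopping_table(physics)
  check_energy_range(energy, table)
  j <- tbl_col(table, material)
  exp(stats::approx(table$log_e, table$log_s[, j], xout = log(energy),
                    rule = 2)$y)
}

#' CSDA range
#'
#' Continuous-slowing-down range \eqn{R(E)=\int_0^E dE'/S(E')}.
#'
#' @inheritParams electronic_stopping_power
#' @return Range in cm; 0 at zero energy.
#' @export
csda_range <- function(energy, material = "water", physics = default_physics()) {
  table <- as_stopping_table(physics)
  check_energy_range(energy, table, allow_zero = TRUE)
  j <- tbl_col(table, material)
  out <- numeric(length(energy))
  pos <- energy > 0
  if (any(pos)) {
    e <- pmax(energy[pos], table$energies[1])
    out[pos] <- exp(stats::approx(table$log_e, table$log_r[, j],
                                  xout = log(e), rule = 2)$y)
  }
  out
}

#' Energy from CSDA range (inverse range-energy relation)
#'
#' @param range_cm CSDA range in cm (vectorised).
#' @inheritParams electronic_stopping_power
#' @return Kinetic energy in MeV.
#' @export
energy_at_range <- function(range_cm, material = "water",
                            physics = default_physics()) {
  table <- as_stopping_table(physics)
  j <- tbl_col(table, material)
  rmin <- table$csda[1, j]
  rmax <- table$csda[nrow(table$csda), j]
  if (any(range_cm < rmin | range_cm > rmax)) {
    stop(sprintf("range outside table span [%.3g, %.3g] cm", rmin, rmax))
  }
  exp(stats::approx(table$log_r[, j], table$log_e, xout = log(range_cm))$y)
}

#' Residual range in water behind the energy absorber
#'
#' Water range left to a proton of the given energy after traversing an
#' absorber of fixed water-equivalent thickness, floored at zero.
#'
#' @param energy Kinetic energy in MeV.
#' @param absorber_wet Water-equivalent thickness of the absorber in cm;
#'   default is the calibrated WET of the 4-cm absorber.
#' @inheritParams electronic_stopping_power
#' @export
residual_range_water <- function(energy, absorber_wet = NULL,
                                 physics = default_physics()) {
  if (is.null(absorber_wet)) absorber_wet <- physics$absorber$wet
  if (any(absorber_wet < 0)) stop("absorber_wet must be >= 0")
  pmax(csda_range(energy, "water", physics) - absorber_wet, 0)
}

# relativistic momentum * velocity, pv = p c beta, in MeV
proton_pv <- function(energy) {
  etot <- energy + PROTON_MASS_MEV
  pc2 <- etot^2 - PROTON_MASS_MEV^2
  pc2 / etot
}

#' Highland multiple-Coulomb-scattering angle
#'
#' Projected scattering-angle sigma
#' \eqn{\theta_0 = (14.1/pv)\sqrt{t/X_0}\,[1+\frac19\log_{10}(t/X_0)]}.
#' The logarithmic correction is evaluated on `slab` (the total traversed
#' thickness of the material slab), so that subdividing a slab into
#' condensed-history steps leaves the accumulated variance unchanged.
#'
#' @param energy Kinetic energy in MeV.
#' @param path Step path length in cm (must be positive).
#' @param material Material name.
#' @param slab Total slab thickness in cm used for the log correction;
#'   defaults to `path`.
#' @inheritParams electronic_stopping_power
#' @return Projected angle sigma in radians.
#' @export
highland_angle <- function(energy, path, material = "water",
                           physics = default_physics(), slab = path) {
  if (any(path <= 0)) stop("path must be > 0")
  if (any(energy <= 1)) stop("energy must be > 1 MeV")
  table <- as_stopping_table(physics)
  m <- table$materials[tbl_col(table, material), ]
  x0_cm <- m$x0_g_cm2 / m$density
  t_rl <- path / x0_cm
  corr <- pmax(1 + log10(slab / x0_cm) / 9, 0.25)
  HIGHLAND_E / proton_pv(energy) * sqrt(t_rl) * corr
}

#' Gaussian energy-straggling sigma (Bohr)
#'
#' @param energy_in,energy_out Energies in MeV bracketing the step
#'   (`energy_in > energy_out >= 0`; validation only, Bohr straggling is
#'   energy independent).
#' @param path Path length in cm.
#' @inheritParams highland_angle
#' @return Sigma of the energy-loss fluctuation in MeV.
#' @export
straggling_sigma <- function(energy_in, energy_out, path, material = "water",
                             physics = default_physics()) {
  if (any(energy_out < 0) || any(energy_in <= energy_out)) {
    stop("require energy_in > energy_out >= 0")
  }
  if (any(path < 0)) stop("path must be >= 0")
  table <- as_stopping_table(physics)
  m <- table$materials[tbl_col(table, material), ]
  sqrt(BOHR_K * m$density * m$z_over_a * path)
}

#' Printed range-energy anchor points of the nozzle
#'
#' The (beam energy, residual range in water) pairs that characterise the
#' nozzle with its 4-cm energy absorber: 74.9 MeV -> 0.5 cm,
#' 142.5 MeV -> 10 cm, 192.4 MeV -> 20 cm.
#'
#' @return A `data.frame` with columns `energy` (MeV) and `residual` (cm).
#' @export
range_energy_anchors <- function() {
  data.frame(energy = c(74.9, 142.5, 192.4), residual = c(0.5, 10, 20))
}

#' Calibrate the energy absorber
#'
#' Fits the single energy-independent water-equivalent thickness (WET) of
#' the 4-cm absorber by least squares to the range-energy anchor points,
#' and adjusts the absorber plastic density so that the physical 4-cm slab
#' reproduces that WET at the mid anchor energy.  The anchors are not
#' exactly consistent with one WET; the least-squares constant reproduces
#' all three within +/- 0.5 cm.
#'
#' @param materials Material table.
#' @param table Stopping table built from `materials` (rebuilt internally
#'   after the density update).
#' @param anchors Anchor data frame, see [range_energy_anchors()].
#' @param thickness Physical absorber thickness in cm.
#' @return List with elements `wet` (cm), `density` (g/cm^3 of the
#'   absorber plastic), `residuals` (anchor fit residuals, cm).
#' @export
calibrate_absorber <- function(materials, table = stopping_table(materials),
                               anchors = range_energy_anchors(),
                               thickness = 4) {
  rw <- csda_range(anchors$energy, "water", table)
  wet <- mean(rw - anchors$residual)          # least-squares constant
  # WET of the physical slab at the mid anchor, as a function of density
  e_ref <- anchors$energy[2]
  wet_of_rho <- function(rho) {
    mm <- materials
    mm$density[mm$name == "abs_plastic"] <- rho
    tt <- stopping_table(mm)
    r_abs <- csda_range(e_ref, "abs_plastic", tt)
    if (r_abs <= thickness) return(csda_range(e_ref, "water", tt))
    e_out <- energy_at_range(r_abs - thickness, "abs_plastic", tt)
    csda_range(e_ref, "water", tt) - csda_range(e_out, "water", tt)
  }
  rho <- stats::uniroot(function(r) wet_of_rho(r) - wet,
                        interval = c(0.7, 1.8), tol = 1e-6)$root
  list(wet = wet, density = rho,
       residuals = (rw - wet) - anchors$residual)
}

#' Assemble the physics bundle
#'
#' Builds the material table, the stopping/range tables and the calibrated
#' absorber in one object used by every other module.  The result is
#' cached; pass `rebuild = TRUE` (or a custom material path) to refresh.
#'
#' @param material_path Optional path to a custom material file.
#' @param rebuild Force a rebuild of the cached default bundle.
#' @return An object of class `proton_physics`: list with `materials`,
#'   `table` (calibrated), `absorber` (`wet`, `density`, `thickness`).
#' @export
proton_physics <- function(material_path = NULL, rebuild = FALSE) {
  materials <- load_materials(material_path)
  cal <- calibrate_absorber(materials)
  materials$density[materials$name == "abs_plastic"] <- cal$density
  structure(list(materials = materials,
                 table = stopping_table(materials),
                 absorber = list(wet = cal$wet, density = cal$density,
                                 thickness = 4,
                                 residuals = cal$residuals)),
            class = "proton_physics")
}

#' @rdname proton_physics
#' @export
default_physics <- function(rebuild = FALSE) {
  if (rebuild || is.null(.pbs_cache$physics)) {
    .pbs_cache$physics <- proton_physics()
  }
  .pbs_cache$physics
}

as_stopping_table <- function(physics) {
  if (inherits(physics, "stopping_table")) return(physics)
  if (inherits(physics, "proton_physics")) return(physics$table)
  stop("expected a 'proton_physics' or 'stopping_table' object")
}

# Flattened physics tables in the fixed material order used by the C++
# transport kernel: 1 air, 2 abs_plastic, 3 brass, 4 water.
physics_for_engine <- function(physics = default_physics()) {
  table <- physics$table
  ord <- c("air", "abs_plastic", "brass", "water")
  j <- match(ord, colnames(table$stopping))
  m <- physics$materials[match(ord, physics$materials$name), ]
  list(log_e = table$log_e,
       log_s = table$log_s[, j, drop = FALSE],
       log_r = table$log_r[, j, drop = FALSE],
       density = m$density,
       z_over_a = m$z_over_a,
       x0_cm = m$x0_g_cm2 / m$density,
       lambda_cm = m$lambda_g_cm2 / m$density)
}
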