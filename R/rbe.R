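# Linear-quadratic variable RBE model (McNamara et al. 2015) and the
# point metrics comparing the unscattered and all-proton channels at the
# surface and target-center evaluation points.

#' Coefficients of the LQ-based RBE model
#'
#' `RBE_max = c0 + c1 * LETd / (alpha/beta)` and
#' `RBE_min = c2 - c3 * sqrt(alpha/beta) * LETd`, with the published
#' coefficients c0 = 0.99064, c1 = 0.35605 Gy/(keV/um), c2 = 1.1012 and
#' c3 = 0.0038703 Gy^(-1/2) (keV/um)^(-1).
#'
#' @param alpha_beta_surface,alpha_beta_target Reference photon
#'   alpha/beta ratios in Gy used at the surface and target-center
#'   evaluation points.
#' @return List of class `rbe_params`.
#' @export
rbe_params <- function(alpha_beta_surface = 3, alpha_beta_target = 10) {
  stopifnot(alpha_beta_surface > 0, alpha_beta_target > 0)
  structure(list(c0 = 0.99064, c1 = 0.35605, c2 = 1.1012, c3 = 0.0038703,
                 alpha_beta_surface = alpha_beta_surface,
                 alpha_beta_target = alpha_beta_target),
            class = "rbe_params")
}

#' Asymptotic RBE values of the LQ model
#'
#' `rbe_max()` is the low-dose limit and `rbe_min()` the high-dose limit
#' of [rbe_mcnamara()] at given LET.
#'
#' @param letd Dose-averaged LET in keV/um.
#' @param alpha_beta Photon alpha/beta in Gy.
#' @param params [rbe_params()].
#' @export
rbe_max <- function(letd, alpha_beta, params = rbe_params()) {
  params$c0 + params$c1 * letd / alpha_beta
}

#' @rdname rbe_max
#' @export
rbe_min <- function(letd, alpha_beta, params = rbe_params()) {
  params$c2 - params$c3 * sqrt(alpha_beta) * letd
}

#' LQ-based variable RBE
#'
#' \deqn{RBE(D,\alpha/\beta,LET_d) = \frac{1}{2D}\left(
#'   \sqrt{(\alpha/\beta)^2 + 4D(\alpha/\beta)RBE_{max}
#'         + 4 RBE_{min}^2 D^2} - \alpha/\beta\right)}
#' The low-dose limit equals `RBE_max`, the high-dose limit `RBE_min`.
#'
#' @param dose Physical proton dose per fraction in Gy (must be > 0; use
#'   [rbe_max()] for the zero-dose limit).
#' @param alpha_beta Photon alpha/beta in Gy.
#' @param letd Dose-averaged LET in keV/um (>= 0).
#' @param params [rbe_params()].
#' @return Dimensionless RBE (vectorised over the inputs).
#' @export
rbe_mcnamara <- function(dose, alpha_beta, letd, params = rbe_params()) {
  if (any(dose <= 0)) stop("dose must be > 0 (low-dose limit is rbe_max)")
  if (any(letd < 0)) stop("letd must be >= 0")
  rmx <- rbe_max(letd, alpha_beta, params)
  rmn <- rbe_min(letd, alpha_beta, params)
  ab <- alpha_beta
  (sqrt(ab^2 + 4 * dose * ab * rmx + 4 * rmn^2 * dose^2) - ab) / (2 * dose)
}

#' Surface x-position of the maximum scattered dose
#'
#' Returns the x coordinate of the voxel maximising the
#' collimator-scattered dose along y = 0 at depth `z_s`.  Ties are broken
#' toward the smallest |x| and then toward negative x.
#'
#' @param grids A [finalize_tallies()] result.
#' @param z_s Evaluation depth in cm (default 0.5 cm).
#' @param y_half Half-width in cm of the y band averaged over (default:
#'   the single voxel row containing y = 0).
#' @param symmetrize Average the profile with its x mirror before taking
#'   the argmax (the square-field problem is x-symmetric).
#' @return x in cm (voxel centre).
#' @export
find_xs <- function(grids, z_s = 0.5, y_half = 0, symmetrize = FALSE) {
  g <- grids$grid
  iz <- voxel_index(z_s, g$z0, g$voxel_cm, g$nz)
  iy <- if (y_half > 0) voxel_band(grids$axes$y, 0, y_half)
        else voxel_index(0, g$y0, g$voxel_cm, g$ny)
  prof <- apply(grids$dose[, iy, iz, 1, drop = FALSE], 1, mean)
  if (all(prof <= 0)) stop("scattered-dose profile is identically zero")
  if (symmetrize) prof <- (prof + rev(prof)) / 2
  x <- grids$axes$x
  ord <- order(-prof, abs(x), x)
  x[ord[1]]
}

# index sets of the two evaluation regions used by evaluate_target; the
# surface y strip stays inside the aperture span in y so that it samples
# the wall-parallel scattered-dose line uniformly
evaluation_regions <- function(grids, target, z_s = 0.5, z_c_half = 0.3) {
  g <- grids$grid
  ax <- grids$axes
  z_c <- target$range_R - target$sobp_S / 2
  if (z_c >= g$nz * g$voxel_cm) stop("target-center depth outside the grid")
  w <- min(target$field_FS / 4, 2)
  list(z_c = z_c,
       centre = list(ix = voxel_band(ax$x, 0, w),
                     iy = voxel_band(ax$y, 0, w),
                     iz = voxel_band(ax$z, z_c, z_c_half)),
       iz_s = voxel_index(z_s, g$z0, g$voxel_cm, g$nz),
       iy_strip = voxel_band(ax$y, 0, min(target$field_FS / 4, 4)))
}

# batch-based standard error of a LET difference over a region:
# per-batch estimates of letd(S+US) - letd(US) from the batch partitions
region_dletd_se <- function(tally, ix, iy, iz) {
  rb <- region_batch_sums(tally, ix, iy, iz)
  nb <- ncol(rb$eps)
  est <- vapply(seq_len(nb), function(b) {
    e_us <- rb$eps[2, b]
    e_tot <- rb$eps[1, b] + rb$eps[2, b]
    if (e_us <= 0 || e_tot <= 0) return(NA_real_)
    (rb$epsl[1, b] + rb$epsl[2, b]) / e_tot - rb$epsl[2, b] / e_us
  }, numeric(1))
  if (all(is.na(est))) return(NA_real_)
  stats::sd(est, na.rm = TRUE) / sqrt(sum(!is.na(est)))
}

#' Point metrics for one target geometry
#'
#' Computes the evaluation quantities at the representative surface depth
#' `z_s = 5 mm` and at the target-center depth `z_c = R - S/2`: the
#' maximum collimator-scattered dose along x at the surface and the
#' scattered dose at the center (both as % of the unscattered dose at the
#' center), the dose-averaged LET of the S, US and S+US channels at both
#' points, and the RBE of the US and S+US channels (alpha/beta = 3 Gy at
#' the surface, 10 Gy at the center, evaluated at the local total dose).
#'
#' To keep point estimates stable at desk-scale statistics, "points" are
#' small symmetry-respecting regions: the center values average over a
#' central box, and the surface profile is averaged over a central y
#' strip and x-mirror-symmetrised before the peak search.
#'
#' @param grids A [finalize_tallies()] result.
#' @param target The [target_spec()] (defaults to the plan stored in
#'   `grids`).
#' @param params [rbe_params()].
#' @param z_s Surface evaluation depth in cm.
#' @param rbe_fun RBE model function with signature
#'   `(dose, alpha_beta, letd, params)`; the McNamara model by default
#'   (swapping it changes only the RBE fields).
#' @return One-row `data.frame` (a metrics record).
#' @export
evaluate_target <- function(grids, target = NULL, params = rbe_params(),
                            z_s = 0.5, rbe_fun = rbe_mcnamara) {
  if (is.null(target)) target <- grids$plan$target
  stopifnot(inherits(target, "target_spec"))
  reg <- evaluation_regions(grids, target, z_s)
  g <- grids$grid
  ax <- grids$axes

  cen <- region_stats(grids, reg$centre$ix, reg$centre$iy, reg$centre$iz)
  d_us_c <- cen$dose[["US"]]
  if (d_us_c <= 0) stop("no unscattered dose at the target center")

  # with no scattered channel at all (collimator-free geometry) the peak
  # search is undefined; evaluate on the axis instead
  has_s <- any(grids$dose[, , reg$iz_s, 1] > 0)
  x_s <- if (has_s) {
    find_xs(grids, z_s, y_half = min(target$field_FS / 4, 4),
            symmetrize = TRUE)
  } else 0
  ixs <- voxel_index(c(x_s, -x_s), g$x0, g$voxel_cm, g$nx)  # mirror pair
  # peak dose: the maximising voxel column (with its x mirror);
  # LET and RBE: a +/- 1 voxel window around it for statistical stability
  sur <- region_stats(grids, unique(ixs), reg$iy_strip, reg$iz_s)
  ixw <- unique(pmin(pmax(c(outer(ixs, -1:1, "+")), 1), g$nx))
  surw <- region_stats(grids, ixw, reg$iy_strip, reg$iz_s)

  ab_s <- params$alpha_beta_surface
  ab_c <- params$alpha_beta_target
  d_sur <- surw$dose[["S+US"]]
  d_cen <- cen$dose[["S+US"]]
  rbe_us_s <- rbe_fun(d_sur, ab_s, surw$letd[["US"]], params)
  rbe_tot_s <- rbe_fun(d_sur, ab_s, surw$letd[["S+US"]], params)
  rbe_us_c <- rbe_fun(d_cen, ab_c, cen$letd[["US"]], params)
  rbe_tot_c <- rbe_fun(d_cen, ab_c, cen$letd[["S+US"]], params)
  tl <- grids$tally
  dletd_s_se <- if (is.null(tl)) NA_real_ else
    region_dletd_se(tl, ixw, reg$iy_strip, reg$iz_s)
  dletd_c_se <- if (is.null(tl)) NA_real_ else
    region_dletd_se(tl, reg$centre$ix, reg$centre$iy, reg$centre$iz)

  frac <- function(v) 100 * v / d_us_c
  data.frame(label = target$label,
             range_R = target$range_R, sobp_S = target$sobp_S,
             field_FS = target$field_FS,
             x_s = x_s, z_s = z_s, z_c = reg$z_c,
             D_US_center = d_us_c,
             D_S_surface_frac = frac(sur$dose[["S"]]),
             D_S_surface_frac_se = frac(sur$dose_se[["S"]]),
             D_S_center_frac = frac(cen$dose[["S"]]),
             D_S_center_frac_se = frac(cen$dose_se[["S"]]),
             letd_S_surface = surw$letd[["S"]],
             letd_US_surface = surw$letd[["US"]],
             letd_tot_surface = surw$letd[["S+US"]],
             letd_S_center = cen$letd[["S"]],
             letd_US_center = cen$letd[["US"]],
             letd_tot_center = cen$letd[["S+US"]],
             dletd_surface = surw$letd[["S+US"]] - surw$letd[["US"]],
             dletd_surface_se = dletd_s_se,
             dletd_center = cen$letd[["S+US"]] - cen$letd[["US"]],
             dletd_center_se = dletd_c_se,
             rbe_US_surface = rbe_us_s, rbe_tot_surface = rbe_tot_s,
             rbe_US_center = rbe_us_c, rbe_tot_center = rbe_tot_c,
             rbe_inc_surface = rbe_tot_s - rbe_us_s,
             rbe_inc_center = rbe_tot_c - rbe_us_c,
             stringsAsFactors = FALSE)
}

#' Voxel-wise scatter-dose versus LET-increase analysis
#'
#' Lists every voxel receiving a collimator-scattered dose above `d_min`
#' together with the LET increase
#' `delta = LETd(S+US) - LETd(US)`, and summarises the two regions of the
#' cloud: the largest LET increase among voxels with a large scattered
#' dose (> `d_high`), and the largest scattered dose among voxels with a
#' large LET increase (> `dletd_high`).
#'
#' At desk-scale statistics a single low-energy history can deposit a
#' sizeable dose in one voxel; voxels whose channels are not supported by
#' every batch (or whose batch relative error exceeds `max_rse`) are
#' low-statistics artefacts and are excluded when `reliable_only` is set.
#'
#' @param grids A [finalize_tallies()] result.
#' @param d_min Inclusion threshold on the scattered dose in Gy.
#' @param d_high High-scattered-dose threshold in Gy.
#' @param dletd_high High LET-increase threshold in keV/um.
#' @param reliable_only Drop low-statistics voxels (default `TRUE`).
#' @param max_rse Batch relative-error bound used by the reliability
#'   filter.
#' @param min_total_dose Total-dose threshold in Gy applied to the
#'   two-region *summary* (not to the point cloud): LET statements are
#'   only made for positions receiving at least 15% of the target-center
#'   dose (0.3 Gy at the 2 Gy prescription).
#' @return List with `points` (data.frame `x`, `y`, `z`, `D_S`, `D_tot`,
#'   `dletd`) and `summary` (named numerics `max_dletd_high_dose`,
#'   `max_ds_high_dletd`; `NA` when a region is empty).
#' @export
scatter_analysis <- function(grids, d_min = 0.01, d_high = 0.08,
                             dletd_high = 1, reliable_only = TRUE,
                             max_rse = 0.35, min_total_dose = 0.3) {
  ds <- grids$dose[, , , 1]
  if (reliable_only && !is.null(grids$n_batches_hit)) {
    nb <- grids$tally$nbatch
    ok <- grids$n_batches_hit[, , , 1] == nb &
          grids$n_batches_hit[, , , 2] == nb &
          !is.na(grids$dose_rse[, , , 1]) &
          grids$dose_rse[, , , 1] <= max_rse &
          !is.na(grids$dose_rse[, , , 2]) &
          grids$dose_rse[, , , 2] <= max_rse
    ds <- ifelse(ok, ds, 0)
  }
  keep <- which(ds > d_min, arr.ind = TRUE)
  ax <- grids$axes
  if (nrow(keep) == 0) {
    return(list(points = data.frame(x = numeric(), y = numeric(),
                                    z = numeric(), D_S = numeric(),
                                    D_tot = numeric(), dletd = numeric()),
                summary = c(max_dletd_high_dose = NA_real_,
                            max_ds_high_dletd = NA_real_)))
  }
  lt_tot <- grids$letd[, , , 3][keep]
  lt_us <- grids$letd[, , , 2][keep]
  dletd <- lt_tot - lt_us
  pts <- data.frame(x = ax$x[keep[, 1]], y = ax$y[keep[, 2]],
                    z = ax$z[keep[, 3]], D_S = ds[keep],
                    D_tot = grids$dose[, , , 3][keep], dletd = dletd)
  ok <- is.finite(pts$dletd) & pts$D_tot >= min_total_dose
  hi_d <- ok & pts$D_S > d_high
  hi_l <- ok & pts$dletd > dletd_high
  list(points = pts,
       summary = c(max_dletd_high_dose =
                     if (any(hi_d)) max(pts$dletd[hi_d]) else NA_real_,
                   max_ds_high_dletd =
                     if (any(hi_l)) max(pts$D_S[hi_l]) else NA_real_))
}
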