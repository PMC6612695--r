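# Conversion of raw per-voxel, per-channel tallies into absolute dose and
# dose-averaged LET grids, batch-based uncertainties, profile extraction
# and the grid text format.

MEV_PER_G_TO_GY <- 1.602176634e-10   # MeV/g -> Gy

#' Finalize tallies into dose and LET grids
#'
#' Converts the accumulated energy deposits into absolute dose per voxel
#' and forms the dose-averaged LET
#' \eqn{LET_d = \sum L\,\varepsilon / \sum \varepsilon} per channel, with
#' the merged (S+US) channel built from the channel sums so that the
#' mixture identity holds exactly.
#'
#' @param tally A `tally_grid` from [run_field()].
#' @param plan The plan that produced it (for bookkeeping fields).
#' @return Object of class `proton_grids`: arrays `dose` and `letd` of
#'   dimension `c(nx, ny, nz, 3)` with channels `S`, `US`, `S+US` (dose
#'   in Gy, LET in keV/um, LET `NA` where no energy was deposited), the
#'   voxel axes, and the raw tally for batch statistics.
#' @export
finalize_tallies <- function(tally, plan = NULL) {
  stopifnot(inherits(tally, "tally_grid"))
  g <- tally$grid
  eps <- rowSums(tally$eps, dims = 4)    # sum over batches
  epsl <- rowSums(tally$epsL, dims = 4)
  mass_g <- g$voxel_cm^3 * 1.0           # water, 1 g/cm^3
  scale <- MEV_PER_G_TO_GY / mass_g
  dims <- c(g$nx, g$ny, g$nz, 3)
  dose <- array(0, dims)
  letd <- array(NA_real_, dims)
  dose[, , , 1] <- eps[, , , 1] * scale
  dose[, , , 2] <- eps[, , , 2] * scale
  dose[, , , 3] <- dose[, , , 1] + dose[, , , 2]
  eps_tot <- eps[, , , 1] + eps[, , , 2]
  epsl_tot <- epsl[, , , 1] + epsl[, , , 2]
  letd[, , , 1] <- ifelse(eps[, , , 1] > 0, epsl[, , , 1] / eps[, , , 1], NA)
  letd[, , , 2] <- ifelse(eps[, , , 2] > 0, epsl[, , , 2] / eps[, , , 2], NA)
  letd[, , , 3] <- ifelse(eps_tot > 0, epsl_tot / eps_tot, NA)
  # per-voxel, per-channel batch statistics: relative error of the dose
  # and the number of batches with any signal (low-statistics voxels --
  # dominated by one or two histories -- are flagged, not trusted)
  nb <- tally$nbatch
  rse <- array(NA_real_, dims)
  nhit <- array(0L, c(g$nx, g$ny, g$nz, 2))
  for (ch in 1:2) {
    bm <- tally$eps[, , , ch, , drop = FALSE]
    mu <- eps[, , , ch] / nb
    v <- rowSums(bm^2, dims = 4)[, , , 1] / nb - mu^2
    rse[, , , ch] <- ifelse(mu > 0,
                            sqrt(pmax(v, 0) / nb) / mu, NA)
    nhit[, , , ch] <- rowSums(bm > 0, dims = 4)[, , , 1]
  }
  mu_t <- eps_tot / nb
  bt <- tally$eps[, , , 1, , drop = FALSE] + tally$eps[, , , 2, , drop = FALSE]
  v_t <- rowSums(bt^2, dims = 4)[, , , 1] / nb - mu_t^2
  rse[, , , 3] <- ifelse(mu_t > 0, sqrt(pmax(v_t, 0) / nb) / mu_t, NA)
  structure(list(dose = dose, letd = letd, dose_rse = rse, n_batches_hit = nhit,
                 channels = c("S", "US", "S+US"),
                 axes = grid_axes(g), grid = g,
                 tally = tally, plan = plan),
            class = "proton_grids")
}

#' Pool the mirror symmetry of a square field
#'
#' The rectangular-target problem is symmetric under `x -> -x` and
#' `y -> -y` by construction (symmetric spot map, centred aperture).
#' Averaging the raw tallies over the four mirror images leaves every
#' expectation unchanged and halves the statistical error of voxel-level
#' quantities; useful before voxel-wise LET analyses.
#'
#' @param tally A `tally_grid` from [run_field()].
#' @return A `tally_grid` with mirror-pooled sums.
#' @export
symmetrize_tally <- function(tally) {
  stopifnot(inherits(tally, "tally_grid"))
  mirror_mean <- function(a) {
    nx <- dim(a)[1]; ny <- dim(a)[2]
    (a +
     a[nx:1, , , , , drop = FALSE] +
     a[, ny:1, , , , drop = FALSE] +
     a[nx:1, ny:1, , , , drop = FALSE]) / 4
  }
  tally$eps <- mirror_mean(tally$eps)
  tally$epsL <- mirror_mean(tally$epsL)
  tally
}

#' @export
print.proton_grids <- function(x, ...) {
  g <- x$grid
  cat(sprintf("proton dose/LETd grids: %d x %d x %d voxels (%.1f mm), channels %s\n",
              g$nx, g$ny, g$nz, g$voxel_cm * 10,
              paste(x$channels, collapse = "/")))
  invisible(x)
}

# 1-based voxel index containing a coordinate (half-open intervals)
voxel_index <- function(coord, origin, h, n) {
  i <- floor((coord - origin) / h) + 1
  if (any(i < 1 | i > n)) stop("coordinate outside the grid")
  as.integer(i)
}

# indices of voxels whose centres satisfy |c - centre| <= half
voxel_band <- function(axis_centres, centre, half) {
  which(abs(axis_centres - centre) <= half + 1e-9)
}

# region-summed eps / epsL per channel and per batch.
# Returns list(eps = 2 x nbatch, epsl = 2 x nbatch) matrices.
region_batch_sums <- function(tally, ix, iy, iz) {
  nb <- tally$nbatch
  eps <- matrix(0, 2, nb)
  epsl <- matrix(0, 2, nb)
  for (ch in 1:2) {
    for (b in seq_len(nb)) {
      eps[ch, b] <- sum(tally$eps[ix, iy, iz, ch, b])
      epsl[ch, b] <- sum(tally$epsL[ix, iy, iz, ch, b])
    }
  }
  list(eps = eps, epsl = epsl)
}

# mean dose (Gy), letd (keV/um) and batch SE of the dose over a voxel
# region, per channel c(S, US, S+US)
region_stats <- function(grids, ix, iy, iz) {
  tally <- grids$tally
  g <- grids$grid
  rb <- region_batch_sums(tally, ix, iy, iz)
  nvox <- length(ix) * length(iy) * length(iz)
  nb <- tally$nbatch
  scale <- MEV_PER_G_TO_GY / (g$voxel_cm^3) / nvox
  eps3 <- rbind(rb$eps, colSums(rb$eps))
  epsl3 <- rbind(rb$epsl, colSums(rb$epsl))
  dose_b <- eps3 * nb * scale            # per-batch dose estimates
  dose <- rowSums(eps3) * scale
  se <- apply(dose_b, 1, stats::sd) / sqrt(nb)
  letd <- ifelse(rowSums(eps3) > 0, rowSums(epsl3) / rowSums(eps3), NA)
  list(dose = stats::setNames(dose, c("S", "US", "S+US")),
       dose_se = stats::setNames(se, c("S", "US", "S+US")),
       letd = stats::setNames(letd, c("S", "US", "S+US")),
       eps = rowSums(eps3), epsl = rowSums(epsl3))
}

#' Extract an axis profile
#'
#' Dose (and LET) of one channel along one axis, the other two
#' coordinates fixed (optionally averaged over a transverse band).
#'
#' @param grids A [finalize_tallies()] result.
#' @param axis `"x"` or `"z"`.
#' @param channel `"S"`, `"US"` or `"S+US"`.
#' @param at Named list of fixed coordinates in cm, e.g.
#'   `list(y = 0, z = 0.5)`.
#' @param band Half-width in cm of the averaging band applied to the
#'   fixed transverse coordinates.
#' @return `data.frame` with the axis coordinate, `dose` and `letd`.
#' @export
extract_profile <- function(grids, axis = c("x", "z"),
                            channel = "S", at = list(), band = 0) {
  axis <- match.arg(axis)
  ax <- grids$axes
  g <- grids$grid
  ch <- match(channel, grids$channels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  origin <- c(x = g$x0, y = g$y0, z = g$z0)
  sel <- function(name, n) {
    if (is.null(at[[name]])) return(seq_len(n))
    if (band > 0) return(voxel_band(ax[[name]], at[[name]], band))
    voxel_index(at[[name]], origin[[name]], g$voxel_cm, n)
  }
  ix <- sel("x", g$nx); iy <- sel("y", g$ny); iz <- sel("z", g$nz)
  d <- grids$dose[ix, iy, iz, ch, drop = FALSE]
  keep <- switch(axis, x = 1, z = 3)
  prof <- apply(d, keep, mean)
  coord <- switch(axis, x = ax$x[ix], z = ax$z[iz])
  lt <- apply(grids$letd[ix, iy, iz, ch, drop = FALSE], keep,
              function(v) mean(v, na.rm = TRUE))
  data.frame(coord = coord, dose = prof, letd = lt)
}

#' Write / read dose-LET grids as a documented text format
#'
#' A human-readable header (grid shape, voxel size, channels, units)
#' followed by one line per voxel/channel value; intended for archival of
#' small grids and cross-tool exchange.
#'
#' @param grids A `proton_grids` object.
#' @param path Output path.
#' @export
write_grids <- function(grids, path) {
  g <- grids$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pbscatter grid file v1",
               sprintf("# shape %d %d %d channels 3", g$nx, g$ny, g$nz),
               sprintf("# voxel_cm %.6g origin %.6g %.6g %.6g",
                       g$voxel_cm, g$x0, g$y0, g$z0),
               "# units dose=Gy letd=keV/um; order: channel-major, z, y, x",
               "# channels S US S+US"), con)
  vals <- cbind(dose = as.vector(grids$dose),
                letd = as.vector(grids$letd))
  utils::write.table(format(vals, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grids
#' @export
read_grids <- function(path) {
  hdr <- readLines(path, n = 5)
  shape <- as.integer(strsplit(sub("# shape ", "", hdr[2]), " ")[[1]][1:3])
  geom <- as.numeric(strsplit(sub("# voxel_cm ", "", hdr[3]), " ")[[1]][c(1, 3:5)])
  vals <- utils::read.table(path, skip = 5, header = TRUE)
  dims <- c(shape, 3)
  grid <- structure(list(voxel_cm = geom[1], nx = shape[1], ny = shape[2],
                         nz = shape[3], x0 = geom[2], y0 = geom[3],
                         z0 = geom[4]),
                    class = "phantom_grid")
  structure(list(dose = array(as.numeric(vals$dose), dims),
                 letd = array(as.numeric(vals$letd), dims),
                 channels = c("S", "US", "S+US"),
                 axes = grid_axes(grid), grid = grid,
                 tally = NULL, plan = NULL),
            class = "proton_grids")
}
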