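#' Species-resolved charge-density profile along the membrane normal
#'
#' Decomposes the bilayer into parallel layers perpendicular to Oz and
#' averages, over the frames of the analysis window, the partial charge of
#' each named atom group falling in each layer. Every frame is first
#' recentred so the mean z of the lipid phosphorus atoms (or, optionally, of
#' all lipid atoms) is zero. The layer at grid point z collects charges with
#' recentred coordinate in (z - dz, z + dz]; the density is that charge
#' divided by the layer volume `area_xy * 2 dz` (e/nm^3). With the defaults
#' (`step = 0.1`, `dz = 0.05` nm) the layers tile the slab without overlap
#' and each group's integrated density equals its total charge in the slab.
#'
#' @param traj a `memion_trajectory` with partial charges assigned.
#' @param groups named list of atom index vectors (see [select_atoms()]).
#' @param window analysis window (NULL, `c(t0, t1)` ns or `"last <x>ns"`).
#' @param dz layer half-width, nm.
#' @param step grid spacing, nm.
#' @param z_range grid extent: the grid is `seq(-z_range, z_range, step)`.
#' @param center_on `"lipid_p"` (mean LIPID_P z, default) or `"lipid_com"`
#'   (unweighted mean of all DOPC/CHOL atom z) as the membrane centre.
#' @return Object of class `memion_charge_profile`: `z_grid`, `densities`
#'   (matrix, grid x groups, e/nm^3), `area_xy` (mean box cross-section,
#'   nm^2), `dz`, `step`, `window_frames`, and `group_charge` (mean total
#'   charge of each group inside the slab, e).
#' @export
compute_charge_profile <- function(traj, groups, window = NULL,
                                   dz = 0.05, step = 0.1, z_range = 3.5,
                                   center_on = c("lipid_p", "lipid_com")) {
  center_on <- match.arg(center_on)
  stopifnot(dz > 0, step > 0, z_range > 0)
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list of atom index vectors")
  idx <- .resolve_window(traj, window)
  at <- traj$atoms
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0L)
      warning("group '", g, "' selects no atoms; its profile is zero")
  }
  zg <- seq(-z_range, z_range, by = step)
  ng <- length(zg)
  dens <- matrix(0, nrow = ng, ncol = length(groups),
                 dimnames = list(NULL, names(groups)))
  gchg <- stats::setNames(numeric(length(groups)), names(groups))
  area_acc <- 0
  ctr_idx <- if (center_on == "lipid_p") which(at$role == "LIPID_P")
             else which(at$species %in% c("DOPC", "CHOL"))
  if (length(ctr_idx) == 0L)
    stop("no atoms available to define the membrane centre (need LIPID_P roles)")
  tiled <- isTRUE(all.equal(2 * dz, step))
  for (f in idx) {
    fr <- traj$frames[[f]]
    z <- fr$coords[, 3] - mean(fr$coords[ctr_idx, 3])
    area <- fr$box[1] * fr$box[2]
    area_acc <- area_acc + area
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      if (length(rows) == 0L) next
      q <- at$partial_charge[rows]
      zq <- z[rows]
      if (tiled) {
        # layer k covers (zg[k]-dz, zg[k]+dz]; tiling -> one bin per atom
        bin <- ceiling((zq - (zg[1] - dz)) / step)
        keep <- bin >= 1L & bin <= ng
        chg <- numeric(ng)
        if (any(keep)) {
          tb <- tapply(q[keep], bin[keep], sum)
          chg[as.integer(names(tb))] <- tb
        }
      } else {
        chg <- vapply(zg, function(z0) sum(q[zq > z0 - dz & zq <= z0 + dz]),
                      numeric(1))
      }
      dens[, gi] <- dens[, gi] + chg / (area * 2 * dz)
      gchg[gi] <- gchg[gi] + if (tiled) sum(chg) else
        sum(q[zq > zg[1] - dz & zq <= zg[ng] + dz])
    }
  }
  nf <- length(idx)
  structure(list(z_grid = zg, densities = dens / nf,
                 area_xy = area_acc / nf, dz = dz, step = step,
                 window_frames = idx, n_frames = nf,
                 group_charge = gchg / nf, center_on = center_on),
            class = "memion_charge_profile")
}

#' @export
print.memion_charge_profile <- function(x, ...) {
  cat("Charge-density profile: z in [", min(x$z_grid), ", ", max(x$z_grid),
      "] nm, step ", x$step, " nm, dz ", x$dz, " nm, ", x$n_frames,
      " frame(s)\n", sep = "")
  cat("Groups:", paste(colnames(x$densities), collapse = ", "), "\n")
  cat("Mean slab charge per group (e):",
      paste(sprintf("%s=%.3g", names(x$group_charge), x$group_charge),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.memion_charge_profile <- function(x, ...) {
  graphics::matplot(x$z_grid, x$densities, type = "l", lty = 1,
                    xlab = "z (nm)", ylab = "charge density (e/nm^3)", ...)
  graphics::legend("topright", legend = colnames(x$densities),
                   col = seq_len(ncol(x$densities)), lty = 1, bty = "n")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Extract charge-density peaks for one group
#'
#' Scans the group's profile for local extrema (strict rise on one side,
#' non-strict on the other, so plateau edges count once) whose magnitude
#' exceeds a noise floor, by default 3x the median absolute density over the
#' outermost 1 nm at both ends of the grid. Peaks are returned sorted by
#' decreasing magnitude.
#'
#' @param profile a `memion_charge_profile`.
#' @param group group name present in the profile.
#' @param noise_floor override the automatic floor (e/nm^3).
#' @return Object of class `memion_peaks`: data.frame (`z_nm`, `sign`,
#'   `amplitude`) plus the floor used. Empty for an all-zero profile.
#' @export
find_extrema <- function(profile, group, noise_floor = NULL) {
  stopifnot(inherits(profile, "memion_charge_profile"))
  if (!group %in% colnames(profile$densities))
    stop("group '", group, "' not present in profile (has: ",
         paste(colnames(profile$densities), collapse = ", "), ")")
  d <- profile$densities[, group]
  z <- profile$z_grid
  if (is.null(noise_floor)) {
    edge <- abs(z) >= max(abs(z)) - 1
    noise_floor <- 3 * stats::median(abs(d[edge]))
  }
  n <- length(d)
  is_max <- is_min <- rep(FALSE, n)
  if (n >= 3L) {
    i <- 2:(n - 1)
    is_max[i] <- d[i] > d[i - 1] & d[i] >= d[i + 1]
    is_min[i] <- d[i] < d[i - 1] & d[i] <= d[i + 1]
  }
  keep <- (is_max | is_min) & abs(d) > noise_floor
  pk <- data.frame(z_nm = z[keep],
                   sign = ifelse(d[keep] > 0, "+", "-"),
                   amplitude = d[keep],
                   stringsAsFactors = FALSE)
  pk <- pk[order(-abs(pk$amplitude)), , drop = FALSE]
  rownames(pk) <- NULL
  structure(list(peaks = pk, group = group, noise_floor = noise_floor),
            class = "memion_peaks")
}

#' @export
print.memion_peaks <- function(x, ...) {
  cat("Peaks for group '", x$group, "' (noise floor ",
      signif(x$noise_floor, 3), " e/nm^3):\n", sep = "")
  if (nrow(x$peaks) == 0L) cat("  none\n") else print(x$peaks, ...)
  invisible(x)
}

#' Separation of the dominant symmetric peak pair
#'
#' Distance (nm) between the largest-magnitude extremum of the given sign at
#' z < 0 and at z > 0; with the lipid-phosphorus group and sign `"-"` this is
#' the phosphate peak-to-peak separation used as a bilayer-thickness proxy.
#'
#' @param peaks a `memion_peaks` object.
#' @param sign `"-"` (default) or `"+"`.
#' @return Numeric separation in nm, or NA if either side lacks such a peak.
#' @export
peak_separation <- function(peaks, sign = "-") {
  pk <- peaks$peaks[peaks$peaks$sign == sign, , drop = FALSE]
  lo <- pk$z_nm[pk$z_nm < 0]
  hi <- pk$z_nm[pk$z_nm > 0]
  if (!length(lo) || !length(hi)) return(NA_real_)
  hi[1] - lo[1]  # rows already sorted by |amplitude|
}
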