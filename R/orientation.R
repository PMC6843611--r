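#' Per-frame membrane geometry: midplane and leaflet assignment
#'
#' The membrane centre is the mean z of all lipid phosphorus (`LIPID_P`)
#' atoms in the frame. Each molecule is assigned to the UPPER leaflet if its
#' reference atom (the first of `N_PLUS`, `SULFATE_S`, `CHOL_O`, `LIPID_P`
#' present) lies above the centre, else LOWER.
#'
#' @param traj a `memion_trajectory` with roles assigned.
#' @param frame frame index (1-based).
#' @return list with `center_z` (nm) and `leaflet`, a data.frame
#'   (`molecule_id`, `species`, `leaflet`).
#' @export
membrane_frame_geometry <- function(traj, frame = 1L) {
  at <- traj$atoms
  co <- traj$frames[[frame]]$coords
  ip <- which(at$role == "LIPID_P")
  if (length(ip) < 2L)
    stop("need at least 2 LIPID_P atoms to define the membrane centre ",
         "(found ", length(ip), "); assign roles first")
  center_z <- mean(co[ip, 3])
  ref <- .reference_atom_rows(at)
  leaflet <- ifelse(co[ref$row, 3] > center_z, "UPPER", "LOWER")
  list(center_z = center_z,
       leaflet = data.frame(molecule_id = ref$molecule_id,
                            species = ref$species,
                            leaflet = leaflet,
                            stringsAsFactors = FALSE))
}

# one reference-atom row per molecule, by role priority
.reference_atom_rows <- function(at) {
  pri <- c("N_PLUS", "SULFATE_S", "CHOL_O", "LIPID_P")
  cand <- at$role %in% pri
  rows <- which(cand)
  ord <- order(at$molecule_id[rows], match(at$role[rows], pri))
  rows <- rows[ord]
  keep <- !duplicated(at$molecule_id[rows])
  rows <- rows[keep]
  list(row = rows, molecule_id = at$molecule_id[rows], species = at$species[rows])
}

#' Surfactant orientation angles eta and theta
#'
#' For every surfactant molecule (KOR105, BAC, SDS) in every frame of the
#' window, builds the head vector `h` from the quaternary nitrogen to the
#' para-ring carbon and the tail vector `t` from the charged anchor (N+ for
#' the cationic ions, S for SDS) to the terminal tail carbon, unwrapping each
#' partner atom by minimum image relative to the anchor. Angles are measured
#' against the *outward* unit normal of the molecule's leaflet (+Oz for the
#' upper leaflet, -Oz for the lower): `eta = angle(n, h)` (absent for SDS,
#' which has no ring) and `theta = angle(n, t)`, both in degrees in
#' \[0, 180\]. Molecules with coincident anchor atoms in a frame are skipped
#' with a warning.
#'
#' @param traj a `memion_trajectory` with roles assigned.
#' @param window analysis window: NULL (all frames), `c(t0, t1)` in ns, or
#'   `"last <x>ns"`.
#' @return data.frame with columns `time_ns`, `molecule_id`, `species`,
#'   `leaflet`, `eta_deg`, `theta_deg`.
#' @export
compute_orientation_angles <- function(traj, window = NULL) {
  at <- traj$atoms
  idx <- .resolve_window(traj, window)
  surf <- at$species %in% c("KOR105", "BAC", "SDS")
  mols <- unique(at$molecule_id[surf])
  if (length(mols) == 0L)
    stop("no surfactant molecules (KOR105/BAC/SDS) in the trajectory")

  # per-molecule anchor rows (vectorised across molecules)
  row_of <- function(role, mids) {
    r <- match(paste(mids, role), paste(at$molecule_id, at$role))
    r
  }
  anchor <- row_of("N_PLUS", mols)
  sulf <- row_of("SULFATE_S", mols)
  anchor[is.na(anchor)] <- sulf[is.na(anchor)]
  para <- row_of("PARA_C", mols)
  term <- row_of("TERM_C", mols)
  if (any(is.na(anchor)) || any(is.na(term)))
    stop("surfactant molecules lack anchor roles; run assign_roles() first")
  species <- at$species[anchor]

  out <- vector("list", length(idx))
  nskip <- 0L
  for (k in seq_along(idx)) {
    f <- idx[k]
    fr <- traj$frames[[f]]
    co <- fr$coords
    geo <- membrane_frame_geometry(traj, f)
    leaf <- geo$leaflet$leaflet[match(mols, geo$leaflet$molecule_id)]
    nz <- ifelse(leaf == "UPPER", 1, -1)  # outward normal z-component

    a <- co[anchor, , drop = FALSE]
    tvec <- .min_image_rel(co[term, , drop = FALSE], a, fr$box)
    theta <- .angle_signed_axis(tvec, nz)
    eta <- rep(NA_real_, length(mols))
    hasring <- !is.na(para)
    if (any(hasring)) {
      hvec <- .min_image_rel(co[para[hasring], , drop = FALSE],
                             a[hasring, , drop = FALSE], fr$box)
      eta[hasring] <- .angle_signed_axis(hvec, nz[hasring])
    }
    bad <- is.na(theta) | (hasring & is.na(eta))
    nskip <- nskip + sum(bad)
    out[[k]] <- data.frame(time_ns = fr$time, molecule_id = mols,
                           species = species, leaflet = leaf,
                           eta_deg = eta, theta_deg = theta,
                           stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  }
  if (nskip > 0L)
    warning(nskip, " molecule-frame record(s) skipped: zero-length anchor vector")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# minimum-image displacement of points b relative to anchors a (rowwise)
.min_image_rel <- function(b, a, box) {
  d <- b - a
  d - sweep(d, 2L, box, function(x, L) L * round(x / L))
}

# angle (deg) between row vectors v and the axis (0, 0, nz) with nz = +/-1
.angle_signed_axis <- function(v, nz) {
  nv <- sqrt(rowSums(v^2))
  ct <- (v[, 3] * nz) / nv
  ct <- pmin(1, pmax(-1, ct))
  deg <- acos(ct) * 180 / pi
  deg[nv == 0] <- NA_real_
  deg
}

#' Angle distribution density
#'
#' Normalised histogram density of an orientation angle on \[0, 180\] degrees,
#' the per-degree probability density whose integral over the support is 1.
#'
#' @param records data.frame from [compute_orientation_angles()].
#' @param angle_name `"eta"` or `"theta"`.
#' @param bin_width_deg bin width in degrees (default 2, resolving ~20-degree
#'   features without histogram noise).
#' @return An object of class `memion_angle_density` with `bin_centers`,
#'   `density` (per degree), `angle_name`, `n_samples` and `mode_deg` (bin
#'   centre of maximal density).
#' @export
angle_density <- function(records, angle_name = c("eta", "theta"),
                          bin_width_deg = 2) {
  angle_name <- match.arg(angle_name)
  col <- paste0(angle_name, "_deg")
  x <- records[[col]]
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    stop("no finite ", angle_name, " angles in the supplied records")
  stopifnot(bin_width_deg > 0, 180 %% bin_width_deg == 0)
  breaks <- seq(0, 180, by = bin_width_deg)
  # angles exactly 0 fall in the first bin
  cnt <- tabulate(pmin(pmax(ceiling(x / bin_width_deg), 1L),
                       length(breaks) - 1L), nbins = length(breaks) - 1L)
  dens <- cnt / (length(x) * bin_width_deg)
  centers <- breaks[-length(breaks)] + bin_width_deg / 2
  structure(list(bin_centers = centers, density = dens,
                 angle_name = toupper(angle_name), n_samples = length(x),
                 bin_width_deg = bin_width_deg,
                 mode_deg = centers[which.max(dens)]),
            class = "memion_angle_density")
}

#' @export
print.memion_angle_density <- function(x, ...) {
  cat("Angle density (", x$angle_name, "): ", x$n_samples, " samples, bin ",
      x$bin_width_deg, " deg, mode at ", x$mode_deg, " deg\n", sep = "")
  invisible(x)
}

#' @export
plot.memion_angle_density <- function(x, ...) {
  graphics::plot(x$bin_centers, x$density, type = "l",
                 xlab = sprintf("%s (degrees)", x$angle_name),
                 ylab = "density (1/degree)", ...)
  graphics::abline(v = x$mode_deg, lty = 3)
  invisible(x)
}
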