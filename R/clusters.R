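#' Cholesterol cluster sizes in one frame
#'
#' Builds a graph on cholesterol hydroxyl oxygens (`CHOL_O`) with an edge
#' wherever the minimum-image O-O distance is below the cutoff (0.7 nm, the
#' criterion used for sterol clustering in bilayer simulations) and returns
#' the connected-component sizes, singletons included.
#'
#' @param traj a `memion_trajectory` with `CHOL_O` roles assigned.
#' @param frame frame index.
#' @param cutoff nm; must be below half the smallest box edge.
#' @param leaflet optional `"UPPER"`/`"LOWER"` to cluster one leaflet only.
#' @return Integer vector of cluster sizes (empty if no cholesterol).
#' @export
cluster_sizes_frame <- function(traj, frame = 1L, cutoff = 0.7, leaflet = NULL) {
  at <- traj$atoms
  fr <- traj$frames[[frame]]
  if (cutoff >= min(fr$box) / 2)
    stop("cutoff (", cutoff, " nm) must be < half the smallest box edge (",
         min(fr$box) / 2, " nm) for the minimum-image convention")
  rows <- which(at$role == "CHOL_O")
  if (!is.null(leaflet)) {
    geo <- membrane_frame_geometry(traj, frame)
    lf <- geo$leaflet$leaflet[match(at$molecule_id[rows], geo$leaflet$molecule_id)]
    rows <- rows[lf == leaflet]
  }
  n <- length(rows)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  co <- fr$coords[rows, , drop = FALSE]
  adj <- .pbc_adjacency(co, fr$box, cutoff)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  unname(igraph::components(g)$csize)
}

# symmetric logical adjacency under 3D minimum image
.pbc_adjacency <- function(co, box, cutoff) {
  n <- nrow(co)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(co[, k], co[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  adj <- d2 < cutoff^2
  diag(adj) <- FALSE
  adj
}

#' Cholesterol cluster-size distribution over a window
#'
#' Mean number of clusters of each size per frame, computed frame by frame
#' over the analysis window. Per frame, sizes times counts always sum to the
#' number of cholesterol molecules. Size-1 "clusters" (isolated molecules)
#' are tabulated too; `summary()` reports the distribution with and without
#' them.
#'
#' @inheritParams cluster_sizes_frame
#' @param traj a `memion_trajectory`.
#' @param window analysis window (NULL, `c(t0, t1)` ns or `"last <x>ns"`).
#' @param per_leaflet cluster each leaflet separately and pool the sizes.
#' @return Object of class `memion_cluster_dist`: data.frame (`size`,
#'   `mean_count`), `cutoff`, `n_chol`, `n_frames`.
#' @export
cluster_size_distribution <- function(traj, window = NULL, cutoff = 0.7,
                                      per_leaflet = FALSE) {
  idx <- .resolve_window(traj, window)
  n_chol <- length(unique(traj$atoms$molecule_id[traj$atoms$role == "CHOL_O"]))
  tab <- integer(max(1L, n_chol))
  for (f in idx) {
    sizes <- if (per_leaflet)
      c(cluster_sizes_frame(traj, f, cutoff, "UPPER"),
        cluster_sizes_frame(traj, f, cutoff, "LOWER"))
    else cluster_sizes_frame(traj, f, cutoff)
    if (length(sizes))
      tab <- tab + tabulate(sizes, nbins = length(tab))
  }
  mean_count <- tab / length(idx)
  keep <- mean_count > 0
  structure(list(distribution = data.frame(size = which(keep),
                                           mean_count = mean_count[keep]),
                 cutoff = cutoff, n_chol = n_chol, n_frames = length(idx),
                 per_leaflet = per_leaflet),
            class = "memion_cluster_dist")
}

#' @export
print.memion_cluster_dist <- function(x, ...) {
  cat("Cholesterol cluster-size distribution (cutoff ", x$cutoff, " nm, ",
      x$n_chol, " molecules, ", x$n_frames, " frame(s)",
      if (x$per_leaflet) ", per leaflet" else "", "):\n", sep = "")
  print(x$distribution, row.names = FALSE)
  d <- x$distribution
  multi <- d[d$size > 1L, , drop = FALSE]
  cat("Mean clusters/frame incl. singletons: ", sum(d$mean_count),
      "; size >= 2 only: ", sum(multi$mean_count), "\n", sep = "")
  invisible(x)
}

#' Detect cholesterol plunge (midplane-excursion) events
#'
#' Follows each cholesterol oxygen's distance from the per-frame membrane
#' centre. An event opens when |z - center| drops below `band_halfwidth`
#' and closes when it leaves the band; events whose dwell (time between the
#' first and last frame inside the band) is below `min_dwell` are dropped.
#' `reached_interface` records whether the oxygen came within half the band
#' width of the centre; `returned_to_same_leaflet` compares the leaflet just
#' before entry with the leaflet just after exit (NA if the event is still
#' open at the last frame, or opens at the first).
#'
#' @param traj a `memion_trajectory` with `CHOL_O` roles assigned.
#' @param band_halfwidth nm (default 0.3).
#' @param min_dwell ns (default 1).
#' @return data.frame with one row per event: `molecule_id`, `t_start`,
#'   `dwell`, `returned_to_same_leaflet`, `reached_interface`, `closed`.
#' @export
detect_plunges <- function(traj, band_halfwidth = 0.3, min_dwell = 1.0) {
  at <- traj$atoms
  rows <- which(at$role == "CHOL_O")
  times <- vapply(traj$frames, `[[`, numeric(1), "time")
  nf <- length(times)
  empty <- data.frame(molecule_id = integer(0), t_start = numeric(0),
                      dwell = numeric(0), returned_to_same_leaflet = logical(0),
                      reached_interface = logical(0), closed = logical(0))
  if (length(rows) == 0L || nf == 0L) return(empty)
  # z offset of every CHOL_O from the membrane centre, frames x molecules
  zrel <- matrix(NA_real_, nrow = nf, ncol = length(rows))
  ip <- which(at$role == "LIPID_P")
  if (length(ip) < 2L)
    stop("need LIPID_P atoms to define the membrane centre for plunge detection")
  for (f in seq_len(nf)) {
    co <- traj$frames[[f]]$coords
    zrel[f, ] <- co[rows, 3] - mean(co[ip, 3])
  }
  events <- list()
  for (j in seq_along(rows)) {
    inside <- abs(zrel[, j]) < band_halfwidth
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      f0 <- starts[k]; f1 <- ends[k]
      dwell <- times[f1] - times[f0]
      if (dwell < min_dwell) next
      closed <- f1 < nf
      ret <- NA
      if (closed && f0 > 1L) {
        ret <- sign(zrel[f0 - 1L, j]) == sign(zrel[f1 + 1L, j])
      }
      events[[length(events) + 1L]] <- data.frame(
        molecule_id = at$molecule_id[rows[j]],
        t_start = times[f0], dwell = dwell,
        returned_to_same_leaflet = ret,
        reached_interface = min(abs(zrel[f0:f1, j])) < band_halfwidth / 2,
        closed = closed)
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}
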