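# Internal helpers shared across modules: unit constants, periodic-image
# arithmetic, and analysis-window resolution.

# Physical constants (SI). Package units are nm, ns, degrees, elementary
# charge and mV throughout the user-facing API.
.const <- list(
  R    = 8.314462618,     # J/(mol K)
  F    = 96485.33212,     # C/mol
  e    = 1.602176634e-19, # C
  eps0 = 8.8541878128e-12 # F/m
)

#' @keywords internal
#' @noRd
min_image <- function(d, box) {
  # wrap displacement components into (-box/2, box/2]
  d - box * round(d / box)
}

# Minimum-image displacement vectors between rows of a and a single point b
# (matrix - vector), orthorhombic box of edge lengths `box` (length 3).
.min_image_mat <- function(a, b, box) {
  d <- sweep(a, 2L, b)
  d - sweep(d, 2L, box, function(x, L) L * round(x / L))
}

# Resolve a window specification against a trajectory's frame times.
# `window` may be NULL (all frames), a numeric c(t0, t1) interval in ns,
# or the string "last <x>ns" / "last <x> ns".
.resolve_window <- function(traj, window) {
  times <- vapply(traj$frames, `[[`, numeric(1), "time")
  if (is.null(window)) return(seq_along(times))
  if (is.character(window)) {
    stopifnot(length(window) == 1L)
    m <- regmatches(window, regexec("^\\s*last\\s*([0-9.]+)\\s*ns\\s*$", window,
                                    ignore.case = TRUE))[[1]]
    if (length(m) != 2L)
      stop("unparseable window specification: '", window,
           "' (expected \"last <x>ns\" or a numeric interval)", call. = FALSE)
    span <- as.numeric(m[2])
    window <- c(max(times) - span, max(times))
  }
  if (!is.numeric(window) || length(window) != 2L || window[1] > window[2])
    stop("window must be NULL, \"last <x>ns\", or c(t0, t1) with t0 <= t1",
         call. = FALSE)
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L)
    stop("analysis window [", window[1], ", ", window[2],
         "] ns contains no frames (trajectory spans [",
         min(times), ", ", max(times), "] ns)", call. = FALSE)
  idx
}

# angle in degrees between vector(s) v (matrix, rows) and unit axis n (length 3)
.angle_deg <- function(v, n) {
  nv <- sqrt(rowSums(v^2))
  ct <- as.vector(v %*% n) / nv
  ct <- pmin(1, pmax(-1, ct))
  deg <- acos(ct) * 180 / pi
  deg[nv == 0] <- NA_real_
  deg
}

.species_levels <- c("DOPC", "CHOL", "KOR105", "BAC", "SDS", "WATER", "ION", "OTHER")
.role_levels <- c("N_PLUS", "PARA_C", "TERM_C", "SULFATE_S", "LIPID_P",
                  "LIPID_N", "CHOL_O", "NONE")

# residue-name -> species normalisation used by the readers
.species_from_resname <- function(resname) {
  x <- toupper(trimws(resname))
  out <- rep("OTHER", length(x))
  out[x %in% c("DOPC")] <- "DOPC"
  out[x %in% c("CHOL", "CHL1", "CLOL")] <- "CHOL"
  out[x %in% c("KOR", "KOR1", "K105", "KOR105")] <- "KOR105"
  out[x %in% c("BAC", "BACL")] <- "BAC"
  out[x %in% c("SDS")] <- "SDS"
  out[x %in% c("SOL", "WAT", "TIP3", "HOH", "SPC", "WATER")] <- "WATER"
  out[x %in% c("K", "CL", "NA", "POT", "CLA", "SOD", "ION", "KCL")] <- "ION"
  out
}
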