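# Synthetic membrane systems with known ground truth. The generator emulates
# the statistical structure of a flat bilayer simulation -- headgroup planes,
# embedded surfactant ions with prescribed orientation-angle distributions,
# clustered cholesterol -- without any force field or dynamics: frames differ
# only by i.i.d. Gaussian positional jitter (thermal roughness stand-in).

#' Specification of a synthetic membrane system
#'
#' @param n_lipids_per_leaflet lipids per leaflet (each contributes a
#'   phosphorus and a nitrogen pseudo-atom).
#' @param leaflet_z half-thickness of the phosphorus plane, nm (1.8 for a
#'   fluid PC bilayer, 2.2 for the thicker cholesterol-rich state).
#' @param roughness_sigma per-frame Gaussian positional jitter SD, nm.
#' @param area_per_lipid nm^2; sets the lateral lattice and box size.
#' @param surfactants named list (names KOR105/BAC/SDS), each
#'   `list(count, eta0_deg, theta0_deg, kappa, nplus_depth_z)`; `eta0_deg`
#'   of NA (SDS) means no aromatic ring / no PARA_C atom. Molecules are
#'   split evenly between the leaflets.
#' @param cholesterol `list(count, thomas_parent_rate, offspring_sigma)`:
#'   a Thomas clustered point process per leaflet (parents Poisson with
#'   intensity `thomas_parent_rate` per nm^2, each molecule attached to a
#'   uniformly chosen parent with isotropic Gaussian displacement
#'   `offspring_sigma` nm).
#' @param charges named vector role -> partial charge (e).
#' @param n_frames,frame_dt number of frames and frame spacing (ns).
#' @param seed integer; fixes every downstream draw.
#' @return list of class `memion_synthetic_spec`.
#' @export
synthetic_spec <- function(n_lipids_per_leaflet = 101,
                           leaflet_z = 1.8,
                           roughness_sigma = 0.05,
                           area_per_lipid = 0.65,
                           surfactants = list(),
                           cholesterol = list(count = 0,
                                              thomas_parent_rate = 0.05,
                                              offspring_sigma = 0.3),
                           charges = c(N_PLUS = 1, SULFATE_S = -1,
                                       LIPID_P = -1, LIPID_N = 1,
                                       PARA_C = 0, TERM_C = 0, CHOL_O = 0),
                           n_frames = 100,
                           frame_dt = 1,
                           seed = 1L) {
  stopifnot(n_lipids_per_leaflet >= 2, leaflet_z > 0, roughness_sigma >= 0,
            area_per_lipid > 0, n_frames >= 1, frame_dt > 0)
  for (sp in names(surfactants)) {
    s <- surfactants[[sp]]
    stopifnot(s$count >= 0, s$kappa >= 0, s$nplus_depth_z > 0)
  }
  stopifnot(cholesterol$count >= 0)
  structure(list(n_lipids_per_leaflet = n_lipids_per_leaflet,
                 leaflet_z = leaflet_z, roughness_sigma = roughness_sigma,
                 area_per_lipid = area_per_lipid, surfactants = surfactants,
                 cholesterol = cholesterol, charges = charges,
                 n_frames = n_frames, frame_dt = frame_dt,
                 seed = as.integer(seed)),
            class = "memion_synthetic_spec")
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope), radians.
# kappa = 0 degenerates to the uniform circle.
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
    }
  }
  out
}

# polar angle in [0, 180] deg from a von Mises draw about mean0 (deg):
# a direction's angle to an axis is defined up to reflection, so fold.
.rangle_deg <- function(n, mean0, kappa) {
  x <- .rvonmises(n, mean0 * pi / 180, kappa) * 180 / pi
  x <- abs(x %% 360)
  x[x > 180] <- 360 - x[x > 180]
  x
}

# unit direction at polar angle a_deg (from the outward normal, z-sign nz)
# and azimuth phi
.dir_from_angles <- function(a_deg, phi, nz) {
  a <- a_deg * pi / 180
  cbind(sin(a) * cos(phi), sin(a) * sin(phi), nz * cos(a))
}

#' Generate a synthetic membrane trajectory with ground truth
#'
#' Lipids sit on a jittered square lattice at z = +/- `leaflet_z` (P atoms,
#' charge -1 e by default) with N atoms 0.1 nm further out (+1 e).
#' Surfactant anchor triplets (N+ or S, para-ring C, terminal tail C) are
#' placed so the realized eta and theta are independent folded von Mises
#' draws about the prescribed modes, respecting each leaflet's outward
#' normal; cholesterol oxygens follow a Thomas clustered point process in
#' each leaflet. Frames add i.i.d. Gaussian jitter (`roughness_sigma`) to
#' every coordinate.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `trajectory` (a `memion_trajectory`, roles and charges
#'   already assigned), `manifest` (ground truth: spec, box, per-molecule
#'   placements and realized angle draws, cholesterol parent assignments)
#'   and `role_map` (nested list suitable for [assign_roles()] after a GRO
#'   round trip).
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "memion_synthetic_spec"))
  set.seed(spec$seed)
  s <- sqrt(spec$area_per_lipid)
  nx <- ceiling(sqrt(spec$n_lipids_per_leaflet))
  L <- nx * s
  box <- c(L, L, 2 * spec$leaflet_z + 4)

  atoms <- list(); base <- list(); mol_tab <- list()
  mol_id <- 0L; atom_id <- 0L
  add_atom <- function(species, name, role, xyz) {
    atom_id <<- atom_id + 1L
    atoms[[atom_id]] <<- data.frame(
      atom_id = atom_id, molecule_id = mol_id, species = species,
      atom_name = name, role = role,
      partial_charge = unname(spec$charges[role] %||% 0),
      stringsAsFactors = FALSE)
    base[[atom_id]] <<- xyz
  }

  # --- lipids on a jittered lattice, both leaflets
  lat <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(nx) - 0.5) * s
  if (spec$n_lipids_per_leaflet > nrow(lat))
    stop("packing failure: ", spec$n_lipids_per_leaflet,
         " lipids requested but the lattice holds ", nrow(lat))
  for (lz in c(1, -1)) {
    pick <- lat[sample.int(nrow(lat), spec$n_lipids_per_leaflet), ]
    jit <- matrix(stats::runif(2 * spec$n_lipids_per_leaflet, -0.15, 0.15) * s,
                  ncol = 2)
    for (i in seq_len(spec$n_lipids_per_leaflet)) {
      mol_id <- mol_id + 1L
      xy <- as.numeric(pick[i, ]) + jit[i, ]
      add_atom("DOPC", "P", "LIPID_P", c(xy, lz * spec$leaflet_z))
      add_atom("DOPC", "N", "LIPID_N", c(xy + 0.05, lz * (spec$leaflet_z + 0.1)))
      mol_tab[[mol_id]] <- data.frame(
        molecule_id = mol_id, species = "DOPC",
        leaflet = if (lz > 0) "UPPER" else "LOWER",
        x = xy[1], y = xy[2], z = lz * spec$leaflet_z,
        eta_deg = NA_real_, theta_deg = NA_real_, parent = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }

  # --- surfactants: anchor + geometric realisation of the drawn angles
  Lh <- 0.45; Lt <- 1.2  # nm: head (N+ -> para C) and tail vector lengths
  for (sp in names(spec$surfactants)) {
    cfg <- spec$surfactants[[sp]]
    if (cfg$count == 0) next
    n_up <- ceiling(cfg$count / 2)
    leafs <- rep(c(1, -1), c(n_up, cfg$count - n_up))
    has_ring <- !is.null(cfg$eta0_deg) && is.finite(cfg$eta0_deg)
    eta <- if (has_ring) .rangle_deg(cfg$count, cfg$eta0_deg, cfg$kappa)
           else rep(NA_real_, cfg$count)
    theta <- .rangle_deg(cfg$count, cfg$theta0_deg, cfg$kappa)
    phi1 <- stats::runif(cfg$count, 0, 2 * pi)
    phi2 <- stats::runif(cfg$count, 0, 2 * pi)
    xy <- cbind(stats::runif(cfg$count, 0, L), stats::runif(cfg$count, 0, L))
    anchor_role <- if (sp == "SDS") "SULFATE_S" else "N_PLUS"
    anchor_name <- if (sp == "SDS") "S1" else "N1"
    for (i in seq_len(cfg$count)) {
      mol_id <- mol_id + 1L
      nz <- leafs[i]
      anc <- c(xy[i, ], nz * cfg$nplus_depth_z)
      add_atom(sp, anchor_name, anchor_role, anc)
      if (has_ring)
        add_atom(sp, "CP", "PARA_C",
                 anc + Lh * .dir_from_angles(eta[i], phi1[i], nz)[1, ])
      add_atom(sp, "CT", "TERM_C",
               anc + Lt * .dir_from_angles(theta[i], phi2[i], nz)[1, ])
      mol_tab[[mol_id]] <- data.frame(
        molecule_id = mol_id, species = sp,
        leaflet = if (nz > 0) "UPPER" else "LOWER",
        x = anc[1], y = anc[2], z = anc[3],
        eta_deg = eta[i], theta_deg = theta[i], parent = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }

  # --- cholesterol: Thomas process per leaflet
  ch <- spec$cholesterol
  if (ch$count > 0) {
    n_up <- ceiling(ch$count / 2)
    for (lz in c(1, -1)) {
      n_here <- if (lz > 0) n_up else ch$count - n_up
      if (n_here == 0) next
      n_par <- max(1L, stats::rpois(1, ch$thomas_parent_rate * L * L))
      parents <- cbind(stats::runif(n_par, 0, L), stats::runif(n_par, 0, L))
      pa <- sample.int(n_par, n_here, replace = TRUE)
      off <- matrix(stats::rnorm(2 * n_here, 0, ch$offspring_sigma), ncol = 2)
      pos <- (parents[pa, , drop = FALSE] + off) %% L
      for (i in seq_len(n_here)) {
        mol_id <- mol_id + 1L
        zo <- lz * (spec$leaflet_z - 0.4)  # hydroxyl below the P plane
        add_atom("CHOL", "O3", "CHOL_O", c(pos[i, ], zo))
        mol_tab[[mol_id]] <- data.frame(
          molecule_id = mol_id, species = "CHOL",
          leaflet = if (lz > 0) "UPPER" else "LOWER",
          x = pos[i, 1], y = pos[i, 2], z = zo,
          eta_deg = NA_real_, theta_deg = NA_real_, parent = pa[i],
          stringsAsFactors = FALSE)
      }
    }
  }

  atoms_df <- do.call(rbind, atoms)
  base_m <- do.call(rbind, base)
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    jit <- matrix(stats::rnorm(length(base_m), 0, spec$roughness_sigma),
                  ncol = 3)
    frames[[f]] <- list(time = (f - 1) * spec$frame_dt, box = box,
                        coords = base_m + jit)
  }
  traj <- memion_trajectory(atoms_df, frames)

  role_map <- list()
  for (sp in unique(atoms_df$species)) {
    sub <- unique(atoms_df[atoms_df$species == sp & atoms_df$role != "NONE",
                           c("atom_name", "role", "partial_charge")])
    role_map[[sp]] <- stats::setNames(
      lapply(seq_len(nrow(sub)), function(i)
        list(role = sub$role[i], charge = sub$partial_charge[i])),
      sub$atom_name)
  }
  manifest <- structure(list(spec = spec, box = box,
                             molecules = do.call(rbind, mol_tab)),
                        class = "memion_manifest")
  list(trajectory = traj, manifest = manifest, role_map = role_map)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.memion_manifest <- function(x, ...) {
  cat("Synthetic-system manifest: box ",
      paste(signif(x$box, 4), collapse = " x "), " nm, ",
      nrow(x$molecules), " molecules, seed ", x$spec$seed, "\n", sep = "")
  print(table(x$molecules$species, x$molecules$leaflet))
  invisible(x)
}

#' Write a generated system to disk
#'
#' Emits a multi-frame GRO trajectory, the ground-truth manifest as JSON and
#' the matching role map as YAML, so the written system can be re-read with
#' [read_trajectory()] + [assign_roles()].
#'
#' @param system result of [generate_system()].
#' @param prefix output path prefix; writes `<prefix>.gro`,
#'   `<prefix>_manifest.json`, `<prefix>_roles.yaml`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_system <- function(system, prefix) {
  paths <- c(gro = paste0(prefix, ".gro"),
             manifest = paste0(prefix, "_manifest.json"),
             roles = paste0(prefix, "_roles.yaml"))
  write_gro(system$trajectory, paths["gro"])
  man <- system$manifest
  jsonlite::write_json(
    list(spec = unclass(man$spec), box = man$box, molecules = man$molecules),
    paths["manifest"], auto_unbox = TRUE, digits = NA, na = "null")
  yaml::write_yaml(system$role_map, paths["roles"])
  invisible(paths)
}

#' Generate synthetic boundary-potential measurements with IFC scans
#'
#' Produces a measured-looking concentration series: the adsorption-model
#' curve plus additive Gaussian noise, and one electrostriction capacitance
#' scan per concentration whose parabola vertex sits at that (noisy)
#' boundary potential.
#'
#' @param params an [adsorption_params()] object (ground truth).
#' @param cond an [electrolyte_conditions()] object.
#' @param conc_uM bulk concentrations, micromolar.
#' @param noise_sd additive noise on the potentials, mV.
#' @param ifc list: `C0` (a.u.), `alpha` (1/mV^2), `voltages` (scan offsets
#'   around the vertex, mV), `noise` (multiplicative capacitance noise SD).
#' @param seed integer seed.
#' @return list: `curve` (`memion_bp_curve`, method `"IFC"`), `scans`
#'   (list of `memion_ifc_scan`), `true_curve` (noise-free model curve).
#' @export
generate_measurements <- function(params, cond = electrolyte_conditions(),
                                  conc_uM,
                                  noise_sd = 2,
                                  ifc = list(C0 = 1, alpha = 2e-5,
                                             voltages = seq(-100, 100, by = 2),
                                             noise = 0.01),
                                  seed = 1L) {
  stopifnot(noise_sd >= 0, ifc$C0 > 0, ifc$alpha > 0, ifc$noise >= 0)
  set.seed(as.integer(seed))
  true_curve <- adsorption_curve(params, cond, conc_uM)
  dphi <- true_curve$dphi_mV + stats::rnorm(length(conc_uM), 0, noise_sd)
  scans <- lapply(dphi, function(v) {
    U <- v + ifc$voltages
    C <- ifc$C0 * (1 + ifc$alpha * (U - v)^2) *
      (1 + stats::rnorm(length(U), 0, ifc$noise))
    ifc_scan(U, abs(C))
  })
  list(curve = boundary_potential_curve(conc_uM, dphi, method = "IFC"),
       scans = scans, true_curve = true_curve)
}
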