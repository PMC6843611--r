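#' Membrane trajectory container
#'
#' A `memion_trajectory` bundles a topology (one row per atom: identity,
#' molecule membership, species, atom name, analysis role and partial charge)
#' with a list of frames (time in ns, orthorhombic box edge lengths in nm,
#' and an n x 3 coordinate matrix in nm). The membrane normal is fixed to the
#' third coordinate axis (Oz), the convention for flat bilayer simulations.
#'
#' @param atoms data.frame with columns `atom_id`, `molecule_id`, `species`,
#'   `atom_name`, `role`, `partial_charge`.
#' @param frames list of frames; each a list with elements `time` (ns),
#'   `box` (length-3 numeric, nm) and `coords` (n x 3 matrix, nm).
#' @return An object of class `memion_trajectory`.
#' @export
memion_trajectory <- function(atoms, frames) {
  stopifnot(is.data.frame(atoms), length(frames) >= 1L)
  need <- c("atom_id", "molecule_id", "species", "atom_name", "role", "partial_charge")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  times <- vapply(frames, `[[`, numeric(1), "time")
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.matrix(fr$coords) || nrow(fr$coords) != n)
      stop("frame ", i, " has ", NROW(fr$coords),
           " coordinate rows but the topology has ", n, " atoms")
    if (length(fr$box) != 3L || any(!is.finite(fr$box)) || any(fr$box <= 0))
      stop("frame ", i, ": box must be three positive edge lengths (orthorhombic)")
  }
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (any(!is.finite(atoms$partial_charge)))
    stop("partial charges must be finite")
  structure(list(atoms = atoms, frames = frames, normal_axis = 3L),
            class = "memion_trajectory")
}

#' @export
print.memion_trajectory <- function(x, ...) {
  tm <- vapply(x$frames, `[[`, numeric(1), "time")
  cat("Membrane trajectory: ", nrow(x$atoms), " atoms, ",
      length(x$frames), " frame(s), t = ", min(tm), "..", max(tm), " ns\n", sep = "")
  sp <- table(x$atoms$species[!duplicated(x$atoms$molecule_id)])
  cat("Molecules:", paste(names(sp), sp, sep = ":", collapse = "  "), "\n")
  tagged <- sum(x$atoms$role != "NONE")
  cat("Roles assigned: ", tagged, " atom(s)\n", sep = "")
  invisible(x)
}

#' Number of atoms / frames in a trajectory
#' @param traj a `memion_trajectory`.
#' @return integer count.
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(traj) length(traj$frames)

# ---- GRO format ------------------------------------------------------------

# Parse one GRO frame starting at line `at` of `lines`; returns NULL at EOF.
.parse_gro_frame <- function(lines, at, frame_index) {
  if (at > length(lines)) return(NULL)
  title <- lines[at]
  n <- suppressWarnings(as.integer(trimws(lines[at + 1L])))
  if (is.na(n))
    stop("GRO parse error: expected atom count on line ", at + 1L)
  if (at + 1L + n + 1L > length(lines))
    stop("GRO parse error: truncated frame (", n, " atoms declared)")
  body <- lines[(at + 2L):(at + 1L + n)]
  resid  <- as.integer(substr(body, 1, 5))
  resnam <- trimws(substr(body, 6, 10))
  atnam  <- trimws(substr(body, 11, 15))
  atid   <- as.integer(substr(body, 16, 20))
  xyz <- matrix(c(as.numeric(substr(body, 21, 28)),
                  as.numeric(substr(body, 29, 36)),
                  as.numeric(substr(body, 37, 44))), ncol = 3L)
  boxline <- strsplit(trimws(lines[at + 1L + n + 1L]), "\\s+")[[1]]
  boxv <- as.numeric(boxline)
  if (length(boxv) >= 9L && any(abs(boxv[4:9]) > 1e-9))
    stop("triclinic box encountered; only orthorhombic boxes are supported")
  box <- boxv[1:3]
  # time from "t= <x>" in the title when present, else the frame index
  tm <- NA_real_
  m <- regmatches(title, regexec("t\\s*=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(m) == 2L) tm <- as.numeric(m[2])
  if (!is.finite(tm)) tm <- as.numeric(frame_index - 1L)
  list(resid = resid, resname = resnam, atom_name = atnam, atom_id = atid,
       coords = xyz, box = box, time = tm, next_at = at + n + 3L)
}

.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  first <- NULL
  at <- 1L
  k <- 1L
  repeat {
    fr <- .parse_gro_frame(lines, at, k)
    if (is.null(fr)) break
    if (is.null(first)) first <- fr
    else if (nrow(fr$coords) != nrow(first$coords))
      stop("frame ", k, " has ", nrow(fr$coords), " atoms but frame 1 has ",
           nrow(first$coords))
    frames[[k]] <- list(time = fr$time, box = fr$box, coords = fr$coords)
    at <- fr$next_at
    k <- k + 1L
    if (at > length(lines) || !nzchar(trimws(lines[at]))) break
  }
  atoms <- data.frame(
    atom_id = first$atom_id,
    molecule_id = first$resid,
    species = .species_from_resname(first$resname),
    atom_name = first$atom_name,
    role = "NONE",
    partial_charge = 0,
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, frames = frames)
}

#' Write a trajectory in GRO format
#'
#' Writes all frames of a trajectory as a (possibly multi-frame) GRO file,
#' with the frame time embedded in each title line (`t= <ns>`). Coordinates
#' are written at GRO's fixed 3-decimal (1e-3 nm) precision.
#'
#' @param traj a `memion_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  resname <- .resname_for_species(at$species)
  for (fr in traj$frames) {
    writeLines(sprintf("memion t= %.4f", fr$time), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$molecule_id %% 100000L, resname, substr(at$atom_name, 1, 5),
                       at$atom_id %% 100000L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

.resname_for_species <- function(species) {
  map <- c(DOPC = "DOPC", CHOL = "CHL1", KOR105 = "KOR", BAC = "BAC",
           SDS = "SDS", WATER = "SOL", ION = "ION", OTHER = "UNK")
  out <- unname(map[species])
  out[is.na(out)] <- "UNK"
  out
}

# ---- PDB format (via bio3d) ------------------------------------------------

.read_pdb_traj <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n <- nrow(pdb$atom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  box <- c(10, 10, 10)
  # CRYST1 record (Angstrom); bio3d does not always expose it, so re-scan
  cl <- grep("^CRYST1", readLines(path, n = 50L), value = TRUE)
  if (length(cl)) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33)))
    ang <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3))
      stop("triclinic box encountered; only orthorhombic boxes are supported")
    box <- v / 10
  }
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    co <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE) / 10  # Angstrom -> nm
    list(time = as.numeric(i - 1L), box = box, coords = co)
  })
  atoms <- data.frame(
    atom_id = pdb$atom$eleno,
    molecule_id = pdb$atom$resno,
    species = .species_from_resname(pdb$atom$resid),
    atom_name = trimws(pdb$atom$elety),
    role = "NONE",
    partial_charge = 0,
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, frames = frames)
}

# ---- Reader entry point ----------------------------------------------------

#' Read a membrane trajectory
#'
#' Reads a topology (GRO or PDB) and, optionally, a separate coordinate
#' trajectory (multi-frame GRO or multi-MODEL PDB) whose atom count must match
#' the topology. Times are in ns (parsed from GRO title lines where present,
#' otherwise the frame index) and coordinates in nm.
#'
#' Compressed binary trajectories (XTC/TRR/DCD) are not read directly;
#' convert them to multi-frame GRO or PDB first (e.g. `gmx trjconv`).
#'
#' @param topology_path GRO or PDB file defining the atoms.
#' @param trajectory_path optional multi-frame GRO or multi-MODEL PDB file
#'   supplying the frames; when omitted the topology's own frame(s) are used.
#' @return A [memion_trajectory()].
#' @export
read_trajectory <- function(topology_path, trajectory_path = NULL) {
  top <- .read_any(topology_path)
  if (is.null(trajectory_path)) {
    return(memion_trajectory(top$atoms, top$frames))
  }
  trj <- .read_any(trajectory_path)
  n_top <- nrow(top$atoms)
  n_trj <- nrow(trj$frames[[1]]$coords)
  if (n_top != n_trj)
    stop("atom-count mismatch: topology '", basename(topology_path), "' has ",
         n_top, " atoms but trajectory '", basename(trajectory_path),
         "' has ", n_trj)
  memion_trajectory(top$atoms, trj$frames)
}

.read_any <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = .read_gro(path),
         pdb = .read_pdb_traj(path),
         xtc = ,
         trr = ,
         dcd = stop("binary trajectory format '.", ext, "' is not supported; ",
                    "convert to multi-frame GRO or PDB (e.g. gmx trjconv -f in.",
                    ext, " -o out.gro)"),
         stop("unknown trajectory format '.", ext, "' for '", path, "'"))
}

# ---- Role maps -------------------------------------------------------------

#' Read a role map from YAML
#'
#' The role map identifies, per species, which atom names carry which analysis
#' role (quaternary nitrogen `N_PLUS`, para-ring carbon `PARA_C`, terminal
#' tail carbon `TERM_C`, sulfate sulfur `SULFATE_S`, lipid phosphorus/nitrogen
#' `LIPID_P`/`LIPID_N`, cholesterol hydroxyl oxygen `CHOL_O`) and what partial
#' charge each named atom bears. Format:
#'
#' ```yaml
#' DOPC:
#'   P:  {role: LIPID_P, charge: -1}
#'   N:  {role: LIPID_N, charge:  1}
#' KOR105:
#'   N1: {role: N_PLUS, charge: 1}
#'   CP: {role: PARA_C, charge: 0}
#'   CT: {role: TERM_C, charge: 0}
#' ```
#'
#' @param path YAML file.
#' @return Nested list `species -> atom_name -> list(role, charge)`.
#' @export
read_role_map <- function(path) {
  rm <- yaml::read_yaml(path)
  .validate_role_map(rm)
  rm
}

.validate_role_map <- function(role_map) {
  stopifnot(is.list(role_map))
  for (sp in names(role_map)) {
    for (an in names(role_map[[sp]])) {
      ent <- role_map[[sp]][[an]]
      if (is.null(ent$role) || !(ent$role %in% .role_levels))
        stop("role map entry ", sp, "/", an, ": missing or unknown role")
      if (is.null(ent$charge) || !is.finite(as.numeric(ent$charge)))
        stop("role map entry ", sp, "/", an, ": missing or non-finite charge")
    }
  }
  invisible(role_map)
}

# Roles each species must carry for downstream analyses.
.required_roles <- list(
  KOR105 = c("N_PLUS", "PARA_C", "TERM_C"),
  BAC    = c("N_PLUS", "PARA_C", "TERM_C"),
  SDS    = c("SULFATE_S", "TERM_C"),
  DOPC   = c("LIPID_P", "LIPID_N"),
  CHOL   = c("CHOL_O")
)

#' Assign analysis roles and partial charges
#'
#' Applies a role map (see [read_role_map()]) to the topology: every atom whose
#' `(species, atom_name)` pair appears in the map receives that role and
#' partial charge. Assignment is idempotent. Validation then requires every
#' molecule of a species covered by the map to carry that species' full role
#' set (e.g. each KOR105 one `N_PLUS`, one `PARA_C`, one `TERM_C`), and each
#' role at most once per molecule.
#'
#' @param traj a `memion_trajectory`.
#' @param role_map nested list `species -> atom_name -> list(role, charge)`,
#'   or a path to such a YAML file.
#' @param validate check role coverage per molecule (default TRUE).
#' @return The trajectory with `role` and `partial_charge` filled in.
#' @export
assign_roles <- function(traj, role_map, validate = TRUE) {
  if (is.character(role_map)) role_map <- read_role_map(role_map)
  .validate_role_map(role_map)
  at <- traj$atoms
  for (sp in names(role_map)) {
    for (an in names(role_map[[sp]])) {
      ent <- role_map[[sp]][[an]]
      hit <- at$species == sp & at$atom_name == an
      at$role[hit] <- ent$role
      at$partial_charge[hit] <- as.numeric(ent$charge)
    }
  }
  traj$atoms <- at
  if (validate) .validate_roles(traj, names(role_map))
  traj
}

.validate_roles <- function(traj, species) {
  at <- traj$atoms
  bad <- character(0)
  for (sp in intersect(species, names(.required_roles))) {
    req <- .required_roles[[sp]]
    mols <- unique(at$molecule_id[at$species == sp])
    for (m in mols) {
      roles <- at$role[at$molecule_id == m & at$species == sp]
      cnt <- table(factor(roles[roles != "NONE"], levels = .role_levels))
      if (any(cnt[req] != 1L))
        bad <- c(bad, sprintf("%s molecule %d (has: %s; needs one each of: %s)",
                              sp, m,
                              paste(names(cnt)[cnt > 0], collapse = ","),
                              paste(req, collapse = ",")))
      if (any(cnt > 1L))
        bad <- c(bad, sprintf("%s molecule %d: duplicated role(s) %s", sp, m,
                              paste(names(cnt)[cnt > 1L], collapse = ",")))
    }
  }
  if (length(bad))
    stop("role validation failed for ", length(bad), " molecule(s):\n  ",
         paste(utils::head(bad, 10L), collapse = "\n  "), call. = FALSE)
  invisible(traj)
}

#' Select atom indices by species, role or atom name
#'
#' @param traj a `memion_trajectory`.
#' @param species,role,atom_name optional filters; an atom must match all
#'   that are given.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(traj, species = NULL, role = NULL, atom_name = NULL) {
  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(species)) keep <- keep & at$species %in% species
  if (!is.null(role)) keep <- keep & at$role %in% role
  if (!is.null(atom_name)) keep <- keep & at$atom_name %in% atom_name
  which(keep)
}
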