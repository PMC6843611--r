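# Builders for small hand-constructed trajectories.

atom_row <- function(id, mol, species, name, role, q) {
  data.frame(atom_id = id, molecule_id = mol, species = species,
             atom_name = name, role = role, partial_charge = q,
             stringsAsFactors = FALSE)
}

# coords: one n x 3 matrix, or a list of them (one per frame)
mk_traj <- function(atoms, coords, box = c(10, 10, 10), dt = 1, t0 = 0) {
  if (is.matrix(coords)) coords <- list(coords)
  frames <- lapply(seq_along(coords), function(i)
    list(time = t0 + (i - 1) * dt, box = box, coords = coords[[i]]))
  memion_trajectory(atoms, frames)
}

# four-lipid scaffold defining a midplane at z = 0 (P at +/-1.8, N at +/-1.9)
scaffold <- function() {
  at <- rbind(
    atom_row(1L, 1L, "DOPC", "P", "LIPID_P", -1),
    atom_row(2L, 1L, "DOPC", "N", "LIPID_N", 1),
    atom_row(3L, 2L, "DOPC", "P", "LIPID_P", -1),
    atom_row(4L, 2L, "DOPC", "N", "LIPID_N", 1),
    atom_row(5L, 3L, "DOPC", "P", "LIPID_P", -1),
    atom_row(6L, 3L, "DOPC", "N", "LIPID_N", 1),
    atom_row(7L, 4L, "DOPC", "P", "LIPID_P", -1),
    atom_row(8L, 4L, "DOPC", "N", "LIPID_N", 1))
  co <- rbind(c(1, 1, 1.8), c(1, 1, 1.9),
              c(3, 3, 1.8), c(3, 3, 1.9),
              c(1, 3, -1.8), c(1, 3, -1.9),
              c(3, 1, -1.8), c(3, 1, -1.9))
  list(atoms = at, coords = co)
}

# scaffold plus extra atoms appended (extra = list(atoms=..., coords=matrix))
mk_membrane_traj <- function(extra_atoms = NULL, extra_coords = NULL,
                             frames = 1L, box = c(10, 10, 10), dt = 1) {
  sc <- scaffold()
  at <- sc$atoms
  co <- sc$coords
  if (!is.null(extra_atoms)) {
    extra_atoms$atom_id <- max(at$atom_id) + seq_len(nrow(extra_atoms))
    at <- rbind(at, extra_atoms)
    co <- rbind(co, extra_coords)
  }
  mk_traj(at, rep(list(co), frames), box = box, dt = dt)
}

# one CHOL molecule = one O atom at each supplied position
mk_chol_traj <- function(pos, box = c(10, 10, 10), with_scaffold = FALSE) {
  n <- nrow(pos)
  at <- do.call(rbind, lapply(seq_len(n), function(i)
    atom_row(i, i, "CHOL", "O3", "CHOL_O", 0)))
  if (with_scaffold) {
    sc <- scaffold()
    sc$atoms$atom_id <- sc$atoms$atom_id + n
    sc$atoms$molecule_id <- sc$atoms$molecule_id + n
    at <- rbind(at, sc$atoms)
    pos <- rbind(pos, sc$coords)
  }
  mk_traj(at, pos, box = box)
}
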