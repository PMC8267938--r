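# Fixture builders shared across the suite. Everything is generated in code;
# no binary data.

# One fixed-column ATOM line.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = substr(trimws(name), 1, 1), altloc = " ",
                          occupancy = 1.00, record = "ATOM") {
  nm <- if (nchar(name) < 4 && nchar(element) == 1) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, x, y, z,
          occupancy, 0, toupper(element))
}

# A minimal structure straight from a coordinate matrix.
make_structure <- function(xyz, atom_name = "CA", resname = "GLY",
                           element = "C", resno = seq_len(nrow(xyz)),
                           chain = "A") {
  n <- nrow(xyz)
  molecular_structure(data.frame(
    serial = seq_len(n),
    atom_name = rep_len(atom_name, n), resname = rep_len(resname, n),
    chain = rep_len(chain, n), resno = rep_len(resno, n),
    element = rep_len(element, n), mass = element_mass(rep_len(element, n)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], record = "ATOM",
    stringsAsFactors = FALSE))
}

# Trajectory from a list of frames over one topology.
make_trajectory <- function(topology, frames, frame_interval_ps = 10) {
  xyz <- array(unlist(frames), dim = c(nrow(topology), 3, length(frames)))
  trajectory(topology, xyz, frame_interval_ps)
}

# A phenylalanine with the full heavy-atom set plus backbone.
make_phe <- function(resno = 183) {
  names <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  el <- c("N", "C", "C", "O", rep("C", 7))
  set.seed(42)
  xyz <- matrix(rnorm(length(names) * 3, sd = 2), ncol = 3)
  molecular_structure(data.frame(
    serial = seq_along(names), atom_name = names, resname = "PHE",
    chain = "A", resno = resno, element = el, mass = element_mass(el),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], record = "ATOM",
    stringsAsFactors = FALSE))
}

# Random proper rotation matrix (via QR with det fix), seeded by caller.
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(xyz, R, t) xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
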