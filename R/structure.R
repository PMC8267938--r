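#' Molecular structure and trajectory containers
#'
#' A `MolecularStructure` is a data frame of atom records (file order
#' preserved) with columns `serial`, `atom_name`, `resname`, `chain`, `resno`
#' (author numbering), `element`, `mass` (amu), `x`, `y`, `z` (Angstrom) and
#' `record` ("ATOM" or "HETATM"). A `Trajectory` couples one topology with an
#' `A x 3 x F` coordinate array and a frame interval in ps.
#'
#' @param atoms data frame with the columns listed above.
#' @return an object of class `MolecularStructure`.
#' @export
molecular_structure <- function(atoms) {
  needed <- c("serial", "atom_name", "resname", "chain", "resno",
              "element", "mass", "x", "y", "z", "record")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (!all(atoms$mass > 0)) stop("non-positive atomic mass in atom table")
  rownames(atoms) <- NULL
  structure(atoms, class = c("MolecularStructure", "data.frame"))
}

#' @rdname molecular_structure
#' @param x object to query.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.MolecularStructure <- function(x) nrow(x)

#' @export
n_atoms.Trajectory <- function(x) dim(x$coords)[1]

#' Extract the coordinate matrix of a structure
#'
#' @param structure a `MolecularStructure`.
#' @return numeric `A x 3` matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Build a trajectory from a topology and a coordinate array
#'
#' @param topology a `MolecularStructure`.
#' @param coords numeric array `A x 3 x F` (or an `A x 3` matrix for a
#'   single frame), Angstrom.
#' @param frame_interval_ps time between saved frames, ps (default 10, the
#'   usual save interval of production MD output).
#' @return an object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, frame_interval_ps = 10) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology))
    stop("coordinate array has ", dim(coords)[1], " atoms but topology has ",
         nrow(topology))
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0)
    stop("frame_interval_ps must be positive")
  structure(list(topology = topology, coords = coords,
                 frame_interval_ps = frame_interval_ps),
            class = "Trajectory")
}

#' @rdname trajectory
#' @param x a `Trajectory`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.Trajectory <- function(x) dim(x$coords)[3]

#' @rdname trajectory
#' @param i frame index (1-based).
#' @export
frame_coords <- function(x, i) {
  stopifnot(inherits(x, "Trajectory"), i >= 1, i <= n_frames(x))
  x$coords[, , i, drop = TRUE]
}

#' @export
print.MolecularStructure <- function(x, ...) {
  cat("<MolecularStructure> ", nrow(x), " atoms, ",
      length(unique(paste(x$chain, x$resno))), " residues, chains: ",
      paste(sort(unique(x$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("<Trajectory> ", n_frames(x), " frames x ", n_atoms(x),
      " atoms, frame interval ", x$frame_interval_ps, " ps\n", sep = "")
  invisible(x)
}
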