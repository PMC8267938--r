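## Fixed-column PDB reader/writer (ATOM/HETATM, MODEL/ENDMDL multi-model
## dialect). Columns follow the PDB v3.3 standard:
##   1-6 record, 7-11 serial, 13-16 name, 17 altLoc, 18-20 resName,
##   22 chainID, 23-26 resSeq, 31-38 x, 39-46 y, 47-54 z, 55-60 occupancy,
##   77-78 element.

.substr_trim <- function(lines, a, b) trimws(substr(lines, a, b))

.num_field <- function(lines, a, b, what, line_no) {
  raw <- .substr_trim(lines, a, b)
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & nzchar(raw) | !nzchar(raw))
  if (length(bad))
    stop("malformed ", what, " field at line ", line_no[bad[1]],
         ": '", raw[bad[1]], "'")
  val
}

## Resolve alternate locations: within each (chain, resno, atom_name) group
## keep the record with the highest occupancy; ties resolved in favour of
## altloc 'A' (then lowest altloc code).
.resolve_altloc <- function(df) {
  if (all(df$altloc == "" | is.na(df$altloc))) return(df)
  key <- paste(df$chain, df$resno, df$atom_name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- df$occupancy[idx]
    occ[is.na(occ)] <- 1
    best <- idx[occ == max(occ)]
    if (length(best) > 1L) {
      alts <- df$altloc[best]
      best <- if (any(alts == "A")) best[alts == "A"][1] else best[order(alts)][1]
    }
    best
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

.parse_pdb_block <- function(lines, line_no) {
  rec <- substr(lines, 1, 6)
  df <- data.frame(
    serial    = .num_field(lines, 7, 11, "serial", line_no),
    atom_name = .substr_trim(lines, 13, 16),
    altloc    = substr(lines, 17, 17),
    resname   = .substr_trim(lines, 18, 20),
    chain     = substr(lines, 22, 22),
    resno     = .num_field(lines, 23, 26, "residue number", line_no),
    x         = .num_field(lines, 31, 38, "x coordinate", line_no),
    y         = .num_field(lines, 39, 46, "y coordinate", line_no),
    z         = .num_field(lines, 47, 54, "z coordinate", line_no),
    occupancy = suppressWarnings(as.numeric(.substr_trim(lines, 55, 60))),
    element   = .substr_trim(lines, 77, 78),
    record    = trimws(rec),
    stringsAsFactors = FALSE
  )
  df$altloc[df$altloc == " "] <- ""
  no_el <- !nzchar(df$element)
  if (any(no_el)) df$element[no_el] <- .infer_element(substr(lines[no_el], 13, 16))
  df <- .resolve_altloc(df)
  df$mass <- element_mass(df$element)
  df$altloc <- NULL
  df$occupancy <- NULL
  molecular_structure(df[, c("serial", "atom_name", "resname", "chain",
                             "resno", "element", "mass", "x", "y", "z",
                             "record")])
}

#' Read a (multi-model) PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Alternate locations are resolved
#' by keeping the highest-occupancy copy (ties favour altloc 'A'). The element
#' is taken from columns 77-78 or inferred from the atom name; masses come
#' from the built-in standard-atomic-weight table. With
#' `model_policy = "all"`, MODEL/ENDMDL blocks become trajectory frames that
#' share the first model's topology.
#'
#' @param file path to a PDB file (or `text` given directly).
#' @param model_policy `"first"` returns a [molecular_structure()]; `"all"`
#'   returns a [trajectory()] of all models.
#' @param text optional character scalar or vector of PDB lines, used instead
#'   of `file`.
#' @param frame_interval_ps frame spacing for multi-model reads, ps.
#' @return a `MolecularStructure` or a `Trajectory`.
#' @export
read_pdb <- function(file, model_policy = c("first", "all"), text = NULL,
                     frame_interval_ps = 10) {
  model_policy <- match.arg(model_policy)
  lines <- if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text)) strsplit(text, "\n")[[1]] else text
  } else readLines(file, warn = FALSE)
  line_no <- seq_along(lines)
  rec6 <- substr(lines, 1, 6)
  is_atom <- rec6 %in% c("ATOM  ", "HETATM") | trimws(rec6) %in% c("ATOM", "HETATM")
  is_model_open <- startsWith(lines, "MODEL")
  is_model_close <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")

  if (!any(is_model_open)) {
    s <- .parse_pdb_block(lines[is_atom], line_no[is_atom])
    if (model_policy == "first") return(s)
    return(trajectory(s, coords(s), frame_interval_ps))
  }

  open_count <- cumsum(is_model_open)
  in_model <- open_count > cumsum(is_model_close)
  atom_idx <- which(is_atom & in_model)
  blocks <- split(atom_idx, open_count[atom_idx])
  if (!length(blocks)) stop("MODEL records present but contain no atoms")
  first <- .parse_pdb_block(lines[blocks[[1]]], line_no[blocks[[1]]])
  if (model_policy == "first") return(first)

  nf <- length(blocks)
  xyz <- array(NA_real_, dim = c(nrow(first), 3L, nf))
  xyz[, , 1] <- coords(first)
  if (nf > 1) for (k in 2:nf) {
    b <- .parse_pdb_block(lines[blocks[[k]]], line_no[blocks[[k]]])
    if (nrow(b) != nrow(first))
      stop("topology mismatch: model ", k, " has ", nrow(b),
           " atoms, model 1 has ", nrow(first))
    xyz[, , k] <- coords(b)
  }
  trajectory(first, xyz, frame_interval_ps)
}

.format_pdb_atoms <- function(top, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  name <- vapply(seq_len(nrow(top)), function(i) {
    nm <- top$atom_name[i]
    if (nchar(nm) > 4L) stop("atom name '", nm, "' exceeds PDB field width")
    ## standard alignment: 1-letter elements start in column 14
    if (nchar(nm) < 4L && nchar(top$element[i]) == 1L) paste0(" ", nm) else nm
  }, character(1))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          top$record, top$serial %% 100000, name, "", top$resname, top$chain,
          top$resno, "", xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          toupper(top$element))
}

#' Write structures and trajectories as PDB or XYZ text
#'
#' Multi-frame objects are written as MODEL/ENDMDL blocks (PDB) or stacked
#' frames (XYZ). Round-trip guarantee: `read(write(T))` reproduces
#' coordinates to 3 decimals (PDB, the format's fixed precision) or to the
#' written decimals exactly (XYZ, 6 decimals).
#'
#' @param x a `MolecularStructure` or `Trajectory`.
#' @param file optional path; when `NULL` the text is returned invisibly only.
#' @return character vector of lines, invisibly.
#' @export
write_pdb <- function(x, file = NULL) {
  if (inherits(x, "MolecularStructure")) x <- trajectory(x, coords(x))
  stopifnot(inherits(x, "Trajectory"))
  nf <- n_frames(x)
  out <- character(0)
  for (f in seq_len(nf)) {
    body <- .format_pdb_atoms(x$topology, x$coords[, , f, drop = TRUE])
    out <- c(out,
             if (nf > 1) sprintf("MODEL     %4d", f),
             body,
             if (nf > 1) "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' @rdname write_pdb
#' @export
write_xyz <- function(x, file = NULL) {
  if (inherits(x, "MolecularStructure")) x <- trajectory(x, coords(x))
  stopifnot(inherits(x, "Trajectory"))
  na <- n_atoms(x)
  out <- unlist(lapply(seq_len(n_frames(x)), function(f) {
    xyz <- x$coords[, , f, drop = TRUE]
    if (na == 1L) xyz <- matrix(xyz, 1L, 3L)
    c(as.character(na),
      sprintf("frame %d t= %.4f ps", f, (f - 1) * x$frame_interval_ps),
      sprintf("%-2s %14.6f %14.6f %14.6f", x$topology$element, xyz[, 1],
              xyz[, 2], xyz[, 3]))
  }))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Read an XYZ frame series
#'
#' @param file path (or `text` lines). Frames are `natoms / comment / records`
#'   blocks with identical atom counts.
#' @param topology optional `MolecularStructure` to attach; when absent a
#'   minimal topology is built from the element symbols.
#' @param text optional character vector of lines.
#' @param frame_interval_ps frame spacing, ps.
#' @return a `Trajectory`.
#' @export
read_xyz <- function(file, topology = NULL, text = NULL, frame_interval_ps = 10) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text)) strsplit(text, "\n")[[1]] else text
  } else readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  frames <- list()
  elements <- NULL
  while (pos <= length(lines)) {
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na < 1L) stop("malformed XYZ atom count at line ", pos)
    if (pos + 1L + na > length(lines)) stop("truncated XYZ frame starting at line ", pos)
    recs <- lines[(pos + 2L):(pos + 1L + na)]
    toks <- strsplit(trimws(recs), "[[:space:]]+")
    el <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(v)) stop("malformed XYZ coordinate record: '", paste(tk, collapse = " "), "'")
      v
    }, numeric(3)))
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("topology mismatch between XYZ frames")
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + na
  }
  if (is.null(topology)) {
    n <- length(elements)
    topology <- molecular_structure(data.frame(
      serial = seq_len(n), atom_name = elements, resname = "UNK",
      chain = "A", resno = seq_len(n), element = elements,
      mass = element_mass(elements), x = frames[[1]][, 1],
      y = frames[[1]][, 2], z = frames[[1]][, 3], record = "ATOM",
      stringsAsFactors = FALSE))
  } else if (nrow(topology) != length(elements)) {
    stop("supplied topology has ", nrow(topology), " atoms but XYZ frames have ",
         length(elements))
  }
  xyz <- array(unlist(frames), dim = c(length(elements), 3L, length(frames)))
  trajectory(topology, xyz, frame_interval_ps)
}
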