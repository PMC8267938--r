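## Toy two-lobe ("clamshell") structure generator.
##
## Layout: the hinge is the z-axis through the origin. The N-lobe (residues
## 1-269) is fixed; the C-lobe (residues 270-428) rotates rigidly about the
## hinge. The four inter-domain anchor groups sit on circles of radius R
## about the hinge:
##   A1 (residues 42-48, N-lobe)  at polar angle 90 degrees,
##   B1 (residues 298-302, C-lobe) at 90 + phi1 degrees,
##   A2 (residues 209-227, N-lobe) at -90 degrees,
##   B2 (residues 363-365, C-lobe) at -90 - phi2 degrees,
## so a hinge rotation by theta gives D1 = 2 R sin((phi1 + theta)/2)
## (increasing) and D2 = 2 R sin((phi2 - theta)/2) (decreasing): the
## clamp-like anti-correlation of the two cleft distances. phi1 is chosen so
## that D1 at theta = 0 equals the configured closed-state center exactly.

.toy_anchor_radius <- 15

.unit <- function(v) v / sqrt(sum(v^2))

.rz <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

## Place atom D given positions A, B, C, bond length r (C-D), angle theta
## (B-C-D, degrees) and torsion tau (A-B-C-D, degrees); the torsion sign
## convention matches dihedral_angle().
.place_atom <- function(A, B, C, r, theta_deg, tau_deg) {
  th <- theta_deg * pi / 180; ta <- -tau_deg * pi / 180
  bc <- .unit(C - B)
  n <- .unit(c((B - A)[2] * bc[3] - (B - A)[3] * bc[2],
               (B - A)[3] * bc[1] - (B - A)[1] * bc[3],
               (B - A)[1] * bc[2] - (B - A)[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-bc * cos(th) + m * sin(th) * cos(ta) + n * sin(th) * sin(ta))
}

## Rough heavy-atom sidechain offsets (relative to CA) per residue type used
## by the toy builder. Geometry is approximate; only topology (names,
## elements) and rigid-body behaviour matter downstream.
.sidechain_atoms <- function(resname) {
  hex <- rbind(c(0, 0, 0), c(0.695, 1.204, 0), c(2.085, 1.204, 0),
               c(2.78, 0, 0), c(2.085, -1.204, 0), c(0.695, -1.204, 0))
  chain <- function(n) {
    dirs <- matrix(c(0.94, 0.33, 0.1, 0.94, -0.33, -0.1), 2, 3, byrow = TRUE)
    t(vapply(seq_len(n), function(k)
      1.5 * colSums(dirs[rep_len(1:2, k), , drop = FALSE]), numeric(3)))
  }
  shift <- function(off, base = c(1.0, 0.9, 0.6)) sweep(off, 2, base, "+")
  switch(resname,
    ARG = list(names = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
               el = c("C", "C", "C", "N", "C", "N", "N"),
               xyz = rbind(chain(5),
                           chain(5)[5, ] + c(1.1, 0.8, 0.2),
                           chain(5)[5, ] + c(1.1, -0.8, -0.2))),
    LYS = list(names = c("CB", "CG", "CD", "CE", "NZ"),
               el = c("C", "C", "C", "C", "N"), xyz = chain(5)),
    SER = list(names = c("CB", "OG"), el = c("C", "O"), xyz = chain(2)),
    VAL = list(names = c("CB", "CG1", "CG2"), el = c("C", "C", "C"),
               xyz = rbind(chain(1), chain(1)[1, ] + c(0.9, 0.9, 0.4),
                           chain(1)[1, ] + c(0.9, -0.9, -0.4))),
    ALA = list(names = "CB", el = "C", xyz = chain(1)),
    MET = list(names = c("CB", "CG", "SD", "CE"),
               el = c("C", "C", "S", "C"), xyz = chain(4)),
    ASP = list(names = c("CB", "CG", "OD1", "OD2"),
               el = c("C", "C", "O", "O"),
               xyz = rbind(chain(2), chain(2)[2, ] + c(1.0, 0.8, 0.3),
                           chain(2)[2, ] + c(1.0, -0.8, -0.3))),
    GLU = list(names = c("CB", "CG", "CD", "OE1", "OE2"),
               el = c("C", "C", "C", "O", "O"),
               xyz = rbind(chain(3), chain(3)[3, ] + c(1.0, 0.8, 0.3),
                           chain(3)[3, ] + c(1.0, -0.8, -0.3))),
    PHE = list(names = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
               el = rep("C", 7),
               xyz = rbind(c(0.4, 1.0, 0.9),
                           shift(hex[c(1, 2, 3, 4, 5, 6), , drop = FALSE],
                                 c(1.3, 1.9, 1.5)))),
    HIS = list(names = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
               el = c("C", "C", "N", "C", "C", "N"),
               xyz = rbind(c(0.4, 1.0, 0.9),
                           shift(hex[c(1, 2, 6, 3, 5), , drop = FALSE],
                                 c(1.3, 1.9, 1.5)))),
    stop("no sidechain template for ", resname))
}

## The five monitored hydrogen-bond pairs with their toy donor/acceptor
## realization. `dir` is the unit vector along which the donor H (1.0 A) and
## the scheduled acceptor atom (2.9 A on / 6.5 A off) are placed.
.toy_pairs <- list(
  list(label = "R14-D262",  donor_res = 14,  donor_atom = "NH1", h_atom = "HH11",
       acc_res = 262, acc_atom = "OD1", dir = c(0.20,  0.15, 0.97)),
  list(label = "M242-R265", donor_res = 265, donor_atom = "NH1", h_atom = "HH11",
       acc_res = 242, acc_atom = "SD",  dir = c(-0.15, 0.20, 0.97)),
  list(label = "A188-H404", donor_res = 188, donor_atom = "N",   h_atom = "H",
       acc_res = 404, acc_atom = "ND1", dir = c(0.25, -0.10, 0.96)),
  list(label = "S44-V193",  donor_res = 44,  donor_atom = "OG",  h_atom = "HG",
       acc_res = 193, acc_atom = "O",   dir = c(-0.20, -0.15, 0.97)),
  list(label = "K42-E295",  donor_res = 42,  donor_atom = "NZ",  h_atom = "HZ1",
       acc_res = 295, acc_atom = "OE1", dir = c(0.10,  0.25, 0.96))
)
.toy_pair_dirs <- lapply(.toy_pairs, function(p) .unit(p$dir))

#' The five monitored hydrogen-bond pairs
#'
#' Residue-pair hydrogen bonds spanning the cofactor pocket (R14-D262,
#' M242-R265), the SET/MYND interface (S44-V193), and the lobe-lobe
#' interfaces (A188-H404, K42-E295), as [hbond_spec()] objects with the
#' default geometric criteria.
#'
#' @param ... passed to [hbond_spec()] (cutoffs, mode).
#' @return named list of [hbond_spec()]s.
#' @export
toy_hbond_pairs <- function(...) {
  out <- lapply(.toy_pairs, function(p)
    hbond_spec(p$donor_res, p$acc_res, label = p$label, ...))
  names(out) <- vapply(.toy_pairs, `[[`, character(1), "label")
  out
}

#' Build the toy two-lobe structure
#'
#' Constructs a coarse clamshell model whose residue numbering mirrors the
#' landmarks of the SMYD3 analysis, so every preset selection resolves: one
#' CA per residue 1-428 (N-lobe 1-269, rigid C-lobe 270-428 attached at the
#' hinge), full heavy sidechains for residues 14, 42, 44, 183, 188, 239 and
#' 242, the acceptor/donor atoms of the five monitored hydrogen-bond pairs
#' (with donor hydrogens), and the four anchor groups of the D1/D2
#' inter-domain distances. At hinge angle zero D1 equals the configured
#' closed-state center to 1e-6 Angstrom by construction; the D3
#' sidechain-centroid distance and the tyrosine-239 CA-CB-CG-CD2 torsion are
#' likewise set exactly to their configured values. Deterministic for a
#' given configuration.
#'
#' @param config a [toy_model_config()]; `config$centers[1]` becomes the
#'   closed-state D1.
#' @param d2_closed D2 at hinge angle zero, Angstrom. The default (17) gives
#'   the hinge room to open to D1 ~ 22 Angstrom before D2 closes; use the
#'   crystallographic value only for static calibration structures.
#' @param d3 sidechain-centroid distance between residues 183 and 239,
#'   Angstrom (default 7.70, the crystallographic channel width).
#' @param y239_torsion CA-CB-CG-CD2 torsion of tyrosine 239, degrees
#'   (default 183.11, the crystallographic rotamer).
#' @return a [molecular_structure()] with a `toy_hinge` attribute consumed
#'   by [embed_d1_to_coordinates()].
#' @export
build_toy_structure <- function(config = toy_model_config(), d2_closed = 17,
                                d3 = 7.70, y239_torsion = 183.11) {
  R <- .toy_anchor_radius
  d1_closed <- config$centers[1]
  if (d1_closed >= 2 * R || d2_closed >= 2 * R)
    stop("anchor distances must be below the hinge diameter ", 2 * R)
  phi1 <- 2 * asin(d1_closed / (2 * R))
  phi2 <- 2 * asin(d2_closed / (2 * R))
  on_circle <- function(alpha) R * c(cos(alpha), sin(alpha), 0)
  anchors <- list(a1 = on_circle(pi / 2),
                  b1 = on_circle(pi / 2 + phi1),
                  a2 = on_circle(-pi / 2),
                  b2 = on_circle(-pi / 2 - phi2))
  groups <- list(a1 = 42:48, b1 = 298:302, a2 = 209:227, b2 = 363:365)

  sc_res <- c("14" = "ARG", "42" = "LYS", "44" = "SER", "183" = "PHE",
              "188" = "ALA", "193" = "VAL", "239" = "TYR", "242" = "MET",
              "262" = "ASP", "265" = "ARG", "295" = "GLU", "404" = "HIS")

  rows <- list()
  add <- function(resno, resname, name, el, xyz) {
    xyz <- as.matrix(xyz); dimnames(xyz) <- NULL
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = name, resname = resname, resno = resno, element = el,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  }

  ## generic CA backbone: two arcs flanking the hinge, N-lobe on the left,
  ## C-lobe on the right, with a mild zig-zag in z to break collinearity
  ca_pos <- function(i, lobe) {
    t <- if (lobe == "N") (i - 135) / 269 else (i - 349) / 159
    sgn <- if (lobe == "N") -1 else 1
    c(sgn * (24 + 6 * cos(2.2 * pi * t)), 20 * t, 2.5 * sin(7 * pi * t))
  }
  grp_members <- sort(unlist(groups))
  for (i in 1:428) {
    lobe <- if (i <= 269) "N" else "C"
    rn <- unname(sc_res[as.character(i)])
    base <- if (i %in% grp_members) {
      g <- names(groups)[vapply(groups, function(g) i %in% g, logical(1))][1]
      k <- match(i, groups[[g]]); n <- length(groups[[g]])
      anchors[[g]] + c(0.9 * (k - (n + 1) / 2), 0.45 * (-1)^k,
                       0.3 * ((k %% 3) - 1))
    } else ca_pos(i, lobe)
    resname <- if (is.na(rn)) "GLY" else rn
    add(i, resname, "CA", "C", matrix(base, 1, 3))
    if (!is.na(rn) && rn != "TYR") {
      sc <- .sidechain_atoms(rn)
      add(i, rn, sc$names, sc$el, sweep(sc$xyz, 2, base, "+"))
    }
    if (i == 188) add(i, "ALA", "N", "N", matrix(base + c(-1.2, 0.6, 0.2), 1, 3))
    if (i == 193) add(i, "VAL", "O", "O", matrix(base + c(0.9, 1.0, 0.2), 1, 3))
  }

  ## tyrosine 239: ring built by torsion placement so the CA-CB-CG-CD2
  ## dihedral equals y239_torsion exactly
  ca239 <- ca_pos(239, "N")
  cb <- ca239 + 1.53 * .unit(c(0.9, 0.35, 0.3))
  cg <- .place_atom(ca239 + c(0, 0, 1), ca239, cb, 1.51, 114, 60)
  cd2 <- .place_atom(ca239, cb, cg, 1.39, 120, y239_torsion)
  cd1 <- .place_atom(ca239, cb, cg, 1.39, 120, (y239_torsion + 180) %% 360)
  ce2 <- .place_atom(cb, cg, cd2, 1.39, 120, 180)
  ce1 <- .place_atom(cb, cg, cd1, 1.39, 120, 180)
  cz <- cg + 2.78 * .unit((ce1 + ce2) / 2 - cg)
  oh <- cg + (2.78 + 1.36) * .unit(cz - cg)
  add(239, "TYR", c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
      c(rep("C", 7), "O"), rbind(cb, cg, cd1, cd2, ce1, ce2, cz, oh))

  df <- do.call(rbind, rows)
  df <- df[order(df$resno), , drop = FALSE]

  ## recentre each anchor group so its heavy-atom mass-weighted centroid
  ## lands exactly on its anchor point (sidechains of K42/S44 included)
  df$mass <- element_mass(df$element)
  for (g in names(groups)) {
    in_grp <- df$resno %in% groups[[g]]
    heavy <- in_grp & df$element != "H"
    w <- df$mass[heavy] / sum(df$mass[heavy])
    ctr <- c(sum(df$x[heavy] * w), sum(df$y[heavy] * w), sum(df$z[heavy] * w))
    shift <- anchors[[g]] - ctr
    df$x[in_grp] <- df$x[in_grp] + shift[1]
    df$y[in_grp] <- df$y[in_grp] + shift[2]
    df$z[in_grp] <- df$z[in_grp] + shift[3]
  }

  ## set the D3 sidechain-centroid distance exactly by translating residue 239
  sc_centroid <- function(resno) {
    sel <- df$resno == resno & df$element != "H" &
      !(df$atom_name %in% .backbone_names)
    w <- df$mass[sel] / sum(df$mass[sel])
    c(sum(df$x[sel] * w), sum(df$y[sel] * w), sum(df$z[sel] * w))
  }
  g183 <- sc_centroid(183); g239 <- sc_centroid(239)
  shift <- (g183 + d3 * .unit(g239 - g183)) - g239
  sel239 <- df$resno == 239
  df$x[sel239] <- df$x[sel239] + shift[1]
  df$y[sel239] <- df$y[sel239] + shift[2]
  df$z[sel239] <- df$z[sel239] + shift[3]

  ## hydrogen-bond triads: donor H at 1.0 A, acceptor at the bonded ("on")
  ## position 2.9 A from the donor heavy atom, collinear
  for (j in seq_along(.toy_pairs)) {
    p <- .toy_pairs[[j]]; u <- .toy_pair_dirs[[j]]
    d_idx <- which(df$resno == p$donor_res & df$atom_name == p$donor_atom)
    a_idx <- which(df$resno == p$acc_res & df$atom_name == p$acc_atom)
    stopifnot(length(d_idx) == 1L, length(a_idx) == 1L)
    dpos <- c(df$x[d_idx], df$y[d_idx], df$z[d_idx])
    hpos <- dpos + 1.0 * u
    apos <- dpos + 2.9 * u
    df[a_idx, c("x", "y", "z")] <- as.list(apos)
    rows_h <- data.frame(atom_name = p$h_atom, resname = df$resname[d_idx],
                         resno = p$donor_res, element = "H",
                         x = hpos[1], y = hpos[2], z = hpos[3],
                         mass = element_mass("H"), stringsAsFactors = FALSE)
    df <- rbind(df, rows_h)
  }
  df <- df[order(df$resno), , drop = FALSE]

  df$serial <- seq_len(nrow(df))
  df$chain <- "A"
  df$record <- "ATOM"
  s <- molecular_structure(df[, c("serial", "atom_name", "resname", "chain",
                                  "resno", "element", "mass", "x", "y", "z",
                                  "record")])
  attr(s, "toy_hinge") <- list(
    radius = R, phi1 = phi1, phi2 = phi2, d1_closed = d1_closed,
    d2_closed = d2_closed, clobe_resno = 270:428,
    theta_range = c(-phi1 + 1e-3, phi2 - 0.02))
  s
}

#' Synthetic stand-in for the SMYD3 crystal structure
#'
#' A toy structure calibrated, by construction, to the descriptor values of
#' the closed-state SMYD3 crystal structure (PDB 5EX0): D1 = 8.93, D2 =
#' 8.11, D3 = 7.70 Angstrom and tyrosine-239 CA-CB-CG-CD2 torsion 183.11
#' degrees. It is NOT the deposited structure (which cannot be redistributed
#' or fetched offline) but an independently constructed surrogate used to
#' verify that the measurement pipeline (parsing, selection resolution,
#' mass-weighted centroids, torsion evaluation) reproduces known geometry.
#'
#' @return a [molecular_structure()].
#' @export
synthetic_crystal_structure <- function() {
  cfg <- toy_model_config(centers = c(8.93, 10.5, 13.5))
  build_toy_structure(cfg, d2_closed = 8.11, d3 = 7.70, y239_torsion = 183.11)
}
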