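#' Dynamic cross-correlation map
#'
#' After superposing every frame onto the trajectory-average structure (see
#' [rmsf()] for the two-pass scheme), computes
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>) over the CA displacement
#' vectors dr from their mean positions. The matrix is symmetric with unit
#' diagonal and entries in [-1, 1]. Residues with zero positional variance
#' have undefined correlations; these are reported as 0 and flagged in the
#' `zero_variance` attribute.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param spec selection of residue-representative atoms (default: CAs).
#' @param fit_spec selection used for the superposition (default: `spec`);
#'   set `fit = FALSE` to skip fitting (for synthetic constructions).
#' @param fit superpose frames first? Default `TRUE`.
#' @return matrix of class `dccm` with residue labels as dimnames and a
#'   logical `zero_variance` attribute.
#' @export
dccm <- function(traj, spec = selection_spec(atom_names = "CA"),
                 fit_spec = spec, fit = TRUE) {
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames")
  top <- traj$topology
  sel <- resolve_selection(top, spec)
  if (length(sel) < 2L) stop("DCCM needs at least 2 residues")
  xyz <- if (fit) {
    .fit_all_frames(traj, resolve_selection(top, fit_spec), top$mass)
  } else traj$coords
  sub <- xyz[sel, , , drop = FALSE]            # n x 3 x F
  mean_pos <- apply(sub, c(1, 2), mean)
  dev <- sub - array(mean_pos, dim = dim(sub)) # displacement vectors
  n <- length(sel); nf <- dim(sub)[3]
  ## <dr_i . dr_j> = (1/F) sum_f sum_k dev[i,k,f] dev[j,k,f]
  flat <- matrix(aperm(dev, c(1, 3, 2)), nrow = n)  # n x (F*3)
  cov_ij <- flat %*% t(flat) / nf
  v <- diag(cov_ij)
  zero_var <- v <= 0 | !is.finite(v)
  denom <- sqrt(outer(pmax(v, .Machine$double.eps), pmax(v, .Machine$double.eps)))
  C <- cov_ij / denom
  C[zero_var, ] <- 0; C[, zero_var] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  labels <- paste0(top$chain[sel], top$resno[sel])
  dimnames(C) <- list(labels, labels)
  structure(C, zero_variance = zero_var, class = c("dccm", "matrix", "array"))
}

#' Export a DCCM as CSV
#'
#' Square matrix with residue labels as header row and first column.
#' @param x a [dccm()] matrix.
#' @param file output path.
#' @export
write_dccm_csv <- function(x, file) {
  df <- data.frame(residue = rownames(x),
                   apply(unclass(x), 2, .fmt_num),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

#' Geometric hydrogen-bond specification
#'
#' A residue-pair hydrogen bond: the pair is considered bonded in a frame if
#' ANY donor-candidate / acceptor-candidate atom combination between the two
#' residues, in either direction, satisfies the geometric criteria:
#' heavy-atom distance <= `distance_cutoff` and, in `"with-hydrogens"` mode,
#' some hydrogen covalently attached to the donor heavy atom (name-prefix
#' match within 1.2 Angstrom) with donor-H-acceptor angle >=
#' `angle_cutoff`. `"heavy-only"` mode applies the distance criterion alone
#' (the fallback for hydrogen-free crystal structures); `"auto"` picks
#' with-hydrogens when the structure contains any hydrogens.
#'
#' Candidate donor/acceptor heavy atoms default to all N, O and S atoms of
#' each residue.
#'
#' @param res_a,res_b residue numbers (or `c(chain, resno)` pairs given as
#'   lists `list(chain=, resno=)`).
#' @param label pair label, e.g. `"K42-E295"`.
#' @param distance_cutoff heavy-heavy distance cutoff, Angstrom (default 3.5).
#' @param angle_cutoff donor-H-acceptor angle cutoff, degrees (default 135).
#' @param mode `"auto"`, `"with-hydrogens"` or `"heavy-only"`.
#' @param donor_atoms,acceptor_atoms optional atom-name whitelists applied to
#'   the donor/acceptor candidates of either residue.
#' @return object of class `hbond_spec`.
#' @export
hbond_spec <- function(res_a, res_b, label = NULL,
                       distance_cutoff = 3.5, angle_cutoff = 135,
                       mode = c("auto", "with-hydrogens", "heavy-only"),
                       donor_atoms = NULL, acceptor_atoms = NULL) {
  mode <- match.arg(mode)
  if (distance_cutoff <= 0) stop("distance cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180)
    stop("angle cutoff must be in (0, 180]")
  norm_res <- function(r) if (is.list(r)) r else list(chain = NULL, resno = r)
  a <- norm_res(res_a); b <- norm_res(res_b)
  structure(list(res_a = a, res_b = b,
                 label = label %||% paste0(a$resno, "-", b$resno),
                 distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff, mode = mode,
                 donor_atoms = donor_atoms, acceptor_atoms = acceptor_atoms),
            class = "hbond_spec")
}

.residue_atoms <- function(top, res) {
  keep <- top$resno == res$resno
  if (!is.null(res$chain)) keep <- keep & top$chain == res$chain
  which(keep)
}

.polar_heavy <- function(top, idx) idx[toupper(top$element[idx]) %in% c("N", "O", "S")]

.attached_hydrogens <- function(top, frame, donor_idx) {
  ## hydrogens of the same residue whose name shares the donor's suffix and
  ## that sit within covalent range (<= 1.2 A) of the donor heavy atom
  res_idx <- which(top$resno == top$resno[donor_idx] &
                   top$chain == top$chain[donor_idx])
  h <- res_idx[toupper(top$element[res_idx]) == "H"]
  if (!length(h)) return(integer(0))
  d2 <- rowSums((frame[h, , drop = FALSE] -
                 matrix(frame[donor_idx, ], length(h), 3, byrow = TRUE))^2)
  h[d2 <= 1.2^2]
}

.angle_deg <- function(a, b, c) {
  ## angle at vertex b
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect a hydrogen bond in a single frame
#'
#' @param frame numeric `A x 3` coordinate matrix.
#' @param topology the `MolecularStructure` the frame belongs to.
#' @param spec an [hbond_spec()].
#' @return logical scalar.
#' @export
detect_hbond <- function(frame, topology, spec) {
  stopifnot(inherits(spec, "hbond_spec"))
  frame <- as.matrix(frame)
  ia <- .residue_atoms(topology, spec$res_a)
  ib <- .residue_atoms(topology, spec$res_b)
  if (!length(ia) || !length(ib))
    stop("hydrogen-bond pair ", spec$label, ": residue ",
         if (!length(ia)) spec$res_a$resno else spec$res_b$resno,
         " not found in topology")
  mode <- spec$mode
  if (mode == "auto") {
    mode <- if (any(toupper(topology$element) == "H")) "with-hydrogens" else "heavy-only"
  }
  filt <- function(idx, names) if (is.null(names)) idx else idx[topology$atom_name[idx] %in% names]
  ## either direction: (donor in a, acceptor in b) or (donor in b, acceptor in a)
  for (dir in 1:2) {
    don <- filt(.polar_heavy(topology, if (dir == 1) ia else ib), spec$donor_atoms)
    acc <- filt(.polar_heavy(topology, if (dir == 1) ib else ia), spec$acceptor_atoms)
    for (d in don) for (a in acc) {
      dist <- sqrt(sum((frame[d, ] - frame[a, ])^2))
      if (dist > spec$distance_cutoff) next
      if (mode == "heavy-only") return(TRUE)
      for (h in .attached_hydrogens(topology, frame, d)) {
        if (.angle_deg(frame[d, ], frame[h, ], frame[a, ]) >= spec$angle_cutoff)
          return(TRUE)
      }
    }
  }
  FALSE
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Occupancy is the exact percentage of frames in which the bond is formed:
#' `100 * sum(mask) / n_frames`. The per-frame presence mask is returned for
#' state-conditioned downstream analysis.
#'
#' @param traj a `Trajectory`.
#' @param spec an [hbond_spec()].
#' @return object of class `hbond_occupancy`: list with `label`, `occupancy`
#'   (percent) and logical `mask`.
#' @export
hbond_occupancy <- function(traj, spec) {
  mask <- vapply(seq_len(n_frames(traj)), function(f)
    detect_hbond(traj$coords[, , f], traj$topology, spec), logical(1))
  structure(list(label = spec$label,
                 occupancy = 100 * sum(mask) / length(mask),
                 mask = mask),
            class = "hbond_occupancy")
}

#' @export
print.hbond_occupancy <- function(x, ...) {
  cat(sprintf("<hbond_occupancy> %s: %.2f%% of %d frames\n",
              x$label, x$occupancy, length(x$mask)))
  invisible(x)
}

#' Deterministic 1-D k-means clustering with representative frames
#'
#' Clusters a descriptor series (typically RoG) into `k` groups by Lloyd's
#' algorithm with deterministic farthest-point seeding: the first seed is the
#' frame-1 value and each further seed is the value farthest from its nearest
#' existing seed (ties -> earliest frame). The representative of each cluster
#' is the frame whose value is nearest the cluster mean (ties -> earliest
#' frame) — the "center frame" used to depict a conformational state.
#'
#' @param series a [descriptor_series()] or numeric vector.
#' @param k number of clusters (>= 1, <= number of distinct values).
#' @param seed recorded for provenance; the algorithm itself is
#'   deterministic and consumes no random numbers.
#' @param max_iter,tol Lloyd iteration controls.
#' @return list with `labels` (per-frame cluster index, clusters ordered by
#'   ascending center), `centers`, `representatives` (frame indices) and
#'   `wcss` (within-cluster sum of squares).
#' @export
cluster_representative <- function(series, k, seed = 0L,
                                   max_iter = 100L, tol = 1e-6) {
  x <- as.numeric(series)
  if (k < 1L) stop("k must be >= 1")
  if (length(x) < k) stop("series shorter than k")
  if (length(unique(x)) < k)
    stop("degenerate clustering: k exceeds the number of distinct values")
  ## deterministic farthest-point seeding
  centers <- x[1]
  while (length(centers) < k) {
    dmin <- vapply(x, function(v) min(abs(v - centers)), numeric(1))
    centers <- c(centers, x[which.max(dmin)])
  }
  for (it in seq_len(max_iter)) {
    lab <- apply(abs(outer(x, centers, "-")), 1, which.min)
    new_centers <- vapply(seq_len(k), function(j)
      if (any(lab == j)) mean(x[lab == j]) else centers[j], numeric(1))
    if (max(abs(new_centers - centers)) < tol) { centers <- new_centers; break }
    centers <- new_centers
  }
  ord <- order(centers)
  relabel <- match(seq_len(k), ord)
  lab <- relabel[lab]
  centers <- centers[ord]
  reps <- vapply(seq_len(k), function(j) {
    idx <- which(lab == j)
    idx[which.min(abs(x[idx] - centers[j]))]
  }, integer(1))
  wcss <- sum((x - centers[lab])^2)
  list(labels = lab, centers = centers, representatives = reps,
       wcss = wcss, seed = seed)
}
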