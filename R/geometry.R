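#' Optimal rigid-body superposition (weighted Kabsch)
#'
#' Finds the proper rotation and translation minimizing the weighted sum of
#' squared deviations between the mobile and reference frames over the fit
#' selection. Reflections are excluded (det(R) = +1), so the result is always
#' a physical rigid motion.
#'
#' @param mobile,reference numeric `A x 3` coordinate matrices.
#' @param fit_sel integer atom indices used for the fit (default: all atoms).
#' @param weights per-fit-atom weights, typically masses (default: equal).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `fitted` (all mobile atoms transformed) and `rmsd` (weighted, over the
#'   fit selection, Angstrom). The transform maps mobile coordinates as
#'   `x %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, fit_sel = NULL, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(mobile))
  if (length(fit_sel) < 3L) stop("superposition needs at least 3 fit atoms")
  X <- mobile[fit_sel, , drop = FALSE]
  Y <- reference[fit_sel, , drop = FALSE]
  if (nrow(X) != nrow(Y)) stop("fit selections differ in length")
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  if (length(w) != nrow(X)) stop("weights length must match fit selection")
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (!is.finite(d) || d == 0) stop("degenerate fit configuration (collinear atoms?)")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cy - as.vector(R %*% cx)
  fitted <- mobile %*% t(R) + matrix(trans, nrow(mobile), 3, byrow = TRUE)
  dev <- fitted[fit_sel, , drop = FALSE] - Y
  fit_rmsd <- sqrt(sum(w * rowSums(dev^2)))
  ## guard against silent collinearity: rank-deficient covariance means the
  ## rotation about the degenerate axis is arbitrary
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate fit configuration (collinear atoms?)")
  list(rotation = R, translation = trans, fitted = fitted, rmsd = fit_rmsd)
}

#' Mass-weighted RMSD between two frames
#'
#' RMSD = sqrt( sum_i m_i |X_i - Y_i|^2 / M ) over the selection, with
#' M = sum_i m_i. With `fit = TRUE` (the default) the mobile frame is first
#' superposed onto the reference by a mass-weighted Kabsch fit on the same
#' selection, the standard convention of trajectory RMSD analysis; without
#' fitting the RMSD conflates rigid diffusion with conformational change.
#'
#' @param x,y numeric `A x 3` coordinate matrices (mobile, reference).
#' @param sel integer atom indices (default: all atoms).
#' @param masses per-atom masses for all atoms of the frame (amu); default
#'   equal weights.
#' @param fit superpose before measuring?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(x, y, sel = NULL, masses = NULL, fit = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(sel)) sel <- seq_len(nrow(x))
  if (length(sel) == 0L) stop("empty selection in rmsd()")
  m <- if (is.null(masses)) rep(1, nrow(x)) else masses
  if (any(m[sel] <= 0)) stop("non-positive masses in rmsd()")
  if (fit) {
    x <- superpose(x, y, fit_sel = sel, weights = m[sel])$fitted
  }
  dev <- x[sel, , drop = FALSE] - y[sel, , drop = FALSE]
  sqrt(sum(m[sel] * rowSums(dev^2)) / sum(m[sel]))
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of the selected atoms from their mass-weighted
#' centroid; the global compactness measure of a conformation.
#'
#' @inheritParams rmsd
#' @param frame numeric `A x 3` coordinate matrix.
#' @return RoG in Angstrom.
#' @export
radius_of_gyration <- function(frame, sel = NULL, masses = NULL) {
  frame <- as.matrix(frame)
  if (is.null(sel)) sel <- seq_len(nrow(frame))
  if (length(sel) == 0L) stop("empty selection in radius_of_gyration()")
  m <- if (is.null(masses)) rep(1, nrow(frame)) else masses
  X <- frame[sel, , drop = FALSE]
  w <- m[sel] / sum(m[sel])
  ctr <- colSums(X * w)
  sqrt(sum(w * rowSums(sweep(X, 2, ctr)^2)))
}

.centroid <- function(frame, sel, masses, weighting) {
  X <- frame[sel, , drop = FALSE]
  if (weighting == "geometric") return(colMeans(X))
  w <- masses[sel] / sum(masses[sel])
  colSums(X * w)
}

#' Distance between two group centroids
#'
#' Euclidean distance between the (mass-weighted or geometric) centroids of
#' two atom groups; the machinery behind the D1/D2/D3 inter-domain distances.
#'
#' @param frame numeric `A x 3` coordinate matrix.
#' @param sel_a,sel_b integer atom index vectors for the two groups.
#' @param masses per-atom masses (amu) for all atoms of the frame.
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @param label optional name reported in error messages (e.g. a preset id).
#' @return distance in Angstrom.
#' @export
group_distance <- function(frame, sel_a, sel_b, masses = NULL,
                           weighting = c("mass", "geometric"), label = NULL) {
  weighting <- match.arg(weighting)
  frame <- as.matrix(frame)
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop("empty selection in group_distance()",
         if (!is.null(label)) paste0(" for preset '", label, "'") else "")
  m <- if (is.null(masses)) rep(1, nrow(frame)) else masses
  sqrt(sum((.centroid(frame, sel_a, m, weighting) -
            .centroid(frame, sel_b, m, weighting))^2))
}

#' Torsion angle of four atoms, in degrees on [0, 360)
#'
#' Signed dihedral about the b-c axis mapped into the [0, 360) range, so that
#' flipped sidechain rotamers near 270 degrees are representable without a
#' branch cut at 180.
#'
#' @param frame numeric `A x 3` coordinate matrix.
#' @param idx integer vector of four distinct atom indices (a, b, c, d).
#' @return angle in degrees, in [0, 360).
#' @export
dihedral_angle <- function(frame, idx) {
  frame <- as.matrix(frame)
  if (length(idx) != 4L || anyDuplicated(idx)) stop("need four distinct atom indices")
  p <- frame[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("degenerate dihedral geometry (collinear atom triple)")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / nb, sum(n1 * n2)) * 180 / pi
  ang %% 360
}
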