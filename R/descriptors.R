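#' Per-frame descriptor series
#'
#' A named scalar time series over trajectory frames, carrying its units and
#' the frame interval so time axes and CSV exports are unambiguous.
#'
#' @param name descriptor name (e.g. `"d1"`, `"rog"`, `"dihedral_y239"`).
#' @param values numeric per-frame values; must be finite.
#' @param units `"angstrom"` or `"degrees"`.
#' @param frame_interval_ps frame spacing, ps.
#' @return object of class `descriptor_series` (a numeric vector with
#'   attributes).
#' @export
descriptor_series <- function(name, values, units = c("angstrom", "degrees"),
                              frame_interval_ps = 10) {
  units <- match.arg(units)
  if (!all(is.finite(values))) stop("non-finite values in descriptor series '", name, "'")
  structure(as.numeric(values), name = name, units = units,
            frame_interval_ps = frame_interval_ps,
            class = c("descriptor_series", "numeric"))
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat("<descriptor_series> ", attr(x, "name"), " [", attr(x, "units"), "], ",
      length(x), " frames @ ", attr(x, "frame_interval_ps"), " ps\n", sep = "")
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Export a descriptor series as CSV
#'
#' Columns `frame_index` (1-based), `time_ps`, and a value column named
#' `<name>_<units>`. Numeric values are written with 6 significant digits so
#' re-runs are byte-identical.
#'
#' @param series a [descriptor_series()].
#' @param file output path.
#' @export
write_series_csv <- function(series, file) {
  stopifnot(inherits(series, "descriptor_series"))
  dt <- attr(series, "frame_interval_ps")
  df <- data.frame(
    frame_index = seq_along(series),
    time_ps = .fmt_num((seq_along(series) - 1) * dt),
    value = .fmt_num(as.numeric(series)))
  names(df)[3] <- paste0(attr(series, "name"), "_", attr(series, "units"))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

.fmt_num <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

.traj_apply <- function(traj, fun) {
  vapply(seq_len(n_frames(traj)),
         function(f) fun(matrix(traj$coords[, , f], ncol = 3)), numeric(1))
}

#' Trajectory-level descriptors
#'
#' Convenience wrappers that evaluate the frame-level geometry operations
#' along a whole trajectory and return a [descriptor_series()].
#'
#' `traj_group_distance()` evaluates a centroid-centroid distance (see
#' [group_distance()]); `traj_preset_distance()` does so for the built-in
#' D1/D2/D3 presets; `traj_rog()` the radius of gyration; `traj_rmsd()` the
#' mass-weighted RMSD against a reference frame (after per-frame Kabsch
#' fitting by default); `traj_dihedral()` a named torsion.
#'
#' @param traj a `Trajectory`.
#' @param spec_a,spec_b [selection_spec()]s for the two groups.
#' @param weighting `"mass"` or `"geometric"` centroids.
#' @param name series name.
#' @return a [descriptor_series()].
#' @export
traj_group_distance <- function(traj, spec_a, spec_b,
                                weighting = "mass", name = "distance") {
  top <- traj$topology
  ia <- resolve_selection(top, spec_a)
  ib <- resolve_selection(top, spec_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty selection in traj_group_distance() for '", name, "'")
  vals <- .traj_apply(traj, function(fr)
    group_distance(fr, ia, ib, top$mass, weighting, label = name))
  descriptor_series(name, vals, "angstrom", traj$frame_interval_ps)
}

#' @rdname traj_group_distance
#' @param preset one of `"d1"`, `"d2"`, `"d3"`.
#' @param chain optional chain restriction.
#' @export
traj_preset_distance <- function(traj, preset = c("d1", "d2", "d3"),
                                 chain = NULL, weighting = "mass") {
  preset <- match.arg(preset)
  ps <- preset_distance_selections(chain)[[preset]]
  traj_group_distance(traj, ps$a, ps$b, weighting, name = preset)
}

#' @rdname traj_group_distance
#' @param spec selection for the RoG atoms (default: heavy protein atoms).
#' @export
traj_rog <- function(traj, spec = selection_spec(class = "heavy")) {
  top <- traj$topology
  sel <- resolve_selection(top, spec)
  if (length(sel) == 0L) stop("empty selection in traj_rog()")
  vals <- .traj_apply(traj, function(fr) radius_of_gyration(fr, sel, top$mass))
  descriptor_series("rog", vals, "angstrom", traj$frame_interval_ps)
}

#' @rdname traj_group_distance
#' @param ref reference frame index (default 1).
#' @param spec selection for the RMSD atoms (default: CA atoms).
#' @param fit superpose each frame onto the reference first?
#' @export
traj_rmsd <- function(traj, ref = 1L,
                      spec = selection_spec(atom_names = "CA"), fit = TRUE) {
  top <- traj$topology
  sel <- resolve_selection(top, spec)
  if (length(sel) == 0L) stop("empty selection in traj_rmsd()")
  refxyz <- frame_coords(traj, ref)
  vals <- .traj_apply(traj, function(fr)
    rmsd(fr, refxyz, sel, top$mass, fit = fit))
  descriptor_series("rmsd", vals, "angstrom", traj$frame_interval_ps)
}

#' @rdname traj_group_distance
#' @param resno residue number of the torsion.
#' @param atoms four atom names, in order (default the tyrosine
#'   CA-CB-CG-CD2 sidechain torsion).
#' @export
traj_dihedral <- function(traj, resno, atoms = c("CA", "CB", "CG", "CD2"),
                          chain = NULL, name = NULL) {
  top <- traj$topology
  idx <- vapply(atoms, function(a) {
    i <- resolve_selection(top, selection_spec(chain, resno, atom_names = a))
    if (length(i) != 1L)
      stop("residue ", resno, " atom ", a, ": found ", length(i), " matches")
    i
  }, integer(1))
  vals <- .traj_apply(traj, function(fr) dihedral_angle(fr, idx))
  descriptor_series(name %||% paste0("dihedral_", resno), vals, "degrees",
                    traj$frame_interval_ps)
}

#' Per-residue root mean square fluctuation
#'
#' Each frame is superposed onto the trajectory-average structure using a
#' two-pass scheme (fit all frames to frame 1, average, refit to the
#' average), then the RMSF of each residue's CA atom about its mean position
#' is reported. Rigid global motion therefore contributes nothing.
#'
#' @param traj a `Trajectory`.
#' @param spec selection providing the per-residue representative atoms;
#'   must resolve to CA atoms (default: all CAs).
#' @param fit_spec selection used for the superposition fit (default: same
#'   as `spec`).
#' @return data frame with columns `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, spec = selection_spec(atom_names = "CA"),
                 fit_spec = spec) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  top <- traj$topology
  sel <- resolve_selection(top, spec)
  if (length(sel) == 0L || !all(top$atom_name[sel] == "CA"))
    stop("RMSF selection must resolve to CA atoms")
  fit_sel <- resolve_selection(top, fit_spec)
  fitted <- .fit_all_frames(traj, fit_sel, top$mass)
  sub <- fitted[sel, , , drop = FALSE]
  mean_pos <- apply(sub, c(1, 2), mean)
  dev2 <- apply((sub - array(mean_pos, dim = dim(sub)))^2, c(1, 3), sum)
  data.frame(chain = top$chain[sel], resno = top$resno[sel],
             rmsf = sqrt(rowMeans(dev2)))
}

## Two-pass fit: frames -> frame 1, average, frames -> average.
## Returns an A x 3 x F array of fitted coordinates.
.fit_all_frames <- function(traj, fit_sel, masses) {
  nf <- n_frames(traj)
  w <- masses[fit_sel]
  out <- array(NA_real_, dim = dim(traj$coords))
  ref <- traj$coords[, , 1]
  for (f in seq_len(nf))
    out[, , f] <- superpose(traj$coords[, , f], ref, fit_sel, w)$fitted
  avg <- apply(out, c(1, 2), mean)
  for (f in seq_len(nf))
    out[, , f] <- superpose(traj$coords[, , f], avg, fit_sel, w)$fitted
  out
}
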