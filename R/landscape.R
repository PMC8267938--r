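#' Free-energy landscape by Boltzmann inversion
#'
#' Bins the sampled descriptor(s) into a normalized (joint) histogram g and
#' inverts it: dG = -kB T ln g on occupied bins, then shifts so the minimum
#' over occupied bins is exactly zero. Empty bins are flagged and carry +Inf;
#' they are never silently capped (capping fabricates barrier heights).
#' kB = 0.0019872041 kcal/(mol K). One-dimensional profiles are produced when
#' `y` is absent.
#'
#' @param x a [descriptor_series()] or numeric vector (first axis).
#' @param y optional second series of equal length (second axis).
#' @param bin_width bin width in the descriptor units (default 0.1 Angstrom,
#'   the conventional choice for distance/RMSD axes).
#' @param temperature simulation temperature, K (default 300).
#' @return object of class `pmf_grid`: list with `axes` (names), `mids`
#'   (bin centers per axis), `breaks`, `dG` (vector or matrix, kcal/mol,
#'   +Inf on empty bins), `occupied` (logical mask), `counts`,
#'   `temperature`, `bin_width`.
#' @export
pmf <- function(x, y = NULL, bin_width = 0.1, temperature = 300) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  xv <- as.numeric(x)
  if (!length(xv)) stop("pmf needs at least one sample")
  axes <- c(if (inherits(x, "descriptor_series")) attr(x, "name") else "x",
            if (!is.null(y)) {
              if (inherits(y, "descriptor_series")) attr(y, "name") else "y"
            })
  brk <- function(v) {
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi + bin_width / 2, by = bin_width)
  }
  bx <- brk(xv)
  ix <- findInterval(xv, bx, rightmost.closed = TRUE)
  if (is.null(y)) {
    counts <- tabulate(ix, nbins = length(bx) - 1L)
  } else {
    yv <- as.numeric(y)
    if (length(yv) != length(xv)) stop("x and y series differ in length")
    by <- brk(yv)
    iy <- findInterval(yv, by, rightmost.closed = TRUE)
    counts <- matrix(0L, length(bx) - 1L, length(by) - 1L)
    tab <- table(factor(ix, levels = seq_len(nrow(counts))),
                 factor(iy, levels = seq_len(ncol(counts))))
    counts <- matrix(as.integer(tab), nrow(counts), ncol(counts))
  }
  g <- counts / sum(counts)
  occupied <- counts > 0L
  dG <- ifelse(occupied, -kB_kcal * temperature * log(pmax(g, .Machine$double.xmin)), Inf)
  dG <- dG - min(dG[occupied])
  mids <- list(bx[-1] - bin_width / 2)
  breaks <- list(bx)
  if (!is.null(y)) { mids <- c(mids, list(by[-1] - bin_width / 2)); breaks <- c(breaks, list(by)) }
  names(mids) <- names(breaks) <- axes
  structure(list(axes = axes, mids = mids, breaks = breaks, dG = dG,
                 occupied = occupied, counts = counts,
                 temperature = temperature, bin_width = bin_width),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("<pmf_grid> ", paste(x$axes, collapse = " x "), ", ",
      sum(x$occupied), "/", length(x$occupied), " occupied bins, T = ",
      x$temperature, " K, bin width ", x$bin_width, "\n", sep = "")
  cat("  dG range on occupied bins: 0 to ",
      .fmt_num(max(x$dG[x$occupied])), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Export a PMF grid as long-format CSV plus a JSON sidecar
#'
#' CSV columns: bin centers per axis, `dG_kcal_mol` (blank on empty bins)
#' and `occupied`. The sidecar records axes, temperature and bin width.
#'
#' @param grid a [pmf()] result.
#' @param file CSV path; the sidecar is written next to it as
#'   `<file>.meta.json`.
#' @export
write_pmf_csv <- function(grid, file) {
  stopifnot(inherits(grid, "pmf_grid"))
  if (length(grid$axes) == 1L) {
    df <- data.frame(grid$mids[[1]],
                     dG_kcal_mol = ifelse(grid$occupied, .fmt_num(grid$dG), ""),
                     occupied = grid$occupied)
    names(df)[1] <- grid$axes[1]
  } else {
    idx <- expand.grid(i = seq_along(grid$mids[[1]]), j = seq_along(grid$mids[[2]]))
    df <- data.frame(grid$mids[[1]][idx$i], grid$mids[[2]][idx$j],
                     dG_kcal_mol = ifelse(grid$occupied[cbind(idx$i, idx$j)],
                                          .fmt_num(grid$dG[cbind(idx$i, idx$j)]), ""),
                     occupied = grid$occupied[cbind(idx$i, idx$j)])
    names(df)[1:2] <- grid$axes
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  meta <- list(axes = grid$axes, temperature_K = grid$temperature,
               bin_width = grid$bin_width,
               boltzmann_constant_kcal_mol_K = kB_kcal)
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Closed / intermediate / open state partition of the hinge distance
#'
#' An ordered labelled partition of [0, Inf): closed [0, b1), intermediate
#' [b1, b2), open [b2, Inf). The default boundaries 9.5 and 12.0 Angstrom are
#' the midpoints of the gaps between the observed state centers (~8-9,
#' ~10-11, ~13-14 Angstrom) of the SMYD3 hinge distance D1.
#'
#' @param boundaries numeric `c(b1, b2)`, Angstrom, `b1 < b2`.
#' @param labels three state names, low to high.
#' @return object of class `state_definition`.
#' @export
state_definition <- function(boundaries = c(9.5, 12.0),
                             labels = c("closed", "intermediate", "open")) {
  if (length(boundaries) != length(labels) - 1L)
    stop("need one fewer boundary than labels")
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("state boundaries must be strictly increasing")
  structure(list(boundaries = boundaries, labels = labels),
            class = "state_definition")
}

#' Assign frames to conformational states
#'
#' Each frame receives the label of the interval containing its distance
#' value; boundary values belong to the upper interval (half-open
#' convention).
#'
#' @param series a [descriptor_series()] or numeric vector of distances
#'   (Angstrom, non-negative).
#' @param states a [state_definition()].
#' @return factor of per-frame labels with the state names as levels.
#' @export
classify_states <- function(series, states = state_definition()) {
  x <- as.numeric(series)
  if (any(x < 0)) stop("negative distances cannot be classified")
  idx <- findInterval(x, states$boundaries) + 1L  # boundary -> upper interval
  factor(states$labels[idx], levels = states$labels)
}

#' Per-state occupancy table
#'
#' Exact frame fractions per state, as percentages summing to 100. States
#' with no frames are reported as 0.
#'
#' @param labels factor of per-frame state labels (from
#'   [classify_states()] or a generator's ground truth).
#' @return object of class `state_occupancy`: data frame with columns
#'   `state`, `frames`, `percent`.
#' @export
occupancy_table <- function(labels) {
  labels <- as.factor(labels)
  if (!length(labels)) stop("occupancy table needs at least one frame")
  counts <- table(labels)
  df <- data.frame(state = names(counts),
                   frames = as.integer(counts),
                   percent = 100 * as.integer(counts) / length(labels))
  structure(df, class = c("state_occupancy", "data.frame"))
}

#' Free-energy difference between two states from their populations
#'
#' dG(a -> b) = -kB T ln(p_b / p_a): the population-ratio companion of
#' Boltzmann inversion.
#'
#' @param occupancy a [occupancy_table()] result.
#' @param state_a,state_b state names.
#' @param temperature K (default 300).
#' @return kcal/mol.
#' @export
state_free_energy_difference <- function(occupancy, state_a, state_b,
                                         temperature = 300) {
  p <- function(s) {
    row <- occupancy$percent[occupancy$state == s]
    if (!length(row)) stop("state '", s, "' not present in occupancy table")
    row
  }
  pa <- p(state_a); pb <- p(state_b)
  if (pa == 0 || pb == 0)
    stop("undefined ratio: state '", if (pa == 0) state_a else state_b,
         "' has zero occupancy")
  -kB_kcal * temperature * log(pb / pa)
}
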