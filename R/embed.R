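#' Map a D1 series onto 3-D coordinates of the toy structure
#'
#' For each frame the C-lobe is rigidly rotated about the hinge so that the
#' D1 preset distance, recomputed from the coordinates, reproduces the input
#' value; the hinge angle is solved by bisection to 1e-6 Angstrom. The
#' clamshell geometry guarantees D2 varies oppositely to D1. Scheduled
#' hydrogen-bond pairs have their acceptor atom placed inside (2.9 Angstrom,
#' collinear) or outside (6.5 Angstrom) the detection criteria per frame.
#'
#' @param structure a structure from [build_toy_structure()] (carries the
#'   `toy_hinge` attribute).
#' @param d1 target D1 values per frame, Angstrom (a
#'   [descriptor_series()] or numeric vector).
#' @param hbond_schedule optional named list of logical per-frame vectors,
#'   one per pair label of [toy_hbond_pairs()]; `TRUE` means the bond is
#'   formed in that frame.
#' @param labels optional ground-truth state labels to carry along.
#' @param frame_interval_ps frame spacing; defaults to the series attribute
#'   or 10 ps.
#' @param seed seed record carried into the bundle metadata.
#' @return object of class `toy_bundle`: list with `trajectory`, `d1`
#'   (ground truth), `labels`, `hbond_schedule`, `seed`.
#' @export
embed_d1_to_coordinates <- function(structure, d1, hbond_schedule = NULL,
                                    labels = NULL, frame_interval_ps = NULL,
                                    seed = NA_integer_) {
  hinge <- attr(structure, "toy_hinge")
  if (is.null(hinge)) stop("structure lacks hinge metadata; build it with build_toy_structure()")
  d1v <- as.numeric(d1)
  nf <- length(d1v)
  if (!nf) stop("empty D1 series")
  dtps <- frame_interval_ps %||%
    (if (inherits(d1, "descriptor_series")) attr(d1, "frame_interval_ps") else 10)

  ps <- preset_distance_selections()
  ia <- resolve_selection(structure, ps$d1$a)
  ib <- resolve_selection(structure, ps$d1$b)
  m <- structure$mass
  base <- coords(structure)
  wa <- m[ia] / sum(m[ia]); wb <- m[ib] / sum(m[ib])
  ga <- colSums(base[ia, , drop = FALSE] * wa)
  gb <- colSums(base[ib, , drop = FALSE] * wb)
  d1_of <- function(theta) sqrt(sum((.rz(theta) %*% gb - ga)^2))

  rng <- hinge$theta_range
  lo_d <- d1_of(rng[1]); hi_d <- d1_of(rng[2])
  if (any(d1v < lo_d - 1e-9) || any(d1v > hi_d + 1e-9))
    stop(sprintf("requested D1 outside the hinge's reachable range [%.3f, %.3f]",
                 lo_d, hi_d))

  solve_theta <- function(target) {
    lo <- rng[1]; hi <- rng[2]
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      val <- d1_of(mid)
      if (abs(val - target) < 1e-7) return(mid)
      if (val < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  clobe <- which(structure$resno %in% hinge$clobe_resno)
  if (!is.null(hbond_schedule)) {
    known <- vapply(.toy_pairs, `[[`, character(1), "label")
    bad <- setdiff(names(hbond_schedule), known)
    if (length(bad)) stop("unknown hydrogen-bond pair(s) in schedule: ",
                          paste(bad, collapse = ", "))
    for (v in hbond_schedule) if (length(v) != nf)
      stop("hydrogen-bond schedule length differs from the D1 series")
  }
  sched_idx <- lapply(names(hbond_schedule %||% list()), function(lbl) {
    p <- .toy_pairs[[match(lbl, vapply(.toy_pairs, `[[`, character(1), "label"))]]
    list(d = which(structure$resno == p$donor_res & structure$atom_name == p$donor_atom),
         a = which(structure$resno == p$acc_res & structure$atom_name == p$acc_atom),
         u = .toy_pair_dirs[[match(lbl, vapply(.toy_pairs, `[[`, character(1), "label"))]],
         on = hbond_schedule[[lbl]])
  })

  xyz <- array(NA_real_, dim = c(nrow(base), 3L, nf))
  for (f in seq_len(nf)) {
    th <- solve_theta(d1v[f])
    fr <- base
    fr[clobe, ] <- base[clobe, , drop = FALSE] %*% t(.rz(th))
    for (sc in sched_idx) {
      dist <- if (sc$on[f]) 2.9 else 6.5
      fr[sc$a, ] <- fr[sc$d, ] + dist * sc$u
    }
    xyz[, , f] <- fr
  }
  res <- list(trajectory = trajectory(structure, xyz, dtps),
              d1 = descriptor_series("d1", d1v, "angstrom", dtps),
              labels = labels, hbond_schedule = hbond_schedule,
              seed = seed)
  class(res) <- "toy_bundle"
  res
}

#' @export
print.toy_bundle <- function(x, ...) {
  cat("<toy_bundle> ", n_frames(x$trajectory), " frames, D1 range ",
      .fmt_num(min(x$d1)), "-", .fmt_num(max(x$d1)), " A",
      if (!is.null(x$hbond_schedule))
        paste0(", ", length(x$hbond_schedule), " scheduled H-bond pair(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Deterministic D1 series from a state-label schedule
#'
#' Places each frame exactly at its state's well center — the degenerate
#' (noise-free) generator used when exact occupancies are required.
#'
#' @param labels character or factor vector of `closed` / `intermediate` /
#'   `open` labels.
#' @param config a [toy_model_config()] providing the well centers.
#' @return a [descriptor_series()].
#' @export
d1_series_from_states <- function(labels, config = toy_model_config()) {
  lv <- c("closed", "intermediate", "open")
  idx <- match(as.character(labels), lv)
  if (anyNA(idx)) stop("labels must be closed/intermediate/open")
  descriptor_series("d1", config$centers[idx], "angstrom",
                    frame_interval_ps = config$timestep * config$stride)
}

#' Generate a complete synthetic trajectory bundle
#'
#' Convenience wrapper: simulate Langevin dynamics on the triple well, embed
#' the resulting D1 series into the toy structure, and attach a
#' hydrogen-bond schedule. This is the generator used to exercise the full
#' analysis pipeline at desk scale.
#'
#' @param config a [toy_model_config()].
#' @param n_frames number of frames in the bundle.
#' @param hbond_schedule optional schedule (see
#'   [embed_d1_to_coordinates()]); default: all five pairs toggled by simple
#'   deterministic duty cycles (50%, alternating).
#' @param x0 initial position for the Langevin run.
#' @return a `toy_bundle`.
#' @export
generate_toy_bundle <- function(config = toy_model_config(), n_frames = 500,
                                hbond_schedule = NULL,
                                x0 = config$centers[1]) {
  sim <- simulate_langevin_d1(config, n_frames * config$stride, x0 = x0)
  s <- build_toy_structure(config)
  d1 <- sim$series
  ## clamp into the reachable hinge range (thermal excursions only)
  hinge <- attr(s, "toy_hinge")
  if (is.null(hbond_schedule)) {
    labs <- vapply(.toy_pairs, `[[`, character(1), "label")
    hbond_schedule <- stats::setNames(lapply(seq_along(labs), function(j)
      (seq_len(length(d1)) + j) %% 2L == 0L), labs)
  }
  embed_d1_to_coordinates(s, d1, hbond_schedule, labels = sim$labels,
                          seed = config$seed)
}
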