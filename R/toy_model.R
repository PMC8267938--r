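#' Three-state toy model configuration
#'
#' Parameters of the one-dimensional triple-well model of the hinge-opening
#' distance (the D1 coordinate) and of the overdamped Langevin dynamics on
#' it. The defaults state the world the analysis assumes: well centers at
#' 8.5 / 10.5 / 13.5 Angstrom (the observed closed / intermediate / open
#' state centers), closed and intermediate wells degenerate at 0 kcal/mol
#' with the open well 0.5 kcal/mol higher, barrier tops 1.5 kcal/mol, 300 K.
#'
#' The potential is a C1 piecewise-quadratic triple well: each well is a
#' parabola with minimum `well_energies[i]` at `centers[i]`, each barrier an
#' inverted parabola with apex `barrier_energies[j]` exactly midway between
#' neighbouring centers, and the pieces join with matching value and slope a
#' quarter-spacing from each stationary point. The outermost well arms
#' continue upward indefinitely, confining the dynamics. Because the barrier
#' apices sit at the midpoints, the generator's ground-truth basin boundaries
#' coincide with the default [state_definition()] boundaries (9.5, 12.0).
#'
#' @param centers well centers, Angstrom, strictly increasing.
#' @param well_energies absolute well minima, kcal/mol.
#' @param barrier_energies barrier apex energies, kcal/mol (one fewer than
#'   wells; each must exceed both neighbouring well energies).
#' @param temperature K.
#' @param friction friction coefficient of the overdamped integrator,
#'   ps^-1 (reduced units; the mobility is 1/friction).
#' @param timestep integration timestep, ps.
#' @param stride save every `stride`-th step as a frame.
#' @param seed integer RNG seed recorded with every output.
#' @return object of class `toy_model_config`.
#' @export
toy_model_config <- function(centers = c(8.5, 10.5, 13.5),
                             well_energies = c(0, 0, 0.5),
                             barrier_energies = c(1.5, 1.5),
                             temperature = 300, friction = 5,
                             timestep = 0.05, stride = 20L, seed = 1L) {
  if (is.unsorted(centers, strictly = TRUE)) stop("well centers must be strictly increasing")
  if (length(well_energies) != length(centers)) stop("one well energy per center")
  if (length(barrier_energies) != length(centers) - 1L)
    stop("need one barrier between each pair of wells")
  for (j in seq_along(barrier_energies)) {
    if (barrier_energies[j] <= max(well_energies[j], well_energies[j + 1]))
      stop("barrier ", j, " does not exceed its neighbouring wells")
  }
  if (temperature <= 0 || friction <= 0 || timestep <= 0) stop("temperature, friction and timestep must be positive")
  cfg <- list(centers = centers, well_energies = well_energies,
              barrier_energies = barrier_energies, temperature = temperature,
              friction = friction, timestep = timestep,
              stride = as.integer(stride), seed = as.integer(seed))
  pot <- .build_triple_well(cfg)
  ## timestep stability: dt * max curvature / friction must stay well below 2
  if (timestep * max(pot$kappa) / friction >= 2)
    stop("unstable timestep: timestep * stiffness / friction >= 2")
  cfg$potential <- pot
  structure(cfg, class = "toy_model_config")
}

## Piecewise-quadratic triple well. Segments alternate well-arm / barrier-arm;
## each (well i, barrier j) half-pair shares curvature
## kappa = (M_j - m_i) / q^2 with q a quarter of the center-to-apex distance,
## which makes value and slope continuous at the join. Segment table:
## for x in [knots[s], knots[s+1]): U = e0[s] + 0.5 * sgn[s] * k[s] * (x - ref[s])^2
.build_triple_well <- function(cfg) {
  cc <- cfg$centers; m <- cfg$well_energies; M <- cfg$barrier_energies
  nb <- length(M)
  apex <- (cc[-length(cc)] + cc[-1]) / 2
  qL <- (apex - cc[-length(cc)]) / 2      # join offset on the left well side
  qR <- (cc[-1] - apex) / 2               # join offset on the right well side
  kL <- (M - m[-length(m)]) / qL^2        # curvature shared by well j / barrier j left
  kR <- (M - m[-1]) / qR^2                # curvature shared by barrier j right / well j+1
  ## segment s covers [bounds[s-1], bounds[s]):
  ## U = e0[s] + 0.5 * sgn[s] * k[s] * (x - ref[s])^2
  ref <- cc[1]; k <- kL[1]; sgn <- 1; e0 <- m[1]; bounds <- numeric(0)
  for (j in seq_len(nb)) {
    bounds <- c(bounds, apex[j] - qL[j], apex[j], apex[j] + qR[j])
    ref <- c(ref, apex[j], apex[j], cc[j + 1])
    k   <- c(k, kL[j], kR[j], kR[j])
    sgn <- c(sgn, -1, -1, 1)
    e0  <- c(e0, M[j], M[j], m[j + 1])
    if (j < nb) {  # split the interior well at its center
      bounds <- c(bounds, cc[j + 1])
      ref <- c(ref, cc[j + 1]); k <- c(k, kL[j + 1])
      sgn <- c(sgn, 1); e0 <- c(e0, m[j + 1])
    }
  }
  U <- function(x) {
    s <- findInterval(x, bounds) + 1L
    e0[s] + 0.5 * sgn[s] * k[s] * (x - ref[s])^2
  }
  dU <- function(x) {
    s <- findInterval(x, bounds) + 1L
    sgn[s] * k[s] * (x - ref[s])
  }
  list(U = U, dU = dU, kappa = k, apex = apex,
       seg_breaks = c(-Inf, bounds, Inf), basin_breaks = apex)
}

#' Evaluate the toy triple-well potential
#'
#' @param config a [toy_model_config()].
#' @param x positions, Angstrom.
#' @return potential energy, kcal/mol (vectorized).
#' @export
toy_potential <- function(config, x) config$potential$U(x)

#' @rdname toy_potential
#' @export
toy_potential_gradient <- function(config, x) config$potential$dU(x)

#' Boltzmann basin weights of the toy potential
#'
#' Numerically integrates exp(-U/kBT) over each basin (watershed partition
#' at the barrier apices) — the analytic ground truth the unbiased Langevin
#' occupancies must converge to.
#'
#' @param config a [toy_model_config()].
#' @param pad how far beyond the outer centers to integrate, Angstrom.
#' @return named numeric vector of basin probabilities summing to 1, named
#'   `closed`, `intermediate`, `open` for the three-well case.
#' @export
boltzmann_basin_weights <- function(config, pad = 6) {
  kT <- kB_kcal * config$temperature
  lims <- c(config$centers[1] - pad, config$potential$basin_breaks,
            config$centers[length(config$centers)] + pad)
  z <- vapply(seq_len(length(lims) - 1L), function(i)
    stats::integrate(function(x) exp(-config$potential$U(x) / kT),
                     lims[i], lims[i + 1], rel.tol = 1e-10)$value, numeric(1))
  w <- z / sum(z)
  names(w) <- if (length(w) == 3L) c("closed", "intermediate", "open")
              else paste0("basin", seq_along(w))
  w
}

#' Ground-truth basin labels of positions on the toy potential
#'
#' @param config a [toy_model_config()].
#' @param x positions, Angstrom.
#' @return factor with levels `closed`, `intermediate`, `open` (three-well
#'   case).
#' @export
toy_basin_labels <- function(config, x) {
  labs <- if (length(config$centers) == 3L) c("closed", "intermediate", "open")
          else paste0("basin", seq_along(config$centers))
  idx <- findInterval(as.numeric(x), config$potential$basin_breaks) + 1L
  factor(labs[idx], levels = labs)
}

#' Overdamped Langevin dynamics on the toy hinge coordinate
#'
#' Integrates x_{t+1} = x_t - (dt/friction) U'(x_t)
#' + sqrt(2 kB T dt / friction) eta with standard normal eta on the
#' triple-well potential, and returns the frame-strided D1 series with
#' ground-truth basin labels. Fixed seed gives bit-reproducible output.
#'
#' @param config a [toy_model_config()].
#' @param n_steps number of integration steps.
#' @param x0 initial position (default: first well center).
#' @param extra_force optional `function(x)` adding a force (used by the
#'   metadynamics engine); `NULL` for unbiased dynamics.
#' @param max_step per-step displacement cap, Angstrom, guarding against
#'   stiff restraint overshoot (never engaged in the well region).
#' @return object of class `d1_simulation`: list with `series` (a strided
#'   [descriptor_series()] named `d1`), `labels` (ground-truth basin factor
#'   for the strided frames), `positions` (all steps), `config`, `seed`.
#' @export
simulate_langevin_d1 <- function(config, n_steps, x0 = config$centers[1],
                                 extra_force = NULL, max_step = 1.0) {
  stopifnot(inherits(config, "toy_model_config"))
  n_steps <- as.integer(n_steps)
  kT <- kB_kcal * config$temperature
  dt <- config$timestep; fr <- config$friction
  set.seed(config$seed)
  noise <- stats::rnorm(n_steps, 0, sqrt(2 * kT * dt / fr))
  dU <- config$potential$dU
  bound <- config$centers[length(config$centers)] + 10
  lower <- config$centers[1] - 10
  x <- x0
  out <- numeric(n_steps)
  if (is.null(extra_force)) {
    for (i in seq_len(n_steps)) {
      step <- -(dt / fr) * dU(x) + noise[i]
      if (step > max_step) step <- max_step else if (step < -max_step) step <- -max_step
      x <- x + step
      out[i] <- x
    }
  } else {
    for (i in seq_len(n_steps)) {
      step <- (dt / fr) * (-dU(x) + extra_force(x)) + noise[i]
      if (step > max_step) step <- max_step else if (step < -max_step) step <- -max_step
      x <- x + step
      out[i] <- x
    }
  }
  if (any(out > bound) || any(out < lower))
    stop("divergent trajectory (|x| beyond grid bound + 10 Angstrom); ",
         "use a smaller timestep")
  keep <- seq(config$stride, n_steps, by = config$stride)
  series <- descriptor_series("d1", out[keep], "angstrom",
                              frame_interval_ps = dt * config$stride)
  list(series = series, labels = toy_basin_labels(config, out[keep]),
       positions = out, config = config, seed = config$seed) ->
    res
  class(res) <- "d1_simulation"
  res
}
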