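#' Well-tempered metadynamics configuration
#'
#' Parameters of the toy biased-sampling engine on the D1 collective
#' variable. Defaults are the conventional setup for hinge-distance
#' metadynamics of a clamshell protein: a 1.0 kJ/mol, 0.5 Angstrom Gaussian
#' deposited every 1 ps with bias factor 15, half-harmonic walls at 6 and 20
#' Angstrom with k = 5000 kJ/mol/Angstrom^2, and a bias grid spanning 5 to
#' 25 Angstrom. Energies are accepted in kJ/mol (the metadynamics
#' convention) and converted internally to kcal/mol (1 kcal = 4.184 kJ).
#'
#' @param gaussian_height_kj initial hill height, kJ/mol.
#' @param gaussian_width hill width (sigma), Angstrom.
#' @param pace_ps deposition interval, ps.
#' @param bias_factor well-tempering factor gamma (> 1).
#' @param wall_lower,wall_upper half-harmonic wall positions, Angstrom.
#' @param wall_k_kj wall force constant, kJ/mol/Angstrom^2.
#' @param grid_min,grid_max bias grid bounds, Angstrom.
#' @param grid_spacing bias grid spacing, Angstrom.
#' @param temperature K.
#' @param run_ns run length, ns.
#' @param fes_average_from fraction of the run after which the bias is
#'   accumulated into the time-averaged free-energy estimate (default 0.5).
#'   Time-averaging removes the oscillatory "ripple" the instantaneous
#'   well-tempered bias retains indefinitely.
#' @return object of class `metadynamics_config`.
#' @export
metadynamics_config <- function(gaussian_height_kj = 1.0, gaussian_width = 0.5,
                                pace_ps = 1, bias_factor = 15,
                                wall_lower = 6, wall_upper = 20,
                                wall_k_kj = 5000, grid_min = 5, grid_max = 25,
                                grid_spacing = 0.05, temperature = 300,
                                run_ns = 50, fes_average_from = 0.5) {
  if (bias_factor <= 1) stop("bias factor gamma must exceed 1")
  if (gaussian_width <= 0) stop("gaussian width must be positive")
  if (wall_lower <= grid_min || wall_upper >= grid_max)
    stop("walls must lie inside the grid bounds")
  structure(list(gaussian_height_kj = gaussian_height_kj,
                 gaussian_width = gaussian_width, pace_ps = pace_ps,
                 bias_factor = bias_factor, wall_lower = wall_lower,
                 wall_upper = wall_upper, wall_k_kj = wall_k_kj,
                 grid_min = grid_min, grid_max = grid_max,
                 grid_spacing = grid_spacing, temperature = temperature,
                 run_ns = run_ns, fes_average_from = fes_average_from),
            class = "metadynamics_config")
}

#' Toy well-tempered metadynamics on the D1 coordinate
#'
#' Overdamped Langevin dynamics on the triple-well potential plus an
#' adaptive bias V(x, t): every `pace_ps` a Gaussian hill of height
#' h0 * exp(-V(x_dep, t) / ((gamma - 1) kB T)) is deposited at the current
#' position. Half-harmonic walls confine the coordinate. The free-energy
#' estimate is F(x) = -(gamma / (gamma - 1)) <V(x, t)>, the bias
#' time-averaged over the second half of the run (see
#' [metadynamics_config()]), shifted so its minimum is zero; the
#' instantaneous end-of-run estimate -(gamma / (gamma - 1)) V(x, t_end) is
#' returned alongside as `fes_final`. All energies are reported in
#' kcal/mol.
#'
#' With zero deposition height the engine reduces exactly (bitwise, same
#' seed) to [simulate_langevin_d1()].
#'
#' @param meta a [metadynamics_config()].
#' @param model a [toy_model_config()] (potential, friction, timestep,
#'   stride, seed).
#' @param x0 initial position (default: first well center).
#' @return object of class `wtmetad_run`: list with `fes` (data frame
#'   `x`, `fes_kcal` on the bias grid), `bias_kcal` (final bias on the
#'   grid), `hills` (data frame `time_ps`, `center`, `height_kcal`),
#'   `series` (strided [descriptor_series()] of D1), `labels`, `meta`,
#'   `model`, `seed`.
#' @export
run_wt_metadynamics <- function(meta = metadynamics_config(),
                                model = toy_model_config(),
                                x0 = model$centers[1]) {
  stopifnot(inherits(meta, "metadynamics_config"),
            inherits(model, "toy_model_config"))
  dt <- model$timestep; fr <- model$friction
  kT <- kB_kcal * model$temperature
  kT_meta <- kB_kcal * meta$temperature
  n_steps <- as.integer(round(meta$run_ns * 1000 / dt))
  pace_steps <- max(1L, as.integer(round(meta$pace_ps / dt)))
  h0 <- kj_to_kcal(meta$gaussian_height_kj)
  wall_k <- kj_to_kcal(meta$wall_k_kj)
  sig <- meta$gaussian_width
  gamma <- meta$bias_factor
  grid <- seq(meta$grid_min, meta$grid_max, by = meta$grid_spacing)
  ng <- length(grid)
  V <- numeric(ng)        # bias potential on the grid, kcal/mol
  dV <- numeric(ng)       # its gradient
  dU <- model$potential$dU
  h <- meta$grid_spacing

  interp <- function(vals, x) {
    ## linear interpolation, clamped to the grid
    if (x <= grid[1]) return(vals[1])
    if (x >= grid[ng]) return(vals[ng])
    i <- floor((x - grid[1]) / h) + 1
    w <- (x - grid[i]) / h
    (1 - w) * vals[i] + w * vals[i + 1]
  }

  set.seed(model$seed)
  noise <- stats::rnorm(n_steps, 0, sqrt(2 * kT * dt / fr))
  max_step <- 1.0
  bound_hi <- meta$grid_max + 10; bound_lo <- meta$grid_min - 10
  x <- x0
  out <- numeric(n_steps)
  hill_t <- numeric(0); hill_x <- numeric(0); hill_h <- numeric(0)
  Vsum <- numeric(ng); n_avg <- 0L
  avg_start <- as.integer(floor(meta$fes_average_from * n_steps))
  for (i in seq_len(n_steps)) {
    fbias <- -interp(dV, x)
    fwall <- if (x > meta$wall_upper) -wall_k * (x - meta$wall_upper)
             else if (x < meta$wall_lower) -wall_k * (x - meta$wall_lower)
             else 0
    step <- (dt / fr) * (-dU(x) + fbias + fwall) + noise[i]
    if (step > max_step) step <- max_step else if (step < -max_step) step <- -max_step
    x <- x + step
    out[i] <- x
    if (x > bound_hi || x < bound_lo)
      stop("divergent metadynamics trajectory; use a smaller timestep")
    if (h0 > 0 && i %% pace_steps == 0L) {
      hh <- h0 * exp(-interp(V, x) / ((gamma - 1) * kT_meta))
      g <- hh * exp(-(grid - x)^2 / (2 * sig^2))
      V <- V + g
      dV <- dV + g * (x - grid) / sig^2
      hill_t <- c(hill_t, i * dt); hill_x <- c(hill_x, x); hill_h <- c(hill_h, hh)
      if (i >= avg_start) { Vsum <- Vsum + V; n_avg <- n_avg + 1L }
    }
  }
  fes_final <- -(gamma / (gamma - 1)) * V
  fes_final <- fes_final - min(fes_final)
  fes <- if (n_avg > 0) -(gamma / (gamma - 1)) * (Vsum / n_avg) else fes_final
  fes <- fes - min(fes)
  keep <- seq(model$stride, n_steps, by = model$stride)
  series <- descriptor_series("d1", out[keep], "angstrom",
                              frame_interval_ps = dt * model$stride)
  structure(list(
    fes = data.frame(x = grid, fes_kcal = fes),
    fes_final = data.frame(x = grid, fes_kcal = fes_final),
    bias_kcal = V,
    hills = data.frame(time_ps = hill_t, center = hill_x, height_kcal = hill_h),
    series = series, labels = toy_basin_labels(model, out[keep]),
    positions = out, meta = meta, model = model, seed = model$seed),
    class = "wtmetad_run")
}

#' @export
print.wtmetad_run <- function(x, ...) {
  cat("<wtmetad_run> ", x$meta$run_ns, " ns, ", nrow(x$hills), " hills, ",
      "FES range 0-", .fmt_num(max(x$fes$fes_kcal)), " kcal/mol\n", sep = "")
  invisible(x)
}
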