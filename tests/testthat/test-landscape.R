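kB <- 0.0019872041

test_that("Boltzmann inversion reproduces closed-form bin ratios", {
  # all samples in one bin
  g1 <- pmf(rep(5.03, 100), bin_width = 0.1, temperature = 300)
  expect_equal(sum(g1$occupied), 1L)
  expect_equal(g1$dG[g1$occupied], 0)
  expect_true(all(is.infinite(g1$dG[!g1$occupied])))

  # two bins, counts 3:1 at 300 K: minority sits kB*300*ln 3 above majority
  x <- c(rep(5.05, 3), 5.15)
  g2 <- pmf(x, bin_width = 0.1, temperature = 300)
  occ <- g2$dG[g2$occupied]
  expect_equal(max(occ) - min(occ), kB * 300 * log(3), tolerance = 1e-12)
  expect_equal(min(occ), 0)

  expect_error(pmf(x, bin_width = -1), "positive")
  expect_error(pmf(x, temperature = 0), "positive")
})

test_that("PMF of harmonic Boltzmann samples recovers the parabola", {
  # samples from exp(-U/kBT) with U = 0.5*kappa*(x-x0)^2 are normal with
  # sd = sqrt(kBT/kappa)
  kappa <- 2.4; x0 <- 10; Temp <- 300
  sd0 <- sqrt(kB * Temp / kappa)
  set.seed(123)
  x <- rnorm(1e5, x0, sd0)
  g <- pmf(x, bin_width = 0.1, temperature = Temp)
  mids <- g$mids[[1]]
  sel <- g$occupied & (0.5 * kappa * (mids - x0)^2 <= 2 * kB * Temp)
  ref <- 0.5 * kappa * (mids[sel] - x0)^2
  est <- g$dG[sel]
  rms <- sqrt(mean((est - (ref - min(ref)))^2))
  expect_lt(rms, 0.1)
})

test_that("PMF is invariant under sample duplication and shift-idempotent", {
  set.seed(131)
  x <- rnorm(2000, 9, 0.7)
  g <- pmf(x)
  gd <- pmf(c(x, x))
  expect_equal(gd$dG, g$dG, tolerance = 1e-12)
  # re-shifting an already-shifted grid changes nothing
  expect_equal(min(g$dG[g$occupied]), 0)
  g2 <- g
  g2$dG[g2$occupied] <- g2$dG[g2$occupied] + 3.2
  reshift <- g2$dG
  reshift[g2$occupied] <- reshift[g2$occupied] - min(reshift[g2$occupied])
  expect_equal(reshift, g$dG, tolerance = 1e-12)
})

test_that("2-D PMF matches the joint histogram inversion", {
  set.seed(139)
  x <- rnorm(5000, 9, 0.5); y <- rnorm(5000, 2, 0.3)
  g <- pmf(x, y, bin_width = 0.1, temperature = 300)
  expect_true(is.matrix(g$dG))
  expect_equal(min(g$dG[g$occupied]), 0)
  # direct check of one bin against the count ratio
  cmax <- max(g$counts)
  i <- which(g$counts == cmax, arr.ind = TRUE)[1, ]
  j <- which(g$occupied & g$counts > 0 & g$counts < cmax, arr.ind = TRUE)[1, ]
  dd <- g$dG[j[1], j[2]] - g$dG[i[1], i[2]]
  expect_equal(dd, -kB * 300 * log(g$counts[j[1], j[2]] / cmax), tolerance = 1e-10)
})

test_that("state classification uses half-open intervals with the stated defaults", {
  st <- state_definition()
  expect_equal(as.character(classify_states(8.93, st)), "closed")
  expect_equal(as.character(classify_states(13.5, st)), "open")
  expect_equal(as.character(classify_states(9.5, st)), "intermediate")
  expect_equal(as.character(classify_states(12.0, st)), "open")
  expect_error(classify_states(-1, st), "negative")
  expect_error(state_definition(c(12, 9.5)), "increasing")
})

test_that("occupancy tables are exact and sum to 100", {
  labs <- factor(c(rep("closed", 3), "open"),
                 levels = c("closed", "intermediate", "open"))
  occ <- occupancy_table(labs)
  expect_equal(occ$percent, c(75, 0, 25))
  expect_equal(sum(occ$percent), 100, tolerance = 1e-9)

  one <- occupancy_table(factor(rep("open", 7),
                                levels = c("closed", "intermediate", "open")))
  expect_equal(one$percent, c(0, 0, 100))

  set.seed(149)
  labs2 <- sample(c("closed", "intermediate", "open"), 997, replace = TRUE)
  occ2 <- occupancy_table(factor(labs2))
  expect_equal(sum(occ2$percent), 100, tolerance = 1e-9)
  expect_equal(occupancy_table(factor(labs2[sample(997)]))$percent, occ2$percent)
})

test_that("Markov-chain occupancies converge to the stationary distribution", {
  # 3-state chain with known stationary distribution
  P <- rbind(c(0.70, 0.24, 0.06),
             c(0.15, 0.70, 0.15),
             c(0.06, 0.24, 0.70))
  pi_st <- Re(eigen(t(P))$vectors[, 1]); pi_st <- pi_st / sum(pi_st)
  set.seed(157)
  n <- 1e5
  states <- integer(n); states[1] <- 1L
  u <- runif(n)
  cum <- t(apply(P, 1, cumsum))
  for (i in 2:n) states[i] <- findInterval(u[i], cum[states[i - 1], ]) + 1L
  labs <- factor(c("closed", "intermediate", "open")[states],
                 levels = c("closed", "intermediate", "open"))
  occ <- occupancy_table(labs)
  expect_true(all(abs(occ$percent - 100 * pi_st) < 1))
})

test_that("population free-energy differences follow -kBT ln(pb/pa)", {
  labs <- factor(c(rep("intermediate", 5363), rep("open", 4637)),
                 levels = c("closed", "intermediate", "open"))
  occ <- occupancy_table(labs)
  dg <- state_free_energy_difference(occ, "intermediate", "open", 300)
  expect_equal(dg, -kB * 300 * log(46.37 / 53.63), tolerance = 1e-10)
  expect_equal(dg, 0.0866, tolerance = 2e-3)
  expect_equal(state_free_energy_difference(occ, "open", "open", 300), 0)
  expect_error(state_free_energy_difference(occ, "closed", "open"), "zero occupancy")

  # two-delta limit: equals the difference of per-state minimum PMF values
  d1 <- c(rep(8.5, 5363), rep(13.5, 4637))
  g <- pmf(d1, bin_width = 0.1, temperature = 300)
  vals <- sort(g$dG[g$occupied])
  expect_equal(vals[2] - vals[1],
               abs(state_free_energy_difference(occ, "intermediate", "open", 300)),
               tolerance = 1e-9)
})

test_that("PMF of triple-well Boltzmann samples recovers well-depth differences", {
  cfg <- toy_model_config()
  kT <- kB * cfg$temperature
  # iid samples by inverse-CDF on a fine grid (independent of the Langevin
  # integrator)
  xs <- seq(6.5, 16.5, by = 0.002)
  dens <- exp(-toy_potential(cfg, xs) / kT)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  set.seed(163)
  samples <- xs[findInterval(runif(1e5), cdf) + 1]
  g <- pmf(samples, bin_width = 0.1, temperature = cfg$temperature)
  fes_at <- function(x0) {
    i <- which.min(abs(g$mids[[1]] - x0)); g$dG[i]
  }
  est <- vapply(cfg$centers, fes_at, numeric(1)); est <- est - min(est)
  tru <- cfg$well_energies - min(cfg$well_energies)
  expect_true(all(abs(est - tru) < 0.3))
})
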