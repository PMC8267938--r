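test_that("superpose recovers rigid motions exactly", {
  set.seed(7)
  X <- matrix(rnorm(15, sd = 3), 5, 3)
  fit <- superpose(X, X)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
  expect_lt(fit$rmsd, 1e-10)

  t0 <- c(5, -2, 1)
  Y <- X + matrix(t0, 5, 3, byrow = TRUE)
  fit2 <- superpose(Y, X)
  expect_lt(fit2$rmsd, 1e-10)
  expect_equal(fit2$translation, -t0, tolerance = 1e-8)

  expect_equal(det(fit2$rotation), 1, tolerance = 1e-8)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "3 fit atoms")
  coll <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(coll, coll + 1), "degenerate|collinear")
})

test_that("Kabsch fit matches a brute-force rotational search", {
  # independent oracle: best of many random rotations (optimal translation is
  # the weighted-centroid match), refined by Nelder-Mead on Euler angles
  set.seed(101)
  X <- matrix(rnorm(15, sd = 2), 5, 3)
  Y <- matrix(rnorm(15, sd = 2), 5, 3)
  w <- runif(5, 0.5, 3); wn <- w / sum(w)

  wrmsd_for_rot <- function(R) {
    Xr <- X %*% t(R)
    shift <- colSums(Y * wn) - colSums(Xr * wn)
    dev <- Xr + matrix(shift, 5, 3, byrow = TRUE) - Y
    sqrt(sum(wn * rowSums(dev^2)))
  }
  euler_rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  # coarse random-quaternion scan
  best <- Inf; best_R <- diag(3)
  for (i in 1:4000) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
    v <- wrmsd_for_rot(R)
    if (v < best) { best <- v; best_R <- R }
  }
  # local refinement from the best grid point
  to_euler <- function(R) c(atan2(R[2, 1], R[1, 1]), -asin(R[3, 1]),
                            atan2(R[3, 2], R[3, 3]))
  opt <- optim(to_euler(best_R), function(a) wrmsd_for_rot(euler_rot(a)),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  oracle_min <- opt$value

  fit <- superpose(X, Y, weights = w)
  expect_equal(fit$rmsd, oracle_min, tolerance = 1e-3)
  expect_lte(fit$rmsd, oracle_min + 1e-6)  # Kabsch is the true minimizer
})

test_that("mass-weighted RMSD matches its closed forms and a term-by-term oracle", {
  X <- rbind(c(1, 0, 0), c(0, 0, 0))
  Y <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(rmsd(X, Y, fit = FALSE), sqrt(0.5), tolerance = 1e-12)
  expect_equal(rmsd(X, X, fit = FALSE), 0)

  set.seed(21)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 4, 3)
  m <- runif(4, 1, 16)
  # independent term-by-term evaluation of the mass-weighted formula
  acc <- 0
  for (i in 1:4) acc <- acc + m[i] * sum((A[i, ] - B[i, ])^2)
  oracle <- sqrt(acc / sum(m))
  expect_equal(rmsd(A, B, masses = m, fit = FALSE), oracle, tolerance = 1e-10)

  expect_equal(rmsd(A, B, masses = m, fit = FALSE),
               rmsd(B, A, masses = m, fit = FALSE), tolerance = 1e-12)
  expect_error(rmsd(A, B, sel = integer(0)), "empty selection")
})

test_that("fitted RMSD is invariant under proper rigid motion of the mobile frame", {
  set.seed(31)
  A <- matrix(rnorm(24, sd = 2), 8, 3)
  B <- matrix(rnorm(24, sd = 2), 8, 3)
  m <- runif(8, 1, 12)
  base <- rmsd(A, B, masses = m, fit = TRUE)
  for (k in 1:5) {
    R <- random_rotation()
    t0 <- rnorm(3, sd = 10)
    expect_equal(rmsd(apply_rigid(A, R, t0), B, masses = m, fit = TRUE),
                 base, tolerance = 1e-8)
  }
})

test_that("radius of gyration matches closed forms and a two-pass loop oracle", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(two), 3)  # d/2 for equal masses

  set.seed(41)
  X <- matrix(rnorm(30, sd = 4), 10, 3)
  m <- runif(10, 1, 16)
  ctr <- colSums(X * m / sum(m))
  acc <- 0
  for (i in 1:10) acc <- acc + m[i] * sum((X[i, ] - ctr)^2)
  expect_equal(radius_of_gyration(X, masses = m), sqrt(acc / sum(m)),
               tolerance = 1e-10)

  R <- random_rotation()
  expect_equal(radius_of_gyration(apply_rigid(X, R, c(10, -3, 2)), masses = m),
               radius_of_gyration(X, masses = m), tolerance = 1e-10)
  expect_error(radius_of_gyration(X, sel = integer(0)), "empty selection")
})

test_that("group distances follow centroid geometry", {
  fr <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(group_distance(fr, 1, 2), 5)
  expect_equal(group_distance(fr, 1:2, 1:2), 0)
  expect_error(group_distance(fr, integer(0), 1, label = "d1"), "d1")

  set.seed(51)
  X <- matrix(rnorm(30), 10, 3)
  m <- runif(10, 1, 16)
  d0 <- group_distance(X, 1:4, 5:10, m)
  R <- random_rotation()
  expect_equal(group_distance(apply_rigid(X, R, c(1, 2, 3)), 1:4, 5:10, m),
               d0, tolerance = 1e-10)
})

test_that("dihedral angles: closed forms, range, and true symmetries", {
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  trans <- rbind(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(dihedral_angle(cis, 1:4), 0)
  expect_equal(dihedral_angle(trans, 1:4), 180)

  set.seed(61)
  for (k in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    a <- dihedral_angle(p, 1:4)
    expect_gte(a, 0); expect_lt(a, 360)
    # torsions are invariant under atom-order reversal...
    expect_equal(dihedral_angle(p, 4:1), a, tolerance = 1e-9)
    # ...and negated by mirror reflection
    pm <- p; pm[, 1] <- -pm[, 1]
    expect_equal((dihedral_angle(pm, 1:4) + a) %% 360, 0, tolerance = 1e-9)
  }
  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral_angle(coll, 1:4), "degenerate|collinear")
})

test_that("RMSF separates internal motion from rigid-body motion", {
  set.seed(71)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  top <- make_structure(base, resno = 1:10)

  static <- make_trajectory(top, list(base, base, base))
  expect_true(all(rmsf(static)$rmsf < 1e-10))

  # one residue alternating +/- a along x about its mean: RMSF exactly a
  a <- 0.8
  up <- base; up[4, 1] <- base[4, 1] + a
  dn <- base; dn[4, 1] <- base[4, 1] - a
  osc <- make_trajectory(top, rep(list(up, dn), 4))
  # fit on the other residues so the oscillation is not absorbed by the fit
  r <- rmsf(osc, spec = selection_spec(atom_names = "CA"),
            fit_spec = selection_spec(resno = c(1:3, 5:10)))
  expect_equal(r$rmsf[4], a, tolerance = 1e-8)
  expect_true(all(r$rmsf[-4] < 1e-8))

  # pure rigid translation: zero RMSF everywhere after fitting
  shifted <- lapply(1:4, function(i) base + matrix(c(i, -i, 2 * i), 10, 3, byrow = TRUE))
  rt <- rmsf(make_trajectory(top, shifted))
  expect_true(all(rt$rmsf < 1e-8))

  expect_error(rmsf(static, spec = selection_spec(atom_names = "CB")),
               "CA")
  expect_error(rmsf(make_trajectory(top, list(base))), "2 frames")
})
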