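test_that("DCCM reproduces in-phase/anti-phase constructions exactly", {
  base <- rbind(c(0, 0, 0), c(10, 0, 0))
  top <- make_structure(base, resno = 1:2)
  osc <- function(s1, s2) lapply(c(-1, 1, -1, 1), function(sgn) {
    fr <- base
    fr[1, 1] <- fr[1, 1] + sgn * s1
    fr[2, 1] <- fr[2, 1] + sgn * s2
    fr
  })
  in_phase <- dccm(make_trajectory(top, osc(0.5, 0.8)), fit = FALSE)
  expect_equal(in_phase[1, 2], 1, tolerance = 1e-12)
  anti <- dccm(make_trajectory(top, osc(0.5, -0.8)), fit = FALSE)
  expect_equal(anti[1, 2], -1, tolerance = 1e-12)
})

test_that("DCCM equals a direct double-loop covariance computation", {
  set.seed(83)
  base <- matrix(rnorm(12, sd = 6), 4, 3)
  top <- make_structure(base, resno = 1:4)
  frames <- lapply(1:6, function(i) base + matrix(rnorm(12, sd = 0.4), 4, 3))
  tr <- make_trajectory(top, frames)
  C <- dccm(tr, fit = FALSE)

  # independent double loop
  arr <- array(unlist(frames), dim = c(4, 3, 6))
  means <- apply(arr, c(1, 2), mean)
  oracle <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    num <- 0; di <- 0; dj <- 0
    for (f in 1:6) {
      u <- arr[i, , f] - means[i, ]
      v <- arr[j, , f] - means[j, ]
      num <- num + sum(u * v); di <- di + sum(u * u); dj <- dj + sum(v * v)
    }
    oracle[i, j] <- num / sqrt(di * dj)
  }
  expect_equal(unclass(C), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(C)))
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(C >= -1 & C <= 1))
})

test_that("DCCM is invariant under global rigid motion when fitted", {
  set.seed(89)
  base <- matrix(rnorm(18, sd = 5), 6, 3)
  top <- make_structure(base, resno = 1:6)
  frames <- lapply(1:5, function(i) base + matrix(rnorm(18, sd = 0.3), 6, 3))
  C0 <- dccm(make_trajectory(top, frames))
  moved <- lapply(frames, function(fr) {
    R <- random_rotation()
    apply_rigid(fr, R, rnorm(3, sd = 8))
  })
  C1 <- dccm(make_trajectory(top, moved))
  expect_equal(unclass(C1), unclass(C0), tolerance = 1e-6)

  expect_error(dccm(make_trajectory(top, frames[1])), "2 frames")
})

test_that("zero-variance residues are flagged and reported as 0", {
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  top <- make_structure(base, resno = 1:3)
  frames <- lapply(c(-1, 1, -1, 1), function(s) {
    fr <- base; fr[1, 1] <- fr[1, 1] + 0.5 * s; fr
  })
  C <- dccm(make_trajectory(top, frames), fit = FALSE)
  zv <- attr(C, "zero_variance")
  expect_identical(zv, c(FALSE, TRUE, TRUE))
  expect_equal(C[1, 2], 0)
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
})

test_that("hydrogen-bond detection follows the geometric criteria", {
  mk <- function(acceptor) molecular_structure(data.frame(
    serial = 1:3, atom_name = c("N", "H", "O"),
    resname = c("GLY", "GLY", "SER"), chain = "A",
    resno = c(1L, 1L, 2L), element = c("N", "H", "O"),
    mass = element_mass(c("N", "H", "O")),
    x = c(0, 1, acceptor[1]), y = c(0, 0, acceptor[2]),
    z = c(0, 0, acceptor[3]), record = "ATOM", stringsAsFactors = FALSE))
  spec <- hbond_spec(1, 2)

  s <- mk(c(2.8, 0, 0))   # collinear, 2.8 A: bonded
  expect_true(detect_hbond(coords(s), s, spec))
  s_far <- mk(c(5, 0, 0)) # 5 A > 3.5 A cutoff
  expect_false(detect_hbond(coords(s_far), s_far, spec))

  # acceptor placed by explicit trigonometry: D-H-A angle exactly 100
  # degrees at donor-acceptor distance 2.9 A
  ang <- 100 * pi / 180
  v <- c(cos(pi - ang), sin(pi - ang), 0)   # direction from H
  ssol <- polyroot(c(1 - 2.9^2, 2 * v[1], 1))
  s_len <- max(Re(ssol))
  A <- c(1, 0, 0) + s_len * v
  expect_equal(sqrt(sum(A^2)), 2.9, tolerance = 1e-9)
  s100 <- mk(A)
  expect_false(detect_hbond(coords(s100), s100, spec))            # 135 cutoff
  expect_true(detect_hbond(coords(s100), s100, hbond_spec(1, 2, angle_cutoff = 95)))

  # heavy-only fallback ignores the angle
  expect_true(detect_hbond(coords(s100), s100, hbond_spec(1, 2, mode = "heavy-only")))
  expect_error(detect_hbond(coords(s), s, hbond_spec(1, 9)), "not found")
})

test_that("hydrogen-bond occupancy counts frames exactly and is permutation-equivariant", {
  on <- c(2.8, 0, 0); off <- c(5.5, 0, 0)
  base <- rbind(c(0, 0, 0), c(1, 0, 0), on)
  top <- molecular_structure(data.frame(
    serial = 1:3, atom_name = c("N", "H", "O"),
    resname = c("GLY", "GLY", "SER"), chain = "A", resno = c(1L, 1L, 2L),
    element = c("N", "H", "O"), mass = element_mass(c("N", "H", "O")),
    x = base[, 1], y = base[, 2], z = base[, 3], record = "ATOM",
    stringsAsFactors = FALSE))
  sched <- seq_len(10) %in% c(1, 4, 8)
  frames <- lapply(sched, function(s) {
    fr <- base; fr[3, ] <- if (s) on else off; fr
  })
  occ <- hbond_occupancy(make_trajectory(top, frames), hbond_spec(1, 2))
  expect_equal(occ$occupancy, 30)
  expect_identical(occ$mask, sched)

  occ_all <- hbond_occupancy(make_trajectory(top, frames[sched]), hbond_spec(1, 2))
  expect_equal(occ_all$occupancy, 100)

  perm <- sample(10)
  occ_p <- hbond_occupancy(make_trajectory(top, frames[perm]), hbond_spec(1, 2))
  expect_equal(occ_p$occupancy, occ$occupancy)
})

test_that("1-D k-means clustering is deterministic and optimal in 1-D", {
  res <- cluster_representative(c(1, 1, 1, 9, 9, 9), k = 2)
  expect_equal(res$labels, c(1, 1, 1, 2, 2, 2))
  expect_equal(res$representatives, c(1L, 4L))

  const <- cluster_representative(rep(5, 8), k = 1)
  expect_equal(unique(const$labels), 1)
  expect_equal(const$representatives, 1L)
  expect_error(cluster_representative(rep(5, 8), k = 2), "degenerate")

  # threshold-scan oracle: in 1-D the optimal 2-partition is induced by a
  # threshold between consecutive sorted values
  set.seed(97)
  x <- c(rnorm(10, 3, 0.4), rnorm(10, 8, 0.6))[sample(20)]
  res2 <- cluster_representative(x, k = 2)
  xs <- sort(x)
  best <- Inf
  for (cut in 1:19) {
    a <- xs[1:cut]; b <- xs[(cut + 1):20]
    w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (w < best) best <- w
  }
  expect_equal(res2$wcss, best, tolerance = 1e-9)

  # label assignment depends only on values, not frame order
  ord <- order(x)
  res3 <- cluster_representative(x[ord], k = 2)
  expect_equal(res3$labels, res2$labels[ord])
})
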