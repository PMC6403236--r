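# Covariance models, projections, FEL, overlap/RMSIP, porcupine modes.

make_planted_system <- function(n_frames = 2000L, variances = c(0.9, 0.3, 0.1),
                                noise_sd = 0.005, seed = 31L) {
  cx <- toy_cache()
  sel <- select_atoms(cx$traj, "backbone")
  modes <- make_planted_modes(3 * length(sel), length(variances),
                              seed = seed)
  tr <- make_gaussian_trajectory(cx$traj, n_frames, modes, variances,
                                 noise_sd = noise_sd, selection = sel,
                                 seed = seed + 1L)
  list(cx = cx, sel = sel, modes = modes, variances = variances, traj = tr)
}

test_that("covariance model satisfies its structural invariants", {
  sys <- make_planted_system(400L)
  m <- build_covariance(sys$traj, sys$sel)
  expect_equal(m$cov, t(m$cov), tolerance = 1e-12)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_gt(min(m$eigenvalues), -1e-10)
  expect_equal(m$trace, sum(m$eigenvalues), tolerance = 1e-8)
  V <- m$eigenvectors[, 1:10]
  expect_equal(crossprod(V), diag(10), tolerance = 1e-8)
  recon <- m$eigenvectors %*% (m$eigenvalues * t(m$eigenvectors))
  expect_lt(max(abs(m$cov - recon)), 1e-8 * m$trace)
})

test_that("degenerate trajectories give the analytic covariance", {
  cx <- toy_cache()
  sel <- select_atoms(cx$traj, "backbone")
  const <- make_gaussian_trajectory(cx$traj, 5, noise_sd = 0,
                                    selection = sel, seed = 1)
  m0 <- build_covariance(const, sel)
  expect_equal(m0$trace, 0, tolerance = 1e-20)
  expect_error(build_covariance(subset_frames(const, 1L), sel),
               "2 frames")
  expect_error(cumulative_variance(m0, 3), "zero trace")
  # rank-1 alternation: mean +/- a v has single eigenvalue a^2
  ref <- matrix(cx$traj$coords[sel, , 1], length(sel), 3)
  v <- make_nonrigid_mode(ref, seed = 4)
  a <- 1e-4
  co <- cx$traj$coords[sel, , c(1, 1, 1, 1)]
  vm <- matrix(v, length(sel), 3, byrow = TRUE)
  co[, , c(1, 3)] <- co[, , c(1, 3)] + rep(a * vm, 2)
  co[, , c(2, 4)] <- co[, , c(2, 4)] - rep(a * vm, 2)
  tr <- trajectory(cx$traj$atoms[sel, ], co)
  m1 <- build_covariance(tr, seq_along(sel))
  expect_equal(m1$eigenvalues[1], a^2, tolerance = 1e-4)
  expect_lt(m1$eigenvalues[2] / m1$eigenvalues[1], 1e-6)
  expect_equal(abs(sum(m1$eigenvectors[, 1] * v)), 1, tolerance = 1e-4)
})

test_that("planted-mode spectrum is recovered and projections match it", {
  sys <- make_planted_system(5000L)
  m <- build_covariance(sys$traj, sys$sel)
  expect_equal(m$eigenvalues[1:3], sys$variances, tolerance = 0.05)
  # spectrum beyond the planted modes is isotropic-noise sized
  expect_lt(sum(m$eigenvalues[-(1:3)]), 0.02 * m$trace)
  expect_equal(cumulative_variance(m, 3),
               sum(sys$variances) / (sum(sys$variances) +
                                       3 * length(sys$sel) * 0.005^2),
               tolerance = 0.02)
  # training-scores variance reproduces the eigenvalues exactly
  proj <- project_trajectory(sys$traj, m, k = 3)
  n <- nrow(proj)
  for (k in 1:3) {
    s <- proj[[paste0("pc", k)]]
    expect_lt(abs(mean(s)), 1e-10)
    expect_equal(mean((s - mean(s))^2), m$eigenvalues[k],
                 tolerance = 1e-8)
  }
  # subspace identity with the planted modes
  planted_model <- list(mean = rep(0, nrow(sys$modes)),
                        eigenvalues = sys$variances,
                        eigenvectors = sys$modes)
  expect_gte(rmsip(planted_model, m, k = 3)$rmsip, 0.99)
})

test_that("projection of the model mean is zero and rank-1 scores are +/-a", {
  sys <- make_planted_system(200L)
  m <- build_covariance(sys$traj, sys$sel)
  mean_traj <- trajectory(sys$cx$traj$atoms,
                          array(0, dim = c(nrow(sys$cx$traj$atoms), 3, 1)))
  mean_traj$coords[sys$sel, , 1] <- matrix(m$mean, length(sys$sel), 3,
                                           byrow = TRUE)
  p0 <- project_trajectory(mean_traj, m, k = 3)
  expect_lt(max(abs(p0[, c("pc1", "pc2", "pc3")])), 1e-10)
})

test_that("FEL obeys the Boltzmann closed form", {
  # all frames in one bin
  s <- matrix(c(rep(0.5, 10), rep(-0.2, 10)), ncol = 2)
  g1 <- fel(s, n_bins = 8)
  expect_equal(sum(is.finite(g1$dG)), 1L)
  expect_equal(min(g1$dG), 0)
  # exactly uniform occupancy over a 4x4 score lattice
  u <- as.matrix(expand.grid(seq(0.1, 0.4, 0.1), seq(0.1, 0.4, 0.1)))
  g2 <- fel(u, n_bins = 4)
  expect_true(all(abs(g2$dG) < 1e-12))
  # occupancy ratio r: dG gap is exactly kB T log(r)
  m <- 20L; r_count <- 54L
  sc <- cbind(c(rep(0.1, r_count), rep(0.9, m)), 0.5)
  g3 <- fel(sc, n_bins = 2)
  finite <- sort(g3$dG[is.finite(g3$dG)])
  kbt <- BOLTZMANN_KJ_MOL_K * 300
  expect_equal(diff(finite), kbt * log(r_count / m), tolerance = 1e-6)
  expect_equal(diff(finite) / log(r_count / m), 2.494, tolerance = 1e-3)
  expect_error(fel(sc, n_bins = 1), "n_bins")
})

test_that("representative frame sits in the global-minimum basin", {
  # two clusters, one 10x more populated
  set.seed(17)
  dense <- cbind(rnorm(200, 0, 0.02), rnorm(200, 0, 0.02))
  sparse <- cbind(rnorm(20, 1, 0.02), rnorm(20, 1, 0.02))
  sc <- rbind(dense, sparse)
  g <- fel(sc, n_bins = 16)
  idx <- representative_frame(g, sc)
  expect_lte(idx, 200L)  # inside the dense cluster
  # constructed grid: nearest-score frame to the known minimum bin centre
  sc2 <- cbind(c(0.0, 0.01, 0.02, 1.0), c(0.0, 0.01, 0.02, 1.0))
  g2 <- fel(sc2, n_bins = 4)
  best_bin <- which(g2$dG == 0, arr.ind = TRUE)
  centre <- c(g2$centers_i[best_bin[1]], g2$centers_j[best_bin[2]])
  d2 <- colSums((t(sc2) - centre)^2)
  expect_equal(representative_frame(g2, sc2), which.min(d2))
  # single frame: that frame
  expect_equal(representative_frame(fel(cbind(0.3, 0.4), n_bins = 4),
                                    cbind(0.3, 0.4)), 1L)
})

test_that("covariance overlap matches an independent matrix-function oracle", {
  skip_if_not_installed("pracma")
  A <- random_spd(6, 101)
  B <- random_spd(6, 102)
  got <- covariance_overlap(as_model(A), as_model(B), k = 6)
  sqa <- pracma::sqrtm(A)$B
  inner <- pracma::sqrtm(sqa %*% B %*% sqa)$B
  d <- sum(diag(A)) + sum(diag(B)) - 2 * sum(diag(inner))
  oracle <- 1 - sqrt(max(d, 0) / (sum(diag(A)) + sum(diag(B))))
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("overlap and RMSIP hit their identity and orthogonality limits", {
  A <- random_spd(9, 103)
  mA <- as_model(A)
  expect_equal(covariance_overlap(mA, mA, k = 9), 1, tolerance = 1e-8)
  expect_equal(rmsip(mA, mA, k = 5)$rmsip, 1, tolerance = 1e-10)
  # rank-1 models on orthogonal directions
  e1 <- c(1, rep(0, 5)); e2 <- c(0, 1, rep(0, 4))
  m1 <- as_model(0.5 * tcrossprod(e1))
  m2 <- as_model(0.5 * tcrossprod(e2))
  expect_equal(covariance_overlap(m1, m2, k = 1), 0, tolerance = 1e-8)
  expect_equal(rmsip(m1, m2, k = 1)$rmsip, 0, tolerance = 1e-10)
  # complete orthonormal bases of the same space: rmsip 1 at k = dim
  Q1 <- qr.Q(qr(matrix(rnorm(36), 6)))
  Q2 <- qr.Q(qr(matrix(rnorm(36), 6)))
  mq1 <- list(mean = rep(0, 6), eigenvalues = rep(1, 6), eigenvectors = Q1)
  mq2 <- list(mean = rep(0, 6), eigenvalues = rep(1, 6), eigenvectors = Q2)
  expect_equal(rmsip(mq1, mq2, k = 6)$rmsip, 1, tolerance = 1e-10)
  # symmetry and sign-flip invariance
  Bm <- as_model(random_spd(9, 104))
  expect_equal(covariance_overlap(mA, Bm, 4), covariance_overlap(Bm, mA, 4),
               tolerance = 1e-6)
  flipped <- Bm; flipped$eigenvectors <- -Bm$eigenvectors
  expect_equal(rmsip(mA, flipped, 4)$rmsip, rmsip(mA, Bm, 4)$rmsip,
               tolerance = 1e-12)
  expect_error(covariance_overlap(as_model(matrix(0, 3, 3)),
                                  as_model(matrix(0, 3, 3)), 3),
               "zero")
})

test_that("porcupine extremes close the rank-1 alternation", {
  cx <- toy_cache()
  sel <- select_atoms(cx$traj, "backbone")
  ref <- matrix(cx$traj$coords[sel, , 1], length(sel), 3)
  v <- make_nonrigid_mode(ref, seed = 6)
  a <- 1e-4
  vm <- matrix(v, length(sel), 3, byrow = TRUE)
  co <- cx$traj$coords[sel, , c(1, 1)]
  co[, , 1] <- co[, , 1] + a * vm
  co[, , 2] <- co[, , 2] - a * vm
  tr <- trajectory(cx$traj$atoms[sel, ], co)
  m <- build_covariance(tr, seq_along(sel))
  pc <- porcupine(m, 1, scale = 1)
  mean_m <- matrix(m$mean, length(sel), 3, byrow = TRUE)
  extremes <- list(pc$plus, pc$minus)
  training <- list(mean_m + a * vm, mean_m - a * vm)
  err <- min(max(abs(extremes[[1]] - training[[1]])),
             max(abs(extremes[[1]] - training[[2]])))
  expect_lt(err, 1e-8)
  # scale 0 collapses both extremes onto the mean
  pc0 <- porcupine(m, 1, scale = 0)
  expect_equal(pc0$plus, pc0$minus)
  expect_equal(pc0$plus, mean_m, tolerance = 1e-12)
  # vector norms flag the planted max-amplitude atom
  amp_atom <- which.max(rowSums(vm^2))
  expect_equal(which.max(pc$norms), amp_atom)
  # a zero-variance model yields zero vectors with a warning
  const <- trajectory(cx$traj$atoms[sel, ], cx$traj$coords[sel, , c(1, 1)])
  mc <- build_covariance(const, seq_along(sel))
  expect_warning(pz <- porcupine(mc, 1, scale = 1), "zero")
  expect_true(all(pz$norms == 0))
})
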