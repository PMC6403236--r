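# Superposition, fluctuation, compactness, exposure and distance metrics.

tetra <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0), c(0, 0, 0.1))

rot_z90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

test_that("Kabsch superposition recovers rigid motions", {
  fit <- kabsch_superpose(tetra, tetra)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  moved <- tetra %*% t(rot_z90) +
    matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  fit2 <- kabsch_superpose(moved, tetra)
  expect_lt(fit2$rmsd, 1e-9)

  expect_error(kabsch_superpose(tetra[1:2, ], tetra[1:2, ]), "3 atoms")
  line <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches an exhaustive rotation-grid minimum", {
  set.seed(11)
  A <- matrix(rnorm(15, sd = 0.4), 5, 3)
  B <- matrix(rnorm(15, sd = 0.4), 5, 3)
  fit <- kabsch_superpose(A, B)
  grid <- grid_min_rmsd(A, B, step_deg = 2)
  expect_lte(fit$rmsd, grid + 1e-12)   # the grid can never beat the optimum
  expect_equal(fit$rmsd, grid, tolerance = 1e-3)
})

test_that("RMSD series is zero for identical or rigidly shifted frames", {
  cx <- toy_cache()
  nfr <- 8L
  coords <- array(rep(cx$traj$coords[, , 1], nfr),
                  dim = c(nrow(cx$traj$atoms), 3, nfr))
  tr <- trajectory(cx$traj$atoms, coords)
  expect_true(all(rmsd_series(tr, "backbone")$value < 1e-12))
  # growing translations are removed by the fit
  for (k in seq_len(nfr)) coords[, 1, k] <- coords[, 1, k] + 0.2 * k
  tr2 <- trajectory(cx$traj$atoms, coords)
  expect_true(all(rmsd_series(tr2, "backbone")$value < 1e-9))
  expect_error(rmsd_series(tr, "resid 9999"), "empty")
})

test_that("RMSD of planted isotropic noise matches an independent fit", {
  skip_if_not_installed("bio3d")
  sigma <- 0.02
  n_atoms <- 200L
  nfr <- 100L
  set.seed(42)
  ref <- matrix(runif(n_atoms * 3, 0, 3), n_atoms, 3)
  noise <- array(rnorm(n_atoms * 3 * nfr, sd = sigma), c(n_atoms, 3, nfr))
  coords <- array(rep(ref, nfr), c(n_atoms, 3, nfr)) + noise
  at <- tiny_topology(rep("CA", n_atoms), resids = seq_len(n_atoms))
  tr <- trajectory(at, coords)
  # reference frame is the clean structure appended as frame 1
  tr$coords <- array(c(ref, coords), c(n_atoms, 3, nfr + 1))
  mean_rmsd <- mean(rmsd_series(tr, seq_len(n_atoms))$value[-1])
  # independent oracle: bio3d fit + rmsd on the same ensemble
  xyz <- t(apply(tr$coords, 3, function(m) as.numeric(t(m)) * 10))
  fitted <- bio3d::fit.xyz(xyz[1, ], xyz, 1:(3 * n_atoms), 1:(3 * n_atoms))
  oracle <- mean(bio3d::rmsd(fitted[1, ], fitted[-1, ])) / 10
  expect_equal(mean_rmsd, oracle, tolerance = 1e-3)
  expect_equal(mean_rmsd, sigma * sqrt(3), tolerance = 0.1)
})

test_that("RMSF recovers planted per-atom amplitudes and analytic cases", {
  at <- tiny_topology(rep("CA", 40), resids = 1:40)
  # constant trajectory: zero everywhere
  base <- matrix(runif(120, 0, 3), 40, 3)
  trc <- trajectory(at, array(rep(base, 5), c(40, 3, 5)))
  expect_true(all(rmsf(trc, seq_len(40))$value < 1e-12))
  # one atom alternating +/- d along x about the mean: RMSF = d
  d <- 0.05
  co <- array(rep(base, 4), c(40, 3, 4))
  co[7, 1, ] <- base[7, 1] + c(d, -d, d, -d)
  tr2 <- trajectory(at, co)
  prof <- rmsf(tr2, seq_len(40), fit_selection = (1:40)[-7])
  expect_equal(prof$value[7], d, tolerance = 1e-9)
  # planted Gaussian amplitudes recovered at many frames
  set.seed(7)
  amps <- runif(40, 0.01, 0.06)
  nfr <- 5000L
  noise <- array(rnorm(40 * 3 * nfr), c(40, 3, nfr)) * amps
  tr3 <- trajectory(at, array(rep(base, nfr), c(40, 3, nfr)) + noise)
  prof3 <- rmsf(tr3, seq_len(40))
  expect_equal(prof3$value, sqrt(3) * amps, tolerance = 0.05)
  expect_error(rmsf(trc, 1:40, window_ns = 1e-9), "2 frames")
})

test_that("chain RMSF correlation reproduces closed-form Pearson r", {
  a <- c(0.1, 0.2, 0.15, 0.3, 0.25, 0.12, 0.18, 0.22, 0.28, 0.16)
  expect_equal(rmsf_chain_correlation(a, a), 1)
  expect_equal(rmsf_chain_correlation(a, -a + 0.5), -1)
  b <- c(0.12, 0.19, 0.2, 0.28, 0.2, 0.15, 0.2, 0.2, 0.3, 0.14)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(rmsf_chain_correlation(a, b), manual, tolerance = 1e-12)
  expect_error(rmsf_chain_correlation(a, rep(1, 10)), "zero variance")
})

test_that("radius of gyration matches analytic fixtures", {
  at <- tiny_topology(c("CA", "CA"), resids = 1:2)
  tr <- one_frame(at, rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
  expect_equal(radius_of_gyration(tr, 1:2, mass_weighted = FALSE)$value, 0.5)
  expect_equal(radius_of_gyration(tr, 1L)$value, 0)
  sq <- tiny_topology(rep("CA", 4), resids = 1:4)
  trs <- one_frame(sq, rbind(c(0.5, 0.5, 0), c(0.5, -0.5, 0),
                             c(-0.5, 0.5, 0), c(-0.5, -0.5, 0)))
  expect_equal(radius_of_gyration(trs, 1:4)$value, sqrt(0.5),
               tolerance = 1e-12)
})

test_that("COM distance is mass-weighted and exact on closed forms", {
  at <- tiny_topology(c("CA", "CA"), resids = 1:2)
  tr <- one_frame(at, rbind(c(0, 0, 0), c(0.7, 0, 0)))
  expect_equal(com_distance(tr, 1L, 2L)$value, 0.7)
  expect_equal(com_distance(tr, 1:2, 1:2)$value, 0)
  # two unequal-mass pairs with hand-computed centres
  at4 <- tiny_topology(c("C", "O", "C", "O"), resids = 1:4)
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 2, 0))
  tr4 <- one_frame(at4, co)
  mc <- element_mass("C"); mo <- element_mass("O")
  comA <- (mc * co[1, ] + mo * co[2, ]) / (mc + mo)
  comB <- (mc * co[3, ] + mo * co[4, ]) / (mc + mo)
  expect_equal(com_distance(tr4, 1:2, 3:4)$value,
               sqrt(sum((comA - comB)^2)), tolerance = 1e-12)
})

test_that("minimum distance equals an exhaustive double loop", {
  at <- tiny_topology(c("N", "O"), resids = 1:2)
  tr <- one_frame(at, rbind(c(0, 0, 0), c(0.29, 0, 0)))
  expect_equal(min_distance(tr, 1L, 2L)$value, 0.29)
  trc <- one_frame(at, rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(min_distance(trc, 1L, 2L)$value, 0)
  expect_error(min_distance(tr, 1:2, 2L), "overlap")

  set.seed(3)
  n <- 50L
  atn <- tiny_topology(rep("C", n), resids = seq_len(n))
  trn <- one_frame(atn, matrix(runif(3 * n, 0, 2), n, 3))
  ia <- 1:20; ib <- 21:50
  got <- min_distance(trn, ia, ib)$value
  brute <- Inf
  for (i in ia) for (j in ib) {
    brute <- min(brute, sqrt(sum((trn$coords[i, , 1] -
                                    trn$coords[j, , 1])^2)))
  }
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("SASA matches the analytic sphere and buries enclosed atoms", {
  # isolated atom: exact sphere area within quadrature error
  one <- sasa(matrix(0, 1, 3), elements = "X", probe_radius = 0.14,
              n_points = 960, radii = c(X = 0.15))
  expect_equal(one$total, 4 * pi * 0.29^2, tolerance = 0.01)
  # two identical atoms far apart: exact additivity
  two <- sasa(rbind(c(0, 0, 0), c(10, 0, 0)), elements = c("X", "X"),
              n_points = 960, radii = c(X = 0.15))
  expect_equal(two$total, 2 * one$total, tolerance = 1e-9)
  # an atom fully inside a much larger expanded sphere is buried
  big <- sasa(rbind(c(0, 0, 0), c(0.05, 0, 0)), elements = c("X", "Y"),
              n_points = 960, radii = c(X = 0.05, Y = 1.0))
  expect_equal(big$per_atom[1], 0)
  expect_error(sasa(matrix(0, 1, 3), elements = "ZZ"), "radius")
})

test_that("SASA decreases monotonically as two atoms approach", {
  seps <- seq(1.0, 0.1, by = -0.1)
  totals <- vapply(seps, function(s) {
    sasa(rbind(c(0, 0, 0), c(s, 0, 0)), elements = c("C", "C"),
         n_points = 480)$total
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-12))
})

test_that("metrics are invariant under global rigid motion of all frames", {
  cx <- toy_cache()
  tr <- make_gaussian_trajectory(cx$traj, 5, noise_sd = 0.01, seed = 9)
  shift <- matrix(c(1.5, -2, 0.7), nrow(tr$atoms), 3, byrow = TRUE)
  tr2 <- tr
  for (k in 1:5) {
    tr2$coords[, , k] <- tr$coords[, , k] %*% t(rot_z90) + shift
  }
  expect_equal(rmsd_series(tr2, "backbone")$value,
               rmsd_series(tr, "backbone")$value, tolerance = 1e-9)
  expect_equal(rmsf(tr2, "backbone")$value, rmsf(tr, "backbone")$value,
               tolerance = 1e-9)
  expect_equal(radius_of_gyration(tr2, "heavy")$value,
               radius_of_gyration(tr, "heavy")$value, tolerance = 1e-12)
  expect_equal(min_distance(tr2, "chain A", "chain B")$value,
               min_distance(tr, "chain A", "chain B")$value,
               tolerance = 1e-12)
  # SASA is rotation-invariant only up to quadrature: the test-point
  # sphere is fixed in the lab frame
  expect_equal(sasa(tr2, "heavy", n_points = 120)$total,
               sasa(tr, "heavy", n_points = 120)$total, tolerance = 2e-3)
})
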