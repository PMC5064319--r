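# PCA / essential-dynamics convergence diagnostics.

proj_series <- function(p, T_) {
  attr(p, "T") <- T_
  class(p) <- "ProjectionSeries"
  p
}

test_that("RMSD traces: identity, rotation and noisy frames", {
  s <- make_polymer(8)
  base <- structure_xyz(s)
  m <- matrix(base, ncol = 3, byrow = TRUE)
  R <- matrix(c(cos(1), -sin(1), 0, sin(1), cos(1), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- as.numeric(t(m %*% t(R) - 3))
  tr <- new_trajectory(s, rbind(base, rot))
  r <- rmsd_trace(tr, reference = base)
  expect_equal(r[1], 0, tolerance = 1e-8)
  expect_lt(r[2], 1e-6)
  # isotropic Gaussian noise sigma: mean RMSD equals sigma*sqrt(3) shrunk
  # by the finite-size fit correction sqrt((3N-7)/(3N)); needs a 3-D
  # (non-collinear) reference so the least-squares fit has generic rank
  sigma <- 0.5
  ref3d <- random_conformation(base, 2, seed = 21)
  set.seed(2)
  frames <- t(replicate(60, ref3d + stats::rnorm(length(base), 0, sigma)))
  tr2 <- new_trajectory(s, frames)
  r2 <- rmsd_trace(tr2, reference = ref3d)
  ca <- xyz_index(select_calpha(s))
  direct <- vapply(seq_len(60), function(i) {
    as.numeric(bio3d::rmsd(ref3d, frames[i, ], a.inds = ca, b.inds = ca,
                           fit = TRUE))
  }, numeric(1))
  expect_equal(as.numeric(r2), direct, tolerance = 1e-10)
  nca <- length(select_calpha(s))
  expected <- sigma * sqrt(3) * sqrt((3 * nca - 7) / (3 * nca))
  expect_lt(abs(attr(r2, "mean") - expected) / expected, 0.1)
})

test_that("covariance of a static trajectory is zero and trace is conserved", {
  s <- make_polymer(6)
  base <- structure_xyz(s)
  tr <- new_trajectory(s, rbind(base, base, base))
  tr$superposed <- TRUE
  C <- covariance_matrix(tr)
  expect_equal(max(abs(C)), 0)
  # trace identity on noisy data
  set.seed(3)
  X <- t(replicate(50, base + stats::rnorm(length(base), 0, 0.3)))
  tr2 <- new_trajectory(s, X); tr2$superposed <- TRUE
  C2 <- covariance_matrix(tr2, mass_weighted = FALSE)
  sel <- xyz_index(select_calpha(s))
  sub <- X[, sel, drop = FALSE]
  msf <- mean(rowSums(sweep(sub, 2, colMeans(sub))^2))
  expect_equal(sum(diag(C2)), msf, tolerance = 1e-10)
  expect_warning(covariance_matrix(new_trajectory(s, X)), "superposed")
})

test_that("planted 1-D oscillation gives a rank-1 covariance", {
  s <- make_polymer(6)
  tr <- make_trajectory(s, modes = mode_spec(amplitudes = 1.2), n_frames = 400,
                        seed = 4)
  tr$superposed <- TRUE  # planted mode is the only motion; no fit needed
  C <- covariance_matrix(tr)
  es <- suppressWarnings(pca_subspace(C, n_modes = 5, source = "planted"))
  expect_gt(es$values[1] / sum(es$all_values), 0.999)
  # eigen residual
  expect_lt(max(abs(C %*% es$vectors[, 1] - es$values[1] * es$vectors[, 1])), 1e-8)
})

test_that("pca subspace is orthonormal with descending eigenvalues", {
  set.seed(6)
  A <- matrix(rnorm(30 * 30), 30)
  C <- crossprod(A) / 30
  es <- suppressWarnings(pca_subspace(C, n_modes = 10, source = "random"))
  expect_equal(crossprod(es$vectors), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(es$values) <= 1e-12))
  expect_true(all(es$values >= 0))
  expect_equal(sum(es$all_values), sum(diag(C)), tolerance = 1e-8)
  expect_error(pca_subspace(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("projections recover planted modes and PCA variances", {
  s <- make_polymer(6)
  tr <- make_trajectory(s, modes = mode_spec(amplitudes = 2, periods = 100),
                        n_frames = 400, seed = 8)
  tr$superposed <- TRUE
  C <- covariance_matrix(tr)
  es <- suppressWarnings(pca_subspace(C, n_modes = 3, source = "planted"))
  p1 <- project_trajectory(tr, es, 1)
  gt <- attr(tr, "ground_truth")$modes[[1]]
  tvec <- seq_len(400) - 1
  planted <- 2 * cos(2 * pi * tvec / 100 + gt$phase)
  planted <- planted - mean(planted)
  # sign-invariant match; Calpha-subspace projection scales the planted
  # displacement by the mode's weight on the Calpha coordinates
  scale <- max(abs(p1)) / max(abs(planted))
  err <- min(max(abs(p1 - scale * planted)), max(abs(p1 + scale * planted)))
  expect_lt(err / max(abs(p1)), 0.05)
  expect_equal(stats::var(as.numeric(p1)) * 399 / 400, es$values[1],
               tolerance = 1e-6)
  # projecting the mean structure gives zero
  mean_frame <- colMeans(tr$xyz)
  tr_mean <- new_trajectory(s, matrix(mean_frame, 1)); tr_mean$superposed <- TRUE
  expect_lt(abs(as.numeric(project_trajectory(tr_mean, es, 1))), 1e-8)
})

test_that("cosine content separates basis cosines and noise", {
  n <- 1e4; T_ <- 1
  t <- seq(0, T_, length.out = n)
  expect_lt(abs(cosine_content(proj_series(cos(pi * t / T_), T_), 1) - 1), 1e-3)
  expect_lt(cosine_content(proj_series(cos(2 * pi * t / T_), T_), 1), 1e-3)
  expect_lt(abs(cosine_content(proj_series(cos(2 * pi * t / T_), T_), 2) - 1), 1e-3)
  # white noise: c1 small in at least 95% of seeded repeats
  small <- vapply(1:100, function(seed) {
    set.seed(seed)
    cosine_content(proj_series(stats::rnorm(n), T_), 1) < 0.05
  }, logical(1))
  expect_gte(mean(small), 0.95)
  expect_warning(cc <- cosine_content(proj_series(rep(0, 10), 1), 1), "zero")
  expect_true(is.nan(cc))
  # bounded in [0,1] on random series
  for (seed in 1:10) {
    set.seed(seed)
    cc <- cosine_content(proj_series(stats::rnorm(200), 1), 1)
    expect_gte(cc, 0); expect_lte(cc, 1)
  }
})

test_that("RMSIP identities: self, orthogonal, symmetric, bounded", {
  make_es <- function(V) {
    out <- list(vectors = V, values = rep(1, ncol(V)), all_values = rep(1, ncol(V)),
                captured = 1, center = rep(0, nrow(V)), selection = NULL,
                mass_weighted = FALSE, source = "x")
    class(out) <- "EssentialSubspace"
    out
  }
  set.seed(10)
  Q <- qr.Q(qr(matrix(rnorm(40 * 40), 40)))
  A <- make_es(Q[, 1:5]); B <- make_es(Q[, 6:10]); Cs <- make_es(Q[, 3:7])
  expect_equal(rmsip(A, A), 1, tolerance = 1e-12)
  expect_equal(rmsip(A, B), 0, tolerance = 1e-12)
  expect_equal(rmsip(A, Cs), rmsip(Cs, A), tolerance = 1e-12)
  # direct double-sum evaluation
  direct <- sqrt(sum(crossprod(Q[, 1:5], Q[, 3:7])^2) / 5)
  expect_equal(rmsip(A, Cs), direct, tolerance = 1e-12)
  expect_gte(rmsip(A, Cs), 0); expect_lte(rmsip(A, Cs), 1)
  expect_error(rmsip(A, make_es(Q[1:30, 1:5])), "dimension")
})

test_that("replica report: copies give RMSIP 1; related replicas beat unrelated", {
  s <- make_polymer(6)
  mk <- function(seed, amps = c(1.5, 0.8)) {
    tr <- make_trajectory(s, modes = mode_spec(amplitudes = amps,
                                               noise_sd = 0.05),
                          n_frames = 120, seed = seed)
    tr$superposed <- TRUE
    tr
  }
  r1 <- mk(1)
  rep_same <- replica_report(list(R1 = r1, R2 = r1), r1, n_modes = 4)
  expect_true(all(abs(rep_same$rmsip - 1) < 1e-8))
  expect_true(all(c("c1", "rmsd_mean", "rmsd_sd") %in% names(rep_same$summary)))
  # replicas sharing a mode model overlap more than an unrelated model
  mk2 <- function(seed, dseed) {
    tr <- make_trajectory(s, modes = mode_spec(amplitudes = c(1.5, 0.8),
                                               noise_sd = 0.05,
                                               direction_seed = dseed),
                          n_frames = 120, seed = seed)
    tr$superposed <- TRUE
    tr
  }
  a1 <- mk2(1, dseed = 100); a2 <- mk2(2, dseed = 100)
  b1 <- mk2(3, dseed = 200)
  es <- function(tr) suppressWarnings(
    pca_subspace(covariance_matrix(tr), n_modes = 2, source = "r"))
  expect_gt(rmsip(es(a1), es(a2)), rmsip(es(a1), es(b1)))
})
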