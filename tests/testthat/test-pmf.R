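test_that("PMF values follow the log-occupancy definition", {
  ens <- helical_ensemble(c(rep(32.05, 4), rep(33.05, 2)),
                          c(rep(0.505, 4), rep(0.605, 2)))
  pmf <- build_pmf2d(ens, twist_bin = 0.1, conj_bin = 0.01)
  occ <- sort(pmf$values[!is.na(pmf$values)])
  expect_equal(occ, c(0, log(2)), tolerance = 1e-12)
  expect_equal(unname(pmf$minimum[["twist"]]), 32.05, tolerance = 0.051)
  # degenerate: everything in one bin
  one <- helical_ensemble(rep(32, 5), rep(0.5, 5))
  expect_error(build_pmf2d(one), "single bin")
})

test_that("an exact quadratic surface is recovered to high precision", {
  cc <- rna_cc()
  fit <- fit_harmonic2d(analytic_pmf2d(cc), n_bp = 19)
  expect_equal(fit$constants$k_omega, 0.18, tolerance = 1e-8)
  expect_equal(fit$constants$k_conj, 3.61, tolerance = 1e-8)
  expect_equal(fit$constants$k_cross, 0.43, tolerance = 1e-8)
  expect_equal(fit$constants$omega0, 32.15, tolerance = 1e-8)
  expect_equal(fit$constants$conj0, 0.52, tolerance = 1e-8)
  expect_lt(fit$residual_rms, 1e-10)
  # DNA constants through the same path
  ccd <- dna_cc()
  fitd <- fit_harmonic2d(analytic_pmf2d(ccd, conj_bin = 5e-4), n_bp = 19)
  expect_equal(fitd$constants$k_conj, 263, tolerance = 1e-8)
  expect_equal(fitd$constants$k_cross, 4.5, tolerance = 1e-8)
})

test_that("sampled reference ensemble returns the generating constants", {
  ens <- rna_ensemble(n_snapshots = 5e4, seed = 2)
  fit <- fit_coupling(ens)
  expect_lt(abs(fit$constants$k_omega - 0.18), 0.01)
  expect_lt(abs(fit$constants$k_conj - 3.61), 0.28)
  expect_lt(abs(fit$constants$k_cross - 0.43), 0.05)
  expect_lt(abs(fit$constants$omega0 - 32.15), 0.1)
  expect_lt(abs(fit$constants$conj0 - 0.52), 0.01)
  # moment oracle: invert the sample covariance instead of fitting the PMF
  K_mom <- solve(stats::cov(ens$records)) / 19
  expect_equal(fit$constants$k_omega, K_mom[1, 1], tolerance = 0.06)
  expect_equal(fit$constants$k_conj, K_mom[2, 2], tolerance = 0.06)
  expect_equal(fit$constants$k_cross, K_mom[1, 2], tolerance = 0.1)
})

test_that("recovered constants are stable under bin refinement", {
  coarse <- fit_coupling(rna_ensemble(n_snapshots = 12500, seed = 6),
                         twist_bin = 0.2, conj_bin = 0.02)
  fine <- fit_coupling(rna_ensemble(n_snapshots = 5e4, seed = 6),
                       twist_bin = 0.1, conj_bin = 0.01)
  expect_equal(coarse$constants$k_omega, fine$constants$k_omega,
               tolerance = 0.1)
  expect_equal(coarse$constants$k_conj, fine$constants$k_conj,
               tolerance = 0.1)
  expect_equal(coarse$constants$k_cross, fine$constants$k_cross,
               tolerance = 0.15)
})

test_that("conditional twist profiles have curvature n_bp * k_omega / 2", {
  ens <- rna_ensemble(n_snapshots = 5e4, seed = 4)
  target <- 19 * 0.18 / 2
  centers <- numeric(3)
  windows <- list(c(0.3, 0.4), c(0.5, 0.6), c(0.7, 0.8))
  for (i in seq_along(windows)) {
    q <- fit_quadratic1d(conditional_profile(ens, windows[[i]]), cutoff = 3)
    expect_equal(q$curvature, target, tolerance = 0.15)
    centers[i] <- q$center
  }
  # minima shift to smaller twist as the groove widens (positive coupling)
  expect_true(all(diff(centers) < 0))
  expect_error(conditional_profile(ens, c(5, 6)), "no snapshots")
})

test_that("1-D quadratic fitting matches analytic profiles", {
  x <- seq(30, 34, by = 0.1)
  p <- pmf1d(x, 1.7 * (x - 32.05)^2)
  q <- fit_quadratic1d(p)
  expect_equal(q$center, 32.05, tolerance = 1e-9)
  expect_equal(q$curvature, 1.7, tolerance = 1e-9)
  # constant offsets do not move the fit
  p2 <- pmf1d(x, 1.7 * (x - 32.05)^2 + 2.4)
  q2 <- fit_quadratic1d(p2)
  expect_equal(q2$center, q$center, tolerance = 1e-9)
  expect_equal(q2$curvature, q$curvature, tolerance = 1e-9)
  expect_error(fit_quadratic1d(pmf1d(x, rep(1, length(x)))), "convex")
})

test_that("conditional mean twist slope equals -k_cross / k_omega", {
  ens <- rna_ensemble(n_snapshots = 5e4, seed = 8)
  sl <- conditional_mean_slope(ens)
  expect_lt(abs(sl$slope - (-0.43 / 0.18)), 3 * sl$stderr)
  # direct regression on the raw samples as a brute-force cross-check
  raw <- unname(stats::coef(stats::lm(twist ~ conj, data = ens$records))[2])
  expect_equal(sl$slope, raw, tolerance = 0.1)
  # decoupled constants: slope indistinguishable from zero
  cc0 <- coupling_constants(0.18, 3.61, 0, omega0 = 32.15, conj0 = 0.52)
  e0 <- sample_pair_ensemble(ensemble_spec(cc0, n_snapshots = 2e4, seed = 8))
  s0 <- conditional_mean_slope(e0)
  expect_lt(abs(s0$slope), 3 * s0$stderr)
  # invariant under the chain-averaging length
  e1 <- sample_pair_ensemble(ensemble_spec(rna_cc(), n_bp = 1,
                                           n_snapshots = 5e4, seed = 8))
  s1 <- conditional_mean_slope(e1, conj_bin = 0.05)
  expect_lt(abs(s1$slope - (-0.43 / 0.18)), 3 * s1$stderr)
})
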