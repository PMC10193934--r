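test_that("generator is reproducible and seed is mandatory", {
  a <- rna_ensemble(n_snapshots = 500, seed = 11)
  b <- rna_ensemble(n_snapshots = 500, seed = 11)
  expect_identical(a$records, b$records)
  c <- rna_ensemble(n_snapshots = 500, seed = 12)
  expect_false(identical(a$records, c$records))
  expect_error(ensemble_spec(rna_cc(), n_snapshots = 10), "seed")
})

test_that("chain-averaged sample covariance converges to K^-1 / n_bp", {
  ens <- rna_ensemble(n_snapshots = 5e4, seed = 3)
  S <- avg_cov(rna_cc(), 19)
  cv <- stats::cov(ens$records)
  n <- nrow(ens$records)
  # 3 x asymptotic standard errors of variance / covariance estimates
  se_var <- function(s2) s2 * sqrt(2 / (n - 1))
  se_cov <- sqrt((S[1, 1] * S[2, 2] + S[1, 2]^2) / n)
  expect_lt(abs(cv[1, 1] - S[1, 1]), 3 * se_var(S[1, 1]))
  expect_lt(abs(cv[2, 2] - S[2, 2]), 3 * se_var(S[2, 2]))
  expect_lt(abs(cv[1, 2] - S[1, 2]), 3 * se_cov)
  expect_equal(S[1, 1], 0.40869, tolerance = 1e-4)  # 2x2 inverse oracle
  expect_equal(mean(ens$records$twist), 32.15,
               tolerance = 3 * sqrt(S[1, 1] / n) / 32.15)
})

test_that("decoupled constants give uncorrelated coordinates", {
  cc <- coupling_constants(0.18, 3.61, 0, omega0 = 32.15, conj0 = 0.52)
  ens <- sample_pair_ensemble(ensemble_spec(cc, n_snapshots = 2e4, seed = 5))
  expect_lt(abs(stats::cor(ens$records$twist, ens$records$conj)),
            3.5 / sqrt(2e4))
})

test_that("tilt force shifts the ensemble mean by the closed form", {
  f <- 1
  ens <- rna_ensemble(n_snapshots = 5e4, seed = 7, tilt_force = f)
  sh <- equilibrium_shift(rna_cc(), f)
  expect_equal(unname(sh), c(-0.9249301, 0.38718), tolerance = 1e-6)
  S <- avg_cov(rna_cc(), 19)
  n <- nrow(ens$records)
  expect_lt(abs(mean(ens$records$twist) - (32.15 + sh[["delta_twist"]])),
            3 * sqrt(S[1, 1] / n))
  expect_lt(abs(mean(ens$records$conj) - (0.52 + sh[["delta_conj"]])),
            3 * sqrt(S[2, 2] / n))
})

test_that("multi-temperature profiles have the constructed U/S structure", {
  grid <- seq(0.3, 0.74, by = 0.01)
  u <- function(g) 400 * (g - 0.52)^2
  # zero entropy slope: identical profiles once converted back to kJ/mol
  p0 <- generate_multi_temperature(u, 0, c(285, 315), grid)
  f1 <- kbt_to_kjmol(p0[[1]]$values, 285)
  f2 <- kbt_to_kjmol(p0[[2]]$values, 315)
  expect_equal(f1, f2, tolerance = 1e-12)
  # linear entropy: two-temperature decomposition recovers the slope exactly
  ps <- generate_multi_temperature(u, 0.024, c(285, 315), grid)
  dec <- decompose_U_S(ps)
  expect_equal(dec$k_SG, 0.024, tolerance = 1e-10)
  # tabulated U input agrees with functional input
  pt <- generate_multi_temperature(data.frame(g = grid, u = u(grid)),
                                   0.024, c(285, 315), grid)
  expect_equal(pt[[1]]$values, ps[[1]]$values, tolerance = 1e-12)
  expect_error(generate_multi_temperature(u, 0.024, 295, grid),
               "two distinct")
})

test_that("synthetic rotation-extension curves recover their true centre", {
  # noiseless symmetric tent: crossing is exact
  cur <- synth_rotation_extension(3, left_slope = 0.05, right_slope = -0.05,
                                  plateau_halfwidth = 0, noise_sd = 0,
                                  seed = 1)
  expect_equal(fit_torsion_relaxed(cur)$center_turn, 3, tolerance = 1e-9)
  # asymmetric slopes with a smooth cap still cross at the centre
  cur2 <- synth_rotation_extension(-4, left_slope = 0.04,
                                   right_slope = -0.07,
                                   plateau_halfwidth = 3, noise_sd = 0,
                                   seed = 1)
  expect_equal(fit_torsion_relaxed(cur2)$center_turn, -4, tolerance = 1e-9)
  # extension rescaling (refractive-index surrogate) leaves the peak alone
  cur3 <- cur2
  cur3$extension <- cur3$extension * 1.37
  expect_equal(fit_torsion_relaxed(cur3)$center_turn,
               fit_torsion_relaxed(cur2)$center_turn, tolerance = 1e-12)
  # default noise: recovery within half a turn
  cur4 <- synth_rotation_extension(7, seed = 42)
  expect_lt(abs(fit_torsion_relaxed(cur4)$center_turn - 7), 0.5)
  expect_error(synth_rotation_extension(3, n_points = 5, seed = 1),
               "at least 8")
  expect_error(synth_rotation_extension(3, left_slope = -1, seed = 1),
               "positive")
})

test_that("complex/standalone pairs encode the requested mean shift", {
  base <- ensemble_spec(rna_cc(), n_snapshots = 2e4, seed = 9)
  pair0 <- synth_complex_pair(base, c(0, 0), seed = 9)
  S <- avg_cov(rna_cc(), 19)
  d0 <- delta_vs_standalone(pair0$complex, pair0$standalone)
  expect_lt(abs(d0$delta_twist), 3 * sqrt(2 * S[1, 1] / 2e4))
  expect_lt(abs(d0$delta_conj), 3 * sqrt(2 * S[2, 2] / 2e4))
  pair <- synth_complex_pair(base, c(1.0, -0.1), seed = 10)
  d <- delta_vs_standalone(pair$complex, pair$standalone)
  expect_lt(abs(d$delta_twist - 1.0), 3 * sqrt(2 * S[1, 1] / 2e4))
  expect_lt(abs(d$delta_conj + 0.1), 3 * sqrt(2 * S[2, 2] / 2e4))
})
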