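test_that("closed-form equilibrium shift matches hand-derived values", {
  expect_equal(equilibrium_shift(rna_cc(), 0),
               c(delta_twist = 0, delta_conj = 0))
  sh <- equilibrium_shift(rna_cc(), 1)
  expect_equal(unname(sh), c(-0.43, 0.18) / 0.4649, tolerance = 1e-12)
  shd <- equilibrium_shift(dna_cc(), 1)
  expect_equal(unname(shd), c(-4.5, 0.18) / 27.09, tolerance = 1e-12)
  expect_equal(unname(shd), c(-0.165, 0.0066), tolerance = 2e-2)
})

test_that("grid minimization of the tilted energy agrees with closed form", {
  sh <- minimize_tilted_oracle(rna_cc(), 1, grid_halfwidth = c(2, 1),
                               grid_step = 1e-3)
  cf <- equilibrium_shift(rna_cc(), 1)
  expect_lt(abs(sh[["delta_twist"]] - cf[["delta_twist"]]), 1e-3)
  expect_lt(abs(sh[["delta_conj"]] - cf[["delta_conj"]]), 1e-3)
  expect_error(minimize_tilted_oracle(rna_cc(), 1,
                                      grid_halfwidth = c(0.5, 0.1)),
               "boundary")
  # property: 100 seeded random positive-definite constant sets
  step <- 0.01
  for (s in 1:100) {
    cc <- random_cc(s)
    set.seed(1000 + s)
    f <- stats::runif(1, -1, 1)
    cf <- equilibrium_shift(cc, f)
    hw <- abs(unname(cf)) * 1.5 + 20 * step
    gr <- minimize_tilted_oracle(cc, f, grid_halfwidth = hw,
                                 grid_step = step)
    expect_lt(abs(gr[["delta_twist"]] - cf[["delta_twist"]]), step)
    expect_lt(abs(gr[["delta_conj"]] - cf[["delta_conj"]]), step)
  }
})

test_that("salt response curve is zero at 1 M and monotone below it", {
  cs <- c(1, 0.5, 0.2, 0.1, 0.05)
  rc <- salt_twist_curve(rna_cc(), electrostatic_params(), cs)
  expect_identical(rc$data$delta_twist[1], 0)
  expect_equal(rc$data$delta_twist[5], -1.72, tolerance = 2e-3)
  # twist drops steadily as salt is lowered
  expect_true(all(diff(rc$data$delta_twist) < 0))
  # sign convention: positive force, positive coupling -> undertwist, widening
  expect_true(all(rc$data$delta_twist[-1] < 0))
  expect_true(all(rc$data$delta_conj[-1] > 0))
})

test_that("response is linear in the force and in the rescale factor", {
  sh1 <- equilibrium_shift(rna_cc(), 0.3)
  sh2 <- equilibrium_shift(rna_cc(), 0.6)
  expect_equal(unname(sh2), 2 * unname(sh1), tolerance = 1e-12)
  r1 <- salt_twist_curve(rna_cc(), electrostatic_params(rescale_alpha = 0.9),
                         c(0.1))
  r2 <- salt_twist_curve(rna_cc(), electrostatic_params(rescale_alpha = 1.8),
                         c(0.1))
  expect_equal(r2$data$delta_twist, 2 * r1$data$delta_twist,
               tolerance = 1e-12)
})

test_that("temperature coefficient is negative with the expected magnitude", {
  expect_identical(temp_twist_coefficient(rna_cc(), 0), 0)
  co <- temp_twist_coefficient(rna_cc(), 0.024, 295)
  expect_equal(co, -0.00905, tolerance = 1e-3)
  expect_lt(co, 0)
  expect_gt(abs(co), 0.008)
  expect_lt(abs(co), 0.016)
  # sign follows the couplings
  cc_neg <- coupling_constants(0.18, 3.61, -0.43)
  expect_gt(temp_twist_coefficient(cc_neg, 0.024, 295), 0)
})

test_that("sampling under a tilt reproduces the closed-form displacement", {
  f <- 0.8
  ens <- rna_ensemble(n_snapshots = 5e4, seed = 13, tilt_force = f)
  fit <- fit_coupling(ens)
  sh <- equilibrium_shift(rna_cc(), f)
  S <- avg_cov(rna_cc(), 19)
  expect_lt(abs(fit$constants$omega0 - (32.15 + sh[["delta_twist"]])),
            3 * sqrt(S[1, 1] / 5e4) + 0.01)
  expect_lt(abs(fit$constants$conj0 - (0.52 + sh[["delta_conj"]])),
            3 * sqrt(S[2, 2] / 5e4) + 0.002)
})

test_that("salt, temperature and force tilts displace along one pathway", {
  # equal-magnitude tilts produced by the three drivers must land on the
  # same line through the reference point
  ep <- electrostatic_params()
  f_salt <- 1.8 * delta_force_salt(0.1, ep)
  f_temp <- thermal_force(25, 0.024, 295)
  f_force <- 0.45
  means <- function(f, seed) {
    e <- rna_ensemble(n_snapshots = 2e4, seed = seed, tilt_force = f)
    c(mean(e$records$twist), mean(e$records$conj))
  }
  slope_ref <- -0.43 / 0.18
  for (fs in list(c(f_salt, 21), c(f_temp, 22), c(f_force, 23))) {
    m <- means(fs[1], fs[2])
    pred <- 32.15 + slope_ref * (m[2] - 0.52)
    expect_lt(abs(m[1] - pred), 0.05)
  }
})
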