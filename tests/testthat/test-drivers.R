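test_that("Debye length follows the monovalent closed form", {
  expect_identical(debye_length(1), 0.3034)
  expect_equal(debye_length(0.25), 0.6068, tolerance = 1e-12)
  expect_equal(debye_length(0.01), 3.034, tolerance = 1e-12)
  expect_error(debye_length(0), "positive")
  expect_error(debye_length(-0.1), "positive")
})

test_that("screened P-P force matches an independent numerical derivative", {
  params <- electrostatic_params()
  # independent oracle: Richardson-extrapolated central difference of the
  # screened potential, built from scratch in test code
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  pot <- function(r, lam) e^2 / (4 * pi * 78.4 * eps0) * 1e9 *
    exp(-r / lam) / r                       # J nm / nm = J
  num_force <- function(c_salt, r = 0.6) {
    lam <- 0.3034 / sqrt(c_salt)
    h <- 1e-3
    d1 <- (pot(r - h, lam) - pot(r + h, lam)) / (2 * h)
    d2 <- (pot(r - h / 2, lam) - pot(r + h / 2, lam)) / h
    (4 * d2 - d1) / 3 / (kB * 295)          # kBT/nm
  }
  for (cs in c(1, 0.3, 0.05, 0.01))
    expect_equal(pp_force(cs, params), num_force(cs), tolerance = 1e-8)
  expect_equal(pp_force(1, params), 0.827, tolerance = 1e-3)
  # screened decay: force vanishes at large separation
  far <- electrostatic_params(pp_distance = 50)
  expect_lt(pp_force(1, far), 1e-10)
  # force grows monotonically as salt is lowered
  cg <- exp(seq(log(0.01), log(1), length.out = 40))
  expect_true(all(diff(vapply(cg, pp_force, numeric(1))) < 0))
})

test_that("salt force change is referenced to 1 M and positive below it", {
  params <- electrostatic_params()
  expect_identical(delta_force_salt(1, params), 0)
  expect_equal(delta_force_salt(0.05, params), 1.0329, tolerance = 1e-3)
  cs <- c(0.01, 0.05, 0.15, 0.5, 0.99)
  expect_true(all(vapply(cs, delta_force_salt, numeric(1),
                         params = params) > 0))
})

test_that("U/S decomposition solves the two-unknown system exactly", {
  grid <- seq(0.3, 0.7, by = 0.02)
  U <- 380 * (grid - 0.5)^2 + 1
  S <- 0.024 * grid + 0.003
  temps <- c(285, 305)
  pmfs <- lapply(temps, function(tt)
    pmf1d(grid, kjmol_to_kbt(U - tt * S, tt), temperature = tt,
          coordinate_label = "conj"))
  dec <- decompose_U_S(pmfs)
  expect_equal(dec$U, U, tolerance = 1e-9)
  expect_equal(dec$S, S, tolerance = 1e-9)
  expect_equal(dec$k_SG, 0.024, tolerance = 1e-10)
  expect_lt(max(dec$residuals), 1e-9)
  # a G-independent offset per profile cannot change the entropy slope
  pmfs_off <- lapply(seq_along(temps), function(i)
    pmf1d(grid, pmfs[[i]]$values + i * 3.1, temperature = temps[i],
          coordinate_label = "conj"))
  expect_equal(decompose_U_S(pmfs_off)$k_SG, dec$k_SG, tolerance = 1e-10)
  expect_error(decompose_U_S(pmfs[1]), ">= 2")
  same_T <- list(pmfs[[1]], pmfs[[1]])
  expect_error(decompose_U_S(same_T), "distinct")
})

test_that("entropy slope survives the full generate/decompose round trip", {
  grid <- seq(0.3, 0.74, by = 0.005)
  pmfs <- generate_multi_temperature(function(g) 400 * (g - 0.52)^2,
                                     s_coeff = 0.024,
                                     temps = c(285, 295, 305, 315),
                                     grid = grid)
  dec <- decompose_U_S(pmfs)
  expect_equal(dec$k_SG, 0.024, tolerance = 1e-6)
  # overdetermined system still has vanishing residuals for exact inputs
  expect_lt(max(dec$residuals), 1e-9)
  # fit window restriction does not change a globally linear slope
  dec_w <- decompose_U_S(pmfs, fit_window = c(0.4, 0.64))
  expect_equal(dec_w$k_SG, 0.024, tolerance = 1e-6)
})

test_that("thermal force converts the entropy slope to kBT/nm", {
  expect_identical(thermal_force(0, 0.024), 0)
  expect_equal(thermal_force(1, 0.024, 295), 0.024 / (8.314462618 * 0.295),
               tolerance = 1e-12)
  expect_equal(thermal_force(1, 0.024, 295), 0.009786, tolerance = 2e-4)
  expect_equal(thermal_force(7, 0.024, 295), 7 * thermal_force(1, 0.024, 295))
})
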