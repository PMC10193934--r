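# Shared fixtures: reference constants and small generators built in code.

rna_cc <- function() {
  coupling_constants(0.18, 3.61, 0.43, omega0 = 32.15, conj0 = 0.52,
                     coordinate_label = "groove_width")
}

dna_cc <- function() {
  coupling_constants(0.18, 263, 4.5, omega0 = 34.3, conj0 = 2.0,
                     coordinate_label = "diameter")
}

rna_ensemble <- function(n_snapshots = 5e4, seed = 1, tilt_force = 0,
                         n_bp = 19) {
  sample_pair_ensemble(ensemble_spec(rna_cc(), n_bp = n_bp,
                                     n_snapshots = n_snapshots,
                                     tilt_force = tilt_force, seed = seed))
}

# population covariance of the chain-averaged coordinates
avg_cov <- function(cc, n_bp = 19) {
  K <- matrix(c(cc$k_omega, cc$k_cross, cc$k_cross, cc$k_conj), 2, 2)
  solve(K) / n_bp
}

# analytic chain-averaged quadratic surface wrapped as a pmf2d
analytic_pmf2d <- function(cc, n_bp = 19, n_sd = 3.5,
                           twist_bin = 0.05, conj_bin = 0.005) {
  S <- avg_cov(cc, n_bp)
  tg <- seq(cc$omega0 - n_sd * sqrt(S[1, 1]), cc$omega0 + n_sd * sqrt(S[1, 1]),
            by = twist_bin)
  cg <- seq(cc$conj0 - n_sd * sqrt(S[2, 2]), cc$conj0 + n_sd * sqrt(S[2, 2]),
            by = conj_bin)
  Kavg <- solve(S)
  vals <- outer(tg - cc$omega0, cg - cc$conj0, function(a, b)
    0.5 * Kavg[1, 1] * a^2 + 0.5 * Kavg[2, 2] * b^2 + Kavg[1, 2] * a * b)
  pmf2d(tg, cg, vals, n_bp = n_bp,
        coordinate_label = cc$coordinate_label)
}

# seeded random positive-definite coupling constants
random_cc <- function(seed) {
  set.seed(seed)
  k_omega <- stats::runif(1, 0.1, 0.4)
  k_conj <- stats::runif(1, 2, 8)
  rho <- stats::runif(1, -0.6, 0.6)
  coupling_constants(k_omega, k_conj, rho * sqrt(k_omega * k_conj))
}
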