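test_that("partition fractions match hand-derived values and normalise", {
  eq <- site_affinities(1e6, 1e6, omega = 1)
  f <- partition_fractions(eq, 1e-6)
  expect_equal(c(f$f0, f$f1, f$f2), c(0.25, 0.50, 0.25))

  coop <- site_affinities(1e6, 1e6, omega = 4)
  f4 <- partition_fractions(coop, 1e-6)
  expect_equal(c(f4$f0, f4$f1, f4$f2), c(1, 2, 4) / 7)

  f0 <- partition_fractions(coop, 0)
  expect_equal(c(f0$f0, f0$f1, f0$f2), c(1, 0, 0))
  expect_error(partition_fractions(coop, -1e-9), "non-negative")
})

test_that("fractions equal the 4-microstate Boltzmann enumeration", {
  withr::with_seed(3, {
    for (i in 1:200) {
      K1 <- 10^runif(1, 3, 8)
      K2 <- 10^runif(1, 3, 8)
      om <- 10^runif(1, -2, 2)
      p <- 10^runif(1, -9, -4)
      f <- partition_fractions(site_affinities(K1, K2, om), p)
      want <- boltzmann_fractions(K1, K2, om, p)
      expect_equal(unname(c(f$f0, f$f1, f$f2)), unname(want), tolerance = 1e-12)
      expect_equal(f$f0 + f$f1 + f$f2, 1, tolerance = 1e-9)
    }
  })
})

test_that("free-protein solver satisfies conservation under depletion", {
  eq <- site_affinities(1e6, 1e6, omega = 1)
  # closed-form check: equal independent sites at p_tot = d_tot = 2.5 uM
  # reduce to the quadratic p^2 + 3.5 p - 2.5 = 0 in uM units
  pf <- solve_free_protein(eq, 2.5e-6, 2.5e-6)
  expect_equal(pf * 1e6, (-3.5 + sqrt(22.25)) / 2, tolerance = 1e-9)

  expect_equal(solve_free_protein(eq, 3e-6, 0), 3e-6)
  expect_equal(solve_free_protein(eq, 0, 2.5e-6), 0)

  withr::with_seed(5, {
    for (i in 1:200) {
      pars <- site_affinities(10^runif(1, 3, 8), 10^runif(1, 3, 8),
                              10^runif(1, -2, 2))
      pt <- 10^runif(1, -8, -4)
      dt <- 10^runif(1, -8, -4)
      pf <- solve_free_protein(pars, pt, dt)
      f <- partition_fractions(pars, pf)
      resid <- abs(pt - pf - dt * (f$f1 + 2 * f$f2)) / max(pt, dt)
      expect_lt(resid, 1e-10)
    }
  })
})

test_that("titration series saturate and deplete monotonically", {
  eq <- site_affinities(1e6, 1e6, omega = 1)
  ser <- simulate_titration(eq, c(0, 1, 2, 4, 8, 20, 100, 1000) * 1e-6, 2.5e-6)
  expect_true(all(diff(ser$f0) <= 1e-12)) # free DNA never increases
  expect_gt(ser$f2[nrow(ser)], 0.99)      # saturating protein -> all dimer
  expect_equal(ser$f0[1], 1)
})

test_that("lane estimator matches hand arithmetic and flags unusable lanes", {
  expect_equal(omega_from_lane(0.25, 0.50, 0.25), 1.0)
  expect_equal(omega_from_lane(1 / 7, 2 / 7, 4 / 7), 4.0)
  expect_equal(omega_from_lane(0.5, 0.5, 0.0), 0.0)
  expect_true(is.na(omega_from_lane(0.5, 0.04, 0.46)))
  expect_error(omega_from_lane(-0.2, 0.5, 0.7), "non-negative")
})

test_that("estimator is exact on noiseless equal-site series", {
  for (om in c(1, 3, 21)) {
    pars <- site_affinities(1.27e6, 1.27e6, om)
    ser <- simulate_titration(pars, seq(0.5, 10, length.out = 8) * 2.5e-6, 2.5e-6)
    est <- estimate_omega(ser)
    expect_equal(est$omega_hat, om, tolerance = 1e-9)
    expect_equal(est$se, 0, tolerance = 1e-9)
  }
})

test_that("estimator bias for unequal sites follows the closed form", {
  # 4 f0 f2 / f1^2 = omega * 4 K1 K2 / (K1 + K2)^2 at any free concentration
  K2 <- 2e5; K1 <- 10 * K2; om <- 3
  pars <- site_affinities(K1, K2, om)
  f <- partition_fractions(pars, 10^seq(-7, -5, length.out = 7))
  got <- omega_from_lane(f$f0, f$f1, f$f2, epsilon_f1 = 0)
  expect_equal(got, rep(om * 4 * K1 * K2 / (K1 + K2)^2, 7), tolerance = 1e-12)
})

test_that("estimate_omega handles replicates, classification and failure modes", {
  flat <- tibble::tibble(f0 = rep(0.25, 4), f1 = rep(0.5, 4), f2 = rep(0.25, 4))
  est <- estimate_omega(flat)
  expect_equal(est$omega_hat, 1)
  expect_equal(est$se, 0)
  expect_equal(est$classification, "none")

  # all monomer fractions below threshold -> actionable error
  sat <- tibble::tibble(f0 = c(0.5, 0.48), f1 = c(0.01, 0.02), f2 = c(0.49, 0.5))
  expect_error(estimate_omega(sat), "mid-titration")

  # replicate-level SEM path
  pars <- site_affinities(1.27e6, 1.27e6, 3)
  ser <- gen_emsa_series(pars, sigma_frac = 0.03, n_replicates = 3, seed = 11)
  est3 <- estimate_omega(ser)
  expect_gt(est3$se, 0)
  expect_equal(est3$classification, "positive")
})

test_that("affinity fit round-trips noiseless simulations", {
  truth <- site_affinities(1.27e6, 1.27e6, omega = 3)
  lanes <- simulate_titration(truth, c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 20) * 1e-6,
                              2.5e-6)
  fit <- fit_affinities(lanes)
  expect_true(fit$converged)
  expect_equal(fit$params$K1, truth$K1, tolerance = 1e-6)
  expect_equal(fit$params$K2, truth$K2, tolerance = 1e-6)
  expect_equal(fit$params$omega, truth$omega, tolerance = 1e-6)
  expect_gte(fit$params$K1, fit$params$K2)

  td <- tidy(fit)
  expect_equal(td$term, c("K1", "K2", "omega"))
  expect_s3_class(glance(fit), "tbl_df")

  # anchoring one site lifts the equal-sites convention
  truth2 <- site_affinities(2e6, 2e5, omega = 5)
  lanes2 <- simulate_titration(truth2, c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 20) * 1e-6,
                               2.5e-6)
  fit2 <- fit_affinities(lanes2, fix = list(K1 = 2e6))
  expect_equal(fit2$params$K2, 2e5, tolerance = 1e-6)
  expect_equal(fit2$params$omega, 5, tolerance = 1e-6)
})

test_that("a series without dimer drives omega to the boundary with a flag", {
  lanes <- simulate_titration(site_affinities(1e6, 1e6, 1e-12),
                              c(1, 2, 4, 8, 12) * 1e-6, 2.5e-6)
  fit <- fit_affinities(lanes)
  expect_true(fit$boundary)
  expect_lt(fit$params$omega, 1e-6)
})

test_that("macroscopic constants follow the sequential-site mapping", {
  eq <- site_affinities(1e6, 1e6, 1)
  m <- macroscopic_constants(eq)
  expect_equal(unname(m["Ka1"]), 2e6)
  expect_equal(unname(m["Ka2"]), 5e5)
  expect_equal(unname(m["Ka1"] / m["Ka2"]), 4) # statistical factor

  m2 <- macroscopic_constants(site_affinities(1e6, 1e4, 1))
  expect_equal(unname(m2["Ka1"]), 1.01e6)
  expect_equal(unname(m2["Ka2"]), 1e10 / 1.01e6, tolerance = 1e-12)

  m0 <- macroscopic_constants(site_affinities(1e6, 1e6, 0))
  expect_equal(unname(m0["Ka2"]), 0)
})

test_that("duplex mass is reproducible, symmetric and validated", {
  # frozen from the average residue-mass table (7A 7T 1C 1G per strand,
  # -61.96 Da end correction per strand)
  m <- duplex_mass(P53_16MER)
  expect_equal(m, 2 * (7 * 313.21 + 7 * 304.20 + 289.18 + 329.21 - 61.96) / 1000)
  expect_equal(m, 9.7566, tolerance = 1e-9)
  expect_equal(duplex_mass(reverse_complement(P53_16MER)), m)
  expect_error(duplex_mass("ACGTN"), "N")
  expect_error(dna_sequence(""), "non-empty")
})

test_that("stoichiometry calls match the printed light-scattering masses", {
  dna <- duplex_mass(P53_16MER)
  expect_equal(infer_stoichiometry(32.7, 12.4, dna)$n_protein, 2L)
  expect_equal(infer_stoichiometry(20.1, 12.4, duplex_mass(DBE2_16MER))$n_protein, 1L)
  expect_equal(infer_stoichiometry(9.76, 12.4, 9.76)$n_protein, 0L)
  expect_error(infer_stoichiometry(2, 12.4, 9.76), "non-negative")
  expect_error(infer_stoichiometry(-1, 12.4, 9.76), "positive")
})
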