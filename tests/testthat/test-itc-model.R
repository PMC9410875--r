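test_that("injection bookkeeping matches the displacement recursion", {
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 20))
  conc <- concentrations_after_injection(prot)

  # first injection, closed form: 750 * (2.5/200) * (1 - 2.5/400) uM
  expect_equal(conc$p_total[1] * 1e6, 750 * (2.5 / 200) * (1 - 2.5 / (2 * 200)),
               tolerance = 1e-12)
  expect_equal(conc$d_total[1], 50e-6 * (1 - 2.5 / 200), tolerance = 1e-15)

  # independent loop oracle re-deriving the recursion step by step
  V0 <- 200e-6; v <- 2.5e-6
  D <- 50e-6; P <- 0
  for (i in 1:20) {
    D <- D * (1 - v / V0)
    P <- P * (1 - v / V0) + 750e-6 * (v / V0) * (1 - v / (2 * V0))
    expect_equal(conc$d_total[i], D, tolerance = 1e-15)
    expect_equal(conc$p_total[i], P, tolerance = 1e-15)
  }

  # injected moles are exactly syringe_conc * volume per injection
  expect_equal(sum(conc$injectant_moles), 750e-6 * 2.5e-6 * 20, tolerance = 1e-12)
  expect_error(itc_protocol(50e-6, 750e-6, c(2.5e-6, 300e-6)), "smaller than")
  expect_error(itc_protocol(50e-6, 750e-6, 2.5e-6), "2 injections")
})

test_that("zero-enthalpy and tight-binding limits behave", {
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 15))
  tr0 <- simulate_itc(prot, list(model = "one_site", Ka = 1e6, dH = 0, n = 1))
  expect_true(all(abs(tr0$ndh) < 1e-12))

  # tight binding: every early injection is fully bound, ndh ~ dH
  trt <- simulate_itc(prot, list(model = "one_site", Ka = 1e12, dH = -10, n = 1))
  expect_equal(trt$ndh[1:5], rep(-10, 5), tolerance = 1e-3)
  expect_true(all(diff(trt$molar_ratio) > 0))
})

test_that("per-injection heats sum to the final cumulative heat without displacement", {
  prot <- itc_protocol(50e-6, 850e-6, rep(2e-6, 25))
  pars <- list(model = "two_site_sequential", Ka1 = 2.5e6, Ka2 = 1e6,
               dH1 = -10, dH2 = 4)
  tr <- simulate_itc(prot, pars, displacement_correction = FALSE)
  q_kcal <- tr$heat_ucal * 1e-9
  expect_equal(sum(q_kcal), tr$Q_cum[nrow(tr)], tolerance = 1e-9)

  # with the correction, heats match an independent re-derivation from Q_cum
  trc <- simulate_itc(prot, pars, displacement_correction = TRUE)
  Q <- trc$Q_cum; Qp <- c(0, Q[-length(Q)])
  want <- Q - Qp + (trc$volume / prot$cell_volume) * (Q + Qp) / 2
  expect_equal(trc$heat_ucal * 1e-9, want, tolerance = 1e-12)
})

test_that("one-site simulator matches an independent mass-action solution", {
  # oracle: solve the one-site equilibrium by bisection on free protein,
  # independently of the quadratic closed form used by the simulator
  oracle_bound <- function(Ka, P, D) {
    g <- function(pf) pf + D * Ka * pf / (1 + Ka * pf) - P
    pf <- uniroot(g, c(0, P), tol = 1e-18)$root
    D * Ka * pf / (1 + Ka * pf)
  }
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 10))
  conc <- concentrations_after_injection(prot)
  tr <- simulate_itc(prot, list(model = "one_site", Ka = 1.27e6, dH = -10, n = 1))
  for (i in seq_len(10)) {
    bound <- oracle_bound(1.27e6, conc$p_total[i], conc$d_total[i])
    expect_equal(tr$Q_cum[i], prot$cell_volume * bound * (-10), tolerance = 1e-8)
  }
})

test_that("two-site model with omega = 1 and equal sites reduces to one site with n = 2", {
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 20))
  K <- 1.27e6
  macro <- macroscopic_constants(site_affinities(K, K, 1))
  tr2 <- simulate_itc(prot, list(model = "two_site_sequential",
                                 Ka1 = unname(macro["Ka1"]),
                                 Ka2 = unname(macro["Ka2"]),
                                 dH1 = -10, dH2 = -10))
  tr1 <- simulate_itc(prot, list(model = "one_site", Ka = K, dH = -10, n = 2))
  expect_equal(tr2$ndh, tr1$ndh, tolerance = 1e-8)
})

test_that("one-site fit recovers the generating parameters", {
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 25))
  tr <- simulate_itc(prot, list(model = "one_site", Ka = 1.27e6, dH = -10, n = 1))
  fit <- fit_itc(tr, prot, "one_site")
  expect_equal(fit$params$Ka, 1.27e6, tolerance = 1e-4)
  expect_equal(fit$params$dH, -10, tolerance = 1e-4)
  expect_equal(fit$params$n, 1, tolerance = 1e-4)
  expect_true(is.na(fit$flag))
  expect_equal(tidy(fit)$term, c("Ka", "dH", "n", "offset"))

  # noisy recovery: 2% relative heat noise
  trn <- gen_itc_trace(prot, list(model = "one_site", Ka = 1.27e6, dH = -10, n = 1),
                       sigma_heat_rel = 0.02, seed = 3)
  fitn <- fit_itc(trn, prot, "one_site")
  expect_equal(fitn$params$Ka, 1.27e6, tolerance = 0.1)
  expect_equal(fitn$params$dH, -10, tolerance = 0.05)
})

test_that("a flat zero trace is flagged unidentifiable", {
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 15))
  tr <- simulate_itc(prot, list(model = "one_site", Ka = 1e6, dH = 0, n = 1))
  fit <- fit_itc(tr, prot, "one_site")
  expect_match(fit$flag, "unidentifiable")
  expect_lt(abs(fit$params$dH), 1e-6)
})

test_that("model comparison selects the generating model", {
  # one-site data -> one_site selected
  prot1 <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 25))
  tr1 <- gen_itc_trace(prot1, list(model = "one_site", Ka = 1.27e6, dH = -10, n = 1),
                       sigma_heat_rel = 0.02, seed = 21)
  cmp1 <- compare_models(tr1, prot1)
  expect_equal(cmp1$selected_model, "one_site")

  # two-site data with opposing enthalpies -> biphasic, two-site selected
  prot2 <- itc_protocol(50e-6, 850e-6, rep(2e-6, 40))
  macro <- macroscopic_constants(site_affinities(1.27e6, 1.27e6, 3))
  tr2 <- gen_itc_trace(prot2, list(model = "two_site_sequential",
                                   Ka1 = unname(macro["Ka1"]),
                                   Ka2 = unname(macro["Ka2"]),
                                   dH1 = -10, dH2 = 4),
                       sigma_heat_rel = 0.02, seed = 22)
  cmp2 <- compare_models(tr2, prot2)
  expect_equal(cmp2$selected_model, "two_site_sequential")
  expect_gte(cmp2$biphasic_index, 1)
  # the raw simulated curve itself is non-monotone (sign change present)
  clean <- simulate_itc(prot2, list(model = "two_site_sequential",
                                    Ka1 = unname(macro["Ka1"]),
                                    Ka2 = unname(macro["Ka2"]),
                                    dH1 = -10, dH2 = 4))
  expect_true(any(diff(clean$ndh) > 0) && any(diff(clean$ndh) < 0))

  # pure noise: no systematic preference for the complex model, and the
  # AICc gap stays far below the genuine two-site signal (the models are
  # not nested, so the null gap is small but not exactly zero)
  null_runs <- lapply(5:10, function(s) {
    trn <- tr1
    withr::with_seed(s, trn$ndh <- rnorm(nrow(trn), sd = 0.05))
    compare_models(trn, prot1, n_starts = 2)
  })
  expect_lte(mean(vapply(null_runs, function(x) {
    x$selected_model == "two_site_sequential"
  }, logical(1))), 0.5)
  expect_lt(median(abs(vapply(null_runs, function(x) x$delta_aicc, numeric(1)))),
            10)
  expect_gt(cmp2$delta_aicc, 20) # the real two-site signal dwarfs the null gap
})

test_that("ITC tables round-trip through the TSV reader", {
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 12))
  tr <- gen_itc_trace(prot, list(model = "one_site", Ka = 1.27e6, dH = -10, n = 1),
                      sigma_heat_rel = 0.02, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_itc_table(tr, path)
  back <- read_itc_table(path, syringe_conc = prot$syringe_conc)
  expect_equal(back$ndh, tr$ndh, tolerance = 1e-9)
  expect_equal(back$volume, tr$volume, tolerance = 1e-12)
})
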