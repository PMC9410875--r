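test_that("EMSA generator is seeded, noise-controlled and round-trips", {
  pars <- wt_affinities()
  a <- gen_emsa_series(pars, sigma_frac = 0.03, n_replicates = 2, seed = 4)
  b <- gen_emsa_series(pars, sigma_frac = 0.03, n_replicates = 2, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, gen_emsa_series(pars, sigma_frac = 0.03,
                                            n_replicates = 2, seed = 5)))

  clean <- gen_emsa_series(pars, sigma_frac = 0, seed = 1)
  sim <- simulate_titration(pars, (0:8) * 2.5e-6, 2.5e-6)
  expect_equal(clean$f0, sim$f0, tolerance = 1e-12)
  expect_equal(clean$f2, sim$f2, tolerance = 1e-12)

  # fractions stay a simplex after noise
  expect_true(all(abs(a$f0 + a$f1 + a$f2 - 1) < 1e-12))
  expect_true(all(a$f0 >= 0 & a$f1 >= 0 & a$f2 >= 0))

  # table round trip through the TSV reader
  path <- withr::local_tempfile(fileext = ".tsv")
  write_emsa_table(a, path)
  back <- read_emsa_table(path)
  expect_equal(back$f0, a$f0, tolerance = 1e-9)
  expect_equal(back$p_total, a$p_total, tolerance = 1e-12)
  expect_equal(back$replicate, a$replicate)
})

test_that("EMSA reader renormalises small departures and rejects large ones", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "lane\tp_total_uM\td_total_uM\tf_free\tf_mono\tf_dimer",
    "1\t2.5\t2.5\t0.30\t0.40\t0.31",  # sums to 1.01 -> renormalised
    "2\t5.0\t2.5\t0.20\t0.40\t0.40"
  ), path)
  tab <- read_emsa_table(path)
  expect_equal(tab$f0 + tab$f1 + tab$f2, c(1, 1), tolerance = 1e-12)

  writeLines(c(
    "lane\tp_total_uM\td_total_uM\tf_free\tf_mono\tf_dimer",
    "1\t2.5\t2.5\t0.50\t0.40\t0.31"   # sums to 1.21 -> error
  ), path)
  expect_error(read_emsa_table(path), "refusing to renormalise")
})

test_that("scenarios map probe variants onto parameter changes", {
  base <- site_affinities(1.27e6, 1.27e6, 3)
  expect_identical(apply_scenario(base, "WT"), base)

  m1 <- apply_scenario(base, "mut1")
  expect_equal(m1$K1, base$K1 * 0.002)
  expect_equal(m1$omega, 1)

  m2 <- apply_scenario(base, "mut2")
  expect_equal(m2$omega, 1)
  expect_equal(m2$K2, base$K2 * 0.8)
  # its noiseless series estimates omega ~ 1 (cooperativity vanished)
  ser2 <- simulate_titration(m2, seq(0.5, 10, length.out = 8) * 2.5e-6, 2.5e-6)
  est2 <- estimate_omega(ser2)
  expect_equal(est2$omega_hat, 1, tolerance = 0.05)
  expect_equal(est2$classification, "none")

  # both sites scrambled: essentially no occupancy at gel concentrations
  m3 <- apply_scenario(base, "mut3")
  ser3 <- simulate_titration(m3, (1:8) * 2.5e-6, 2.5e-6)
  expect_true(all(ser3$f0 > 0.6))
  expect_true(all(ser3$f2 < 0.02))

  # spacers and cation depletion pull cooperativity toward 1
  for (sc in c("spacer_S1", "spacer_S2", "Mg_depleted")) {
    s <- apply_scenario(base, sc)
    expect_lt(s$omega, base$omega)
    expect_gte(s$omega, 1)
  }
  expect_lt(apply_scenario(base, "spacer_S2")$omega,
            apply_scenario(base, "spacer_S1")$omega)
  expect_error(apply_scenario(base, "mut9"), "Unknown scenario")
})

test_that("ITC trace generator is seeded and reduces to the simulator", {
  prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 15))
  pars <- list(model = "one_site", Ka = 1.27e6, dH = -10, n = 1)
  expect_identical(gen_itc_trace(prot, pars, sigma_heat_rel = 0.02, seed = 2),
                   gen_itc_trace(prot, pars, sigma_heat_rel = 0.02, seed = 2))
  expect_equal(gen_itc_trace(prot, pars, sigma_heat_rel = 0, seed = 2)$ndh,
               simulate_itc(prot, pars)$ndh)
})

test_that("promoter generator implants sites recoverable by the scanner", {
  imp <- tibble::tibble(site = c("TATTTAT", "GTAAACA"),
                        position = c(40L, 120L), strand = c("-", "+"))
  prom <- gen_promoter(200, implant = imp, seed = 8)
  expect_identical(prom$bases, gen_promoter(200, implant = imp, seed = 8)$bases)

  hits <- scan_motif(prom, FBE)
  # the minus-strand implant is written as its plus-strand reverse complement
  expect_equal(substr(prom$bases, 41, 47), reverse_complement("TATTTAT"))
  expect_true(any(hits$start == 40 & hits$strand == "+")) # rc(TATTTAT) = ATAAATA matches on +
  expect_true(any(hits$start == 120 & hits$strand == "+" & hits$site == "GTAAACA"))

  expect_error(gen_promoter(50, tibble::tibble(site = "TATTTAT", position = 48L,
                                               strand = "+")), "fit")
  expect_error(
    gen_promoter(50, tibble::tibble(site = c("TATTTAT", "ATTATCG"),
                                    position = c(10L, 12L), strand = c("+", "+"))),
    "overlap"
  )
})

test_that("background hit rate matches the analytic window probability", {
  # P(uniform window matches RYAAAYA) = 2*2*1*1*1*2*1 / 4^7 = 8 / 16384 per
  # strand-window; count over many seeded windows and compare binomially
  p <- 8 / 16384
  n_draws <- 40
  len <- 1500
  windows_per_seq <- (len - 7 + 1) * 2
  total_hits <- sum(vapply(seq_len(n_draws), function(s) {
    nrow(scan_motif(gen_promoter(len, seed = 1000 + s), FBE))
  }, numeric(1)))
  n_windows <- n_draws * windows_per_seq
  expect_lt(abs(total_hits - n_windows * p), 4 * sqrt(n_windows * p * (1 - p)))
})
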