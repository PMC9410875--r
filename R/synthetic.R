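# Seeded generators emulating every experimental input the pipeline
# consumes: EMSA titration tables, ITC traces, promoter sequences with
# implanted sites, plus named mutation/spacer scenarios. All generators are
# pure functions of (parameters, seed).

#' Default wild-type two-site parameters for demonstrations and tests
#'
#' Both microscopic constants set from the measured one-site dissociation
#' constant of the isolated consensus element (KD 0.79 uM, i.e. K ~ 1.27e6
#' per molar) and a cooperativity factor of 3 — a documented convention for
#' the wild-type two-site probe, not a fitted value.
#'
#' @return A [site_affinities()] object.
#' @export
wt_affinities <- function() site_affinities(K1 = 1 / 0.79e-6, K2 = 1 / 0.79e-6, omega = 3)

#' Apply a named experimental scenario to two-site parameters
#'
#' Scenarios map the probe variants studied experimentally onto parameter
#' changes:
#' * `WT` — unchanged.
#' * `mut1` — first site replaced by a run of C's: `K1` floored to
#'   `floor_factor * K1` (weak residual binding), cooperativity removed.
#' * `mut2` — second site scrambled: `omega = 1` and `K2` mildly reduced
#'   (`reduce_factor`), reproducing the near-1 cooperativity factor of that
#'   probe.
#' * `mut3` — both sites scrambled: both constants floored, `omega = 1`
#'   (essentially no occupancy at experimental concentrations).
#' * `spacer_S1`, `spacer_S2` — 1 or 2 bp inserted between the sites;
#'   cooperativity moves toward 1 (retaining 30% / 10% of the excess).
#' * `Mg_depleted` — divalent-cation-dependent protein-protein contact
#'   removed; cooperativity moves toward 1 (25% of the excess retained).
#'
#' @param base A [site_affinities()] object.
#' @param scenario One of the names above.
#' @param floor_factor Multiplier for an "abolished" site (default 0.002:
#'   a scrambled element retains only nonspecific-level affinity).
#' @param reduce_factor Multiplier for a mildly weakened site (default 0.8).
#' @return A [site_affinities()] object.
#' @export
apply_scenario <- function(base, scenario, floor_factor = 0.002,
                           reduce_factor = 0.8) {
  stopifnot(inherits(base, "site_affinities"))
  toward_1 <- function(om, keep) 1 + (om - 1) * keep
  switch(scenario,
    WT = base,
    mut1 = site_affinities(base$K1 * floor_factor, base$K2, omega = 1),
    mut2 = site_affinities(base$K1, base$K2 * reduce_factor, omega = 1),
    mut3 = site_affinities(base$K1 * floor_factor, base$K2 * floor_factor, omega = 1),
    spacer_S1 = site_affinities(base$K1, base$K2, omega = toward_1(base$omega, 0.3)),
    spacer_S2 = site_affinities(base$K1, base$K2, omega = toward_1(base$omega, 0.1)),
    Mg_depleted = site_affinities(base$K1, base$K2, omega = toward_1(base$omega, 0.25)),
    abort(sprintf(
      "Unknown scenario '%s'; expected WT, mut1, mut2, mut3, spacer_S1, spacer_S2 or Mg_depleted.",
      scenario
    ))
  )
}

#' Generate a noisy EMSA titration series
#'
#' Simulates the noiseless titration ([simulate_titration()]) and adds
#' independent Gaussian noise (SD `sigma_frac`) to each species fraction,
#' then clips to `[0, 1]` and renormalises each lane to sum to 1. With
#' `n_replicates > 1` the series is replicated with independent noise and a
#' `replicate` column. Byte-identical output for a given seed.
#'
#' @param params A [site_affinities()] object.
#' @param p_totals Total protein concentrations, molar (default: molar
#'   ratios 0-8 over a 2.5 uM probe).
#' @param d_total Probe concentration, molar (default 2.5 uM).
#' @param sigma_frac Gaussian SD on fractions (default 0.03).
#' @param n_replicates Number of replicate series (default 1).
#' @param seed Integer seed.
#' @return Tibble like [simulate_titration()] plus `replicate`.
#' @export
gen_emsa_series <- function(params,
                            p_totals = seq(0, 8, by = 1) * 2.5e-6,
                            d_total = 2.5e-6,
                            sigma_frac = 0.03, n_replicates = 1, seed = 1) {
  if (sigma_frac < 0) abort("`sigma_frac` must be >= 0.")
  clean <- simulate_titration(params, p_totals, d_total)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      out <- clean
      if (sigma_frac > 0) {
        f <- as.matrix(out[, c("f0", "f1", "f2")])
        f <- f + matrix(rnorm(length(f), sd = sigma_frac), nrow = nrow(f))
        f <- pmin(pmax(f, 0), 1)
        f <- f / rowSums(f)
        out$f0 <- f[, 1]; out$f1 <- f[, 2]; out$f2 <- f[, 3]
      }
      dplyr::mutate(out, replicate = rep_i, .before = 1)
    })
  })
}

#' Generate a noisy ITC trace
#'
#' [simulate_itc()] plus Gaussian noise on the per-injection heats. The
#' noise SD is `sigma_heat_rel * max(abs(heat))`, applied to the raw heats
#' and propagated to the normalized heats. Seeded and deterministic.
#'
#' @param protocol An [itc_protocol()].
#' @param params Thermodynamic parameter list (see [simulate_itc()]).
#' @param sigma_heat_rel Relative noise level (default 0.02).
#' @param seed Integer seed.
#' @return Tibble like [simulate_itc()].
#' @export
gen_itc_trace <- function(protocol, params, sigma_heat_rel = 0.02, seed = 1) {
  if (sigma_heat_rel < 0) abort("`sigma_heat_rel` must be >= 0.")
  tr <- simulate_itc(protocol, params)
  if (sigma_heat_rel > 0) {
    withr::with_seed(seed, {
      sdq <- sigma_heat_rel * max(abs(tr$heat_ucal))
      noise <- rnorm(nrow(tr), sd = sdq)
      tr$heat_ucal <- tr$heat_ucal + noise
      tr$ndh <- tr$ndh + noise * 1e-9 / tr$injectant_moles
    })
  }
  tr
}

#' Generate a random promoter sequence with implanted sites
#'
#' Background bases are i.i.d. uniform over A/C/G/T; implants are written
#' verbatim at the requested 0-based positions (minus-strand implants are
#' written as their reverse complement on the plus strand). Implants must
#' not overlap each other.
#'
#' @param length Sequence length.
#' @param implant Optional tibble/data.frame with columns `site`, `position`
#'   (0-based plus-strand start), `strand` (`"+"`/`"-"`).
#' @param seed Integer seed.
#' @param id,offset Passed to [dna_sequence()].
#' @return A [dna_sequence()].
#' @export
gen_promoter <- function(length, implant = NULL, seed = 1, id = "promoter",
                         offset = 0L) {
  if (length < 1) abort("`length` must be positive.")
  bases <- withr::with_seed(seed, sample(c("A", "C", "G", "T"), length, replace = TRUE))
  if (!is.null(implant) && nrow(implant) > 0) {
    iv <- tibble(start = implant$position,
                 end = implant$position + nchar(implant$site))
    if (any(iv$start < 0) || any(iv$end > length)) abort("Implant does not fit.")
    iv <- dplyr::arrange(iv, .data$start)
    if (nrow(iv) > 1 && any(head(iv$end, -1) > tail(iv$start, -1))) {
      abort("Implants overlap each other.")
    }
    for (k in seq_len(nrow(implant))) {
      s <- toupper(implant$site[k])
      if (identical(implant$strand[k], "-")) s <- reverse_complement(s)
      bases[(implant$position[k] + 1):(implant$position[k] + nchar(s))] <-
        strsplit(s, "", fixed = TRUE)[[1]]
    }
  }
  dna_sequence(paste(bases, collapse = ""), id = id, offset = offset)
}
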