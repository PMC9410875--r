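# ITC titration simulation: perfusion-cell bookkeeping and equilibrium
# isotherms for one-site and sequential two-site binding.

#' Define an ITC titration protocol
#'
#' @param cell_conc Macromolecule (DNA) concentration in the cell, molar.
#' @param syringe_conc Titrant (protein) concentration in the syringe, molar.
#' @param injection_volumes Vector of injection volumes, liters (>= 2
#'   injections).
#' @param cell_volume Active cell volume, liters (default 200 ul).
#' @param temperature Kelvin (default 298).
#' @return Object of class `itc_protocol`.
#' @examples
#' # 50 uM DNA in the cell, 750 uM protein, 20 x 2.5 ul injections
#' itc_protocol(50e-6, 750e-6, rep(2.5e-6, 20))
#' @export
itc_protocol <- function(cell_conc, syringe_conc, injection_volumes,
                         cell_volume = 200e-6, temperature = 298) {
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0 || temperature <= 0) {
    abort("All protocol quantities must be positive.")
  }
  if (length(injection_volumes) < 2L || any(injection_volumes <= 0)) {
    abort("At least 2 injections with positive volumes are required.")
  }
  if (any(injection_volumes >= cell_volume)) {
    abort("Injection volumes must be smaller than the cell volume.")
  }
  structure(
    list(cell_conc = cell_conc, syringe_conc = syringe_conc,
         injection_volumes = as.numeric(injection_volumes),
         cell_volume = cell_volume, temperature = temperature),
    class = "itc_protocol"
  )
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat(sprintf(
    "<itc_protocol> cell %.3g uM / syringe %.3g uM; %d injections (%.2g-%.2g ul) into %.0f ul at %g K\n",
    x$cell_conc * 1e6, x$syringe_conc * 1e6, length(x$injection_volumes),
    min(x$injection_volumes) * 1e6, max(x$injection_volumes) * 1e6,
    x$cell_volume * 1e6, x$temperature
  ))
  invisible(x)
}

#' Cell concentrations after each injection
#'
#' Standard constant-volume displacement bookkeeping: each injection of
#' volume `v` into active volume `V0` dilutes the existing cell contents by
#' `(1 - v/V0)` while the newly injected titrant enters with the average
#' factor `(1 - v/(2 V0))` (it is itself partially displaced during the
#' injection). The recursion per injection `i` is
#' `D_i = D_{i-1} (1 - v_i/V0)` and
#' `P_i = P_{i-1} (1 - v_i/V0) + C_syr (v_i/V0) (1 - v_i/(2 V0))`.
#'
#' @param protocol An [itc_protocol()].
#' @return Tibble with one row per injection: `injection`, `volume`,
#'   `d_total`, `p_total` (molar, cell concentrations after the injection),
#'   `injectant_moles`.
#' @export
concentrations_after_injection <- function(protocol) {
  stopifnot(inherits(protocol, "itc_protocol"))
  V0 <- protocol$cell_volume
  v <- protocol$injection_volumes
  n <- length(v)
  D <- numeric(n); P <- numeric(n)
  d_prev <- protocol$cell_conc; p_prev <- 0
  for (i in seq_len(n)) {
    dil <- 1 - v[i] / V0
    D[i] <- d_prev * dil
    P[i] <- p_prev * dil + protocol$syringe_conc * (v[i] / V0) * (1 - v[i] / (2 * V0))
    d_prev <- D[i]; p_prev <- P[i]
  }
  tibble(injection = seq_len(n), volume = v, d_total = D, p_total = P,
         injectant_moles = protocol$syringe_conc * v)
}

# One-site equilibrium: n identical independent sites per macromolecule.
# Bound site concentration from the quadratic mass-action closed form.
one_site_bound <- function(Ka, n, P, D) {
  S <- n * D
  b <- P + S + 1 / Ka
  (b - sqrt(pmax(b^2 - 4 * P * S, 0))) / 2
}

# Cumulative cell heat content (kcal) for plain total-concentration vectors;
# shared hot path of simulate_itc and fit_itc.
itc_cum_heat <- function(d_tot, p_tot, V0, model, pars) {
  if (model == "one_site") {
    bound <- one_site_bound(pars$Ka, pars$n %||% 1, p_tot, d_tot)
    V0 * bound * pars$dH
  } else {
    micro <- microscopic_from_macroscopic(pars$Ka1, pars$Ka2)
    pf <- vapply(seq_along(p_tot), function(i) {
      solve_free_one(micro, p_tot[i], d_tot[i])
    }, numeric(1))
    fr <- fractions_raw(micro$K1, micro$K2, micro$omega, pf)
    V0 * d_tot * (fr$f1 * pars$dH1 + fr$f2 * (pars$dH1 + pars$dH2))
  }
}

# Normalized per-injection heats from precomputed bookkeeping (plain vectors).
itc_ndh_raw <- function(conc, V0, model, pars, displacement = TRUE) {
  Q <- itc_cum_heat(conc$d_total, conc$p_total, V0, model, pars)
  Q_prev <- c(0, Q[-length(Q)])
  q <- Q - Q_prev
  if (displacement) q <- q + (conc$volume / V0) * (Q + Q_prev) / 2
  q / conc$injectant_moles
}

#' Simulate an ITC titration
#'
#' For each injection, computes post-injection cell totals (see
#' [concentrations_after_injection()]), solves the binding equilibrium and
#' converts the change in cell heat content into the per-injection heat.
#'
#' Models (`params` is a named list):
#' * `one_site`: fields `Ka` (per molar), `dH` (kcal/mol), `n` (site
#'   multiplicity). Cumulative heat `Q_i = V0 * bound_i * dH`.
#' * `two_site_sequential`: fields `Ka1`, `Ka2` (macroscopic, per molar),
#'   `dH1`, `dH2` (kcal/mol, stepwise). Mapped internally to equivalent-site
#'   microscopic parameters; `Q_i = V0 * D_i * (f1 dH1 + f2 (dH1 + dH2))`.
#'
#' The per-injection heat is `q_i = Q_i - Q_{i-1} + correction`, where the
#' displacement correction `(v_i/V0) * (Q_i + Q_{i-1})/2` accounts for heat
#' content carried out with the displaced volume
#' (`displacement_correction = FALSE` disables it, in which case the
#' per-injection heats sum exactly to the final cumulative heat).
#'
#' @param protocol An [itc_protocol()].
#' @param params Named list of thermodynamic parameters (see above) with a
#'   `model` field, or the model given separately via `model`.
#' @param model `"one_site"` or `"two_site_sequential"`; defaults to
#'   `params$model`.
#' @param displacement_correction Apply the displaced-heat correction
#'   (default `TRUE`).
#' @return Tibble (`itc_trace`): `injection`, `volume`, `d_total`,
#'   `p_total`, `molar_ratio`, `injectant_moles`, `Q_cum` (kcal), `heat_ucal`
#'   and `ndh` (normalized heat, kcal per mol injectant).
#' @examples
#' prot <- itc_protocol(50e-6, 750e-6, rep(2.5e-6, 20))
#' simulate_itc(prot, list(model = "one_site", Ka = 1.27e6, dH = -10, n = 1))
#' @export
simulate_itc <- function(protocol, params, model = params$model,
                         displacement_correction = TRUE) {
  stopifnot(inherits(protocol, "itc_protocol"))
  model <- match.arg(model, c("one_site", "two_site_sequential"))
  conc <- concentrations_after_injection(protocol)
  V0 <- protocol$cell_volume

  if (model == "one_site" && !all(c("Ka", "dH") %in% names(params))) {
    abort("one_site needs Ka and dH.")
  }
  if (model == "two_site_sequential" &&
      !all(c("Ka1", "Ka2", "dH1", "dH2") %in% names(params))) {
    abort("two_site_sequential needs Ka1, Ka2, dH1 and dH2.")
  }
  Q <- itc_cum_heat(conc$d_total, conc$p_total, V0, model, params)

  Q_prev <- c(0, head(Q, -1))
  q <- Q - Q_prev
  if (isTRUE(displacement_correction)) {
    q <- q + (conc$volume / V0) * (Q + Q_prev) / 2
  }
  conc |>
    dplyr::mutate(
      molar_ratio = .data$p_total / .data$d_total,
      Q_cum = Q,
      heat_ucal = q * 1e9, # kcal -> ucal
      ndh = q / .data$injectant_moles
    )
}

# ---- ITC table I/O ----------------------------------------------------------

#' Read an ITC injection table
#'
#' TSV schema: columns `injection`, `volume_ul` and either `heat_ucal` or
#' `ndh_kcal_per_mol` (normalized heat). When only raw heats are present the
#' normalized heat is derived using `syringe_conc`.
#'
#' @param path Path to a TSV file.
#' @param syringe_conc Syringe concentration (molar), required to normalize
#'   raw heats.
#' @return Tibble with `injection`, `volume` (liters), `heat_ucal`, `ndh`.
#' @export
read_itc_table <- function(path, syringe_conc = NULL) {
  if (!file.exists(path)) abort(sprintf("ITC table not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("injection", "volume_ul") %in% names(raw))) {
    abort("ITC table needs columns injection and volume_ul.")
  }
  out <- tibble(injection = raw$injection, volume = raw$volume_ul * 1e-6)
  if ("ndh_kcal_per_mol" %in% names(raw)) {
    out$ndh <- raw$ndh_kcal_per_mol
    out$heat_ucal <- if ("heat_ucal" %in% names(raw)) raw$heat_ucal else {
      if (is.null(syringe_conc)) NA_real_
      else raw$ndh_kcal_per_mol * syringe_conc * out$volume * 1e9
    }
  } else if ("heat_ucal" %in% names(raw)) {
    if (is.null(syringe_conc)) {
      abort("`syringe_conc` is required to normalize raw heats.")
    }
    out$heat_ucal <- raw$heat_ucal
    out$ndh <- raw$heat_ucal * 1e-9 / (syringe_conc * out$volume)
  } else {
    abort("ITC table needs heat_ucal or ndh_kcal_per_mol.")
  }
  out
}

#' Write an ITC trace to a TSV file
#'
#' @param trace Tibble from [simulate_itc()] or [gen_itc_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itc_table <- function(trace, path) {
  readr::write_tsv(
    tibble(injection = trace$injection, volume_ul = trace$volume * 1e6,
           heat_ucal = trace$heat_ucal, ndh_kcal_per_mol = trace$ndh),
    path, progress = FALSE
  )
  invisible(path)
}
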