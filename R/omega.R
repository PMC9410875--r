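# Cooperativity factor estimation from EMSA band fractions, and the EMSA
# table I/O used to exchange titration data.

#' Per-lane cooperativity factor from band fractions
#'
#' The statistical-factor-corrected ratio `4 f0 f2 / f1^2`. For two
#' equivalent sites (`K1 = K2`) it equals the generating cooperativity
#' factor omega exactly at every protein concentration. For unequal sites
#' it equals `omega * 4 K1 K2 / (K1 + K2)^2 <= omega` (documented estimator
#' bias; exact again as `K1 -> K2`). Lanes with `f1` at or below `epsilon_f1`
#' return `NA` — the ratio's variance explodes as the monomer band vanishes.
#'
#' @param f0,f1,f2 Fractions of free, singly-bound and doubly-bound DNA;
#'   vectorised.
#' @param epsilon_f1 Usability threshold on the monomer fraction
#'   (default 0.05).
#' @return Numeric vector of per-lane omega estimates (`NA` for unusable
#'   lanes).
#' @examples
#' omega_from_lane(0.25, 0.50, 0.25) # 1
#' omega_from_lane(1 / 7, 2 / 7, 4 / 7) # 4
#' @export
omega_from_lane <- function(f0, f1, f2, epsilon_f1 = 0.05) {
  if (any(c(f0, f1, f2) < -1e-9, na.rm = TRUE)) abort("Fractions must be non-negative.")
  out <- 4 * f0 * f2 / f1^2
  out[f1 <= epsilon_f1] <- NA_real_
  out
}

#' Estimate the cooperativity factor from an EMSA titration series
#'
#' Applies [omega_from_lane()] to every usable lane and summarises: the
#' point estimate is the mean across usable lanes, the standard error is the
#' sample standard deviation divided by `sqrt(n_used)`. When a `replicate`
#' column is present the estimate is computed per replicate first and the
#' standard error is the SEM across replicates, matching the mean +/- SEM
#' (n = 3) convention of triplicate gels.
#'
#' A lane is usable when the monomer fraction exceeds `epsilon_f1` (the
#' squared denominator's variance explodes below it) and the free-DNA and
#' dimer fractions both exceed `epsilon_band`: bands near densitometry
#' background have unbounded relative error and skew the ratio upward, so
#' only lanes where all three species are quantifiable contribute.
#'
#' A classification is attached: `"positive"` (omega clearly above 1),
#' `"negative"` (clearly below), `"none"` otherwise. "Clearly" means
#' beyond 2 standard errors, or beyond +/-0.25 when no spread is available.
#'
#' @param series Tibble with columns `f0`, `f1`, `f2` (e.g. from
#'   [simulate_titration()], [gen_emsa_series()] or [read_emsa_table()]);
#'   optional `replicate` column.
#' @param epsilon_f1 Monomer-fraction usability threshold (default 0.05).
#' @param epsilon_band Measurability floor on the free-DNA and dimer
#'   fractions (default 0.1).
#' @return Object of class `omega_estimate`: fields `omega_hat`, `se`,
#'   `n_used`, `classification`, `per_lane`.
#' @export
estimate_omega <- function(series, epsilon_f1 = 0.05, epsilon_band = 0.1) {
  need <- c("f0", "f1", "f2")
  if (!all(need %in% names(series))) {
    abort("`series` must have columns f0, f1, f2.")
  }
  per_lane <- series |>
    dplyr::mutate(
      omega_lane = omega_from_lane(.data$f0, .data$f1, .data$f2,
                                   epsilon_f1 = epsilon_f1),
      omega_lane = dplyr::if_else(
        .data$f0 > epsilon_band & .data$f2 > epsilon_band,
        .data$omega_lane, NA_real_
      )
    )
  usable <- per_lane |> dplyr::filter(!is.na(.data$omega_lane))
  if (nrow(usable) == 0L) {
    abort(paste(
      "No usable lanes: every monomer fraction is at or below the usability",
      "threshold. Include mid-titration lanes where the singly-bound band is",
      "populated."
    ))
  }
  if ("replicate" %in% names(usable) && length(unique(usable$replicate)) > 1L) {
    by_rep <- usable |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(omega = mean(.data$omega_lane), .groups = "drop")
    omega_hat <- mean(by_rep$omega)
    n_used <- nrow(usable)
    se <- sd(by_rep$omega) / sqrt(nrow(by_rep))
  } else {
    omega_hat <- mean(usable$omega_lane)
    n_used <- nrow(usable)
    se <- if (n_used > 1) sd(usable$omega_lane) / sqrt(n_used) else 0
  }
  structure(
    list(
      omega_hat = omega_hat, se = se, n_used = n_used,
      classification = classify_omega(omega_hat, se),
      per_lane = per_lane
    ),
    class = "omega_estimate"
  )
}

classify_omega <- function(omega_hat, se) {
  band <- if (is.finite(se) && se > 0) 2 * se else 0.25
  if (omega_hat - 1 > band) "positive"
  else if (1 - omega_hat > band) "negative"
  else "none"
}

#' @export
print.omega_estimate <- function(x, ...) {
  cat(sprintf(
    "<omega_estimate> omega = %.3g +/- %.2g (n_used = %d lanes): %s cooperativity\n",
    x$omega_hat, x$se, x$n_used,
    switch(x$classification, positive = "positive", negative = "negative", "no")
  ))
  invisible(x)
}

#' @rdname estimate_omega
#' @param x An `omega_estimate` object.
#' @param ... Unused.
#' @method tidy omega_estimate
#' @export
tidy.omega_estimate <- function(x, ...) {
  tibble(term = "omega", estimate = x$omega_hat, std.error = x$se,
         n_used = x$n_used, classification = x$classification)
}

#' @rdname estimate_omega
#' @method glance omega_estimate
#' @export
glance.omega_estimate <- function(x, ...) {
  tibble(omega_hat = x$omega_hat, se = x$se, n_used = x$n_used,
         classification = x$classification)
}

# ---- EMSA table I/O ---------------------------------------------------------

#' Read an EMSA titration table
#'
#' TSV schema: columns `lane`, `p_total_uM`, `d_total_uM`, `f_free`,
#' `f_mono`, `f_dimer` (optional `replicate`). Fraction triples are
#' renormalised when they sum to 1 within +/-0.02; a larger departure is an
#' error. Concentrations are converted to molar on read.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `lane`, `p_total`, `d_total` (molar), `f0`,
#'   `f1`, `f2` and `replicate` if present.
#' @export
read_emsa_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("EMSA table not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("lane", "p_total_uM", "d_total_uM", "f_free", "f_mono", "f_dimer")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("EMSA table is missing columns: %s", paste(missing, collapse = ", ")))
  }
  tot <- raw$f_free + raw$f_mono + raw$f_dimer
  bad <- which(abs(tot - 1) > 0.02)
  if (length(bad) > 0) {
    abort(sprintf(
      "Fractions in lane(s) %s sum to %s - outside 1 +/- 0.02; refusing to renormalise.",
      paste(raw$lane[bad], collapse = ", "),
      paste(sprintf("%.3f", tot[bad]), collapse = ", ")
    ))
  }
  out <- tibble(
    lane = raw$lane,
    p_total = raw$p_total_uM * 1e-6,
    d_total = raw$d_total_uM * 1e-6,
    f0 = raw$f_free / tot, f1 = raw$f_mono / tot, f2 = raw$f_dimer / tot
  )
  if ("replicate" %in% names(raw)) out$replicate <- raw$replicate
  out
}

#' Write an EMSA titration table
#'
#' Inverse of [read_emsa_table()]: writes the TSV schema with
#' concentrations in micromolar.
#'
#' @param series Tibble with `lane`, `p_total`, `d_total` (molar), `f0`,
#'   `f1`, `f2`, optional `replicate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emsa_table <- function(series, path) {
  out <- tibble(
    lane = series$lane,
    p_total_uM = series$p_total * 1e6,
    d_total_uM = series$d_total * 1e6,
    f_free = series$f0, f_mono = series$f1, f_dimer = series$f2
  )
  if ("replicate" %in% names(series)) {
    out <- dplyr::bind_cols(tibble(replicate = series$replicate), out)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
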