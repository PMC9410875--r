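# Equilibrium two-site lattice binding model with cooperativity.
#
# A duplex carries two microscopic sites with association constants K1, K2
# (per molar) and a unitless cooperativity factor omega multiplying the
# statistical weight of the doubly-bound state:
#   Z(p) = 1 + (K1 + K2) p + omega K1 K2 p^2,  p = free protein (M)
# Species fractions: f0 = 1/Z, f1 = (K1+K2) p / Z, f2 = omega K1 K2 p^2 / Z.

#' Two-site affinities with a cooperativity factor
#'
#' @param K1,K2 Microscopic association constants (per molar) for the two
#'   sites; both must be positive.
#' @param omega Unitless cooperativity factor (weight multiplier on the
#'   doubly-bound state); `omega > 1` positive cooperativity, `1`
#'   independent sites, `< 1` negative. Must be non-negative.
#' @return An object of class `site_affinities`.
#' @examples
#' site_affinities(K1 = 1.27e6, K2 = 1.27e6, omega = 3)
#' @export
site_affinities <- function(K1, K2 = K1, omega = 1) {
  if (!is.numeric(K1) || K1 <= 0 || !is.finite(K1)) abort("`K1` must be positive and finite.")
  if (!is.numeric(K2) || K2 <= 0 || !is.finite(K2)) abort("`K2` must be positive and finite.")
  if (!is.numeric(omega) || omega < 0 || !is.finite(omega)) abort("`omega` must be >= 0 and finite.")
  structure(list(K1 = as.numeric(K1), K2 = as.numeric(K2), omega = as.numeric(omega)),
            class = "site_affinities")
}

#' @export
print.site_affinities <- function(x, ...) {
  cat(sprintf(
    "<site_affinities> K1 = %.4g /M (KD %.3g uM), K2 = %.4g /M (KD %.3g uM), omega = %.4g\n",
    x$K1, 1e6 / x$K1, x$K2, 1e6 / x$K2, x$omega
  ))
  invisible(x)
}

#' Species fractions of a two-site DNA at a given free protein concentration
#'
#' Evaluates the two-site lattice partition function
#' `Z = 1 + (K1 + K2) p + omega K1 K2 p^2` and returns the fractions of
#' free (`f0`), singly-bound (`f1`, the monomer shift in an EMSA) and
#' doubly-bound (`f2`, the dimer shift) duplex. Fractions sum to 1.
#'
#' @param params A [site_affinities()] object.
#' @param p_free Free protein concentration(s), molar; vectorised.
#' @return Tibble with columns `p_free`, `f0`, `f1`, `f2`.
#' @examples
#' eq <- site_affinities(1e6, 1e6, omega = 4)
#' partition_fractions(eq, 1e-6) # (1/7, 2/7, 4/7)
#' @export
partition_fractions <- function(params, p_free) {
  stopifnot(inherits(params, "site_affinities"))
  if (any(!is.finite(p_free)) || any(p_free < 0)) {
    abort("`p_free` must be non-negative and finite.")
  }
  s1 <- (params$K1 + params$K2) * p_free
  s2 <- params$omega * params$K1 * params$K2 * p_free^2
  Z <- 1 + s1 + s2
  tibble(p_free = p_free, f0 = 1 / Z, f1 = s1 / Z, f2 = s2 / Z)
}

# Raw species fractions as plain vectors (hot path: no tibble allocation).
fractions_raw <- function(K1, K2, omega, p) {
  s1 <- (K1 + K2) * p
  s2 <- omega * K1 * K2 * p^2
  Z <- 1 + s1 + s2
  list(f0 = 1 / Z, f1 = s1 / Z, f2 = s2 / Z)
}

# Protein bound per duplex at free concentration p: f1 + 2 f2.
bound_per_duplex <- function(params, p) {
  f <- fractions_raw(params$K1, params$K2, params$omega, p)
  f$f1 + 2 * f$f2
}

#' Solve for free protein under ligand depletion
#'
#' In an EMSA lane the DNA probe and the protein are at comparable
#' concentrations, so the free protein must be solved from the conservation
#' relation `p_total = p_free + d_total * (f1 + 2 f2)` rather than
#' approximated by the total. Bound protein is monotone increasing in
#' `p_free`, so the root on `[0, p_total]` is unique; it is bracketed with
#' [stats::uniroot()] (Brent) and polished by Newton steps to a relative
#' conservation residual below 1e-10.
#'
#' @param params A [site_affinities()] object.
#' @param p_total Total protein (molar), scalar or vector.
#' @param d_total Total DNA duplex (molar).
#' @return Free protein concentration(s), molar.
#' @examples
#' eq <- site_affinities(1e6, 1e6, omega = 1)
#' solve_free_protein(eq, 2.5e-6, 2.5e-6) * 1e6 # ~0.6085 uM
#' @export
solve_free_protein <- function(params, p_total, d_total) {
  stopifnot(inherits(params, "site_affinities"))
  if (any(p_total < 0) || any(d_total < 0)) {
    abort("`p_total` and `d_total` must be non-negative.")
  }
  vapply(p_total, function(pt) solve_free_one(params, pt, d_total), numeric(1))
}

solve_free_one <- function(params, p_total, d_total) {
  if (p_total == 0) return(0)
  if (d_total == 0) return(p_total)
  K1 <- params$K1; K2 <- params$K2; om <- params$omega
  ks <- K1 + K2; kp <- om * K1 * K2
  # residual of conservation and its analytic derivative
  g <- function(p) {
    s1 <- ks * p; s2 <- kp * p * p
    Z <- 1 + s1 + s2
    p + d_total * (s1 + 2 * s2) / Z - p_total
  }
  # safeguarded Newton on the bracket [0, p_total]
  lo <- 0; hi <- p_total
  p <- p_total / 2
  tol <- 1e-12 * max(p_total, d_total)
  for (i in 1:200) {
    s1 <- ks * p; s2 <- kp * p * p
    Z <- 1 + s1 + s2
    nu <- (s1 + 2 * s2) / Z
    res <- p + d_total * nu - p_total
    if (abs(res) <= tol) break
    if (res > 0) hi <- p else lo <- p
    ds1 <- ks; ds2 <- 2 * kp * p
    dnu <- ((ds1 + 2 * ds2) * Z - (s1 + 2 * s2) * (ds1 + ds2)) / Z^2
    p_new <- p - res / (1 + d_total * dnu)
    if (!is.finite(p_new) || p_new <= lo || p_new >= hi) p_new <- (lo + hi) / 2
    if (abs(p_new - p) <= .Machine$double.eps * max(p, 1e-300)) { p <- p_new; break }
    p <- p_new
  }
  p
}

#' Simulate a noiseless EMSA titration series
#'
#' For each total protein concentration, solves the free protein under
#' depletion and evaluates the species fractions — the model twin of a
#' quantitative EMSA titration at fixed probe concentration.
#'
#' @param params A [site_affinities()] object.
#' @param p_totals Vector of total protein concentrations (molar).
#' @param d_total Total DNA duplex concentration (molar).
#' @return Tibble with columns `lane`, `p_total`, `d_total`, `p_free`,
#'   `f0`, `f1`, `f2` (concentrations molar).
#' @export
simulate_titration <- function(params, p_totals, d_total) {
  stopifnot(inherits(params, "site_affinities"))
  if (any(p_totals < 0)) abort("`p_totals` must be non-negative.")
  if (d_total <= 0) abort("`d_total` must be positive.")
  p_free <- solve_free_protein(params, p_totals, d_total)
  fr <- partition_fractions(params, p_free)
  tibble(
    lane = seq_along(p_totals),
    p_total = as.numeric(p_totals), d_total = as.numeric(d_total),
    p_free = p_free, f0 = fr$f0, f1 = fr$f1, f2 = fr$f2
  )
}

#' Macroscopic (sequential) association constants
#'
#' Maps microscopic two-site parameters to the macroscopic stepwise
#' constants used by sequential-site calorimetry models:
#' `Ka1 = K1 + K2` and `Ka2 = omega K1 K2 / (K1 + K2)`. For equal
#' independent sites (`K1 = K2 = K`, `omega = 1`) this gives the familiar
#' statistical-factor pair `(2K, K/2)`.
#'
#' @param params A [site_affinities()] object.
#' @return Named numeric vector `c(Ka1, Ka2)`, per molar.
#' @export
macroscopic_constants <- function(params) {
  stopifnot(inherits(params, "site_affinities"))
  c(Ka1 = params$K1 + params$K2,
    Ka2 = params$omega * params$K1 * params$K2 / (params$K1 + params$K2))
}

# Inverse mapping used by the sequential ITC model: equivalent-site
# microscopic parameters reproducing macroscopic (Ka1, Ka2). Plain list so
# optimizers may probe extreme values without tripping validation.
microscopic_from_macroscopic <- function(Ka1, Ka2) {
  list(K1 = Ka1 / 2, K2 = Ka1 / 2, omega = 4 * Ka2 / Ka1)
}
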