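# Full-model least-squares fit of the two-site binding parameters to an
# EMSA titration series (assumption-free alternative to the per-lane ratio
# estimator).

#' Fit two-site affinities and cooperativity to an EMSA titration series
#'
#' Weighted least squares of the predicted versus observed species fractions
#' `(f0, f1, f2)` across lanes. Parameters are optimised in log space with
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]); the free protein is solved
#' per lane inside the objective, so ligand depletion is handled exactly.
#' Five fixed multi-starts guard against local minima.
#'
#' Identifiability: the two-site partition function depends on the
#' microscopic parameters only through `K1 + K2` and `omega * K1 * K2`, so
#' species fractions alone cannot separate the three. By default the fit
#' therefore ties `K2 = K1` (equivalent-sites convention) and reports the
#' two identifiable quantities through that convention; supplying outside
#' information via `fix` (for example `K1` measured on a single-site probe)
#' lifts the degeneracy and frees the remaining parameters. Fitted outputs
#' are canonicalised to `K1 >= K2`.
#'
#' @param series Tibble with columns `p_total`, `d_total` (molar), `f0`,
#'   `f1`, `f2` — at least 4 lanes spanning sub- to super-stoichiometric
#'   protein.
#' @param fix Optional named list fixing parameters at given values, e.g.
#'   `list(omega = 1)` for an independent-sites fit or `list(K1 = 1.27e6)`
#'   to anchor one site. Fixing (or thereby freeing) `K1`/`K2` disables the
#'   equal-sites tie.
#' @param weights Optional per-lane weights (length `nrow(series)`),
#'   default unit weights.
#' @return Object of class `emsa_fit`: `params` ([site_affinities()]),
#'   `rss`, `se` (approximate log-scale standard errors), `converged`,
#'   `boundary` flag (omega driven to ~0), `fitted` lane tibble, `series`.
#' @examples
#' truth <- site_affinities(1.27e6, 1.27e6, omega = 3)
#' lanes <- simulate_titration(truth, seq(0.5, 20, length.out = 8) * 1e-6, 2.5e-6)
#' fit <- fit_affinities(lanes)
#' tidy(fit)
#' @export
fit_affinities <- function(series, fix = NULL, weights = NULL) {
  need <- c("p_total", "d_total", "f0", "f1", "f2")
  if (!all(need %in% names(series))) {
    abort("`series` needs columns p_total, d_total, f0, f1, f2 (molar units).")
  }
  if (nrow(series) < 4L) abort("At least 4 lanes are required to fit 3 parameters.")
  w <- weights %||% rep(1, nrow(series))
  if (length(w) != nrow(series)) abort("`weights` must have one entry per lane.")
  fixed <- fix %||% list()
  # equal-sites tie unless the user anchors K1 or K2 externally
  tie_k2 <- !any(c("K1", "K2") %in% names(fixed))
  free_names <- setdiff(c("K1", "K2", "omega"), names(fixed))
  if (tie_k2) free_names <- setdiff(free_names, "K2")

  obs <- as.matrix(series[, c("f0", "f1", "f2")])
  wvec <- rep(sqrt(w), times = 3)

  p_tot <- series$p_total
  d_tot <- rep_len(series$d_total, nrow(series))
  residual_fn <- function(theta) {
    pars <- as.list(pmin(pmax(exp(theta), 1e-30), 1e30))
    names(pars) <- free_names
    pars <- modifyList(pars, fixed)
    if (tie_k2) pars$K2 <- pars$K1
    # plain list, not the validating constructor: the optimizer may probe
    # extreme values that are clamped rather than rejected
    params <- list(K1 = pars$K1, K2 = pars$K2, omega = max(pars$omega, 1e-12))
    pf <- vapply(seq_along(p_tot), function(i) {
      solve_free_one(params, p_tot[i], d_tot[i])
    }, numeric(1))
    fr <- fractions_raw(params$K1, params$K2, params$omega, pf)
    wvec * (c(fr$f0, fr$f1, fr$f2) - c(obs))
  }

  # Fixed multi-starts bracketing the stoichiometric concentration scale.
  k_scale <- 1 / max(stats::median(series$p_total), 1e-12)
  starts <- list(
    c(K1 = k_scale, K2 = k_scale, omega = 1),
    c(K1 = 10 * k_scale, K2 = 10 * k_scale, omega = 3),
    c(K1 = k_scale, K2 = 0.1 * k_scale, omega = 10),
    c(K1 = 0.1 * k_scale, K2 = 0.1 * k_scale, omega = 0.3),
    c(K1 = 3 * k_scale, K2 = 3 * k_scale, omega = 30)
  )

  best <- NULL
  for (s in starts) {
    theta0 <- log(s[free_names])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, fn = residual_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-14, ptol = 1e-14, maxiter = 500
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) abort("All optimizer starts failed; check the input series.")

  fit <- best$fit
  pars <- as.list(exp(fit$par))
  names(pars) <- free_names
  pars <- modifyList(pars, fixed)
  if (tie_k2) pars$K2 <- pars$K1
  boundary <- pars$omega < 1e-6

  # canonical orientation K1 >= K2
  if (pars$K2 > pars$K1) pars[c("K1", "K2")] <- pars[c("K2", "K1")]
  params <- site_affinities(pars$K1, pars$K2, max(pars$omega, 0))

  # approximate log-scale standard errors from the LM Hessian
  se <- tryCatch({
    dof <- max(length(fit$fvec) - length(fit$par), 1)
    covm <- solve(fit$hessian) * best$rss / dof
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(fit$par)))
  names(se) <- free_names

  fitted <- simulate_titration(params, series$p_total, series$d_total[1])
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn("Levenberg-Marquardt did not report clean convergence; returning best-so-far.")
  }
  structure(
    list(params = params, rss = best$rss, se = se, converged = converged,
         boundary = boundary, fitted = fitted, series = as_tibble(series),
         n_lanes = nrow(series)),
    class = "emsa_fit"
  )
}

#' @export
print.emsa_fit <- function(x, ...) {
  cat("<emsa_fit>\n")
  print(x$params)
  cat(sprintf("  RSS = %.3g over %d lanes; converged: %s%s\n",
              x$rss, x$n_lanes, x$converged,
              if (x$boundary) "; omega at ~0 boundary" else ""))
  invisible(x)
}

#' @rdname fit_affinities
#' @param x An `emsa_fit` object.
#' @param ... Unused.
#' @method tidy emsa_fit
#' @export
tidy.emsa_fit <- function(x, ...) {
  est <- c(K1 = x$params$K1, K2 = x$params$K2, omega = x$params$omega)
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error.log = unname(x$se[names(est)])
  )
}

#' @rdname fit_affinities
#' @method glance emsa_fit
#' @export
glance.emsa_fit <- function(x, ...) {
  tibble(rss = x$rss, n_lanes = x$n_lanes, converged = x$converged,
         boundary = x$boundary,
         KD1_uM = 1e6 / x$params$K1, KD2_uM = 1e6 / x$params$K2,
         omega = x$params$omega)
}

#' @rdname fit_affinities
#' @param object An `emsa_fit` object (for `autoplot`).
#' @method autoplot emsa_fit
#' @export
autoplot.emsa_fit <- function(object, ...) {
  obs <- object$series |>
    dplyr::select("p_total", "f0", "f1", "f2") |>
    tidyr::pivot_longer(c("f0", "f1", "f2"),
                        names_to = "species", values_to = "fraction")
  pred <- object$fitted |>
    dplyr::select("p_total", "f0", "f1", "f2") |>
    tidyr::pivot_longer(c("f0", "f1", "f2"),
                        names_to = "species", values_to = "fraction")
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$p_total * 1e6,
                                    y = .data$fraction,
                                    colour = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred) +
    ggplot2::labs(x = "total protein (uM)", y = "species fraction",
                  colour = NULL,
                  title = "Two-site binding fit to EMSA fractions") +
    ggplot2::theme_minimal()
}
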