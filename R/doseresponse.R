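#' Auxiliary eta of the analytic time-dependent EC50
#'
#' At the half-maximal dose of a covalent-occupancy dose-response read out at
#' time `t_dr`, the observed rate satisfies `kobs = -eta / t_dr` with
#' `eta = ln((1 + exp(-kinactapp t_dr)) / 2)`. eta lies in `[-ln 2, 0)`,
#' approaching 0 as `kinactapp * t_dr -> 0` and `-ln 2` as it grows.
#'
#' @param kinactapp Apparent inactivation rate constant (s^-1), >= 0.
#' @param t_dr Dose-response stop time (s), > 0.
#' @return eta (dimensionless, vectorized).
#' @examples
#' eta_ec50(5e-5, 7.1 * 3600)
#' @export
eta_ec50 <- function(kinactapp, t_dr) {
  stopifnot(all(kinactapp >= 0), all(t_dr > 0))
  x <- kinactapp * t_dr
  log1p(expm1(-x) / 2)
}

#' Analytic time-dependent EC50 for covalent occupancy
#'
#' Closed-form approximation of the dose giving half-maximal covalent
#' occupancy at the stop time `t_dr`:
#' `EC50 = -KIapp * eta / (kinactapp * t_dr + eta)`, derived by equating the
#' pseudo-first-order growth factor at the half-maximum with the
#' Michaelis-Menten analog of kobs. As `kinactapp -> 0` the EC50 approaches
#' KIapp, which in that limit equals the reversible affinity Kd; the
#' approximation degrades when `kon * [I]0 < kinactapp` at the midpoint or
#' when the bimolecular step is nonlinear (enzyme/inhibitor depletion).
#'
#' @inheritParams eta_ec50
#' @param KIapp Apparent inactivation constant (uM), > 0.
#' @return EC50 in uM (vectorized over `kinactapp`).
#' @examples
#' ec50_analytic(5e-5, 0.505, 7.1 * 3600)
#' @export
ec50_analytic <- function(kinactapp, KIapp, t_dr) {
  stopifnot(all(KIapp > 0))
  e <- eta_ec50(kinactapp, t_dr)
  x <- kinactapp * t_dr
  out <- ifelse(x < 1e-12, KIapp, -KIapp * e / (x + e))
  as.numeric(out)
}

#' Simulate a covalent-occupancy dose-response curve
#'
#' Integrates the reduced two-step scheme (full ODEs, bimolecular association
#' included) at each dose and records the covalent occupancy at the stop time
#' `t_dr`. The analytic amplitude `1 - exp(-kinactapp t_dr)`, eta and analytic
#' EC50 are attached for comparison with the simulated curve.
#'
#' @param kon Association rate constant (uM^-1 s^-1).
#' @param koffapp Apparent dissociation rate constant (s^-1).
#' @param kinactapp Apparent inactivation rate constant (s^-1).
#' @param E0 Total enzyme (uM).
#' @param t_dr Stop time (s).
#' @param doses Dose array (uM); default 50 log-spaced doses spanning
#'   1e-2x to 1e2x the analytic EC50.
#' @param n_doses Number of doses for the default grid.
#' @param rtol,atol Integration tolerances.
#' @return An object of class `dose_response_result`: `data` (tibble of dose
#'   and covalent occupancy `co`), `amplitude`, `eta`, `ec50_analytic`,
#'   `KIapp`, `t_dr` and the input parameters.
#' @examples
#' \donttest{
#' dr <- dose_response(kon = 1e-2, koffapp = 5e-3, kinactapp = 5e-5,
#'                     E0 = 1e-3, t_dr = 7.1 * 3600, n_doses = 12)
#' }
#' @export
dose_response <- function(kon, koffapp, kinactapp, E0, t_dr, doses = NULL,
                          n_doses = 50, rtol = 1e-8, atol = 1e-12) {
  stopifnot(kon > 0, koffapp >= 0, kinactapp > 0, E0 > 0, t_dr > 0)
  KIapp <- (koffapp + kinactapp) / kon
  ec50 <- ec50_analytic(kinactapp, KIapp, t_dr)
  if (is.null(doses))
    doses <- 10^seq(log10(1e-2 * ec50), log10(1e2 * ec50),
                    length.out = n_doses)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  co <- vapply(doses, function(d)
    co_at_t(kon, koffapp, kinactapp, E0, d, t_dr, rtol, atol), 0)
  structure(list(
    data = tibble::tibble(dose = doses, co = co),
    amplitude = -expm1(-kinactapp * t_dr),
    eta = eta_ec50(kinactapp, t_dr),
    ec50_analytic = ec50, KIapp = KIapp, t_dr = t_dr,
    params = list(kon = kon, koffapp = koffapp, kinactapp = kinactapp,
                  E0 = E0)), class = "dose_response_result")
}

# CO at a single (dose, time) for the reduced two-step scheme.
co_at_t <- function(kon, koffapp, kinactapp, E0, dose, t, rtol = 1e-8,
                    atol = 1e-12) {
  sch <- build_scheme("scheme1", E0 = E0, I0 = dose, kon = kon,
                      koffapp = koffapp, kinactapp = kinactapp)
  tc <- simulate_scheme(sch, t_grid = c(0, t / 2, t), rtol = rtol,
                        atol = atol)
  tc[["E-I"]][nrow(tc)] / E0
}

#' @export
print.dose_response_result <- function(x, ...) {
  cat("<dose_response_result> ", nrow(x$data), " doses at t_dr = ",
      format(x$t_dr), " s\n", sep = "")
  cat(sprintf("  amplitude = %.6g, eta = %.6g, analytic EC50 = %.6g uM\n",
              x$amplitude, x$eta, x$ec50_analytic))
  invisible(x)
}

#' @rdname dose_response
#' @param x A `dose_response_result`.
#' @param ... Unused.
#' @export
glance.dose_response_result <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, eta = x$eta,
                 ec50_analytic = x$ec50_analytic, KIapp = x$KIapp,
                 t_dr = x$t_dr, n_doses = nrow(x$data))
}

#' Locate the simulated dose-response midpoint by bisection
#'
#' Finds the dose at which the simulated covalent occupancy at `t_dr` equals
#' half of the analytic amplitude `1 - exp(-kinactapp t_dr)`, by root
#' bracketing on the full ODE solution. Serves as the numerical reference
#' against which [ec50_analytic()] is judged.
#'
#' @inheritParams dose_response
#' @return Midpoint dose in uM.
#' @export
ec50_simulated <- function(kon, koffapp, kinactapp, E0, t_dr, rtol = 1e-8,
                           atol = 1e-12) {
  target <- -expm1(-kinactapp * t_dr) / 2
  ec0 <- ec50_analytic(kinactapp, (koffapp + kinactapp) / kon, t_dr)
  f <- function(d) co_at_t(kon, koffapp, kinactapp, E0, d, t_dr, rtol,
                           atol) - target
  lo <- ec0 * 1e-3; hi <- ec0 * 1e3
  for (i in 1:10) {
    if (f(lo) < 0) break
    lo <- lo / 10
  }
  for (i in 1:10) {
    if (f(hi) > 0) break
    hi <- hi * 10
  }
  stats::uniroot(f, c(lo, hi), tol = ec0 * 1e-8)$root
}

#' Fit the Hill equation to a dose-response curve
#'
#' Least-squares fit of `response = amplitude / (1 + (EC50 / dose)^n)`.
#' `amplitude` and/or `ec50` can be fixed (for example to their analytic
#' values, leaving the Hill coefficient n as the sole free parameter); free
#' parameters are initialized from the data (n at 1, EC50 at the half-maximum
#' dose, amplitude at the maximal response). Non-monotone responses are
#' refused.
#'
#' @param data Data frame with dose and response columns.
#' @param dose,response Column names; defaults `"dose"` and `"co"` match
#'   [dose_response()] output (pass the result's `data` element, or pipe a
#'   `dose_response_result` through [tidy_dose_response()]).
#' @param amplitude,ec50 Optional fixed values; `NULL` leaves them free.
#' @param monotone_tol Relative tolerance for the monotonicity check.
#' @return An object of class `hill_fit` with `amplitude`, `ec50`, `n`,
#'   logical flags for which were fixed, and the underlying `nls` fit.
#' @examples
#' d <- 10^seq(-2, 2, length.out = 20)
#' fit_hill(data.frame(dose = d, co = 0.7 / (1 + 1 / d)))
#' @export
fit_hill <- function(data, dose = "dose", response = "co", amplitude = NULL,
                     ec50 = NULL, monotone_tol = 1e-3) {
  if (inherits(data, "dose_response_result")) data <- data$data
  data <- tibble::as_tibble(data)
  if (!all(c(dose, response) %in% names(data)))
    stop("data must have columns '", dose, "' and '", response, "'",
         call. = FALSE)
  ord <- order(data[[dose]])
  d <- data[[dose]][ord]
  y <- data[[response]][ord]
  if (length(d) < 3) stop("need at least 3 doses", call. = FALSE)
  if (any(diff(y) < -monotone_tol * max(abs(y))))
    stop("responses are not monotone in dose; refusing the Hill fit",
         call. = FALSE)
  amp_fixed <- !is.null(amplitude)
  ec_fixed <- !is.null(ec50)
  A0 <- amplitude %||% max(y)
  e0 <- ec50 %||% stats::approx(y, d, xout = max(y) / 2, ties = "ordered")$y
  if (!is.finite(e0) || e0 <= 0) e0 <- exp(mean(log(d)))
  start <- list(n = 1)
  lower <- c(n = 0)
  if (!ec_fixed) {
    start$ec <- e0
    lower <- c(lower, ec = 0)
  }
  if (!amp_fixed) {
    start$A <- A0
    lower <- c(lower, A = 0)
  }
  df <- data.frame(d = d, y = y, Afix = A0, ecfix = e0)
  rhs <- paste0(if (amp_fixed) "Afix" else "A",
                " / (1 + (", if (ec_fixed) "ecfix" else "ec",
                " / d)^n)")
  fit <- minpack.lm::nlsLM(stats::as.formula(paste("y ~", rhs)), data = df,
                           start = start, lower = lower,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  structure(list(
    amplitude = if (amp_fixed) amplitude else cf[["A"]],
    ec50 = if (ec_fixed) ec50 else cf[["ec"]],
    n = cf[["n"]],
    amplitude_fixed = amp_fixed, ec50_fixed = ec_fixed,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    data = tibble::tibble(dose = d, response = y),
    fit = fit), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> amplitude = %.6g%s, EC50 = %.6g uM%s, n = %.4g\n",
    x$amplitude, if (x$amplitude_fixed) " (fixed)" else "",
    x$ec50, if (x$ec50_fixed) " (fixed)" else "", x$n))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "ec50", "n"),
    estimate = c(x$amplitude, x$ec50, x$n),
    fixed = c(x$amplitude_fixed, x$ec50_fixed, FALSE))
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(n = x$n, residual_norm = x$residual_norm,
                 nobs = nrow(x$data))
}

#' Dose-response table of a result object
#'
#' @param x A `dose_response_result`.
#' @return Its dose/CO tibble augmented with the analytic Hill-form curve.
#' @export
tidy_dose_response <- function(x) {
  stopifnot(inherits(x, "dose_response_result"))
  dplyr::mutate(x$data,
                co_analytic = x$amplitude /
                  (1 + (x$ec50_analytic / .data$dose)))
}
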