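#' Fit the observed inactivation rate constant kobs
#'
#' Fits the covalent-occupancy time course to the pseudo-first-order growth
#' factor `CO(t) = 1 - exp(-kobs t)` by unweighted least squares over the full
#' trace. The initial guess is taken from the time to half-plateau.
#'
#' @param data A data frame with a time column and a covalent-occupancy
#'   column (a `kin_occupancy` tibble works directly).
#' @param time,response Column names (strings) of time (s) and covalent
#'   occupancy; default `"time"` and `"covalent_occupancy"`.
#' @return An object of class `kobs_fit` with elements `kobs` (s^-1),
#'   `residual_norm`, `data`, `fit` (the underlying `nls` object) and
#'   `ill_conditioned` (TRUE when the trace plateaus below 0.01, in which case
#'   a warning is also raised and the estimate is best-effort).
#' @examples
#' t <- seq(0, 5e4, length.out = 50)
#' fit_kobs(data.frame(time = t, covalent_occupancy = 1 - exp(-1e-4 * t)))
#' @export
fit_kobs <- function(data, time = "time", response = "covalent_occupancy") {
  data <- tibble::as_tibble(data)
  if (!all(c(time, response) %in% names(data)))
    stop("data must have columns '", time, "' and '", response, "'",
         call. = FALSE)
  t <- data[[time]]
  co <- data[[response]]
  keep <- is.finite(t) & is.finite(co)
  t <- t[keep]; co <- co[keep]
  if (length(t) < 3) stop("need at least 3 timepoints", call. = FALSE)
  ill <- max(co) < 0.01
  if (ill)
    warning("covalent occupancy plateaus below 0.01 within the trace; ",
            "the kobs estimate is ill-conditioned", call. = FALSE)
  k0 <- kobs_init(t, co)
  df <- data.frame(t = t, co = co)
  fit <- minpack.lm::nlsLM(co ~ 1 - exp(-k * t), data = df,
                           start = list(k = k0), lower = 0,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(kobs = stats::coef(fit)[["k"]],
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 data = tibble::tibble(time = t, covalent_occupancy = co),
                 fit = fit, ill_conditioned = ill),
            class = "kobs_fit")
}

kobs_init <- function(t, co) {
  co_end <- co[length(co)]
  if (max(co) >= 0.5) {
    t50 <- t[which(co >= 0.5)[1]]
    if (t50 > 0) return(log(2) / t50)
  }
  t_end <- t[length(t)]
  if (co_end < 1 && co_end > 0 && t_end > 0) return(-log1p(-co_end) / t_end)
  1 / max(t_end, 1)
}

#' @export
print.kobs_fit <- function(x, ...) {
  cat(sprintf("<kobs_fit> kobs = %.6g s^-1 (residual norm %.3g%s)\n",
              x$kobs, x$residual_norm,
              if (x$ill_conditioned) ", ill-conditioned" else ""))
  invisible(x)
}

#' @rdname fit_kobs
#' @param x A `kobs_fit`.
#' @param ... Unused.
#' @export
tidy.kobs_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = "kobs", estimate = x$kobs,
                 std.error = s["k", "Std. Error"])
}

#' @rdname fit_kobs
#' @export
glance.kobs_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, nobs = nrow(x$data),
                 ill_conditioned = x$ill_conditioned)
}

#' Fit the Michaelis-Menten analog of kobs versus dose
#'
#' Nonlinear least-squares fit of
#' `kobs = kinactapp * [I]0 / (KIapp + [I]0)`, the dose dependence of the
#' observed inactivation rate. Also reports the inactivation efficiency
#' `Effinact = kinactapp / KIapp` (the low-dose slope of kobs versus dose) and
#' a low-dose linear-regime check: a straight-line fit through the doses below
#' the fitted KIapp, whose intercept should be ~0 and whose slope should match
#' Effinact when the linear regime is sampled.
#'
#' @param data A data frame with columns `dose` (uM) and `kobs` (s^-1), e.g.
#'   the per-dose table of [dose_rate()].
#' @param dose,kobs Column names, defaulting to `"dose"` and `"kobs"`.
#' @return An object of class `mm_fit` with `kinactapp`, `KIapp`, `Effinact`,
#'   the coefficient covariance matrix `vcov`, the low-dose check
#'   `linear_check` (slope, intercept) and the underlying `nls` fit.
#' @examples
#' d <- 10^seq(-1, 1, length.out = 8) * 0.505
#' fit_mm_analog(data.frame(dose = d, kobs = 5e-5 * d / (0.505 + d)))
#' @export
fit_mm_analog <- function(data, dose = "dose", kobs = "kobs") {
  data <- tibble::as_tibble(data)
  if (!all(c(dose, kobs) %in% names(data)))
    stop("data must have columns '", dose, "' and '", kobs, "'",
         call. = FALSE)
  d <- data[[dose]]; k <- data[[kobs]]
  if (length(d) < 4)
    warning("fewer than 4 doses; the Michaelis-Menten analog fit may be ",
            "poorly constrained", call. = FALSE)
  kmax0 <- max(k)
  KI0 <- stats::approx(k, d, xout = kmax0 / 2, ties = "ordered")$y
  if (!is.finite(KI0) || KI0 <= 0) KI0 <- stats::median(d)
  df <- data.frame(d = d, k = k)
  fit <- minpack.lm::nlsLM(k ~ kmax * d / (KI + d), data = df,
                           start = list(kmax = kmax0, KI = KI0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  kinactapp <- stats::coef(fit)[["kmax"]]
  KIapp <- stats::coef(fit)[["KI"]]
  if (max(d) < 0.2 * KIapp)
    warning("all doses lie far below the fitted KIapp; kinactapp and KIapp ",
            "are unidentifiable separately (slope-only regime)",
            call. = FALSE)
  low <- d < KIapp
  lin <- if (sum(low) >= 2) stats::lm(k[low] ~ d[low]) else NULL
  structure(list(
    kinactapp = kinactapp, KIapp = KIapp,
    Effinact = kinactapp / KIapp,
    vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
    linear_check = if (!is.null(lin))
      c(slope = unname(stats::coef(lin)[2]),
        intercept = unname(stats::coef(lin)[1])) else NULL,
    data = tibble::tibble(dose = d, kobs = k),
    fit = fit), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> kinactapp = %.6g s^-1, KIapp = %.6g uM\n",
              x$kinactapp, x$KIapp))
  cat(sprintf("  Effinact = kinactapp/KIapp = %.6g uM^-1 s^-1\n", x$Effinact))
  if (!is.null(x$linear_check))
    cat(sprintf("  low-dose linear check: slope = %.4g, intercept = %.3g\n",
                x$linear_check[["slope"]], x$linear_check[["intercept"]]))
  invisible(x)
}

#' @rdname fit_mm_analog
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @export
tidy.mm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("kinactapp", "KIapp", "Effinact"),
    estimate = c(x$kinactapp, x$KIapp, x$Effinact),
    std.error = c(s["kmax", "Std. Error"], s["KI", "Std. Error"], NA),
    unit = c("s^-1", "uM", "uM^-1 s^-1"))
}

#' @rdname fit_mm_analog
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(Effinact = x$Effinact,
                 residual_norm = sqrt(sum(stats::resid(x$fit)^2)),
                 nobs = nrow(x$data))
}
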