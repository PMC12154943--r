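#' Rapid-equilibrium reduction of the expanded scheme
#'
#' Reduces the expanded intermediate-state scheme (nonreactive and reactive
#' bound conformations exchanging at `kr`/`knr`) to an effective two-step
#' scheme. Under rapid equilibrium of the bound conformations the reactive
#' probability is `pr = kr / (kr + knr)`, the apparent dissociation rate is
#' `koffapp = (1 - pr) * koff` (only the nonreactive conformation can
#' dissociate) and the apparent inactivation rate is
#' `kinactapp = pr * kinact`.
#'
#' A timescale-separation ratio `(kr + knr) / max(koff, kinact, kon * I_ref)`
#' is reported so the validity of the reduction can be judged; the
#' approximation degrades as the ratio approaches 1.
#'
#' @param kon Association rate constant (uM^-1 s^-1).
#' @param koff Dissociation rate constant of the nonreactive conformation
#'   (s^-1).
#' @param kr,knr Arming / disarming rate constants (s^-1).
#' @param kinact Microscopic inactivation rate constant of the reactive
#'   conformation (s^-1).
#' @param I_ref Reference inhibitor concentration (uM) for the separation
#'   diagnostic.
#' @return An object of class `reduced_params`: pr, pnr, koffapp, kinactapp,
#'   Kd = koff/kon, residence time tau = 1/(koff (1 - pr)) (infinite, flagged,
#'   at pr = 1), the microscopic inputs, and `separation`.
#' @examples
#' reduce_params(kon = 1e-2, koff = 1e-2, kr = 50, knr = 50, kinact = 1e-4)
#' @export
reduce_params <- function(kon, koff, kr, knr, kinact, I_ref = 1) {
  vals <- c(kon = kon, koff = koff, kr = kr, knr = knr, kinact = kinact)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rate constants must be positive and finite", call. = FALSE)
  pr <- kr / (kr + knr)
  pnr <- 1 - pr
  structure(list(
    pr = pr, pnr = pnr,
    koffapp = pnr * koff, kinactapp = pr * kinact,
    Kd = koff / kon,
    tau = if (pr < 1) 1 / (koff * (1 - pr)) else Inf,
    tau_defined = pr < 1,
    kon = kon, koff = koff, kr = kr, knr = knr, kinact = kinact,
    separation = (kr + knr) / max(koff, kinact, kon * I_ref)),
    class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat("<reduced_params> rapid-equilibrium reduction\n")
  cat(sprintf("  pr = %.6g, pnr = %.6g\n", x$pr, x$pnr))
  cat(sprintf("  koffapp = %.6g s^-1, kinactapp = %.6g s^-1\n",
              x$koffapp, x$kinactapp))
  cat(sprintf("  Kd = %.6g uM, tau = %.6g s%s\n", x$Kd, x$tau,
              if (!x$tau_defined) " (undefined: pr = 1)" else ""))
  cat(sprintf("  timescale separation (kr+knr)/max(slow rates) = %.3g\n",
              x$separation))
  invisible(x)
}

#' @rdname reduce_params
#' @param x A `reduced_params` object.
#' @param ... Unused.
#' @export
tidy.reduced_params <- function(x, ...) {
  tibble::tibble(
    term = c("pr", "pnr", "koffapp", "kinactapp", "Kd", "tau", "separation"),
    estimate = c(x$pr, x$pnr, x$koffapp, x$kinactapp, x$Kd, x$tau,
                 x$separation),
    unit = c("", "", "s^-1", "s^-1", "uM", "s", ""))
}

#' Convert a reduced parameter set to a scheme
#'
#' @param x A `reduced_params` object.
#' @param E0,I0 Initial concentrations (uM).
#' @param expanded If `TRUE`, build the expanded scheme (scheme 2) with the
#'   microscopic constants; otherwise the reduced two-step scheme (scheme 3).
#' @return A [kin_scheme()].
#' @export
as_scheme <- function(x, E0, I0, expanded = FALSE) {
  stopifnot(inherits(x, "reduced_params"))
  if (expanded)
    build_scheme("scheme2", E0 = E0, I0 = I0, kon = x$kon, koff = x$koff,
                 kr = x$kr, knr = x$knr, kinact = x$kinact)
  else
    build_scheme("scheme3", E0 = E0, I0 = I0, kon = x$kon, koff = x$koff,
                 kinact = x$kinact, pr = x$pr)
}
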