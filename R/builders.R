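#' Build a canonical covalent-inhibition scheme
#'
#' Constructs one of the five canonical kinetic schemes used throughout the
#' package. Species are named `E` (free enzyme), `I` (free inhibitor), `E..I`
#' (nonreactive, dissociable noncovalent complex; in the reduced two-step
#' schemes, the single noncovalent complex), `E.I` (reactive noncovalent
#' conformation) and `E-I` (covalent adduct), each carrying the matching role
#' tag.
#'
#' * `scheme1`: two-step E + I <-> E..I -> E-I with apparent constants
#'   `kon`, `koffapp`, `kinactapp`.
#' * `scheme2`: expanded scheme E + I <-> E..I <-> E.I -> E-I with `kon`,
#'   `koff`, arming/disarming rates `kr`, `knr` and microscopic `kinact`.
#' * `scheme3`: rapid-equilibrium reduction of scheme 2; dissociation proceeds
#'   at `(1 - pr) * koff` and inactivation at `pr * kinact`, with
#'   `pr = kr / (kr + knr)` passed directly.
#' * `scheme4`: noncovalent version of scheme 2 (no inactivation step).
#' * `scheme5`: pseudo-first-order linearization of the two-step scheme: the
#'   bimolecular association is replaced by a unimolecular step at rate
#'   `kon_I0 = kon * [I]0`.
#'
#' Transitions whose effective rate is exactly zero (for example dissociation
#' in `scheme3` with `pr = 1`) are omitted from the scheme.
#'
#' @param name One of `"scheme1"`, `"scheme2"`, `"scheme3"`, `"scheme4"`,
#'   `"scheme5"`.
#' @param E0,I0 Initial enzyme and inhibitor concentrations (uM). `I0` is not
#'   used by `scheme5`, whose dose enters through `kon_I0`.
#' @param kon Bimolecular association rate constant (uM^-1 s^-1).
#' @param koff,koffapp Microscopic / apparent dissociation rate (s^-1).
#' @param kinact,kinactapp Microscopic / apparent inactivation rate (s^-1).
#' @param kr,knr Arming (nonreactive -> reactive) and disarming rates (s^-1).
#' @param pr Equilibrium probability of the reactive conformation, in `[0, 1]`.
#' @param kon_I0 Pseudo-first-order association rate `kon * [I]0` (s^-1), for
#'   `scheme5`.
#' @return A [kin_scheme()].
#' @examples
#' build_scheme("scheme3", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
#'              kinact = 1e-4, pr = 0.5)
#' @export
build_scheme <- function(name, E0 = NULL, I0 = NULL, kon = NULL, koff = NULL,
                         kinact = NULL, pr = NULL, kr = NULL, knr = NULL,
                         koffapp = NULL, kinactapp = NULL, kon_I0 = NULL) {
  name <- match.arg(name, paste0("scheme", 1:5))
  need <- function(...) {
    vals <- list(...)
    miss <- names(vals)[vapply(vals, is.null, TRUE)]
    if (length(miss))
      stop(name, " requires parameter(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    invisible(vals)
  }
  if (!is.null(pr) && (pr < 0 || pr > 1))
    stop("pr must lie in [0, 1]", call. = FALSE)

  sp <- function(names, initials) {
    roles <- list(E = "free_enzyme", I = "free_inhibitor",
                  `E..I` = "noncovalent_complex",
                  `E.I` = "noncovalent_complex",
                  `E-I` = "covalent_complex")
    tibble::tibble(name = names, initial = initials,
                   roles = unname(roles[names]))
  }
  tr <- function(name, from, to, k)
    if (k > 0) list(kin_transition(name, from, to, k)) else list()

  switch(name,
    scheme1 = {
      need(E0 = E0, I0 = I0, kon = kon, koffapp = koffapp,
           kinactapp = kinactapp)
      kin_scheme(sp(c("E", "I", "E..I", "E-I"), c(E0, I0, 0, 0)), c(
        tr("assoc", c(E = 1, I = 1), c(`E..I` = 1), kon),
        tr("dissoc", c(`E..I` = 1), c(E = 1, I = 1), koffapp),
        tr("inact", c(`E..I` = 1), c(`E-I` = 1), kinactapp)))
    },
    scheme2 = {
      need(E0 = E0, I0 = I0, kon = kon, koff = koff, kr = kr, knr = knr,
           kinact = kinact)
      kin_scheme(sp(c("E", "I", "E..I", "E.I", "E-I"), c(E0, I0, 0, 0, 0)), c(
        tr("assoc", c(E = 1, I = 1), c(`E..I` = 1), kon),
        tr("dissoc", c(`E..I` = 1), c(E = 1, I = 1), koff),
        tr("arm", c(`E..I` = 1), c(`E.I` = 1), kr),
        tr("disarm", c(`E.I` = 1), c(`E..I` = 1), knr),
        tr("inact", c(`E.I` = 1), c(`E-I` = 1), kinact)))
    },
    scheme3 = {
      need(E0 = E0, I0 = I0, kon = kon, koff = koff, kinact = kinact, pr = pr)
      kin_scheme(sp(c("E", "I", "E..I", "E-I"), c(E0, I0, 0, 0)), c(
        tr("assoc", c(E = 1, I = 1), c(`E..I` = 1), kon),
        tr("dissoc", c(`E..I` = 1), c(E = 1, I = 1), (1 - pr) * koff),
        tr("inact", c(`E..I` = 1), c(`E-I` = 1), pr * kinact)))
    },
    scheme4 = {
      need(E0 = E0, I0 = I0, kon = kon, koff = koff, kr = kr, knr = knr)
      kin_scheme(sp(c("E", "I", "E..I", "E.I"), c(E0, I0, 0, 0)), c(
        tr("assoc", c(E = 1, I = 1), c(`E..I` = 1), kon),
        tr("dissoc", c(`E..I` = 1), c(E = 1, I = 1), koff),
        tr("arm", c(`E..I` = 1), c(`E.I` = 1), kr),
        tr("disarm", c(`E.I` = 1), c(`E..I` = 1), knr)))
    },
    scheme5 = {
      need(E0 = E0, kon_I0 = kon_I0, koffapp = koffapp, kinactapp = kinactapp)
      kin_scheme(sp(c("E", "E..I", "E-I"), c(E0, 0, 0)), c(
        tr("assoc", c(E = 1), c(`E..I` = 1), kon_I0),
        tr("dissoc", c(`E..I` = 1), c(E = 1), koffapp),
        tr("inact", c(`E..I` = 1), c(`E-I` = 1), kinactapp)))
    })
}
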