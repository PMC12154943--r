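#' Mass-action rate of change
#'
#' Evaluates the vectorized mass-action rate law: the per-transition fluxes are
#' the products of the source concentrations raised to their stoichiometric
#' coefficients, scaled by the rate constants, and the concentration derivative
#' is that flux row-vector multiplied by the complete stoichiometry matrix
#' `N = N_tgt - N_src`.
#'
#' @param scheme A [kin_scheme()].
#' @param conc Numeric concentration vector (uM), aligned to the scheme's
#'   species order.
#' @return Named numeric vector dC/dt (uM/s).
#' @examples
#' sch <- build_scheme("scheme5", E0 = 3, kon_I0 = 2, koffapp = 1,
#'                     kinactapp = 1)
#' rate_of_change(sch, c(3, 0, 0))
#' @export
rate_of_change <- function(scheme, conc) {
  stopifnot(inherits(scheme, "kin_scheme"))
  if (length(conc) != nrow(scheme$species))
    stop("concentration vector has length ", length(conc), ", scheme has ",
         nrow(scheme$species), " species", call. = FALSE)
  flux <- scheme$k * apply(scheme$N_src, 1L,
                           function(nu) prod(conc^nu))
  stats::setNames(as.numeric(flux %*% scheme$N), scheme$species$name)
}

# Fast closure over the rate law for the integrator: precomputes index/coef
# pairs per transition so the rhs avoids matrix powers with zero exponents.
make_rhs <- function(scheme) {
  m <- nrow(scheme$transitions)
  src_idx <- lapply(seq_len(m), function(i) which(scheme$N_src[i, ] > 0L))
  src_pow <- lapply(seq_len(m), function(i)
    scheme$N_src[i, src_idx[[i]], drop = TRUE])
  k <- unname(scheme$k)
  Nt <- t(scheme$N)
  function(t, y, parms) {
    flux <- vapply(seq_len(m), function(i)
      k[i] * prod(y[src_idx[[i]]]^src_pow[[i]]), 0)
    list(as.numeric(Nt %*% flux))
  }
}

#' Integrate a kinetic scheme
#'
#' Integrates the mass-action ODEs with LSODA (automatic stiff/non-stiff
#' switching; the fast conformational exchange of the expanded schemes makes
#' them stiff by construction). The default output grid is 400 logarithmically
#' spaced points from 0.01 s to `t_end`, preceded by t = 0, where the returned
#' concentrations equal the scheme's initial values exactly.
#'
#' Small negative excursions within the integrator's absolute tolerance are
#' clipped to zero; larger negativity raises an error. Each conserved moiety of
#' the scheme is checked to be constant along the trajectory to within
#' `10 * rtol` (relative); violations raise a warning, or an error when
#' `conservation = "error"`.
#'
#' @param scheme A [kin_scheme()].
#' @param t_end End time (s), used to build the default grid.
#' @param t_grid Optional explicit time grid (s); must start at 0 and be
#'   strictly increasing.
#' @param rtol,atol Relative / absolute integration tolerances (atol in uM).
#' @param max_step Maximum internal step size (s).
#' @param conservation `"warn"` (default) or `"error"` for conserved-moiety
#'   drift beyond tolerance.
#' @return A tibble of class `kin_timecourse` with column `time` (s) and one
#'   column per species (uM); the generating scheme and tolerances are attached
#'   as attributes.
#' @examples
#' sch <- build_scheme("scheme3", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
#'                     kinact = 1e-4, pr = 0.5)
#' tc <- simulate_scheme(sch, t_end = 1e4)
#' @export
simulate_scheme <- function(scheme, t_end = NULL, t_grid = NULL, rtol = 1e-8,
                            atol = 1e-12, max_step = Inf,
                            conservation = c("warn", "error")) {
  stopifnot(inherits(scheme, "kin_scheme"))
  conservation <- match.arg(conservation)
  if (is.null(t_grid)) {
    if (is.null(t_end) || t_end <= 0)
      stop("supply a positive t_end or an explicit t_grid", call. = FALSE)
    t_grid <- default_grid(t_end)
  }
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must start at 0 and be strictly increasing", call. = FALSE)
  y0 <- stats::setNames(scheme$species$initial, scheme$species$name)
  sol <- deSolve::lsoda(y = y0, times = t_grid, func = make_rhs(scheme),
                        parms = NULL, rtol = rtol, atol = atol,
                        hmax = if (is.finite(max_step)) max_step else NULL)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("LSODA failed near t = ", sol[nrow(sol), 1], " s (istate = ",
         diagn[1], ")", call. = FALSE)
  if (nrow(sol) < length(t_grid))
    stop("LSODA stopped early at t = ", sol[nrow(sol), 1], " s", call. = FALSE)
  conc <- sol[, -1, drop = FALSE]
  neg_tol <- atol + rtol * max(abs(y0), 1e-300)
  if (min(conc) < -neg_tol)
    stop("negative concentration beyond integrator tolerance (min = ",
         format(min(conc)), " uM)", call. = FALSE)
  conc[conc < 0] <- 0
  tc <- tibble::as_tibble(as.data.frame(conc))
  names(tc) <- scheme$species$name
  tc <- dplyr::bind_cols(tibble::tibble(time = sol[, 1]), tc)
  tc[1, -1] <- as.list(unname(y0))
  out <- structure(tc, class = c("kin_timecourse", class(tc)),
                   scheme = scheme, rtol = rtol, atol = atol)
  check_conservation(out, action = conservation)
  out
}

default_grid <- function(t_end, n = 400L, t_min = 1e-2) {
  t_min <- min(t_min, t_end / 1e4)
  c(0, exp(seq(log(t_min), log(t_end), length.out = n)))
}

check_conservation <- function(tc, action = "warn") {
  scheme <- attr(tc, "scheme")
  rtol <- attr(tc, "rtol")
  moieties <- conserved_moieties(scheme)
  if (!ncol(moieties)) return(invisible(TRUE))
  conc <- as.matrix(tc[, scheme$species$name])
  totals <- conc %*% moieties
  ref <- totals[1, ]
  drift <- apply(abs(sweep(totals, 2, ref)), 2, max) /
    pmax(abs(ref), .Machine$double.xmin)
  bad <- drift > 10 * rtol & ref > 0
  if (any(bad)) {
    msg <- paste0("conserved moiety drift beyond 10*rtol: ",
                  paste0(colnames(moieties)[bad], " (",
                         format(drift[bad], digits = 3), ")", collapse = ", "))
    if (action == "error") stop(msg, call. = FALSE) else warning(msg,
                                                                 call. = FALSE)
  }
  invisible(!any(bad))
}

#' Occupancy observables of a time course
#'
#' Computes the fraction of enzyme bound noncovalently or covalently
#' (`total_occupancy`) and the covalent occupancy `CO(t) = [E-I] / [E]0`
#' (`covalent_occupancy`) from the species tagged with the
#' `noncovalent_complex` and `covalent_complex` roles.
#'
#' @param timecourse A `kin_timecourse` from [simulate_scheme()].
#' @param E0 Total enzyme (uM); defaults to the summed initial concentration
#'   of all enzyme-containing species of the generating scheme.
#' @return A tibble of class `kin_occupancy` with columns `time`,
#'   `total_occupancy`, `covalent_occupancy`.
#' @export
occupancy <- function(timecourse, E0 = NULL) {
  stopifnot(inherits(timecourse, "kin_timecourse"))
  scheme <- attr(timecourse, "scheme")
  idx_free <- role_index(scheme, "free_enzyme")
  idx_nc <- role_index(scheme, "noncovalent_complex")
  idx_cov <- role_index(scheme, "covalent_complex")
  if (!length(c(idx_free, idx_nc, idx_cov)))
    stop("no species carries an enzyme role tag; occupancy is undefined",
         call. = FALSE)
  if (is.null(E0))
    E0 <- sum(scheme$species$initial[c(idx_free, idx_nc, idx_cov)])
  if (!is.numeric(E0) || E0 <= 0)
    stop("E0 must be positive", call. = FALSE)
  conc <- as.matrix(timecourse[, scheme$species$name])
  bound <- rowSums(conc[, idx_nc, drop = FALSE]) +
    rowSums(conc[, idx_cov, drop = FALSE])
  cov <- rowSums(conc[, idx_cov, drop = FALSE])
  structure(tibble::tibble(time = timecourse$time,
                           total_occupancy = bound / E0,
                           covalent_occupancy = cov / E0),
            class = c("kin_occupancy", class(tibble::tibble())),
            E0 = E0, scheme = scheme)
}
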