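#' Closed-form solution of an all-unimolecular scheme
#'
#' For schemes whose every transition consumes exactly one molecule of one
#' species, the mass-action ODEs are linear, `dC/dt = A C`, and the exact
#' solution is the matrix exponential evaluated by eigen-decomposition of the
#' rate matrix `A`. Used as an independent ground truth for the numerical
#' integrator (the pseudo-first-order scheme 5 qualifies).
#'
#' @param scheme A [kin_scheme()] in which every transition has a single source
#'   species with coefficient 1.
#' @return A list with `A` (rate matrix, species x species), `eigenvalues`
#'   (complex, sorted by decreasing real part) and `trajectory(times)`, a
#'   function returning the exact concentration matrix (rows = times, columns
#'   = species) for the scheme's initial concentrations.
#' @examples
#' sch <- build_scheme("scheme5", E0 = 1, kon_I0 = 1e-2, koffapp = 5e-3,
#'                     kinactapp = 5e-5)
#' linear_oracle(sch)$eigenvalues
#' @export
linear_oracle <- function(scheme) {
  stopifnot(inherits(scheme, "kin_scheme"))
  if (any(rowSums(scheme$N_src) != 1L))
    stop("linear_oracle applies only to all-unimolecular schemes ",
         "(every transition must have a single source with coefficient 1)",
         call. = FALSE)
  n <- nrow(scheme$species)
  A <- matrix(0, n, n, dimnames = list(scheme$species$name,
                                       scheme$species$name))
  for (i in seq_len(nrow(scheme$transitions))) {
    src <- which(scheme$N_src[i, ] == 1L)
    A[, src] <- A[, src] + scheme$k[i] * scheme$N[i, ]
  }
  eg <- eigen(A)
  ord <- order(-Re(eg$values))
  V <- eg$vectors[, ord, drop = FALSE]
  lambda <- eg$values[ord]
  c0 <- scheme$species$initial
  w <- solve(V, c0)
  trajectory <- function(times) {
    out <- vapply(times, function(t)
      Re(V %*% (w * exp(lambda * t)))[, 1], numeric(n))
    out <- t(matrix(out, nrow = n))
    colnames(out) <- scheme$species$name
    out
  }
  list(A = A, eigenvalues = lambda, trajectory = trajectory)
}
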