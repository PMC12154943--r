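# Shared fixtures: canonical parameter sets and generators for random
# schemes, all built in code.

fig1_params <- list(E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                    kinact = 1e-4)

fig4_cases <- list(
  case1 = list(E0 = 1e-3, kon = 5e-4, koffapp = 5e-3, kinactapp = 5e-3),
  case2 = list(E0 = 1e-3, kon = 1e-2, koffapp = 5e-3, kinactapp = 5e-5),
  case3 = list(E0 = 1,    kon = 5e-4, koffapp = 5e-3, kinactapp = 5e-3))

t_dr_fig4 <- 7.1 * 3600

# A random all-unimolecular scheme with <= n_max species and rate constants
# spanning ~6 decades; regenerates until the rate matrix is comfortably
# diagonalizable so the eigen-decomposition oracle is well conditioned.
random_unimolecular_scheme <- function(n_max = 6) {
  repeat {
    n <- sample(2:n_max, 1)
    m <- sample(1:(2 * n), 1)
    sp <- tibble::tibble(name = paste0("S", seq_len(n)),
                         initial = stats::runif(n, 0, 2))
    trs <- lapply(seq_len(m), function(i) {
      pair <- sample(n, 2)
      kin_transition(paste0("t", i),
                     stats::setNames(1, sp$name[pair[1]]),
                     stats::setNames(1, sp$name[pair[2]]),
                     k = 10^stats::runif(1, -3, 3))
    })
    sch <- kin_scheme(sp, trs)
    V <- eigen(linear_oracle(sch)$A)$vectors
    if (kappa(V) < 1e7) return(sch)
  }
}

# A random mass-action scheme (possibly bimolecular) for conservation
# property tests: enzyme-like core E + I <-> C -> P with random rates.
random_two_step_scheme <- function() {
  build_scheme("scheme1",
               E0 = 10^stats::runif(1, -4, 0),
               I0 = 10^stats::runif(1, -2, 1),
               kon = 10^stats::runif(1, -3, -1),
               koffapp = 10^stats::runif(1, -4, -1),
               kinactapp = 10^stats::runif(1, -5, -2))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}
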