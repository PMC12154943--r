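test_that("oracle eigenstructure matches hand-derived cases", {
  ab <- kin_scheme(tibble::tibble(name = c("A", "B"), initial = c(1, 0)),
                   list(kin_transition("t", c(A = 1), c(B = 1), 0.37)))
  ev <- sort(Re(linear_oracle(ab)$eigenvalues))
  expect_equal(ev, c(-0.37, 0))

  # detailed balance: equilibrium ratio equals k_fwd / k_rev
  two <- kin_scheme(tibble::tibble(name = c("A", "B"), initial = c(1, 0)),
                    list(kin_transition("f", c(A = 1), c(B = 1), 0.3),
                         kin_transition("r", c(B = 1), c(A = 1), 0.1)))
  eq <- linear_oracle(two)$trajectory(1e4)
  expect_equal(unname(eq[1, "B"] / eq[1, "A"]), 3, tolerance = 1e-10)

  # pseudo-first-order two-step scheme: slow decay rate from the
  # characteristic polynomial of the non-absorbing block
  a <- 1e-2; b <- 5e-3; cc <- 5e-5
  s5 <- build_scheme("scheme5", E0 = 1, kon_I0 = a, koffapp = b,
                     kinactapp = cc)
  slow <- 0.5 * ((a + b + cc) - sqrt((a + b + cc)^2 - 4 * a * cc))
  ev5 <- sort(-Re(linear_oracle(s5)$eigenvalues))
  expect_equal(ev5[2], slow, tolerance = 1e-12)

  bi <- build_scheme("scheme1", E0 = 1e-3, I0 = 1, kon = 1e-2,
                     koffapp = 1e-2, kinactapp = 1e-4)
  expect_error(linear_oracle(bi), "unimolecular")
})

test_that("ODE trajectories match the eigen-decomposition closed form", {
  set.seed(7)
  rtol <- 1e-8; atol <- 1e-12
  for (i in 1:12) {
    sch <- random_unimolecular_scheme()
    t_end <- 10^stats::runif(1, 1, 4)
    tc <- simulate_scheme(sch, t_end = t_end, rtol = rtol, atol = atol)
    exact <- linear_oracle(sch)$trajectory(tc$time)
    scale <- max(exact)
    expect_lt(max(abs(as.matrix(tc[, -1]) - exact)),
              10 * (rtol * scale + atol))
  }
})

test_that("scheme 5 trajectory matches the oracle at matched tolerance", {
  s5 <- build_scheme("scheme5", E0 = 1, kon_I0 = 1e-2, koffapp = 5e-3,
                     kinactapp = 5e-5)
  tc <- simulate_scheme(s5, t_end = 2e5)
  exact <- linear_oracle(s5)$trajectory(tc$time)
  expect_lt(max(abs(as.matrix(tc[, -1]) - exact)), 10 * 1e-8)
})
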