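test_that("rate_of_change reproduces elementary mass-action rates", {
  ab <- kin_scheme(tibble::tibble(name = c("A", "B"), initial = c(3, 0)),
                   list(kin_transition("t", c(A = 1), c(B = 1), 2)))
  expect_equal(unname(rate_of_change(ab, c(3, 0))), c(-6, 6))

  bi <- build_scheme("scheme1", E0 = 1e-3, I0 = 1, kon = 1e-2,
                     koffapp = 1e-2, kinactapp = 1e-4)
  d <- rate_of_change(bi, c(1e-3, 1, 0, 0))
  expect_equal(unname(d["E"]), -1e-5)
  expect_equal(unname(d["I"]), -1e-5)
  expect_equal(unname(d["E..I"]), 1e-5)

  dimer <- kin_scheme(tibble::tibble(name = c("A", "B"), initial = c(2, 0)),
                      list(kin_transition("dim", c(A = 2), c(B = 1), 0.3)))
  cc <- 1.7
  d2 <- rate_of_change(dimer, c(cc, 0))
  expect_equal(unname(d2), c(-2 * 0.3 * cc^2, 0.3 * cc^2))

  expect_error(rate_of_change(ab, c(1, 2, 3)), "length")
})

test_that("integration matches closed-form decay and starts exactly at C(0)", {
  ab <- kin_scheme(tibble::tibble(name = c("A", "B"), initial = c(1, 0)),
                   list(kin_transition("t", c(A = 1), c(B = 1), 1e-2)))
  tc <- simulate_scheme(ab, t_grid = c(0, 50, 100))
  expect_identical(tc$A[1], 1)
  expect_identical(tc$B[1], 0)
  expect_equal(tc$A[3], exp(-1), tolerance = 1e-7)
  expect_equal(tc$A + tc$B, rep(1, 3), tolerance = 1e-9)

  expect_error(simulate_scheme(ab, t_grid = c(1, 2)), "start at 0")
  expect_error(simulate_scheme(ab, t_grid = c(0, 2, 2)), "increasing")
  expect_error(simulate_scheme(ab), "t_end")
})

test_that("conserved moieties stay constant along random trajectories", {
  set.seed(42)
  for (i in 1:10) {
    sch <- random_two_step_scheme()
    tc <- simulate_scheme(sch, t_end = 1e4)
    mo <- conserved_moieties(sch)
    conc <- as.matrix(tc[, sch$species$name])
    totals <- conc %*% mo
    for (j in seq_len(ncol(totals))) {
      ref <- totals[1, j]
      if (ref > 0)
        expect_lt(max(abs(totals[, j] - ref)) / ref, 10 * 1e-8)
    }
  }
})

test_that("occupancy observables obey their bounds and limits", {
  sch <- build_scheme("scheme3", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                      kinact = 1e-4, pr = 0.5)
  oc <- occupancy(simulate_scheme(sch, t_end = 5e5))
  expect_identical(oc$total_occupancy[1], 0)
  expect_identical(oc$covalent_occupancy[1], 0)
  expect_true(all(oc$covalent_occupancy <= oc$total_occupancy + 1e-9))
  expect_true(all(oc$total_occupancy <= 1 + 1e-9))
  # irreversible covalent step: CO is non-decreasing and absorbs everything
  expect_true(all(diff(oc$covalent_occupancy) >= -1e-9))
  expect_gt(oc$covalent_occupancy[nrow(oc)], 0.999)

  untagged <- kin_scheme(tibble::tibble(name = c("A", "B"),
                                        initial = c(1, 0)),
                         list(kin_transition("t", c(A = 1), c(B = 1), 1)))
  expect_error(occupancy(simulate_scheme(untagged, t_end = 1)),
               "role tag")
})

test_that("steady-state occupancy of the noncovalent scheme increases with pr", {
  p <- fig1_params
  occ_end <- vapply(c(0.1, 0.5, 0.9), function(pr) {
    sch <- build_scheme("scheme4", E0 = p$E0, I0 = p$I0, kon = p$kon,
                        koff = p$koff, kr = pr * 10, knr = (1 - pr) * 10)
    oc <- occupancy(simulate_scheme(sch, t_end = 1e4))
    oc$total_occupancy[nrow(oc)]
  }, 0)
  expect_true(all(diff(occ_end) > 0))
})
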