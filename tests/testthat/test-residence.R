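test_that("mean exit time reduces to 1/koff without a reactive trap", {
  # pr ~ 0: the reactive state is never populated
  sch <- build_scheme("scheme4", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                      kr = 1e-9, knr = 100)
  expect_equal(residence_time(sch), 100, tolerance = 1e-6)
})

test_that("a non-dissociating reactive state extends the residence time", {
  sch <- build_scheme("scheme4", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                      kr = 50, knr = 50)
  expect_equal(residence_time(sch), 200, tolerance = 1e-6)
})

test_that("tau * koff * (1 - pr) = 1 across random rapid-equilibrium draws", {
  set.seed(23)
  for (i in 1:8) {
    koff <- 10^stats::runif(1, -4, -1)
    pr <- stats::runif(1, 0, 0.9)
    total <- 1e4 * koff
    sch <- build_scheme("scheme4", E0 = 1e-3, I0 = 1, kon = 1e-2,
                        koff = koff, kr = pr * total,
                        knr = (1 - pr) * total)
    tau <- residence_time(sch)
    expect_equal(tau * koff * (1 - pr), 1, tolerance = 1e-2)
  }
})

test_that("tau increases with pr at fixed koff", {
  taus <- vapply(c(0, 0.3, 0.6, 0.9), function(pr) {
    sch <- build_scheme("scheme4", E0 = 1e-3, I0 = 1, kon = 1e-2,
                        koff = 1e-2, kr = max(pr, 1e-9) * 100,
                        knr = (1 - pr) * 100)
    residence_time(sch)
  }, 0)
  expect_true(all(diff(taus) > 0))
})

test_that("a bound state with no exit is diagnosed, not integrated forever", {
  sp <- tibble::tibble(name = c("E", "B"), initial = c(1, 0),
                       roles = list("free_enzyme", "noncovalent_complex"))
  trapped <- kin_scheme(sp, list(
    kin_transition("assoc", c(E = 1), c(B = 1), 1e-2)))
  expect_error(residence_time(trapped), "diverges")
})
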