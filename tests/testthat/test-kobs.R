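test_that("fit_kobs recovers the rate of an exact growth factor", {
  t <- seq(0, 5e4, length.out = 60)
  fit <- fit_kobs(data.frame(time = t,
                             covalent_occupancy = 1 - exp(-1e-4 * t)))
  expect_equal(fit$kobs, 1e-4, tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-10)
})

test_that("kobs approaches kinactapp at saturating dose", {
  # kon[I]0 >> koffapp: free enzyme is driven into the complex instantly
  s5 <- build_scheme("scheme5", E0 = 1, kon_I0 = 10, koffapp = 5e-3,
                     kinactapp = 5e-5)
  oc <- occupancy(simulate_scheme(s5, t_end = 1e5))
  fit <- fit_kobs(oc)
  expect_equal(fit$kobs, 5e-5, tolerance = 1e-3)
})

test_that("fitted kobs matches the oracle's slow eigenvalue off saturation", {
  a <- 1e-2 * 0.1  # kon * [I]0 at a tenth of a micromolar
  s5 <- build_scheme("scheme5", E0 = 1, kon_I0 = a, koffapp = 5e-3,
                     kinactapp = 5e-5)
  ev <- sort(-Re(linear_oracle(s5)$eigenvalues))
  slow <- ev[2]
  expect_gt(ev[3] / slow, 50)
  oc <- occupancy(simulate_scheme(s5, t_end = 5 / slow))
  fit <- fit_kobs(oc)
  expect_equal(fit$kobs, slow, tolerance = 1e-2)
})

test_that("a trace that never rises is flagged as ill-conditioned", {
  t <- seq(0, 100, length.out = 20)
  expect_warning(
    fit <- fit_kobs(data.frame(time = t,
                               covalent_occupancy = 1 - exp(-1e-5 * t))),
    "ill-conditioned")
  expect_true(fit$ill_conditioned)
  expect_equal(fit$kobs, 1e-5, tolerance = 1e-3)
})

test_that("the Michaelis-Menten analog self-fit is exact and warns off-regime", {
  kinactapp <- 5e-5; KIapp <- 0.505
  d <- 10^seq(-1, 1, length.out = 8) * KIapp
  fit <- fit_mm_analog(data.frame(dose = d,
                                  kobs = kinactapp * d / (KIapp + d)))
  expect_equal(fit$kinactapp, kinactapp, tolerance = 1e-8)
  expect_equal(fit$KIapp, KIapp, tolerance = 1e-8)
  expect_equal(fit$Effinact, kinactapp / KIapp, tolerance = 1e-8)
  # low-dose linear check: slope ~ Effinact, intercept ~ 0
  expect_equal(unname(fit$linear_check["slope"]), fit$Effinact,
               tolerance = 0.3)
  expect_lt(abs(fit$linear_check[["intercept"]]), 0.1 * kinactapp)

  expect_warning(fit_mm_analog(data.frame(dose = d[1:3],
                                          kobs = kinactapp * d[1:3] /
                                            (KIapp + d[1:3]))),
                 "fewer than 4")
  dlow <- KIapp * 10^seq(-4, -2, length.out = 6)
  expect_warning(fit_mm_analog(data.frame(
    dose = dlow, kobs = kinactapp * dlow / (KIapp + dlow))),
    "slope-only|unidentifiable")
})
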