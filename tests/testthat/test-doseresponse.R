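test_that("eta stays in [-ln 2, 0) with the correct limits", {
  expect_equal(eta_ec50(5e-5, 25560), log((1 + exp(-5e-5 * 25560)) / 2),
               tolerance = 1e-12)
  expect_lt(eta_ec50(1e-12, 1), 0)
  expect_gt(eta_ec50(1e-12, 1), -1e-10)
  expect_equal(eta_ec50(1, 1e6), -log(2), tolerance = 1e-12)
  set.seed(5)
  x <- 10^stats::runif(20, -6, 3)
  e <- eta_ec50(x, 1)
  expect_true(all(e < 0 & e >= -log(2)))
})

test_that("the half-maximum growth-factor identity holds to machine precision", {
  set.seed(9)
  for (i in 1:20) {
    kinactapp <- 10^stats::runif(1, -7, -2)
    t_dr <- 10^stats::runif(1, 2, 6)
    kobs_half <- -eta_ec50(kinactapp, t_dr) / t_dr
    lhs <- -expm1(-kobs_half * t_dr)
    rhs <- 0.5 * -expm1(-kinactapp * t_dr)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("the analytic EC50 approaches Kd as kinactapp vanishes", {
  KIapp <- 0.505
  expect_identical(ec50_analytic(0, KIapp, 25560), KIapp)
  # shrinking kinactapp walks the EC50 towards KIapp (= Kd in the limit)
  ecs <- ec50_analytic(c(1e-4, 1e-5, 1e-6, 1e-7), KIapp, 25560)
  expect_true(all(diff(abs(ecs - KIapp)) < 0))
  expect_equal(ec50_analytic(1e-9, KIapp, 25560), KIapp, tolerance = 1e-4)
  expect_true(all(ecs > 0))
})

test_that("simulated dose-response reaches the analytic amplitude at high dose", {
  cs <- fig4_cases$case2
  dr <- dose_response(kon = cs$kon, koffapp = cs$koffapp,
                      kinactapp = cs$kinactapp, E0 = cs$E0,
                      t_dr = t_dr_fig4, doses = c(0.05, 0.5, 5, 500, 5000))
  expect_equal(dr$amplitude, 1 - exp(-cs$kinactapp * t_dr_fig4),
               tolerance = 1e-12)
  expect_rel_equal(dr$data$co[5], dr$amplitude, 1e-3)
  expect_true(all(diff(dr$data$co) > 0))
})

test_that("Hill fitting recovers exact curves and refuses non-monotone input", {
  d <- 10^seq(-2, 2, length.out = 25)
  y <- 0.72 / (1 + (0.27 / d)^1)
  free_fit <- fit_hill(data.frame(dose = d, co = y))
  expect_equal(free_fit$n, 1, tolerance = 1e-6)
  expect_equal(free_fit$ec50, 0.27, tolerance = 1e-6)
  expect_equal(free_fit$amplitude, 0.72, tolerance = 1e-6)

  fixed_fit <- fit_hill(data.frame(dose = d, co = y), amplitude = 0.72,
                        ec50 = 0.27)
  expect_equal(fixed_fit$n, 1, tolerance = 1e-8)
  expect_true(fixed_fit$amplitude_fixed && fixed_fit$ec50_fixed)

  y2 <- 0.5 / (1 + (1 / d)^1.6)
  steep <- fit_hill(data.frame(dose = d, co = y2))
  expect_equal(steep$n, 1.6, tolerance = 1e-6)

  bad <- y; bad[10] <- bad[14]
  expect_error(fit_hill(data.frame(dose = d, co = bad)), "monotone")
})

test_that("longer stop times wash out the koff dependence of the curve", {
  # when every curve saturates at CO = 1, kinactapp and koff are unresolvable
  t_long <- 71.1 * 3600
  co <- lapply(c(5e-3, 2e-2), function(koffapp) {
    dr <- dose_response(kon = 1e-2, koffapp = koffapp, kinactapp = 5e-5,
                        E0 = 1e-3, t_dr = t_long,
                        doses = 10^seq(0.5, 2, length.out = 6))
    dr$data$co
  })
  expect_lt(max(abs(co[[1]] - co[[2]])), 0.02)
})
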