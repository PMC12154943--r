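make_surface <- function(doses, times, kon = 1e-2, koff = 1e-2,
                         kinact = 1e-4, pr = 0.5, E0 = 1e-3) {
  purrr::map_dfr(doses, function(d) {
    sch <- build_scheme("scheme3", E0 = E0, I0 = d, kon = kon, koff = koff,
                        kinact = kinact, pr = pr)
    tc <- simulate_scheme(sch, t_grid = c(0, times))
    tibble::tibble(dose = d, time = times, co = tc[["E-I"]][-1] / E0)
  })
}

test_that("with pr held fixed, Kd and kinact are recovered from one curve", {
  times <- 10^seq(log10(300), log10(25560), length.out = 12)
  surf <- make_surface(doses = c(0.1, 0.5, 2), times = times)
  fit <- global_fit(surf, free = c("Kd", "kinact"),
                    fixed = list(kon = 1e-2, E0 = 1e-3, pr = 0.5),
                    init = list(Kd = 4, kinact = 4e-4))
  expect_rel_equal(fit$estimates[["Kd"]], 1, 0.02)
  expect_rel_equal(fit$estimates[["kinact"]], 1e-4, 0.02)
  expect_lt(fit$deviance, 1e-10)
})

test_that("strong pr-kinact covariance is surfaced as a diagnostic", {
  times <- 10^seq(log10(300), log10(25560), length.out = 10)
  surf <- make_surface(doses = c(0.05, 0.5, 5), times = times)
  fit <- global_fit(surf, free = c("Kd", "pr", "kinact"),
                    fixed = list(kon = 1e-2, E0 = 1e-3))
  expect_true(is.finite(fit$pr_kinact_correlation))
  expect_gt(abs(fit$pr_kinact_correlation), 0.5)
})

test_that("structurally unidentifiable or malformed requests are refused", {
  surf <- tibble::tibble(dose = rep(c(0.1, 1), each = 5),
                         time = rep(1:5 * 1e3, 2), co = runif(10))
  expect_error(global_fit(surf, free = c("kr", "knr"),
                          fixed = list(kon = 1e-2, E0 = 1e-3)),
               "kr and knr")
  expect_error(global_fit(surf, free = c("Kd", "koff"),
                          fixed = list(kon = 1e-2, E0 = 1e-3)),
               "redundant")
  expect_error(global_fit(surf, free = "Kd",
                          fixed = list(kon = 1e-2, E0 = 1e-3)),
               "missing fixed parameter")
  expect_error(global_fit(surf, free = "Kd", fixed = list(kon = 1e-2)),
               "E0")
  expect_error(global_fit(dplyr::rename(surf, conc = "co"), free = "Kd",
                          fixed = list(kon = 1e-2, E0 = 1e-3)),
               "columns")
})
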