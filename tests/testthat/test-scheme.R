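test_that("stoichiometry matrices encode sources, targets and their difference", {
  sch <- build_scheme("scheme2", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                      kr = 5, knr = 5, kinact = 1e-4)
  expect_identical(colnames(sch$N), c("E", "I", "E..I", "E.I", "E-I"))
  expect_identical(rownames(sch$N),
                   c("assoc", "dissoc", "arm", "disarm", "inact"))
  expect_identical(unname(sch$N["assoc", ]), c(-1L, -1L, 1L, 0L, 0L))
  expect_identical(unname(sch$N["inact", ]), c(0L, 0L, 0L, -1L, 1L))
  expect_identical(sch$N, sch$N_tgt - sch$N_src)

  ab <- kin_scheme(tibble::tibble(name = c("A", "B"), initial = c(1, 0)),
                   list(kin_transition("t", c(A = 1), c(B = 1), 1)))
  expect_identical(unname(ab$N), matrix(c(-1L, 1L), 1))

  dimer <- kin_scheme(tibble::tibble(name = c("A", "B"), initial = c(1, 0)),
                      list(kin_transition("dim", c(A = 2), c(B = 1), 1)))
  expect_identical(unname(dimer$N_src), matrix(c(2L, 0L), 1))
  expect_identical(unname(dimer$N), matrix(c(-2L, 1L), 1))
})

test_that("scheme definition errors name the offending record", {
  sp <- tibble::tibble(name = c("A", "B"), initial = c(1, 0))
  expect_error(
    kin_scheme(sp, list(kin_transition("bad", c(A = 1), c(C = 1), 1))),
    "bad.*unknown species: C")
  expect_error(
    kin_scheme(tibble::tibble(name = c("A", "A"), initial = c(1, 0)),
               list(kin_transition("t", c(A = 1), c(A = 1), 1))),
    "duplicate species")
  expect_error(kin_transition("t", c(A = 0.5), c(B = 1), 1),
               "positive integers")
  expect_error(kin_transition("t", c(A = 1), c(B = 1), -1), "positive")
  expect_error(kin_transition("t", c(A = 1), c(B = 1), 0), "positive")
  expect_error(
    kin_scheme(tibble::tibble(name = "A", initial = -1),
               list(kin_transition("t", c(A = 1), c(A = 1), 1))),
    ">= 0")
  expect_error(
    kin_scheme(tibble::tibble(name = "A", initial = 1, roles = "enzyme"),
               list(kin_transition("t", c(A = 1), c(A = 1), 1))),
    "unknown species role")
})

test_that("reordering species permutes matrix columns identically", {
  set.seed(11)
  sch <- build_scheme("scheme2", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                      kr = 5, knr = 5, kinact = 1e-4)
  for (i in 1:5) {
    perm <- sample(nrow(sch$species))
    trs <- lapply(seq_len(nrow(sch$transitions)), function(j)
      kin_transition(sch$transitions$name[j], sch$transitions$from[[j]],
                     sch$transitions$to[[j]], sch$transitions$k[j]))
    sch_p <- kin_scheme(sch$species[perm, ], trs)
    expect_identical(sch_p$N, sch$N[, perm])
    expect_identical(sch_p$N_src, sch$N_src[, perm])
    expect_identical(sch_p$N_tgt, sch$N_tgt[, perm])
  }
})

test_that("conserved moieties are non-negative and annihilated by N", {
  for (nm in c("scheme2", "scheme4")) {
    sch <- if (nm == "scheme2")
      build_scheme(nm, E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2, kr = 5,
                   knr = 5, kinact = 1e-4)
    else
      build_scheme(nm, E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2, kr = 5,
                   knr = 5)
    mo <- conserved_moieties(sch)
    expect_identical(ncol(mo), 2L)  # total enzyme and total inhibitor
    expect_true(all(mo >= 0))
    expect_true(all(sch$N %*% mo == 0))
    # the enzyme and inhibitor totals lie in the span of the reported basis
    enzyme <- as.integer(sch$species$name != "I")
    inhibitor <- as.integer(sch$species$name != "E")
    for (v in list(enzyme, inhibitor))
      expect_equal(qr(cbind(mo, v))$rank, 2L)
  }
})

test_that("builders map pr onto effective rates and drop zero-rate steps", {
  s3 <- build_scheme("scheme3", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                     kinact = 1e-4, pr = 0.5)
  expect_equal(unname(s3$k["dissoc"]), 5e-3)
  expect_equal(unname(s3$k["inact"]), 5e-5)

  s3_pr1 <- build_scheme("scheme3", E0 = 1e-3, I0 = 1, kon = 1e-2,
                         koff = 1e-2, kinact = 1e-4, pr = 1)
  expect_false("dissoc" %in% s3_pr1$transitions$name)
  expect_equal(unname(s3_pr1$k["inact"]), 1e-4)

  s4 <- build_scheme("scheme4", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
                     kr = 5, knr = 5)
  expect_false(any(vapply(s4$species$roles, function(r)
    "covalent_complex" %in% r, TRUE)))
  expect_identical(nrow(s4$transitions), 4L)

  expect_error(build_scheme("scheme3", E0 = 1, I0 = 1, kon = 1e-2,
                            koff = 1e-2, kinact = 1e-4),
               "requires parameter.*pr")
  expect_error(build_scheme("scheme3", E0 = 1, I0 = 1, kon = 1e-2,
                            koff = 1e-2, kinact = 1e-4, pr = 1.5),
               "pr must lie")
})
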