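test_that("scheme validation enforces the structural invariants", {
  expect_s3_class(two_state_scheme(), "kinetic_scheme")
  # FRET outside [0, 1]
  expect_error(kinetic_scheme(c("unbound", "b"), c(0, 1.2), c(1, 2),
                              matrix(0, 2, 2)), "FRET")
  # negative rate
  expect_error(kinetic_scheme(c("unbound", "b"), c(0, 0.5), c(1, 2),
                              matrix(c(0, -1, 1, 0), 2, 2)), "nonnegative")
  # unbound anchoring
  expect_error(kinetic_scheme(c("u", "b"), c(0, 0.5), c(1, 2),
                              matrix(0, 2, 2)), "unbound")
  expect_error(kinetic_scheme(c("unbound", "b"), c(0.1, 0.5), c(1, 2),
                              matrix(0, 2, 2)), "FRET 0")
  expect_error(kinetic_scheme(c("unbound", "b"), c(0, 0.5), c(0.9, 2),
                              matrix(0, 2, 2)), "PIFE 1")
  # unknown initial state
  expect_error(kinetic_scheme(c("unbound", "b"), c(0, 0.5), c(1, 2),
                              matrix(0, 2, 2), initial = "c"), "initial")
})

test_that("an absorbing initial state yields one full-length segment", {
  sc <- kinetic_scheme("unbound", 0, 1, matrix(0, 1, 1))
  p <- simulate_path(sc, 10, seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$entry, 0)
  expect_equal(p$exit, 10)
})

test_that("first-dwell mean matches the analytic exponential mean", {
  sc <- kinetic_scheme(c("unbound", "b"), c(0, 0.5), c(1, 2),
                       matrix(c(0, 2.0, 0, 0), 2, 2, byrow = TRUE))
  set.seed(42)
  first <- vapply(sample.int(1e6, 1e4), function(s) {
    p <- simulate_path(sc, 1e6, seed = s)
    p$exit[1] - p$entry[1]
  }, numeric(1))
  expect_equal(mean(first), 0.50, tolerance = 0.02)
})

test_that("exo dwell times are exponential with the exo exit rate", {
  # intermediate <-> exo exchange at the measured shuttling rates; exo has
  # a single exit, so its dwells are Exp(4.3)
  sc <- make_preset("aaf_n1", association_rate = 5)
  p <- simulate_path(sc, 4000, seed = 7)
  d <- p$exit - p$entry
  interior <- seq_len(nrow(p)) > 1 & seq_len(nrow(p)) < nrow(p)
  exo <- d[p$state == "exo" & interior]
  expect_gt(length(exo), 5000)
  expect_equal(mean(exo), 1 / 4.3, tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(exo, stats::pexp, 4.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("jump destinations follow the branching ratios", {
  sc <- make_preset("aaf_n1", association_rate = 5)
  p <- simulate_path(sc, 4500, seed = 11)
  from_i <- which(p$state == "intermediate")
  from_i <- from_i[from_i < nrow(p)]
  dest <- p$state[from_i + 1]
  n <- length(dest)
  expect_gt(n, 5000)
  p_exo <- 2.1 / (2.1 + 0.07)
  se <- sqrt(p_exo * (1 - p_exo) / n)
  expect_lt(abs(mean(dest == "exo") - p_exo), 3 * se)
})

test_that("segments are contiguous, positive, and sum exactly to duration", {
  for (s in c(1, 2, 3)) {
    sc <- make_preset("aaf_n1")
    p <- simulate_path(sc, 57.3, seed = s)
    expect_equal(p$entry[1], 0)
    expect_equal(p$exit[nrow(p)], 57.3)
    expect_equal(sum(p$exit - p$entry), 57.3)
    expect_true(all(p$exit > p$entry))
    if (nrow(p) > 1)
      expect_equal(p$entry[-1], p$exit[-nrow(p)])
  }
})

test_that("identical seed and scheme give a bitwise-identical path", {
  sc <- make_preset("unmodified_templating")
  expect_identical(simulate_path(sc, 200, seed = 99),
                   simulate_path(sc, 200, seed = 99))
})

test_that("presets carry the measured emission levels and rates", {
  u <- make_preset("unmodified_templating")
  expect_equal(unname(u$fret[["pol"]]), 0.59)
  expect_equal(unname(u$pife[["pol"]]), 2.0)
  expect_equal(unname(u$rates["pol", "unbound"]), 0.40)

  expect_equal(unname(make_preset("af_templating")$rates["pol", "unbound"]),
               0.10)
  expect_equal(unname(make_preset("aaf_templating")$rates["pol", "unbound"]),
               0.07)

  a <- make_preset("aaf_n1")
  expect_equal(unname(a$fret), c(0, 0.50, 0.63))
  expect_equal(unname(a$pife), c(1, 1.9, 1.9))
  expect_equal(unname(a$rates["intermediate", "exo"]), 2.1)
  expect_equal(unname(a$rates["exo", "intermediate"]), 4.3)
  expect_equal(unname(a$rates["exo", "unbound"]), 0)

  expect_equal(unname(make_preset("af_ternary")$rates["pol", "unbound"]), 2.5)
  expect_equal(unname(make_preset("double_mismatch")$fret[["exo"]]), 0.60)
  expect_equal(unname(make_preset("af_n1")$fret[["intermediate"]]), 0.51)

  expect_error(make_preset("nope"), "aaf_n1")  # catalog listed in the error
})

test_that("direct-dissociation augmentation hits the target split", {
  sc <- make_preset("aaf_n1")
  expect_equal(unname(add_direct_dissociation(sc, 0)$rates["exo", "unbound"]),
               0)
  # f = 1 feasible only when the intermediate cannot dissociate
  sc_no_int_off <- sc
  sc_no_int_off$rates["intermediate", "unbound"] <- 0
  expect_gt(add_direct_dissociation(sc_no_int_off, 1)$rates["exo", "unbound"],
            0)
  expect_error(add_direct_dissociation(sc, 1), "infeasible")

  # Monte-Carlo check of the closed form at f = 0.6: terminal bound state
  # of each dissociation event
  sc6 <- add_direct_dissociation(sc, 0.6)
  term <- character(0)
  for (s in 1:6) {
    p <- simulate_path(sc6, 20000, seed = 100 + s)
    iu <- which(p$state == "unbound")
    iu <- iu[iu > 1]
    term <- c(term, p$state[iu - 1L])
  }
  n <- length(term)
  expect_gt(n, 8000)
  expect_equal(mean(term == "exo"), 0.60, tolerance = 0.035)
})

test_that("schemes round-trip exactly through YAML", {
  sc <- add_direct_dissociation(make_preset("aaf_n1"), 0.6)
  f <- tempfile(fileext = ".yaml")
  write_scheme(sc, f)
  back <- read_scheme(f)
  expect_identical(back$states, sc$states)
  expect_identical(back$rates, sc$rates)
  expect_identical(back$fret, sc$fret)
  expect_identical(back$pife, sc$pife)
  unlink(f)
})
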