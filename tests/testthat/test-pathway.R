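test_that("pause definitions on hand-built paths", {
  # one bout: intermediate 1.5 s before exo, 0.8 s after the last exo visit
  p <- manual_path(c("unbound", "intermediate", "exo", "intermediate",
                     "unbound"),
                   c(2, 1.5, 3, 0.8, 2))
  expect_equal(measure_association_pauses(p)$durations, 1.5)
  expect_equal(measure_dissociation_pauses(p)$durations, 0.8)
  # direct entry and exit: zero pauses
  pd <- manual_path(c("unbound", "exo", "unbound"), c(1, 2, 1))
  expect_equal(measure_association_pauses(pd)$durations, 0)
  expect_equal(measure_dissociation_pauses(pd)$durations, 0)
  # repeated shuttling: first-I before first exo; last-I after last exo
  pm <- manual_path(c("unbound", "intermediate", "exo", "intermediate",
                      "exo", "intermediate", "unbound"),
                    c(1, 0.4, 1, 9, 1, 0.3, 1))
  expect_equal(measure_association_pauses(pm)$durations, 0.4)
  expect_equal(measure_dissociation_pauses(pm)$durations, 0.3)
  # bouts that never reach exo are not events
  pn <- manual_path(c("unbound", "intermediate", "unbound"), c(1, 5, 1))
  expect_error(measure_association_pauses(pn), "no association")
  # bout truncated at trace start: association skipped, dissociation kept
  pt <- manual_path(c("exo", "intermediate", "unbound"), c(2, 0.7, 3))
  expect_error(measure_association_pauses(pt), "no association")
  expect_equal(measure_dissociation_pauses(pt)$durations, 0.7)
})

test_that("ground-truth pauses match the competing-exponential kinetics", {
  sc <- make_preset("aaf_n1")
  pa <- simulate_pause_distribution(sc, 550, duration = 40,
                                    event_class = "association",
                                    mode = "ground_truth", seed = 8)
  # obligatory intermediate: every association pause is strictly positive
  expect_true(all(pa$durations > 0))
  # conditioned on reaching exo, the intermediate dwell is Exp(2.1 + 0.07)
  expect_equal(mean(pa$durations), 1 / (2.1 + 0.07), tolerance = 0.1)
  expect_gt(pa$n_events, 1000)
})

test_that("60%-direct scheme gives the expected zero-length pause share", {
  sc6 <- add_direct_dissociation(make_preset("aaf_n1"), 0.6)
  pd <- simulate_pause_distribution(sc6, 500, duration = 40,
                                    event_class = "dissociation",
                                    mode = "ground_truth", seed = 9)
  expect_gt(pd$n_events, 1500)
  # the pause distribution conditions on bouts that reach exo, so the
  # zero-pause share is f / P(reach exo) = f (a + c) / a, slightly above
  # the unconditional 60% terminal-exo fraction (which the kinetics tests
  # verify directly)
  a <- 2.1; cc <- 0.07
  expect_equal(zero_pause_fraction(pd), 0.60 * (a + cc) / a,
               tolerance = 0.06)
})

test_that("direct-binding-only data shows mostly first-bin pauses", {
  # association goes straight to exo; intermediate exists but is never
  # visited, so any nonzero measured pause is a frame-integration artifact
  st <- c("unbound", "intermediate", "exo")
  r <- matrix(0, 3, 3, dimnames = list(st, st))
  r["unbound", "exo"] <- 0.5
  r["exo", "unbound"] <- 0.4
  sc <- kinetic_scheme(st, c(0, 0.50, 0.63), c(1, 1.9, 1.9), r)
  pa <- simulate_pause_distribution(sc, 80, duration = 40,
                                    event_class = "association",
                                    mode = "pipeline", seed = 10)
  expect_gte(zero_pause_fraction(pa, tol = pa$bin_width - 1e-9), 0.90)
})

test_that("apparent direct transitions shrink with shorter frames", {
  sc <- make_preset("aaf_n1")
  frac <- vapply(c(0.1, 0.05, 0.025), function(ft) {
    pl <- pipeline_idealize(sc, 60, duration = 40, frame_time = ft,
                            seed = 11)
    td <- transition_density(pl$idealized)
    transition_class_fraction(td, c("unbound", "exo"), c("exo", "unbound"))
  }, numeric(1))
  expect_gt(frac[1], 0)
  expect_true(all(diff(frac) < 0))
})

test_that("the direct fraction is recovered by grid search (exact paths)", {
  sc <- make_preset("aaf_n1")
  sc6 <- add_direct_dissociation(sc, 0.6)
  obs <- simulate_pause_distribution(sc6, 800, duration = 40,
                                     mode = "ground_truth", seed = 12)
  fit <- fit_direct_fraction(obs, sc, grid = seq(0, 1, 0.1), n_traces = 400,
                             duration = 40, mode = "ground_truth", seed = 13)
  expect_lte(abs(fit$best_fraction - 0.6), 0.1)
  # replicate seeds agree within one grid step
  fit2 <- fit_direct_fraction(obs, sc, grid = seq(0, 1, 0.1), n_traces = 400,
                              duration = 40, mode = "ground_truth", seed = 14)
  expect_lte(abs(fit2$best_fraction - fit$best_fraction), 0.1)
  # boundary recovery at zero direct dissociation
  obs0 <- simulate_pause_distribution(sc, 800, duration = 40,
                                      mode = "ground_truth", seed = 15)
  fit0 <- fit_direct_fraction(obs0, sc, grid = seq(0, 1, 0.1),
                              n_traces = 400, duration = 40,
                              mode = "ground_truth", seed = 16)
  expect_equal(fit0$best_fraction, 0)
  # infeasible grid points (f near 1 with nonzero intermediate off-rate)
  # carry NA objectives rather than poisoning the argmin
  expect_true(is.na(fit$objective[fit$grid == 1]))
})
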