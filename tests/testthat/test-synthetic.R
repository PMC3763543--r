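test_that("frame integration is the time-weighted mean of state levels", {
  sc <- make_preset("aaf_n1")
  # constant exo path: every frame at 0.63 / PIFE 1.9
  p <- manual_path("exo", 1.0)
  id <- integrate_frames(p, sc, frame_time = 0.05)
  expect_equal(id$n_frames, 20L)
  expect_equal(id$fret, rep(0.63, 20))
  expect_equal(id$pife, rep(1.9, 20))
  # a frame split 50/50 between unbound (0) and intermediate (0.50)
  p2 <- manual_path(c("unbound", "intermediate"), c(0.025, 0.075))
  id2 <- integrate_frames(p2, sc, frame_time = 0.05)
  expect_equal(id2$fret[1], 0.25)
  expect_equal(id2$fret[2], 0.50)
  # partial final frame discarded
  p3 <- manual_path("exo", 0.12)
  expect_equal(integrate_frames(p3, sc, 0.05)$n_frames, 2L)
  expect_error(integrate_frames(manual_path("exo", 0.01), sc, 0.05), "frame")
})

test_that("fast pol/exo shuttling integrates to the average PIFE ~1.5", {
  sc <- kinetic_scheme(c("unbound", "pol", "exo"),
                       fret = c(0, 0.4, 0.63), pife = c(1, 1.2, 1.8),
                       rates = matrix(c(0, 1e6, 0,
                                        0, 0, 400,
                                        0, 400, 0), 3, 3, byrow = TRUE),
                       initial = "pol")
  # deterministic alternation: every frame is exactly 50/50 pol/exo
  p <- manual_path(rep(c("pol", "exo"), 200), rep(0.005, 400))
  id <- integrate_frames(p, sc, frame_time = 0.05)
  expect_equal(id$pife, rep(1.5, id$n_frames))
  # stochastic shuttling at rates >> 1/frame_time: frames concentrate at 1.5
  ps <- simulate_path(sc, 100, seed = 1)
  ids <- integrate_frames(ps, sc, frame_time = 0.05)
  expect_equal(mean(ids$pife), 1.5, tolerance = 0.01)
  expect_lt(stats::sd(ids$pife), 0.1)
})

test_that("FRET emission reproduces the expected apparent-FRET noise", {
  # noiseless: exact intensities
  tr0 <- emit_fret_trace(rep(0.5, 10),
                         emission_model(total_intensity = 1000, noise_sd = 0),
                         seed = 1)
  expect_equal(tr0$donor, rep(500, 10))
  expect_equal(tr0$acceptor, rep(500, 10))
  # determinism
  m <- emission_model(noise_sd = 30)
  expect_identical(emit_fret_trace(rep(0.63, 100), m, seed = 7),
                   emit_fret_trace(rep(0.63, 100), m, seed = 7))
  # propagated noise: sd of IA/(IA+ID) = sigma * sqrt(f^2 + (1-f)^2) / I
  tr <- emit_fret_trace(rep(0.63, 10000), m, seed = 2)
  f <- trace_fret(tr)
  expect_equal(mean(f), 0.63, tolerance = 0.005)
  sd_pred <- 30 * sqrt(0.63^2 + 0.37^2) / 1000
  expect_equal(stats::sd(f), sd_pred, tolerance = 0.05)
  expect_lt(abs(stats::sd(f) - 0.02), 0.005)  # the stated +/- 0.02 error
})

test_that("PIFE emission gives the stated +/- 0.1 error and bleaches", {
  tr0 <- emit_pife_trace(rep(1, 20), emission_model(1000, noise_sd = 0),
                         seed = 1)
  expect_equal(tr0$intensity, rep(1000, 20))
  tr <- emit_pife_trace(rep(2.0, 10000), emission_model(1000, noise_sd = 100),
                        seed = 3)
  z <- tr$intensity / tr$meta$baseline
  expect_equal(mean(z), 2.0, tolerance = 0.01)
  expect_equal(stats::sd(z), 0.1, tolerance = 0.05)
  # photobleach: trace drops to background afterwards
  mb <- emission_model(1000, noise_sd = 20, donor_bleach_rate = 0.02)
  trb <- emit_pife_trace(rep(2.0, 3000), mb, seed = 5)
  tb <- trb$meta$donor_bleach
  expect_true(is.finite(tb) && tb < 150)
  after <- trb$intensity[trb$time >= tb + 0.05]
  expect_lt(mean(after), 100)  # noise-only background, far below 2000
})

test_that("moving average is exact on closed forms and shrinks at edges", {
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- moving_average(imp, 5)
  expect_equal(out[9:13], rep(0.2, 5))
  expect_equal(sum(out > 0), 5L)
  expect_equal(length(out), length(imp))
  expect_error(moving_average(1:10, 4), "odd")
  expect_error(moving_average(1:3, 5), "length")
  # variance of the mean: interior sd shrinks by sqrt(window)
  set.seed(1)
  x <- rnorm(10000)
  sm <- moving_average(x, 5)[3:9998]
  expect_equal(stats::sd(sm), 1 / sqrt(5), tolerance = 0.05)
})

test_that("frame occupancy conserves time", {
  p <- simulate_path(make_preset("aaf_n1"), 50, seed = 3)
  occ <- frame_occupancy(p, 0.05, states = c("unbound", "intermediate", "exo"))
  expect_equal(rowSums(occ), rep(1, nrow(occ)))
  expect_equal(sum(occ) * 0.05, nrow(occ) * 0.05)
})

test_that("noiseless slow-kinetics traces recover the exact segment count", {
  sc <- two_state_scheme(kon = 0.05, koff = 0.05)
  for (s in 1:3) {
    p <- simulate_path(sc, 400, seed = 20 + s)
    id <- integrate_frames(p, sc, 0.05)
    tr <- emit_fret_trace(id$fret, emission_model(noise_sd = 0), seed = 1)
    f <- trace_fret(tr)
    seg_obs <- length(rle(f > 0.29)$lengths)
    # discretization can split a segment only if a dwell < 1 frame occurred
    expect_equal(seg_obs, nrow(p))
  }
})

test_that("generate_dataset is reproducible and keeps ground truth", {
  ds <- generate_dataset("aaf_n1", 120, duration = 10, seed = 5)
  expect_length(ds$traces, 120)
  expect_length(ds$paths, 120)
  expect_equal(ds$manifest$preset, "aaf_n1")
  expect_gte(sum(vapply(ds$traces, function(t) t$n_frames, numeric(1)) >=
                   100), 100)  # >=100 usable for histogramming
  ds2 <- generate_dataset("aaf_n1", 120, duration = 10, seed = 5)
  expect_identical(ds, ds2)
  # single one-frame trace
  d1 <- generate_dataset("aaf_n1", 1, duration = 0.05, seed = 1)
  expect_equal(d1$traces[[1]]$n_frames, 1L)
})
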