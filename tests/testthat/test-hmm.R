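test_that("noiseless three-level traces are recovered exactly", {
  lv <- c(0, 0.50, 0.63)
  tr <- lapply(1:6, function(i)
    rep(lv[c(1, 2, 3, 2, 1, 2, 3, 2)], each = 25))
  fit <- fit_hmm(tr, n_states = 3, seed = 1)
  expect_equal(unname(fit$means), lv, tolerance = 1e-6)
  # transitions only between adjacent levels were observed
  A <- fit$transition_matrix
  expect_equal(A["unbound", "exo"], 0)
  expect_equal(A["exo", "unbound"], 0)
  expect_true(all(abs(rowSums(A) - 1) < 1e-9))
})

test_that("Baum-Welch log-likelihood is non-decreasing", {
  ds <- generate_dataset("aaf_n1", 15, duration = 30, seed = 2)
  fit <- fit_hmm(ds$traces, 3, init = list(means = c(0, 0.5, 0.63)),
                 seed = 1, restarts = 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))
  expect_true(is.finite(fit$loglik))
})

test_that("Viterbi idealization is accurate on slow-kinetics data", {
  sc <- make_preset("aaf_n1")
  sc$rates["intermediate", "exo"] <- 0.2
  sc$rates["exo", "intermediate"] <- 0.4
  sc$rates["intermediate", "unbound"] <- 0.05
  ds <- generate_dataset(sc, 15, duration = 100, seed = 3)
  fit <- fit_hmm(ds$traces, 3, init = list(means = c(0, 0.5, 0.63)),
                 seed = 1, restarts = 1)
  acc <- vapply(seq_along(ds$traces), function(i) {
    ip <- viterbi(fit, ds$traces[[i]])
    occ <- frame_occupancy(ds$paths[[i]], 0.05,
                           states = c("unbound", "intermediate", "exo"))
    truth <- max.col(occ)
    mean(ip$frames == truth[seq_along(ip$frames)])
  }, numeric(1))
  expect_gte(mean(acc), 0.99)
  # constant trace idealizes to a single segment (uniform start so the
  # decoded path is not forced to walk up from the unbound state)
  fit_u <- fit
  fit_u$initial_probs[] <- 1 / 3
  ip1 <- viterbi(fit_u, rep(0.63, 100))
  expect_equal(nrow(ip1$segments), 1L)
  expect_equal(ip1$segments$state, "exo")
})

test_that("Viterbi path scores at least as high as the ground truth", {
  sc <- make_preset("aaf_n1")
  ds <- generate_dataset(sc, 8, duration = 30, seed = 4)
  fit <- fit_hmm(ds$traces, 3, init = list(means = c(0, 0.5, 0.63)),
                 seed = 1, restarts = 1)
  for (i in 1:4) {
    obs <- trace_fret(ds$traces[[i]])
    ip <- viterbi(fit, ds$traces[[i]])
    occ <- frame_occupancy(ds$paths[[i]], 0.05,
                           states = c("unbound", "intermediate", "exo"))
    truth <- max.col(occ)[seq_along(obs)]
    expect_gte(hmm_path_loglik(fit, obs, ip$frames),
               hmm_path_loglik(fit, obs, truth))
  }
})

test_that("over-specified fits expose a degenerate extra state", {
  ds <- generate_dataset(two_state_scheme(kon = 0.5, koff = 0.4), 20,
                         duration = 60, seed = 5)
  fit <- fit_hmm(ds$traces, 3, seed = 2, restarts = 2, max_iter = 200)
  frames <- unlist(lapply(ds$traces, function(t)
    viterbi(fit, t)$frames))
  # the surplus state either stays near-empty (it typically collects the
  # few frame-integration boundary frames), or collapses onto a neighbour
  occ <- tabulate(frames, 3) / length(frames)
  merged <- min(diff(sort(unname(fit$means)))) < 0.02
  expect_true(min(occ) < 0.03 || merged)
})

test_that("naive rate arithmetic: transitions over occupied time", {
  # 21 I->X transitions over exactly 10 s in I gives 2.1 s^-1
  sn <- c("unbound", "intermediate", "exo")
  frames <- c(rep(rep(c(2L, 3L), times = c(9, 2)), 20),
              rep(c(2L, 3L), times = c(20, 2)))
  obs <- c(0, 0.5, 0.63)[frames]
  ip <- manual_ipath(frames, obs, sn)
  rm_ <- rates_from_idealization(ip, method = "naive", min_frames = 1)
  expect_equal(sum(ip$segments$duration_s[ip$segments$state ==
                                            "intermediate"]), 10)
  expect_equal(rm_$rates["intermediate", "exo"], 2.1)
  # absorbing state: no outgoing transitions, zero rates
  ip2 <- manual_ipath(rep(3L, 50), rep(0.63, 50), sn)
  rm2 <- rates_from_idealization(ip2, method = "naive")
  expect_true(all(rm2$rates == 0))
})

test_that("transition density counts pooled segment boundaries", {
  sn <- c("unbound", "bound")
  frames <- inverse.rle(list(values = rep(c(1L, 2L), 20),
                             lengths = rep(5L, 40)))
  ip <- manual_ipath(frames, c(0, 0.6)[frames], sn)
  td <- transition_density(ip, bins = 10)
  expect_equal(td$total, 39L)
  expect_equal(td$class_counts["unbound", "bound"], 20)
  expect_equal(td$class_counts["bound", "unbound"], 19)
  expect_equal(sum(td$counts), 39)
  expect_error(transition_density(manual_ipath(rep(1L, 10), rep(0, 10), sn)),
               "no transitions")
})

test_that("stationary chains have detailed-balance class counts", {
  # ground-truth discretization of a long reversible trajectory
  sc <- make_preset("aaf_n1", association_rate = 1)
  p <- simulate_path(sc, 2000, seed = 6)
  occ <- frame_occupancy(p, 0.05, states = sc$states)
  frames <- max.col(occ)
  ip <- manual_ipath(frames, unname(sc$fret)[frames], sc$states)
  td <- transition_density(ip)
  cc <- td$class_counts
  for (pair in list(c("unbound", "intermediate"), c("intermediate", "exo"))) {
    nij <- cc[pair[1], pair[2]]; nji <- cc[pair[2], pair[1]]
    expect_lt(abs(nij - nji), 3 * sqrt(nij + nji) + 1)
  }
})

test_that("transition-matrix and dwell-based rates agree as a diagnostic", {
  ds <- generate_dataset("aaf_n1", 40, duration = 60, seed = 7)
  fit <- fit_hmm(ds$traces, 3, init = list(means = c(0, 0.5, 0.63)),
                 seed = 1, restarts = 1, max_iter = 100)
  ips <- lapply(ds$traces, function(t) viterbi(fit, t))
  k_dwell <- rates_from_idealization(ips)$rates
  k_A <- rates_from_transition_matrix(fit)
  for (pair in list(c("intermediate", "exo"), c("exo", "intermediate"))) {
    a <- k_dwell[pair[1], pair[2]]; b <- k_A[pair[1], pair[2]]
    expect_gt(a, 0); expect_gt(b, 0)
    expect_lt(abs(a - b) / a, 0.35)
  }
})
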