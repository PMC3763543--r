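#' @useDynLib polshuttle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.default_state_names <- function(k) {
  if (k == 2) c("unbound", "bound")
  else if (k == 3) c("unbound", "intermediate", "exo")
  else paste0("state", seq_len(k))
}

.traces_to_obs <- function(traces) {
  if (is.numeric(traces)) traces <- list(traces)
  lapply(traces, function(tr) {
    v <- if (inherits(tr, "frame_trace")) trace_fret(tr) else as.numeric(tr)
    v[is.finite(v)]
  })
}

#' Data-driven emission initialization for the FRET HMM
#'
#' Estimates initial emission parameters from the pooled frames without
#' ground-truth knowledge. The unbound (zero-FRET) population is not
#' Gaussian — intensity flooring at zero skews the apparent FRET of
#' unbound frames — so a plain mixture fit over all frames tends to spend
#' two components on the zero peak and merge the close bound populations.
#' Instead, frames below `bound_threshold` provide the unbound mean/sd
#' directly, and a Gaussian mixture with `n_states - 1` components is fit
#' to the bound frames only.
#'
#' @param traces List of FRET traces (`frame_trace` or numeric).
#' @param n_states Total number of states including unbound.
#' @param bound_threshold Apparent FRET separating unbound from bound
#'   frames (default 0.25, the midpoint between 0 and the lowest bound
#'   level seen in this system).
#' @param max_frames Subsample size for the mixture fit.
#' @param seed Integer seed.
#' @return List with `means` and `sds`, ordered by mean; suitable as the
#'   `init` argument of [fit_hmm()].
#' @export
hmm_init_from_traces <- function(traces, n_states = 3,
                                 bound_threshold = 0.25,
                                 max_frames = 40000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pooled <- unlist(.traces_to_obs(traces), use.names = FALSE)
  lo <- pooled[pooled < bound_threshold]
  hi <- pooled[pooled >= bound_threshold]
  if (length(lo) < 10 || length(hi) < 50 * (n_states - 1))
    stop("too few frames on one side of bound_threshold = ",
         bound_threshold)
  if (length(hi) > max_frames) hi <- sample(hi, max_frames)
  mix <- fit_population_mixture(hi, n_states - 1, seed = NULL)
  list(means = c(mean(lo), mix$means),
       sds = c(max(stats::sd(lo), 1e-3), mix$sds))
}

#' Fit a Gaussian-emission hidden Markov model to FRET traces
#'
#' Baum-Welch estimation of a discrete-state HMM with 1-D Gaussian
#' emissions shared across all traces. Each hidden state corresponds to a
#' binding orientation (unbound DNA at 0 FRET, intermediate site ~0.50,
#' exo site ~0.63); the per-frame transition matrix encodes the exchange
#' kinetics at the camera frame time. The per-iteration log-likelihood is
#' retained and asserted non-decreasing. States are relabeled in order of
#' increasing emission mean, so state 1 is always the unbound (lowest
#' FRET) state.
#'
#' @param traces List of FRET-channel `frame_trace` objects or numeric
#'   FRET sequences (non-finite frames are dropped).
#' @param n_states Number of hidden states (>= 2).
#' @param init Optional initialization: a [fit_population_mixture()]
#'   result, or a list with `means` (and optionally `sds`). Default:
#'   k-means on the pooled frames.
#' @param seed Integer seed (controls restart perturbations).
#' @param max_iter Maximum Baum-Welch iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param restarts Number of initializations; the first uses `init`
#'   verbatim, the others perturb the emission means.
#' @param state_names Optional state labels, lowest-mean first.
#' @return Object of class `hmm_fit`: `n_states`, `means`, `sds`,
#'   `transition_matrix` (row-stochastic, per frame), `initial_probs`,
#'   `loglik`, `loglik_trace`, `converged`, `state_names`, `n_frames`.
#' @export
fit_hmm <- function(traces, n_states = 3, init = NULL, seed = NULL,
                    max_iter = 500, tol = 1e-6, restarts = 5,
                    state_names = NULL) {
  obs <- .traces_to_obs(traces)
  obs <- obs[lengths(obs) >= 2]
  if (length(obs) == 0) stop("no usable traces")
  k <- as.integer(n_states)
  stopifnot(k >= 2)
  pooled_n <- sum(lengths(obs))
  n_par <- 2 * k + k * (k - 1) + (k - 1)
  if (pooled_n < 10 * n_par)
    stop("too few frames (", pooled_n, ") for ", n_par, " parameters")
  if (!is.null(seed)) set.seed(seed)
  sd_floor <- 1e-4

  pooled <- unlist(obs, use.names = FALSE)
  if (!is.null(init)) {
    mu0 <- sort(as.numeric(init$means))
    if (length(mu0) != k) stop("init means must have length n_states")
    sd0 <- if (!is.null(init$sds)) as.numeric(init$sds)[order(init$means)]
           else rep(stats::sd(pooled) / k, k)
  } else {
    sub <- if (pooled_n > 20000) sample(pooled, 20000) else pooled
    km <- suppressWarnings(stats::kmeans(sub, centers = k, nstart = 5))
    ord <- order(km$centers)
    mu0 <- as.numeric(km$centers)[ord]
    sd0 <- vapply(ord, function(j) {
      xs <- sub[km$cluster == j]
      if (length(xs) > 1) stats::sd(xs) else sd_floor * 10
    }, numeric(1))
  }
  sd0 <- pmax(sd0, sd_floor)

  run_bw <- function(mu, sdv) {
    A <- matrix(0.1 / (k - 1), k, k); diag(A) <- 0.9
    p0 <- rep(1 / k, k)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      S0 <- numeric(k); S1 <- numeric(k); S2 <- numeric(k)
      Xi <- matrix(0, k, k); G1 <- numeric(k)
      ll <- 0
      for (o in obs) {
        e <- hmm_estep(o, mu, sdv, A, p0)
        ll <- ll + e$loglik
        S0 <- S0 + e$S0; S1 <- S1 + e$S1; S2 <- S2 + e$S2
        Xi <- Xi + e$Xi; G1 <- G1 + e$G1
      }
      ll_trace <- c(ll_trace, ll)
      if (ll < ll_old - 1e-6 * abs(ll_old))
        stop("Baum-Welch log-likelihood decreased; numerical failure")
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      mu <- S1 / S0
      sdv <- pmax(sqrt(pmax(S2 / S0 - mu^2, 0)), sd_floor)
      rs <- rowSums(Xi)
      keep <- rs > 0
      A[keep, ] <- Xi[keep, , drop = FALSE] / rs[keep]
      A[!keep, ] <- 0; diag(A)[!keep] <- 1  # absorbing if never left
      p0 <- G1 / sum(G1)
    }
    list(mu = mu, sd = sdv, A = A, p0 = p0,
         loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
         converged = converged)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- if (r == 1) mu0 else mu0 + stats::rnorm(k, 0, 0.03)
    fit <- run_bw(mu, sd0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (r == 1 && fit$converged && !is.null(init)) break  # good init: done
  }
  if (!best$converged)
    warning("Baum-Welch did not converge within ", max_iter,
            " iterations; best restart returned")

  ord <- order(best$mu)
  if (is.null(state_names)) state_names <- .default_state_names(k)
  A <- best$A[ord, ord, drop = FALSE]
  dimnames(A) <- list(state_names, state_names)
  structure(list(n_states = k,
                 means = stats::setNames(best$mu[ord], state_names),
                 sds = stats::setNames(best$sd[ord], state_names),
                 transition_matrix = A,
                 initial_probs = stats::setNames(best$p0[ord], state_names),
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 converged = best$converged, state_names = state_names,
                 n_frames = pooled_n, n_traces = length(obs)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("HMM fit: %d states, %d traces / %d frames, loglik %.1f%s\n",
              x$n_states, x$n_traces, x$n_frames, x$loglik,
              if (x$converged) "" else " (not converged)"))
  print(data.frame(state = x$state_names, mean = unname(x$means),
                   sd = unname(x$sds)), row.names = FALSE)
  invisible(x)
}

#' Idealize a trace with the Viterbi algorithm
#'
#' Most-probable hidden-state sequence of a trace under a fitted HMM,
#' compressed into segments with their per-segment mean observed FRET
#' (the quantity binned in transition density plots).
#'
#' @param fit An [fit_hmm()] result.
#' @param trace A FRET-channel `frame_trace` or numeric FRET sequence.
#' @param frame_time Frame time in seconds (taken from the trace when
#'   possible).
#' @return Object of class `idealized_path`: `frames` (integer state index
#'   per frame), `state_names`, `segments` (data frame: `state`,
#'   `start_frame`, `end_frame`, `n_frames`, `duration_s`, `mean_obs`),
#'   `frame_time`, `logprob`.
#' @export
viterbi <- function(fit, trace, frame_time = 0.05) {
  if (inherits(trace, "frame_trace")) frame_time <- trace$frame_time
  v <- .traces_to_obs(list(trace))[[1]]
  if (length(v) == 0) stop("empty trace")
  vt <- hmm_viterbi(v, unname(fit$means), unname(fit$sds),
                    unname(fit$transition_matrix),
                    unname(fit$initial_probs))
  .new_idealized_path(vt$path, v, fit$state_names, frame_time,
                      logprob = vt$logprob)
}

.new_idealized_path <- function(frames, obs, state_names, frame_time,
                                logprob = NA_real_) {
  r <- rle(frames)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  mean_obs <- vapply(seq_along(starts), function(i)
    mean(obs[starts[i]:ends[i]]), numeric(1))
  seg <- data.frame(state = state_names[r$values],
                    start_frame = starts, end_frame = ends,
                    n_frames = r$lengths,
                    duration_s = r$lengths * frame_time,
                    mean_obs = mean_obs, stringsAsFactors = FALSE)
  structure(list(frames = frames, obs = obs, state_names = state_names,
                 segments = seg, frame_time = frame_time,
                 logprob = logprob),
            class = "idealized_path")
}

#' @export
print.idealized_path <- function(x, ...) {
  cat(sprintf("idealized_path: %d frames, %d segments, states {%s}\n",
              length(x$frames), nrow(x$segments),
              paste(x$state_names, collapse = ", ")))
  invisible(x)
}

#' Merge idealized segments shorter than a resolution floor
#'
#' Segments shorter than `min_frames` are below the effective time
#' resolution of 50 ms camera data and are merged into the longer adjacent
#' segment before rate estimation.
#'
#' @param path An `idealized_path`.
#' @param min_frames Minimum retained segment length in frames.
#' @return A new `idealized_path`.
#' @export
merge_short_segments <- function(path, min_frames = 2) {
  frames <- path$frames
  repeat {
    r <- rle(frames)
    if (length(r$lengths) <= 1 || all(r$lengths >= min_frames)) break
    i <- which(r$lengths < min_frames)[which.min(r$lengths[r$lengths < min_frames])]
    left <- if (i > 1) r$lengths[i - 1] else -1
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1
    r$values[i] <- if (left >= right) r$values[i - 1] else r$values[i + 1]
    frames <- inverse.rle(r)
  }
  .new_idealized_path(frames, path$obs, path$state_names, path$frame_time)
}

#' Log joint probability of a given state sequence under a fitted HMM
#'
#' Used to verify Viterbi optimality: the decoded path must score at least
#' as high as any other sequence, including the ground truth.
#'
#' @param fit An [fit_hmm()] result.
#' @param obs Numeric observation sequence.
#' @param states Integer state indices (1-based, sorted-mean order).
#' @return Log joint probability (emission + transition + initial terms).
#' @export
hmm_path_loglik <- function(fit, obs, states) {
  stopifnot(length(obs) == length(states))
  A <- unname(fit$transition_matrix)
  lp <- log(fit$initial_probs[states[1]]) +
    sum(stats::dnorm(obs, unname(fit$means)[states],
                     unname(fit$sds)[states], log = TRUE))
  if (length(states) > 1) {
    tr <- A[cbind(states[-length(states)], states[-1])]
    lp <- lp + sum(ifelse(tr > 0, log(tr), -1e308))
  }
  unname(lp)
}

#' Transition rate constants from idealized paths
#'
#' Pairwise rate constants pooled over idealized paths. Two estimators are
#' available:
#'
#' `method = "naive"` is the plain dwell/count MLE,
#' k(i -> j) = (number of i -> j transitions) / (total time in i), with
#' stderr k / sqrt(count), after merging segments shorter than
#' `min_frames` (see [merge_short_segments()]). Boundary segments
#' contribute observed time but no event beyond what is observed (the
#' censored-exponential treatment). This estimator is substantially biased
#' downward once dwell times approach the camera frame time, because
#' sub-frame visits are missed and neighbouring dwells merge.
#'
#' `method = "truncated"` (the default) corrects for the resolution floor.
#' The total exit rate of each state is estimated from its uncensored
#' dwells at least `dead_time` long via the left-truncated exponential
#' MLE, r_i = n / sum(tau - dead_time) — exact under memorylessness
#' regardless of how many short dwells were missed — and split across
#' destinations by the observed branching of those dwells. For reversible
#' state pairs whose forward/backward transition counts are statistically
#' consistent with the stationary flux identity N(i->j) = N(j->i), the
#' rate out of the state more exposed to event merging (short partner
#' dwells) is replaced by the flux-balanced value
#' k(i->j) = k(j->i) T_j / T_i, using the per-state Viterbi occupancy
#' times T, which are robust to missed events. Count-asymmetric pairs
#' (net cycle flux, e.g. with a direct dissociation channel) are left
#' uncorrected.
#'
#' @param paths An `idealized_path` or list of them.
#' @param frame_time Frame time in seconds.
#' @param method `"truncated"` (resolution-corrected, default) or
#'   `"naive"`.
#' @param dead_time Detection floor in seconds for the truncated
#'   estimator; default two frames.
#' @param min_frames Merging floor for the naive estimator.
#' @return List of class `rate_matrix`: `rates` (K x K, s^-1), `stderr`,
#'   `counts` (transitions used), `time_s` (per-state Viterbi time),
#'   `method`.
#' @export
rates_from_idealization <- function(paths, frame_time = 0.05,
                                    method = c("truncated", "naive"),
                                    dead_time = 2 * frame_time,
                                    min_frames = 2) {
  method <- match.arg(method)
  if (inherits(paths, "idealized_path")) paths <- list(paths)
  sn <- paths[[1]]$state_names
  k <- length(sn)
  counts <- matrix(0, k, k, dimnames = list(sn, sn))
  time_s <- stats::setNames(numeric(k), sn)
  merged <- if (method == "naive" && min_frames > 1)
    lapply(paths, merge_short_segments, min_frames = min_frames) else paths
  for (p in merged) {
    seg <- p$segments
    si <- match(seg$state, sn)
    time_s <- time_s + tapply(seg$duration_s, factor(si, seq_len(k)),
                              sum, default = 0)
    if (nrow(seg) > 1) {
      from <- si[-nrow(seg)]; to <- si[-1]
      for (t in seq_along(from))
        counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
    }
  }
  if (method == "naive") {
    rates <- counts / rep(pmax(time_s, .Machine$double.eps), k)
    rates[time_s == 0, ] <- 0
    stderr <- rates / sqrt(pmax(counts, 1))
    stderr[counts == 0] <- 0
    return(structure(list(rates = rates, stderr = stderr, counts = counts,
                          time_s = time_s, frame_time = frame_time,
                          method = method),
                     class = "rate_matrix"))
  }
  # truncated estimator: per-state exit rate and branching from dwells
  # at least dead_time long
  rates <- matrix(0, k, k, dimnames = list(sn, sn))
  ncnt <- matrix(0, k, k, dimnames = list(sn, sn))
  r_tot <- stats::setNames(rep(NA_real_, k), sn)
  for (i in seq_len(k)) {
    dw <- extract_dwells(paths, sn[i])
    ok <- !dw$censored & dw$duration_s >= dead_time & !is.na(dw$exit_to)
    if (sum(ok) < 2) next
    r_tot[i] <- sum(ok) / sum(dw$duration_s[ok] - dead_time)
    dest <- table(factor(dw$exit_to[ok], levels = sn))
    ncnt[i, ] <- as.numeric(dest)
    rates[i, ] <- r_tot[i] * as.numeric(dest) / sum(dest)
  }
  # flux-balance refinement for count-symmetric reversible pairs: replace
  # the rate out of the state more exposed to merging (short partner
  # dwells) with the occupancy-ratio value
  miss_risk <- vapply(seq_len(k), function(i) {
    if (is.na(r_tot[i]) || sum(ncnt[i, ]) == 0) return(NA_real_)
    br <- ncnt[i, ] / sum(ncnt[i, ])
    sum(br * (1 - exp(-ifelse(is.na(r_tot), 0, r_tot) * dead_time)))
  }, numeric(1))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    nij <- counts[i, j]; nji <- counts[j, i]
    if (nij < 5 || nji < 5) next
    if (abs(nij - nji) > 3 * sqrt(nij + nji)) next  # net cycle flux
    if (is.na(miss_risk[i]) || is.na(miss_risk[j])) next
    if (miss_risk[i] > miss_risk[j] && time_s[i] > 0)
      rates[i, j] <- rates[j, i] * time_s[j] / time_s[i]
    else if (miss_risk[j] > miss_risk[i] && time_s[j] > 0)
      rates[j, i] <- rates[i, j] * time_s[i] / time_s[j]
  }
  stderr <- rates / sqrt(pmax(ncnt, 1))
  stderr[ncnt == 0] <- 0
  structure(list(rates = rates, stderr = stderr, counts = ncnt,
                 time_s = time_s, frame_time = frame_time,
                 method = method),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("Rate constants (s^-1) from idealized paths:\n")
  print(round(x$rates, 4))
  cat("transition counts:\n")
  print(x$counts)
  invisible(x)
}

#' Rate constants from the HMM per-frame transition matrix
#'
#' The alternative estimator to [rates_from_idealization()]: the
#' continuous-time generator Q recovered from the fitted per-frame
#' transition matrix A via the principal matrix logarithm,
#' Q = logm(A) / dt, which inverts the exact discretization A = expm(Q dt)
#' and therefore avoids the first-order bias of -ln(1 - p)/dt when several
#' transitions can occur within one frame. Small negative off-diagonal
#' entries from estimation noise are clipped to zero.
#'
#' @param fit An [fit_hmm()] result.
#' @param frame_time Frame time in seconds.
#' @param method `"logm"` (default) or `"neglog"` for the elementwise
#'   first-order approximation -ln(1 - p_ij)/dt.
#' @return K x K matrix of rates in s^-1 (diagonal zero).
#' @export
rates_from_transition_matrix <- function(fit, frame_time = 0.05,
                                         method = c("logm", "neglog")) {
  method <- match.arg(method)
  A <- unname(fit$transition_matrix)
  k <- nrow(A)
  if (method == "neglog") {
    Q <- -log(pmax(1 - A, .Machine$double.eps)) / frame_time
  } else {
    e <- eigen(A)
    if (any(Re(e$values) <= 0))
      return(rates_from_transition_matrix(fit, frame_time, "neglog"))
    Q <- Re(e$vectors %*% diag(log(e$values), k) %*% solve(e$vectors)) /
      frame_time
  }
  diag(Q) <- 0
  Q[Q < 0] <- 0
  dimnames(Q) <- dimnames(fit$transition_matrix)
  Q
}

#' Transition density plot data from idealized paths
#'
#' For every segment boundary, bins the pair (mean observed FRET of the
#' preceding segment, mean of the following segment) into a 2-D histogram
#' over \[0, 1\]^2 — the transition density plot that reveals which state
#' pairs interconvert. Also tallies transitions by ordered state-label
#' pair, from which e.g. the fraction of apparent direct
#' unbound <-> exo transitions is read.
#'
#' @param paths An `idealized_path` or list of them.
#' @param bins Number of bins per axis.
#' @return Object of class `transition_density`: `counts` (bins x bins,
#'   rows = FRET before), `breaks`, `total`, `class_counts` (K x K matrix
#'   by state label).
#' @export
transition_density <- function(paths, bins = 50) {
  if (inherits(paths, "idealized_path")) paths <- list(paths)
  sn <- paths[[1]]$state_names
  k <- length(sn)
  before <- numeric(0); after <- numeric(0)
  cls <- matrix(0, k, k, dimnames = list(sn, sn))
  for (p in paths) {
    seg <- p$segments
    if (nrow(seg) < 2) next
    b <- seg$mean_obs[-nrow(seg)]; a <- seg$mean_obs[-1]
    before <- c(before, b); after <- c(after, a)
    fi <- match(seg$state[-nrow(seg)], sn); ti <- match(seg$state[-1], sn)
    for (t in seq_along(fi)) cls[fi[t], ti[t]] <- cls[fi[t], ti[t]] + 1
  }
  if (length(before) == 0) stop("no transitions in the supplied paths")
  breaks <- seq(0, 1, length.out = bins + 1L)
  bi <- cut(pmin(pmax(before, 0), 1), breaks, include.lowest = TRUE)
  ai <- cut(pmin(pmax(after, 0), 1), breaks, include.lowest = TRUE)
  counts <- table(bi, ai)
  structure(list(counts = unclass(counts), breaks = breaks,
                 total = length(before), class_counts = cls),
            class = "transition_density")
}

#' @export
print.transition_density <- function(x, ...) {
  cat(sprintf("transition_density: %d transitions\nclass counts:\n", x$total))
  print(x$class_counts)
  invisible(x)
}

#' Fraction of transitions in a set of ordered state-label classes
#'
#' @param td A [transition_density()] result.
#' @param from,to State labels of the ordered classes to sum (recycled
#'   pairwise).
#' @return Fraction of all transitions falling in those classes.
#' @export
transition_class_fraction <- function(td, from, to) {
  sum(td$class_counts[cbind(from, to)]) / td$total
}
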