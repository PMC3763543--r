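# Normalize an idealized path or a ground-truth state path to the segment
# representation (state, duration_s) used by the pause measurements, with
# flags for trace-boundary censoring.
.path_segments <- function(x) {
  if (inherits(x, "idealized_path")) {
    data.frame(state = x$segments$state,
               duration_s = x$segments$duration_s,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "state_path") || is.data.frame(x)) {
    data.frame(state = x$state, duration_s = x$exit - x$entry,
               stringsAsFactors = FALSE)
  } else stop("expected an idealized_path or state_path")
}

# Split segments into bound bouts: maximal runs of non-unbound segments.
# Returns a list of segment data frames plus whether each bout touches the
# start or end of the trace (entry/exit unobserved).
.bound_bouts <- function(seg) {
  is_bound <- seg$state != "unbound"
  r <- rle(is_bound)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  keep <- which(r$values)
  lapply(keep, function(i) {
    list(seg = seg[starts[i]:ends[i], , drop = FALSE],
         at_start = starts[i] == 1L,
         at_end = ends[i] == nrow(seg))
  })
}

.new_pause_distribution <- function(event_class, durations, bin_width = 0.1) {
  durations <- as.numeric(durations)
  if (length(durations) == 0)
    stop("no ", event_class, " events found")
  top <- max(durations, bin_width)
  breaks <- seq(0, bin_width * ceiling(top / bin_width + 1e-9), bin_width)
  counts <- graphics::hist(durations, breaks = breaks, right = FALSE,
                           plot = FALSE)$counts
  structure(list(event_class = event_class, durations = durations,
                 bin_width = bin_width, breaks = breaks, counts = counts,
                 n_events = length(durations)),
            class = "pause_distribution")
}

#' @export
print.pause_distribution <- function(x, ...) {
  cat(sprintf(
    "pause_distribution (%s): %d events, mean %.3g s, zero-bin fraction %.3f\n",
    x$event_class, x$n_events, mean(x$durations),
    mean(x$durations < x$bin_width)))
  invisible(x)
}

#' Fraction of zero-length (direct-transition) pauses
#'
#' Fraction of measured pauses not exceeding `tol`. With the default
#' `tol = 0` this is the fraction of exact zeros — events with no
#' detectable intermediate visit, i.e. apparent direct transitions; set
#' `tol` to the bin width to get the first-histogram-bin fraction instead.
#' @param pd A `pause_distribution`.
#' @param tol Pauses `<= tol` seconds count as zero.
#' @return A fraction in \[0, 1\].
#' @export
zero_pause_fraction <- function(pd, tol = 0) mean(pd$durations <= tol)

#' Pause lengths preceding exo-site association
#'
#' For every binding event that reaches the exo site, the association
#' pause is the time spent in the intermediate site between leaving the
#' unbound state and first reaching the exo site (0 when the event starts
#' directly in exo). Bouts truncated by the start of the trace are skipped
#' (their entry is unobserved). Applied to idealized paths this includes
#' camera and idealization artifacts; applied to ground-truth state paths
#' it gives the exact kinetic quantity.
#'
#' @param paths An `idealized_path`/`state_path` or list of them.
#' @param bin_width Histogram bin width in seconds (default 0.1 s = two
#'   frames at 50 ms).
#' @return Object of class `pause_distribution`.
#' @export
measure_association_pauses <- function(paths, bin_width = 0.1) {
  if (!is.list(paths) || inherits(paths, c("idealized_path", "data.frame")))
    paths <- list(paths)
  out <- unlist(lapply(paths, function(p) {
    seg <- .path_segments(p)
    vapply(.bound_bouts(seg), function(b) {
      if (b$at_start || !"exo" %in% b$seg$state) return(NA_real_)
      first_exo <- which(b$seg$state == "exo")[1]
      if (first_exo == 1L) 0
      else sum(b$seg$duration_s[seq_len(first_exo - 1L)]
               [b$seg$state[seq_len(first_exo - 1L)] == "intermediate"])
    }, numeric(1))
  }))
  .new_pause_distribution("association_pause", out[!is.na(out)], bin_width)
}

#' Pause lengths following the final exo-site visit before dissociation
#'
#' For every binding event whose last exo-site visit is followed by
#' dissociation, the dissociation pause is the time spent in the
#' intermediate site between leaving the exo site for the last time and
#' unbinding (0 for direct exo -> unbound dissociation). Bouts truncated
#' by the end of the trace are skipped (dissociation unobserved).
#'
#' @inheritParams measure_association_pauses
#' @return Object of class `pause_distribution`.
#' @export
measure_dissociation_pauses <- function(paths, bin_width = 0.1) {
  if (!is.list(paths) || inherits(paths, c("idealized_path", "data.frame")))
    paths <- list(paths)
  out <- unlist(lapply(paths, function(p) {
    seg <- .path_segments(p)
    vapply(.bound_bouts(seg), function(b) {
      if (b$at_end || !"exo" %in% b$seg$state) return(NA_real_)
      last_exo <- max(which(b$seg$state == "exo"))
      n <- nrow(b$seg)
      if (last_exo == n) 0
      else sum(b$seg$duration_s[seq(last_exo + 1L, n)]
               [b$seg$state[seq(last_exo + 1L, n)] == "intermediate"])
    }, numeric(1))
  }))
  .new_pause_distribution("dissociation_pause", out[!is.na(out)], bin_width)
}

#' Run the full camera + idealization pipeline on a kinetic scheme
#'
#' Simulates ground-truth trajectories and pushes them through every stage
#' an experimental trace passes through: frame integration at the camera
#' exposure time, noisy donor/acceptor emission, optional moving-average
#' smoothing, HMM fitting (initialized at the scheme's emission levels)
#' and Viterbi idealization. The returned idealized paths therefore carry
#' the same signal-averaging and exposure-time-integration artifacts as
#' idealized experimental data.
#'
#' @param scheme A [kinetic_scheme()].
#' @param n_traces Number of molecules.
#' @param duration Per-trace duration in seconds.
#' @param frame_time Camera frame time in seconds.
#' @param model An [emission_model()].
#' @param window Optional odd moving-average window (`NULL` for none).
#' @param seed Integer seed.
#' @param hmm_max_iter,hmm_tol Baum-Welch controls.
#' @return List with `idealized` (list of `idealized_path`), `paths`
#'   (ground truth), `fit` (the `hmm_fit`).
#' @export
pipeline_idealize <- function(scheme, n_traces, duration = 40,
                              frame_time = 0.05, model = emission_model(),
                              window = NULL, seed = 1,
                              hmm_max_iter = 100, hmm_tol = 1e-6) {
  ds <- generate_dataset(scheme, n_traces, duration = duration,
                         model = model, seed = seed, channel = "fret",
                         frame_time = frame_time)
  obs <- lapply(ds$traces, trace_fret)
  if (!is.null(window)) obs <- lapply(obs, moving_average, window = window)
  k <- length(scheme$states)
  init <- list(means = sort(unname(scheme$fret)),
               sds = rep(0.03, k))
  fit <- fit_hmm(obs, n_states = k, init = init, seed = seed,
                 max_iter = hmm_max_iter, tol = hmm_tol, restarts = 1)
  idealized <- lapply(obs, function(o) viterbi(fit, o, frame_time))
  list(idealized = idealized, paths = ds$paths, fit = fit)
}

#' Simulate a pause-length distribution through the full pipeline
#'
#' The model-discrimination primitive: given a candidate kinetic scheme,
#' simulate traces, idealize them through the camera + HMM pipeline, and
#' measure the association or dissociation pause-length distribution. With
#' `mode = "ground_truth"` the camera and HMM are bypassed and pauses are
#' measured on the exact state paths (the analytic reference).
#'
#' @inheritParams pipeline_idealize
#' @param event_class `"dissociation"` or `"association"`.
#' @param mode `"pipeline"` (default) or `"ground_truth"`.
#' @param bin_width Pause histogram bin width in seconds.
#' @return Object of class `pause_distribution`.
#' @export
simulate_pause_distribution <- function(scheme, n_traces, duration = 40,
                                        event_class = c("dissociation",
                                                        "association"),
                                        mode = c("pipeline", "ground_truth"),
                                        frame_time = 0.05,
                                        model = emission_model(),
                                        window = NULL, seed = 1,
                                        bin_width = 0.1) {
  event_class <- match.arg(event_class)
  mode <- match.arg(mode)
  measure <- if (event_class == "dissociation") measure_dissociation_pauses
             else measure_association_pauses
  if (mode == "ground_truth") {
    set.seed(seed)
    sub <- sample.int(.Machine$integer.max - 1L, n_traces)
    paths <- lapply(seq_len(n_traces), function(i)
      simulate_path(scheme, duration, seed = sub[i]))
    return(measure(paths, bin_width = bin_width))
  }
  pl <- pipeline_idealize(scheme, n_traces, duration = duration,
                          frame_time = frame_time, model = model,
                          window = window, seed = seed)
  measure(pl$idealized, bin_width = bin_width)
}

# Bin pause durations onto fixed breaks (overflow clamped into the last
# bin) and normalize to probabilities, for histogram-based objectives.
.pause_probs <- function(durations, breaks) {
  d <- pmin(durations, breaks[length(breaks)] - 1e-12)
  graphics::hist(d, breaks = breaks, right = FALSE, plot = FALSE)$counts /
    length(d)
}

.ks_stat <- function(x, y) {
  z <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
}

#' Fit the direct-dissociation fraction by simulation grid search
#'
#' Discriminates dissociation pathways: for each candidate fraction f of
#' dissociations occurring directly from the exo site, the base scheme is
#' augmented via [add_direct_dissociation()], a pause-length distribution
#' is simulated through the same pipeline as the observed one, and the two
#' are compared (summed squared differences of normalized histograms by
#' default, or the Kolmogorov-Smirnov distance). The grid argmin is the
#' best-fit fraction. Grid values infeasible for the scheme's branching
#' ratios (f too close to 1 with a nonzero intermediate off-rate) get `NA`
#' objectives.
#'
#' @param observed A `pause_distribution` of dissociation pauses.
#' @param base_scheme Scheme with zero direct exo -> unbound rate (e.g.
#'   the AAF n+1 preset).
#' @param grid Candidate fractions in \[0, 1\].
#' @param n_traces Traces simulated per grid point.
#' @param duration Per-trace duration in seconds.
#' @param objective `"ls"` or `"ks"`.
#' @param seed Integer seed; independent sub-seeds per grid point.
#' @param refine If `TRUE`, re-scan at 0.01 resolution around the coarse
#'   argmin (useful with deterministic objectives; off by default because
#'   simulation noise is larger than a 0.01 step at feasible trace counts).
#' @param mode,window,frame_time,model Passed to
#'   [simulate_pause_distribution()].
#' @param max_pause_s Upper edge of the comparison histogram.
#' @return Object of class `pathway_fit`: `grid`, `objective`,
#'   `best_fraction`, `objective_kind`, `n_traces`.
#' @export
fit_direct_fraction <- function(observed, base_scheme,
                                grid = seq(0, 1, by = 0.05),
                                n_traces = 2000, duration = 40,
                                objective = c("ls", "ks"), seed = 1,
                                refine = FALSE,
                                mode = c("pipeline", "ground_truth"),
                                window = NULL, frame_time = 0.05,
                                model = emission_model(),
                                max_pause_s = 5) {
  objective <- match.arg(objective)
  mode <- match.arg(mode)
  if (observed$n_events < 2 || length(unique(observed$durations)) < 1)
    stop("degenerate observed pause distribution")
  if (min(grid) > 0 || max(grid) < 1 - 1e-9)
    warning("grid does not cover [0, 1]")
  bw <- observed$bin_width
  breaks <- seq(0, max_pause_s, by = bw)
  p_obs <- .pause_probs(observed$durations, breaks)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(grid) + 100L)
  score_one <- function(f, s) {
    sc <- tryCatch(add_direct_dissociation(base_scheme, f),
                   error = function(e) NULL)
    if (is.null(sc)) return(NA_real_)
    sim <- simulate_pause_distribution(
      sc, n_traces, duration = duration, event_class = "dissociation",
      mode = mode, frame_time = frame_time, model = model, window = window,
      seed = s, bin_width = bw)
    if (objective == "ls")
      sum((.pause_probs(sim$durations, breaks) - p_obs)^2)
    else .ks_stat(sim$durations, observed$durations)
  }
  obj <- vapply(seq_along(grid), function(i) score_one(grid[i], sub[i]),
                numeric(1))
  if (all(is.na(obj))) stop("no feasible grid point")
  best <- grid[which.min(obj)]
  if (refine) {
    fine <- setdiff(round(seq(max(0, best - 0.04), min(1, best + 0.04),
                              by = 0.01), 10), grid)
    if (length(fine)) {
      obj2 <- vapply(seq_along(fine), function(i)
        score_one(fine[i], sub[length(grid) + i]), numeric(1))
      grid <- c(grid, fine); obj <- c(obj, obj2)
      ord <- order(grid); grid <- grid[ord]; obj <- obj[ord]
      best <- grid[which.min(obj)]
    }
  }
  structure(list(grid = grid, objective = obj, best_fraction = best,
                 objective_kind = objective, n_traces = n_traces,
                 mode = mode),
            class = "pathway_fit")
}

#' @export
print.pathway_fit <- function(x, ...) {
  cat(sprintf(
    "pathway_fit: best direct-dissociation fraction %.2f (%s objective, %d traces/point, %s mode)\n",
    x$best_fraction, x$objective_kind, x$n_traces, x$mode))
  invisible(x)
}
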