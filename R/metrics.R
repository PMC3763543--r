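#' Apparent FRET efficiency from donor and acceptor intensities
#'
#' Per-frame apparent FRET, acceptor / (donor + acceptor). Frames whose
#' total intensity is zero (e.g. after donor photobleach) are undefined and
#' returned as `NA`; downstream analyses exclude them rather than imputing.
#'
#' @param donor,acceptor Nonnegative intensity vectors of equal length.
#' @return Numeric vector in \[0, 1\] with `NA` for zero-total frames.
#' @export
#' @examples
#' apparent_fret(c(500, 370), c(500, 630))
apparent_fret <- function(donor, acceptor) {
  if (length(donor) != length(acceptor))
    stop("donor and acceptor must have equal length")
  if (any(donor < 0, na.rm = TRUE) || any(acceptor < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  total <- donor + acceptor
  out <- acceptor / total
  out[!is.na(total) & total == 0] <- NA_real_
  out
}

#' Apparent FRET of a frame_trace
#'
#' Convenience accessor: apparent FRET for a FRET-channel `frame_trace`,
#' or an error for PIFE traces.
#' @param trace A `frame_trace`.
#' @return Numeric vector of apparent FRET values.
#' @export
trace_fret <- function(trace) {
  if (!inherits(trace, "frame_trace") || trace$channel != "fret")
    stop("trace_fret() needs a FRET-channel frame_trace")
  apparent_fret(trace$donor, trace$acceptor)
}

#' Normalize a raw PIFE trace to the unbound-DNA baseline
#'
#' Divides a raw Cy3 intensity trace by the unbound-state intensity so that
#' unbound DNA sits at 1.0 and binding events appear as relative
#' enhancements. By default the baseline is estimated as the mode of the
#' lowest-intensity population (kernel density peak); it can also be
#' supplied explicitly, e.g. from generator ground truth.
#'
#' A single-population trace is ambiguous on its own (an always-unbound and
#' an always-bound molecule look alike up to scale); when the expected
#' unbound intensity range is known, pass `baseline_range` so the absence
#' of unbound frames is detected and reported instead of silently
#' normalizing the bound level to 1.
#'
#' @param raw Nonnegative intensity vector.
#' @param baseline Optional known baseline intensity; when given, the
#'   function is exact division.
#' @param baseline_range Optional length-2 numeric: the intensity window
#'   in which the unbound level must fall; an estimate outside it is an
#'   error.
#' @param min_unbound_fraction Minimum fraction of frames that must lie
#'   within 20% of the estimated baseline for the estimate to be accepted.
#' @return Numeric vector of normalized PIFE values, with the baseline used
#'   attached as attribute `baseline`.
#' @export
normalize_pife <- function(raw, baseline = NULL, baseline_range = NULL,
                           min_unbound_fraction = 0.05) {
  if (length(raw) == 0) stop("empty trace")
  if (is.null(baseline)) {
    d <- stats::density(raw, n = 512)
    ispk <- which(diff(sign(diff(d$y))) == -2) + 1L
    ispk <- ispk[d$y[ispk] >= 0.05 * max(d$y)]
    if (length(ispk) == 0) ispk <- which.max(d$y)
    if (!is.null(baseline_range))
      ispk <- ispk[d$x[ispk] >= baseline_range[1] &
                   d$x[ispk] <= baseline_range[2]]
    if (length(ispk) == 0)
      stop("no unbound frames detected: no intensity population falls in ",
           "the expected baseline range [", baseline_range[1], ", ",
           baseline_range[2], "]; supply `baseline` explicitly")
    baseline <- d$x[min(ispk)]   # lowest-intensity substantial peak
    near <- mean(abs(raw - baseline) <= 0.2 * baseline)
    if (baseline <= 0 || near < min_unbound_fraction)
      stop("no unbound frames detected near the estimated baseline (",
           signif(baseline, 4), "); supply `baseline` explicitly, e.g. ",
           "from a buffer-only segment or generator ground truth")
  }
  if (baseline <= 0) stop("baseline must be positive")
  structure(raw / baseline, baseline = baseline)
}

#' Pooled histogram of an observable over many traces
#'
#' Builds the population histogram used to read off binding orientations:
#' frames from all traces are pooled, optionally filtered, binned, and the
#' density normalized to integrate to 1. Per-trace frame counts are
#' returned so over-weighting by long traces is visible.
#'
#' @param traces List of `frame_trace` objects (or a bare numeric vector of
#'   pooled samples).
#' @param observable `"fret"` or `"pife"`.
#' @param bins Number of bins.
#' @param range Histogram range; defaults to \[0, 1\] for FRET and
#'   \[0.5, 3\] for PIFE.
#' @param frame_filter Optional predicate `function(values)` returning a
#'   logical vector of frames to keep (applied per trace).
#' @param window Optional odd moving-average window applied per trace
#'   before pooling (`NULL` for none).
#' @return List of class `sm_histogram`: `breaks`, `mids`, `counts`,
#'   `density`, `n_samples`, `per_trace_n`.
#' @export
build_histogram <- function(traces, observable = c("fret", "pife"),
                            bins = 50, range = NULL, frame_filter = NULL,
                            window = NULL) {
  observable <- match.arg(observable)
  if (is.null(range))
    range <- if (observable == "fret") c(0, 1) else c(0.5, 3)
  if (is.numeric(traces)) traces <- list(traces)
  if (length(traces) == 0) stop("no traces supplied")
  per_trace <- lapply(traces, function(tr) {
    v <- if (is.numeric(tr)) tr
    else if (tr$channel == "fret") trace_fret(tr)
    else normalize_pife(tr$intensity, baseline = tr$meta$baseline)
    v <- as.numeric(v)
    if (!is.null(window)) v <- moving_average(v, window)
    if (!is.null(frame_filter)) v <- v[which(frame_filter(v))]
    v[is.finite(v)]
  })
  pooled <- unlist(per_trace, use.names = FALSE)
  pooled <- pmin(pmax(pooled, range[1]), range[2])
  if (length(pooled) == 0) stop("no frames left after filtering")
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 density = h$density, n_samples = length(pooled),
                 per_trace_n = lengths(per_trace)),
            class = "sm_histogram")
}

# One EM run for a 1-D Gaussian mixture from given initial parameters.
# Returns NULL on degeneracy (empty component / vanishing sd).
.em_gauss1d <- function(x, mu, sd, w, tol, max_iter, sd_floor) {
  n <- length(x)
  k <- length(mu)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d))) return(NULL)
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
                    sd_floor^2))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(mu = mu, sd = sd, w = w, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace)
}

#' Fit a Gaussian mixture to pooled observable samples
#'
#' Maximum-likelihood 1-D Gaussian mixture by expectation-maximization,
#' used to resolve binding-orientation populations (e.g. the intermediate
#' site at 0.50 FRET from the exo site at 0.63). Multiple restarts guard
#' against local optima: the first uses k-means initialization, the rest
#' perturb it. The per-iteration log-likelihood is retained and checked to
#' be non-decreasing. Components are returned sorted by mean.
#'
#' @param samples Numeric vector (>= `min_samples` finite values).
#' @param n_components Number of components, or `"bic"` to select 1..
#'   `max_components` by the Bayesian information criterion.
#' @param seed Integer seed.
#' @param restarts Number of EM restarts (default 10).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param max_components Upper bound scanned when `n_components = "bic"`.
#' @param min_samples Minimum usable sample count.
#' @return Object of class `population_fit`: `means`, `sds`, `weights`
#'   (sorted by mean), `n_components`, `loglik`, `bic`, `loglik_trace`,
#'   `converged`.
#' @export
#' @examples
#' x <- c(rnorm(300, 0.50, 0.02), rnorm(300, 0.63, 0.02))
#' fit_population_mixture(x, 2, seed = 1)
fit_population_mixture <- function(samples, n_components = 2, seed = NULL,
                                   restarts = 10, tol = 1e-8,
                                   max_iter = 1000, max_components = 4,
                                   min_samples = 50) {
  x <- samples[is.finite(samples)]
  n <- length(x)
  if (n < min_samples)
    stop("need at least ", min_samples, " finite samples, got ", n)
  if (!is.null(seed)) set.seed(seed)
  if (identical(n_components, "bic")) {
    fits <- lapply(seq_len(max_components), function(k)
      fit_population_mixture(x, k, seed = NULL, restarts = restarts,
                             tol = tol, max_iter = max_iter,
                             min_samples = min_samples))
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]])
  }
  k <- as.integer(n_components)
  stopifnot(k >= 1)
  sd_floor <- max(stats::sd(x) * 1e-4, 1e-8)
  best <- NULL
  for (r in seq_len(restarts)) {
    if (r == 1 && k > 1) {
      km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 5))
      mu <- as.numeric(km$centers)
      sd0 <- vapply(seq_len(k), function(j) {
        xs <- x[km$cluster == j]
        if (length(xs) > 1) stats::sd(xs) else sd_floor * 10
      }, numeric(1))
      w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    } else if (r == 1) {
      mu <- mean(x); sd0 <- stats::sd(x); w <- 1
    } else {
      mu <- sample(x, k)
      sd0 <- rep(stats::sd(x) / sqrt(k), k)
      w <- rep(1 / k, k)
    }
    sd0 <- pmax(sd0, sd_floor)
    fit <- .em_gauss1d(x, mu, sd0, w, tol, max_iter, sd_floor)
    if (is.null(fit)) next
    dll <- diff(fit$loglik_trace)
    if (any(dll < -1e-6 * abs(fit$loglik)))
      stop("EM log-likelihood decreased; numerical failure")
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("EM failed to converge in ", restarts, " restarts (all runs ",
         "degenerate); consider fewer components or more samples")
  ord <- order(best$mu)
  p <- 3 * k - 1
  structure(list(n_components = k, means = best$mu[ord],
                 sds = best$sd[ord], weights = best$w[ord],
                 loglik = best$loglik,
                 bic = -2 * best$loglik + p * log(n),
                 loglik_trace = best$loglik_trace,
                 converged = length(best$loglik_trace) < max_iter,
                 n_samples = n),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d component(s), n = %d, BIC = %.1f\n",
              x$n_components, x$n_samples, x$bic))
  print(data.frame(mean = x$means, sd = x$sds, weight = x$weights),
        row.names = FALSE)
  invisible(x)
}

#' Occupancy-weighted signal average under fast exchange
#'
#' The signal expected when a molecule shuttles between states faster than
#' the camera frame time: each frame reports the occupancy-weighted mean of
#' the state levels. Used to test whether an observed level could be a
#' time-average of two known states (e.g. whether ~0.50 FRET / 1.9 PIFE
#' could be rapid pol/exo averaging, which would give PIFE ~1.5).
#'
#' @param levels Numeric state emission levels.
#' @param occupancies Fractional occupancies, summing to 1.
#' @return The weighted mean, a single number.
#' @export
#' @examples
#' fast_exchange_average(c(1.2, 1.8), c(0.5, 0.5))
fast_exchange_average <- function(levels, occupancies) {
  if (length(levels) != length(occupancies))
    stop("levels and occupancies must have equal length")
  if (abs(sum(occupancies) - 1) > 1e-8)
    stop("occupancies must sum to 1")
  sum(levels * occupancies)
}
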