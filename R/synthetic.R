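#' Detection/emission model for synthetic traces
#'
#' Parameters of the camera and fluorophore model used to turn ideal
#' (noise-free) per-frame signals into realistic traces: total fluorescence
#' intensity per frame, additive Gaussian detection noise per channel, and
#' optional exponential photobleaching of donor and acceptor.
#'
#' With the defaults (total 1000 counts/frame, noise 30 counts/frame for
#' FRET, 100 counts/frame for PIFE) the apparent-FRET standard deviation is
#' about 0.02 and the normalized-PIFE standard deviation about 0.1,
#' matching typical experimental uncertainty for this assay.
#'
#' @param total_intensity Total counts per frame (donor + acceptor), also
#'   the unbound-DNA baseline for PIFE traces.
#' @param noise_sd Gaussian noise sd per channel in counts/frame. `NULL`
#'   selects a channel-appropriate default at emission time: 3% of
#'   `total_intensity` for FRET channels, 10% for PIFE.
#' @param donor_bleach_rate,acceptor_bleach_rate Photobleaching rates in
#'   s^-1 (0 disables bleaching).
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(total_intensity = 1000, noise_sd = NULL,
                           donor_bleach_rate = 0, acceptor_bleach_rate = 0) {
  stopifnot(total_intensity > 0,
            is.null(noise_sd) || noise_sd >= 0,
            donor_bleach_rate >= 0, acceptor_bleach_rate >= 0)
  structure(list(total_intensity = total_intensity, noise_sd = noise_sd,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate),
            class = "emission_model")
}

.noise_default <- function(model, channel) {
  if (!is.null(model$noise_sd)) return(model$noise_sd)
  model$total_intensity * if (channel == "pife") 0.10 else 0.03
}

#' Integrate a state path over camera frames
#'
#' Computes the ideal (noise-free) per-frame FRET and PIFE signals implied
#' by a ground-truth state path: the value of frame j is the time-weighted
#' mean of the state emission levels over the half-open frame interval
#' \[j dt, (j+1) dt). This reproduces the exposure-time-integration artifact
#' of real cameras: transitions faster than the frame time appear as
#' intermediate signal levels. A partial final frame is discarded.
#'
#' @param path A `state_path` from [simulate_path()].
#' @param scheme The [kinetic_scheme()] that produced the path (provides
#'   per-state FRET and PIFE levels).
#' @param frame_time Camera frame time in seconds (default 0.05).
#' @return List with numeric vectors `fret` and `pife` (length `n_frames`),
#'   plus `n_frames` and `frame_time`.
#' @export
integrate_frames <- function(path, scheme, frame_time = 0.05) {
  if (!is.data.frame(path) || nrow(path) == 0) stop("empty state path")
  stopifnot(frame_time > 0)
  dur <- attr(path, "total_duration")
  if (is.null(dur)) dur <- path$exit[nrow(path)]
  n_frames <- floor(dur / frame_time + 1e-9)
  if (n_frames < 1)
    stop("path shorter than one frame (duration ", dur, " s)")
  edges <- seq(0, n_frames) * frame_time
  seglen <- path$exit - path$entry
  idx <- findInterval(edges, path$entry)
  frame_mean <- function(level) {
    # cumulative integral of the piecewise-constant level, sampled at edges
    level <- unname(level)
    cum <- c(0, cumsum(level * seglen))
    L <- cum[idx] + (edges - path$entry[idx]) * level[idx]
    diff(L) / frame_time
  }
  list(fret = frame_mean(scheme$fret[path$state]),
       pife = frame_mean(scheme$pife[path$state]),
       n_frames = n_frames, frame_time = frame_time)
}

#' Per-frame state occupancy of a path
#'
#' Fraction of each camera frame spent in each state; rows are frames,
#' columns states. Row sums are 1 for every complete frame.
#'
#' @inheritParams integrate_frames
#' @param states State labels (defaults to those present in the path).
#' @return Numeric matrix `n_frames` x `length(states)`.
#' @export
frame_occupancy <- function(path, frame_time = 0.05, states = NULL) {
  if (is.null(states)) states <- unique(path$state)
  occ <- sapply(states, function(s) {
    lv <- stats::setNames(as.numeric(states == s), states)
    integrate_frames(path, list(fret = lv, pife = lv), frame_time)$fret
  })
  matrix(occ, ncol = length(states), dimnames = list(NULL, states))
}

.new_frame_trace <- function(channel, frame_time, donor = NULL,
                             acceptor = NULL, intensity = NULL, meta = list()) {
  n <- if (channel == "fret") length(donor) else length(intensity)
  structure(list(channel = channel, frame_time = frame_time, n_frames = n,
                 time = (seq_len(n) - 1L) * frame_time,
                 donor = donor, acceptor = acceptor, intensity = intensity,
                 meta = meta),
            class = "frame_trace")
}

#' @export
print.frame_trace <- function(x, ...) {
  cat(sprintf("frame_trace: %s channel, %d frames @ %.3g s (%.1f s total)\n",
              x$channel, x$n_frames, x$frame_time, x$n_frames * x$frame_time))
  invisible(x)
}

#' Emit a noisy donor/acceptor FRET trace
#'
#' Converts ideal per-frame FRET values into donor and acceptor intensity
#' channels: acceptor = total x ideal + noise, donor = total x (1 - ideal)
#' + noise, floored at zero. With nonzero bleach rates, an acceptor bleach
#' time is drawn exponentially, after which energy transfer ceases (ideal
#' treated as 0, all intensity in the donor); after a donor bleach both
#' channels fall to noise-only background.
#'
#' @param ideal_fret Numeric vector of ideal FRET values in \[0, 1\]
#'   (e.g. from [integrate_frames()]).
#' @param model An [emission_model()].
#' @param seed Integer seed for reproducibility.
#' @param frame_time Frame time in seconds.
#' @return A `frame_trace` with `donor` and `acceptor` channels; bleach
#'   times (possibly `Inf`) recorded in `$meta`.
#' @export
emit_fret_trace <- function(ideal_fret, model = emission_model(),
                            seed = NULL, frame_time = 0.05) {
  if (any(ideal_fret < -1e-9 | ideal_fret > 1 + 1e-9))
    stop("ideal FRET values must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ideal_fret)
  sdn <- .noise_default(model, "fret")
  t_acc <- if (model$acceptor_bleach_rate > 0)
    stats::rexp(1, model$acceptor_bleach_rate) else Inf
  t_don <- if (model$donor_bleach_rate > 0)
    stats::rexp(1, model$donor_bleach_rate) else Inf
  tm <- (seq_len(n) - 1L) * frame_time
  eff <- ifelse(tm >= t_acc, 0, ideal_fret)
  total <- ifelse(tm >= t_don, 0, model$total_intensity)
  acceptor <- total * eff + stats::rnorm(n, 0, sdn)
  donor <- total * (1 - eff) + stats::rnorm(n, 0, sdn)
  # after donor bleach there is no excitation to transfer
  acceptor[tm >= t_don] <- stats::rnorm(sum(tm >= t_don), 0, sdn)
  .new_frame_trace("fret", frame_time,
                   donor = pmax(donor, 0), acceptor = pmax(acceptor, 0),
                   meta = list(total_intensity = model$total_intensity,
                               noise_sd = sdn, donor_bleach = t_don,
                               acceptor_bleach = t_acc))
}

#' Emit a noisy single-channel PIFE trace
#'
#' Converts ideal per-frame PIFE values (normalized, 1.0 = unbound) into a
#' raw Cy3 intensity trace: intensity = baseline x ideal + noise, floored
#' at zero, where the baseline is the emission model's `total_intensity`.
#' After a donor (Cy3) bleach the trace drops to noise-only background.
#' The pre-normalization baseline is stored in `$meta$baseline`.
#'
#' @param ideal_pife Numeric vector of ideal normalized PIFE values (>= 0).
#' @inheritParams emit_fret_trace
#' @return A `frame_trace` with a single `intensity` channel.
#' @export
emit_pife_trace <- function(ideal_pife, model = emission_model(),
                            seed = NULL, frame_time = 0.05) {
  if (any(ideal_pife < 0)) stop("ideal PIFE values must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ideal_pife)
  sdn <- .noise_default(model, "pife")
  t_don <- if (model$donor_bleach_rate > 0)
    stats::rexp(1, model$donor_bleach_rate) else Inf
  tm <- (seq_len(n) - 1L) * frame_time
  base <- ifelse(tm >= t_don, 0, model$total_intensity)
  intensity <- base * ideal_pife + stats::rnorm(n, 0, sdn)
  .new_frame_trace("pife", frame_time, intensity = pmax(intensity, 0),
                   meta = list(baseline = model$total_intensity,
                               noise_sd = sdn, donor_bleach = t_don))
}

#' Centered moving average with shrinking edges
#'
#' The smoothing applied to single-molecule traces before display and
#' idealization: a centered moving mean over an odd window (5 or 7 points
#' for 50 ms data). Near the edges the window shrinks symmetrically to the
#' available points so the output has the same length as the input.
#'
#' @param values Numeric vector.
#' @param window Odd integer window size, at most `length(values)`.
#' @return Numeric vector, same length as `values`.
#' @export
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), 5)
moving_average <- function(values, window = 5) {
  if (window %% 2 == 0) stop("window must be odd")
  n <- length(values)
  if (window > n) stop("window exceeds sequence length")
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Generate a synthetic single-molecule dataset
#'
#' Simulates `n_traces` independent molecules under a kinetic scheme and
#' pushes each ground-truth path through the camera model: frame
#' integration at `frame_time`, then noisy emission in the requested
#' channel. Ground-truth paths are retained for supervised evaluation and
#' a manifest records every parameter.
#'
#' @param preset Preset name for [make_preset()], or a [kinetic_scheme()].
#' @param n_traces Number of molecules (>= 1).
#' @param duration Per-trace duration in seconds.
#' @param model An [emission_model()].
#' @param seed Integer seed; per-trace sub-seeds are derived from it.
#' @param channel `"fret"` or `"pife"`.
#' @param frame_time Frame time in seconds.
#' @param association_rate Passed to [make_preset()] when `preset` is a
#'   name.
#' @return List of class `sm_dataset` with elements `traces` (list of
#'   `frame_trace`), `paths` (list of `state_path`), `scheme`, `manifest`.
#' @export
generate_dataset <- function(preset, n_traces, duration = 100,
                             model = emission_model(), seed = 1,
                             channel = c("fret", "pife"), frame_time = 0.05,
                             association_rate = 0.5) {
  channel <- match.arg(channel)
  stopifnot(n_traces >= 1)
  scheme <- if (inherits(preset, "kinetic_scheme")) preset
            else make_preset(preset, association_rate = association_rate)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L * n_traces)
  traces <- vector("list", n_traces)
  paths <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    p <- simulate_path(scheme, duration, seed = sub[2L * i - 1L])
    ideal <- integrate_frames(p, scheme, frame_time)
    traces[[i]] <- if (channel == "fret")
      emit_fret_trace(ideal$fret, model, seed = sub[2L * i], frame_time)
    else
      emit_pife_trace(ideal$pife, model, seed = sub[2L * i], frame_time)
    paths[[i]] <- p
  }
  manifest <- list(
    preset = if (is.character(preset)) preset else "custom",
    n_traces = n_traces, duration = duration, frame_time = frame_time,
    channel = channel, seed = seed,
    total_intensity = model$total_intensity,
    noise_sd = .noise_default(model, channel),
    donor_bleach_rate = model$donor_bleach_rate,
    acceptor_bleach_rate = model$acceptor_bleach_rate)
  structure(list(traces = traces, paths = paths, scheme = scheme,
                 manifest = manifest),
            class = "sm_dataset")
}

#' @export
print.sm_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "sm_dataset: %d %s traces, %g s @ %g s/frame (preset %s, seed %d)\n",
    m$n_traces, m$channel, m$duration, m$frame_time, m$preset, m$seed))
  invisible(x)
}
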