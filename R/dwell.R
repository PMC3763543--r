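#' Segment a trace into unbound/bound intervals by thresholding
#'
#' Classifies each frame as bound (observable above `threshold`) or
#' unbound, suppresses bound runs shorter than `min_frames`, and returns
#' the alternating intervals. The first and last intervals of a trace are
#' flagged censored: their entry or exit was not observed.
#'
#' @param trace A `frame_trace`, or a numeric vector of per-frame
#'   observable values (normalized PIFE or apparent FRET).
#' @param threshold Observable value separating unbound from bound; the
#'   usual choice is the midpoint between the unbound baseline and the
#'   lowest bound population.
#' @param min_frames Minimum bound-run length in frames (default 2);
#'   shorter excursions are treated as noise and merged into the
#'   surrounding unbound time.
#' @param frame_time Frame time in seconds (taken from the trace when one
#'   is supplied).
#' @param window Optional odd moving-average window applied before
#'   thresholding.
#' @return Data frame with columns `bound` (logical), `start_s`, `end_s`,
#'   `duration_s`, `n_frames`, `censored_left`, `censored_right`. Zero rows
#'   (with a warning) when the threshold lies outside the data range.
#' @export
segment_binding_events <- function(trace, threshold, min_frames = 2,
                                   frame_time = 0.05, window = NULL) {
  if (inherits(trace, "frame_trace")) {
    frame_time <- trace$frame_time
    v <- if (trace$channel == "fret") trace_fret(trace)
         else normalize_pife(trace$intensity, baseline = trace$meta$baseline)
  } else v <- as.numeric(trace)
  if (!is.null(window)) v <- moving_average(v, window)
  ok <- is.finite(v)
  if (threshold <= min(v[ok]) || threshold >= max(v[ok])) {
    warning("threshold ", threshold, " lies outside the data range; ",
            "no events segmented")
    return(data.frame(bound = logical(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      n_frames = integer(0), censored_left = logical(0),
                      censored_right = logical(0)))
  }
  bound <- v > threshold
  bound[!ok] <- FALSE
  r <- rle(bound)
  # suppress bound spikes shorter than min_frames
  drop <- r$values & r$lengths < min_frames
  if (any(drop)) {
    r$values[drop] <- FALSE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- data.frame(bound = r$values,
                    start_s = (starts - 1L) * frame_time,
                    end_s = ends * frame_time,
                    duration_s = r$lengths * frame_time,
                    n_frames = r$lengths)
  out$censored_left <- seq_len(nrow(out)) == 1L
  out$censored_right <- seq_len(nrow(out)) == nrow(out)
  out
}

#' Extract a dwell set for one state
#'
#' Collects the dwell durations of a given state from either a segmentation
#' (output of [segment_binding_events()]; `state_label` `"bound"` or
#' `"unbound"`) or an idealized path (see [viterbi()]); in the latter case
#' exit-destination labels are recorded. First/last intervals of each trace
#' are censored.
#'
#' @param x A segmentation data frame, an `idealized_path`, or a list of
#'   either.
#' @param state_label State whose dwells to collect.
#' @return Object of class `dwell_set`: data frame with `duration_s`,
#'   `censored`, `exit_to` (NA when unknown) and attribute `state_label`.
#' @export
extract_dwells <- function(x, state_label = "bound") {
  if (inherits(x, "idealized_path") || is.data.frame(x)) x <- list(x)
  rows <- lapply(x, function(el) {
    if (inherits(el, "idealized_path")) {
      seg <- el$segments
      keep <- seg$state == state_label
      if (!any(keep)) return(NULL)
      idx <- which(keep)
      nxt <- ifelse(idx < nrow(seg), seg$state[pmin(idx + 1L, nrow(seg))],
                    NA_character_)
      data.frame(duration_s = seg$duration_s[idx],
                 censored = idx == 1L | idx == nrow(seg),
                 exit_to = nxt, stringsAsFactors = FALSE)
    } else {
      keep <- if (state_label == "bound") el$bound
              else if (state_label == "unbound") !el$bound
              else stop("segmentations only carry 'bound'/'unbound' states")
      if (!any(keep)) return(NULL)
      idx <- which(keep)
      data.frame(duration_s = el$duration_s[idx],
                 censored = el$censored_left[idx] | el$censored_right[idx],
                 exit_to = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(duration_s = numeric(0), censored = logical(0),
                      exit_to = character(0), stringsAsFactors = FALSE)
  structure(out, state_label = state_label,
            class = c("dwell_set", "data.frame"))
}

#' Censored-exponential maximum-likelihood rate estimate
#'
#' Dissociation (or any first-order) rate from a set of dwell times with
#' right-censoring: k = (number of uncensored dwells) / (total observed
#' time), the MLE of an exponential rate under type-I censoring. Censored
#' dwells contribute observed time but no event, which removes the upward
#' bias a naive 1/mean estimate would suffer. The standard error is
#' k / sqrt(n_uncensored).
#'
#' @param dwells A `dwell_set`, or a numeric vector of durations (then
#'   taken fully uncensored unless `censored` is given).
#' @param censored Optional logical vector parallel to a numeric `dwells`.
#' @param min_events Minimum number of uncensored dwells required.
#' @param dead_time Detection floor in seconds. When > 0, dwells shorter
#'   than `dead_time` are discarded (they are unreliably detected) and the
#'   left-truncated MLE k = n / sum(tau - dead_time) is used, which is
#'   unbiased under memorylessness however many short events the
#'   segmentation missed. Default 0 (plain censored MLE).
#' @return A [rate_estimate()].
#' @export
#' @examples
#' fit_exponential_mle(rep(2.5, 20))   # k = 1/2.5 = 0.4
fit_exponential_mle <- function(dwells, censored = NULL, min_events = 10,
                                dead_time = 0) {
  if (inherits(dwells, "dwell_set")) {
    dur <- dwells$duration_s
    cen <- dwells$censored
  } else {
    dur <- as.numeric(dwells)
    cen <- if (is.null(censored)) rep(FALSE, length(dur)) else censored
  }
  if (any(dur <= 0)) stop("dwell durations must be positive")
  if (dead_time > 0) {
    keep <- dur >= dead_time
    dur <- dur[keep] - dead_time
    cen <- cen[keep]
  }
  n_unc <- sum(!cen)
  if (n_unc == 0) stop("all dwells are censored; no rate is identifiable")
  if (n_unc < min_events)
    stop("only ", n_unc, " uncensored dwells; need at least ", min_events)
  k <- n_unc / sum(dur)
  rate_estimate(k, stderr = k / sqrt(n_unc), n_events = n_unc)
}

.as_rate <- function(x) {
  if (inherits(x, "rate_estimate")) x
  else rate_estimate(x, stderr = 0, n_events = NA_integer_)
}

#' Fold change between two rate constants
#'
#' Ratio k_ref / k_test with first-order (delta-method) propagation of the
#' standard errors.
#'
#' @param k_ref,k_test Rates as [rate_estimate()] objects or bare numbers.
#' @return List with `value` and `stderr`.
#' @export
#' @examples
#' fold_change(0.40, 0.10)$value   # 4
fold_change <- function(k_ref, k_test) {
  a <- .as_rate(k_ref); b <- .as_rate(k_test)
  if (a$value <= 0 || b$value <= 0) stop("rates must be positive")
  v <- a$value / b$value
  se <- v * sqrt((a$stderr / a$value)^2 + (b$stderr / b$value)^2)
  list(value = v, stderr = se)
}

#' Free-energy difference from a ratio of dissociation rates
#'
#' Interprets a slower dissociation rate as a more stable complex:
#' delta G = R T ln(k_fast / k_slow), with
#' R = 1.987 x 10^-3 kcal mol^-1 K^-1. Standard errors of the rates are
#' propagated to the energy.
#'
#' @param k_fast,k_slow Rates in s^-1 ([rate_estimate()] or numeric);
#'   `k_fast` is the reference (less stable) complex.
#' @param temperature Absolute temperature in K (default 295.15 K, room
#'   temperature).
#' @return Object of class `energy_difference`: `value` and `stderr` in
#'   kcal/mol, plus `temperature`.
#' @export
#' @examples
#' delta_g(0.40, 0.10)$value   # ~0.81 kcal/mol
delta_g <- function(k_fast, k_slow, temperature = 295.15) {
  a <- .as_rate(k_fast); b <- .as_rate(k_slow)
  if (a$value <= 0 || b$value <= 0) stop("rates must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  R <- 1.987e-3   # kcal mol^-1 K^-1
  v <- R * temperature * log(a$value / b$value)
  se <- R * temperature *
    sqrt((a$stderr / a$value)^2 + (b$stderr / b$value)^2)
  structure(list(value = v, stderr = se, temperature = temperature),
            class = "energy_difference")
}

#' @export
print.energy_difference <- function(x, ...) {
  cat(sprintf("delta G = %.3g +/- %.2g kcal/mol at %.2f K\n",
              x$value, x$stderr, x$temperature))
  invisible(x)
}
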