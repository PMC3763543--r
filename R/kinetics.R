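#' Define a kinetic scheme for polymerase-DNA binding
#'
#' A kinetic scheme is a continuous-time Markov chain over a small set of
#' binding states (unbound DNA plus one or more bound orientations such as
#' the pol site, the proofreading exo site, or the intermediate site), each
#' carrying the fluorescence observables it produces: an apparent FRET
#' efficiency in \[0, 1\] and a PIFE level normalized to 1.0 for unbound DNA.
#'
#' @param states Character vector of state labels. Must include
#'   `"unbound"`.
#' @param fret Numeric vector of per-state apparent FRET levels in
#'   \[0, 1\]; the unbound state must have FRET 0.
#' @param pife Numeric vector of per-state PIFE levels (>= 0); the unbound
#'   state must have PIFE 1.0.
#' @param rates Square numeric matrix of transition rates in s^-1;
#'   entry (i, j) is the rate from state i to state j. The diagonal is
#'   ignored and stored as zero.
#' @param initial Label of the state occupied at time zero. Defaults to
#'   `"unbound"`.
#'
#' @return An object of class `kinetic_scheme`: a list with elements
#'   `states`, `fret`, `pife`, `rates` (dimnamed matrix) and `initial`.
#' @seealso [make_preset()] for the catalog of schemes matching the
#'   constructs studied experimentally, [simulate_path()].
#' @export
#' @examples
#' sc <- kinetic_scheme(
#'   states = c("unbound", "pol"),
#'   fret = c(0, 0.59), pife = c(1, 2),
#'   rates = matrix(c(0, 0.5, 0.4, 0), 2, 2, byrow = TRUE)
#' )
#' sc
kinetic_scheme <- function(states, fret, pife, rates, initial = "unbound") {
  states <- as.character(states)
  k <- length(states)
  rates <- as.matrix(rates)
  dimnames(rates) <- list(states, states)
  diag(rates) <- 0
  obj <- structure(
    list(states = states,
         fret = stats::setNames(as.numeric(fret), states),
         pife = stats::setNames(as.numeric(pife), states),
         rates = rates,
         initial = initial),
    class = "kinetic_scheme")
  validate_scheme(obj)
  obj
}

#' Validate a kinetic scheme
#'
#' Checks the structural invariants: nonnegative off-diagonal rates, FRET
#' levels in \[0, 1\], the unbound state at FRET 0 / PIFE 1.0, and at least
#' one state reachable from the initial state when any rate is positive.
#'
#' @param scheme A [kinetic_scheme()].
#' @return The scheme, invisibly; stops with a message otherwise.
#' @export
validate_scheme <- function(scheme) {
  if (!inherits(scheme, "kinetic_scheme"))
    stop("not a kinetic_scheme object")
  k <- length(scheme$states)
  if (anyDuplicated(scheme$states))
    stop("invalid scheme: duplicated state labels")
  if (length(scheme$fret) != k || length(scheme$pife) != k)
    stop("invalid scheme: fret/pife levels must match the number of states")
  if (!identical(dim(scheme$rates), c(k, k)))
    stop("invalid scheme: rate matrix must be ", k, " x ", k)
  if (any(!is.finite(scheme$rates)) || any(scheme$rates < 0))
    stop("invalid scheme: rates must be finite and nonnegative")
  if (any(scheme$fret < 0 | scheme$fret > 1))
    stop("invalid scheme: FRET levels must lie in [0, 1]")
  if (any(scheme$pife < 0))
    stop("invalid scheme: PIFE levels must be nonnegative")
  if (!"unbound" %in% scheme$states)
    stop("invalid scheme: an 'unbound' state is required")
  if (scheme$fret[["unbound"]] != 0)
    stop("invalid scheme: unbound state must have FRET 0")
  if (scheme$pife[["unbound"]] != 1)
    stop("invalid scheme: unbound state must have PIFE 1.0")
  if (!scheme$initial %in% scheme$states)
    stop("invalid scheme: initial state '", scheme$initial, "' not in states")
  invisible(scheme)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", length(x$states), "states\n")
  lev <- data.frame(state = x$states, fret = unname(x$fret),
                    pife = unname(x$pife))
  print(lev, row.names = FALSE)
  cat("Rates (s^-1), initial state:", x$initial, "\n")
  print(x$rates)
  invisible(x)
}

#' Simulate an exact state path of a kinetic scheme
#'
#' Draws one realization of the continuous-time Markov chain by the
#' Gillespie algorithm: the dwell in state i is exponential with rate equal
#' to the sum of outgoing rates from i, and the destination is drawn with
#' probability proportional to the individual rates. The path is truncated
#' at `duration`; the final segment is therefore right-censored.
#'
#' @param scheme A [kinetic_scheme()].
#' @param duration Total trajectory duration in seconds (> 0).
#' @param seed Integer seed; identical seed and scheme give an identical
#'   event sequence.
#' @return A `state_path`: a data frame with columns `state`, `entry`,
#'   `exit` (seconds), contiguous segments covering \[0, duration\], with
#'   attribute `total_duration`.
#' @export
#' @examples
#' sc <- make_preset("unmodified_templating")
#' p <- simulate_path(sc, duration = 100, seed = 1)
#' head(p)
simulate_path <- function(scheme, duration, seed = NULL) {
  validate_scheme(scheme)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  exit_rate <- rowSums(scheme$rates)
  k <- length(scheme$states)
  cur <- match(scheme$initial, scheme$states)
  t0 <- 0
  st <- integer(256L); en <- numeric(256L); ex <- numeric(256L)
  n <- 0L
  repeat {
    r <- exit_rate[cur]
    dwell <- if (r > 0) stats::rexp(1L, r) else Inf
    t1 <- t0 + dwell
    n <- n + 1L
    if (n > length(st)) {            # grow buffers geometrically
      st <- c(st, integer(length(st)))
      en <- c(en, numeric(length(en)))
      ex <- c(ex, numeric(length(ex)))
    }
    st[n] <- cur; en[n] <- t0
    if (t1 >= duration) { ex[n] <- duration; break }
    ex[n] <- t1
    cur <- sample.int(k, 1L, prob = scheme$rates[cur, ])
    t0 <- t1
  }
  path <- data.frame(state = scheme$states[st[seq_len(n)]],
                     entry = en[seq_len(n)], exit = ex[seq_len(n)],
                     stringsAsFactors = FALSE)
  structure(path, total_duration = duration, class = c("state_path", "data.frame"))
}

# Catalog of experimentally characterized constructs. FRET/PIFE levels and
# dissociation rates are the measured values for each primer-template;
# association is pseudo-first-order and not separately resolved, so it is a
# free parameter (default 0.5 s^-1, giving several binding events per 100 s).
.preset_catalog <- function(association_rate) {
  a <- association_rate
  two_state <- function(bound, fret, pife, k_off) {
    r <- matrix(0, 2, 2)
    r[1, 2] <- a; r[2, 1] <- k_off
    kinetic_scheme(c("unbound", bound), c(0, fret), c(1, pife), r)
  }
  list(
    # templating-position constructs: single pol-site bound state
    unmodified_templating = function()
      two_state("pol", 0.59, 2.0, 0.40),
    af_templating = function()
      two_state("pol", 0.59, 2.0, 0.10),
    aaf_templating = function()
      two_state("pol", 0.59, 2.0, 0.07),
    # primer extended one position (n+1 constructs)
    unmodified_n1 = function()
      two_state("pol", 0.40, 1.2, 0.40),
    af_n1 = function()
      two_state("intermediate", 0.51, 1.9, 0.10),
    aaf_n1 = function() {
      st <- c("unbound", "intermediate", "exo")
      r <- matrix(0, 3, 3, dimnames = list(st, st))
      r["unbound", "intermediate"] <- a
      r["intermediate", "unbound"] <- 0.07   # AAF binary-complex k_off
      r["intermediate", "exo"] <- 2.1        # k_exo
      r["exo", "intermediate"] <- 4.3        # k_int
      kinetic_scheme(st, c(0, 0.50, 0.63), c(1, 1.9, 1.9), r)
    },
    # mismatch controls for exo- and intermediate-site signatures
    double_mismatch = function()
      two_state("exo", 0.60, 1.8, 0.40),
    single_mismatch = function()
      two_state("intermediate", 0.50, 1.9, 0.40),
    # AF-adducted ternary complex with the next correct dNTP: pol-site
    # binding restored but strongly destabilized
    af_ternary = function()
      two_state("pol", 0.40, 1.2, 2.5)
  )
}

#' Kinetic-scheme presets for the characterized DNA constructs
#'
#' Returns a [kinetic_scheme()] whose emission levels and dissociation
#' rates match the measured values for a given primer-template construct.
#' The catalog covers the unmodified, AF- and AAF-adducted templates with
#' the adduct at the templating position or across from the primer terminus
#' (n+1), the single/double mismatch controls, and the AF ternary complex.
#'
#' The association (unbound -> bound) rate is pseudo-first-order and depends
#' on enzyme concentration; it is a free parameter with default 0.5 s^-1.
#' For the AF n+1 construct only the intermediate site is populated; the
#' `af_n1_hidden_exo` argument optionally adds a spectroscopically silent
#' exo state (same FRET/PIFE as the intermediate) exchanging at the given
#' rates, for exploring whether fast exchange with an unresolved exo state
#' is compatible with the single observed population.
#'
#' @param name One of `"unmodified_templating"`, `"af_templating"`,
#'   `"aaf_templating"`, `"unmodified_n1"`, `"af_n1"`, `"aaf_n1"`,
#'   `"double_mismatch"`, `"single_mismatch"`, `"af_ternary"`.
#' @param association_rate Pseudo-first-order binding rate in s^-1.
#' @param af_n1_hidden_exo Optional numeric of length 2,
#'   `c(to_exo, back)` in s^-1; only used for `name = "af_n1"`.
#' @return A [kinetic_scheme()].
#' @export
#' @examples
#' make_preset("aaf_n1")
make_preset <- function(name, association_rate = 0.5,
                        af_n1_hidden_exo = NULL) {
  catalog <- .preset_catalog(association_rate)
  if (!is.character(name) || length(name) != 1L || !name %in% names(catalog))
    stop("unknown preset '", name, "'; available presets: ",
         paste(names(catalog), collapse = ", "))
  sc <- catalog[[name]]()
  if (name == "af_n1" && !is.null(af_n1_hidden_exo)) {
    stopifnot(length(af_n1_hidden_exo) == 2L, all(af_n1_hidden_exo >= 0))
    st <- c("unbound", "intermediate", "exo")
    r <- matrix(0, 3, 3, dimnames = list(st, st))
    r["unbound", "intermediate"] <- association_rate
    r["intermediate", "unbound"] <- 0.10
    r["intermediate", "exo"] <- af_n1_hidden_exo[1]
    r["exo", "intermediate"] <- af_n1_hidden_exo[2]
    # the hidden exo state is spectroscopically indistinguishable from the
    # intermediate: same FRET/PIFE levels
    sc <- kinetic_scheme(st, c(0, 0.51, 0.51), c(1, 1.9, 1.9), r)
  }
  sc
}

#' List the available kinetic-scheme presets
#' @return Character vector of preset names accepted by [make_preset()].
#' @export
preset_names <- function() names(.preset_catalog(0.5))

#' Add a direct exo-site dissociation channel to a scheme
#'
#' Augments a scheme containing `unbound`, `intermediate` and `exo` states
#' with an exo -> unbound rate chosen so that, over many binding events,
#' the expected fraction of dissociations whose terminal bound state is exo
#' equals `direct_fraction`. The remaining fraction dissociates from the
#' intermediate site.
#'
#' @details
#' With a = k(intermediate -> exo), b = k(exo -> intermediate),
#' c = k(intermediate -> unbound) and unknown d = k(exo -> unbound), a
#' binding event starts in the intermediate (association is
#' unbound -> intermediate). In the embedded jump chain the probability q
#' that the event eventually dissociates from exo satisfies
#'   q = a/(a+c) * ( d/(b+d) + b/(b+d) * q ),
#' (first jump to exo, then either leave directly or return and recurse),
#' which solves to
#'   q = a d / ( (a+c)(b+d) - a b ).
#' Setting q = f and solving for d gives
#'   d = f b c / ( a - f (a + c) ),
#' valid for f < a/(a+c), the supremum reached as d -> Inf. For c = 0 every
#' dissociation is necessarily from exo once d > 0; only f = 1 is feasible
#' and d is set to b to keep the exo dwell comparable to the exchange time.
#'
#' @param scheme A [kinetic_scheme()] with states `unbound`,
#'   `intermediate`, `exo` and zero (or to-be-replaced) exo -> unbound rate.
#' @param direct_fraction Target fraction in \[0, 1\] of dissociation
#'   events that occur directly from the exo site.
#' @return The augmented [kinetic_scheme()].
#' @export
#' @examples
#' sc <- add_direct_dissociation(make_preset("aaf_n1"), 0.6)
#' sc$rates["exo", "unbound"]
add_direct_dissociation <- function(scheme, direct_fraction) {
  validate_scheme(scheme)
  f <- direct_fraction
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("direct_fraction must be a single value in [0, 1]")
  need <- c("unbound", "intermediate", "exo")
  if (!all(need %in% scheme$states))
    stop("scheme must contain states: ", paste(need, collapse = ", "))
  a <- scheme$rates["intermediate", "exo"]
  b <- scheme$rates["exo", "intermediate"]
  cc <- scheme$rates["intermediate", "unbound"]
  if (a <= 0) stop("scheme has no intermediate -> exo transition")
  if (f == 0) {
    d <- 0
  } else if (cc == 0) {
    if (f < 1)
      stop("with no intermediate -> unbound rate every dissociation is ",
           "from exo; only direct_fraction = 1 is feasible")
    d <- b
  } else {
    fmax <- a / (a + cc)
    if (f >= fmax)
      stop(sprintf(
        "direct_fraction %.3f is infeasible for this scheme: the maximum ",
        f), sprintf(
        "terminal-exo fraction is a/(a+c) = %.3f (approached as the direct ",
        fmax), "rate grows without bound)")
    d <- f * b * cc / (a - f * (a + cc))
  }
  scheme$rates["exo", "unbound"] <- d
  scheme
}

#' Construct a rate estimate
#'
#' Container for a first-order rate constant with its standard error and
#' the number of (uncensored) events that informed it.
#'
#' @param value Rate in s^-1.
#' @param stderr Standard error in s^-1.
#' @param n_events Number of events.
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(value, stderr = NA_real_, n_events = NA_integer_) {
  if (!is.na(n_events) && n_events > 0 && value <= 0)
    stop("rate must be positive when events were observed")
  if (!is.na(stderr) && stderr < 0) stop("stderr must be nonnegative")
  structure(list(value = as.numeric(value), stderr = as.numeric(stderr),
                 n_events = as.integer(n_events)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.4g +/- %.3g s^-1 (n = %d events)\n",
              x$value, x$stderr, x$n_events))
  invisible(x)
}

#' Write a kinetic scheme to a YAML file
#'
#' Schemes serialize to a plain-text YAML mapping (states, per-state fret
#' and pife levels, rates as nested from/to maps, initial state). Numeric
#' values are written with 17 significant digits so that reading the file
#' back reproduces the scheme exactly.
#'
#' @param scheme A [kinetic_scheme()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  num <- function(x) as.character(sprintf("%.17g", x))
  rts <- lapply(seq_along(scheme$states), function(i) {
    row <- scheme$rates[i, ]
    as.list(stats::setNames(num(row), scheme$states))
  })
  names(rts) <- scheme$states
  obj <- list(states = as.list(scheme$states),
              fret = as.list(stats::setNames(num(scheme$fret), scheme$states)),
              pife = as.list(stats::setNames(num(scheme$pife), scheme$states)),
              rates = rts,
              initial = scheme$initial)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a kinetic scheme from a YAML file
#' @param path File written by [write_scheme()] (or hand-authored in the
#'   same layout).
#' @return A [kinetic_scheme()].
#' @export
read_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  states <- unlist(obj$states)
  k <- length(states)
  r <- matrix(0, k, k, dimnames = list(states, states))
  for (i in states) for (j in states)
    r[i, j] <- as.numeric(obj$rates[[i]][[j]])
  kinetic_scheme(states,
                 fret = as.numeric(unlist(obj$fret[states])),
                 pife = as.numeric(unlist(obj$pife[states])),
                 rates = r,
                 initial = obj$initial)
}
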