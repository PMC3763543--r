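# Small schemes and hand-built paths used across test files.

two_state_scheme <- function(kon = 0.5, koff = 0.4, bound = "bound",
                             fret = 0.59, pife = 2.0) {
  r <- matrix(c(0, kon, koff, 0), 2, 2, byrow = TRUE)
  kinetic_scheme(c("unbound", bound), c(0, fret), c(1, pife), r)
}

# state_path from explicit segments (state labels + durations in seconds)
manual_path <- function(states, durations) {
  exit <- cumsum(durations)
  entry <- c(0, exit[-length(exit)])
  structure(data.frame(state = states, entry = entry, exit = exit,
                       stringsAsFactors = FALSE),
            total_duration = exit[length(exit)],
            class = c("state_path", "data.frame"))
}

# idealized_path from per-frame state indices and observations
manual_ipath <- function(frames, obs, state_names, frame_time = 0.05) {
  polshuttle:::.new_idealized_path(as.integer(frames), obs, state_names,
                                   frame_time)
}
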