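#!/usr/bin/env Rscript
# Stage 4: HMM idealization of the AAF n+1 construct.
#
# The distinctive behaviour of the AAF-modified n+1 primer-template is
# intramolecular shuttling between the intermediate (~0.50 FRET) and exo
# (~0.63 FRET) sites. This stage fits a 3-state Gaussian-emission HMM to
# 120 simulated trajectories (initialized from a mixture fit of the pooled
# frames, i.e. without using the generator truth), idealizes them by
# Viterbi decoding, estimates the exchange rates with the
# resolution-corrected dwell estimator, and tallies the transition density
# classes.

library(polshuttle)
dir.create("results", showWarnings = FALSE)

ds <- generate_dataset("aaf_n1", n_traces = 120, duration = 100, seed = 501)
obs <- lapply(ds$traces, trace_fret)
init <- hmm_init_from_traces(obs, n_states = 3, seed = 1)
fit <- fit_hmm(obs, n_states = 3, init = init, seed = 1, restarts = 1,
               max_iter = 200)
print(fit)
ips <- lapply(obs, function(o) viterbi(fit, o))

est <- rates_from_idealization(ips)                      # corrected
naive <- rates_from_idealization(ips, method = "naive")  # diagnostic
kA <- rates_from_transition_matrix(fit)                  # diagnostic
rates <- data.frame(
  transition = c("intermediate->exo (k_exo)", "exo->intermediate (k_int)",
                 "intermediate->unbound (k_off)"),
  true = c(2.1, 4.3, 0.07),
  corrected = round(c(est$rates["intermediate", "exo"],
                      est$rates["exo", "intermediate"],
                      est$rates["intermediate", "unbound"]), 3),
  naive = round(c(naive$rates["intermediate", "exo"],
                  naive$rates["exo", "intermediate"],
                  naive$rates["intermediate", "unbound"]), 3),
  matrix_log = round(c(kA["intermediate", "exo"],
                       kA["exo", "intermediate"],
                       kA["intermediate", "unbound"]), 3))
print(rates, row.names = FALSE)
cat("\nThe naive dwell/count estimator underestimates both exchange rates",
    "\n(sub-frame dwells are missed at 50 ms resolution); the corrected",
    "\nestimator recovers them.\n\n")

td <- transition_density(ips)
cat("Transition density classes (counts):\n")
print(td$class_counts)
direct <- transition_class_fraction(td, c("unbound", "exo"),
                                    c("exo", "unbound"))
cat(sprintf(
  "\nApparent direct unbound<->exo transitions: %.1f%% of %d transitions\n",
  100 * direct, td$total))
cat("-> association to the exo site passes through the intermediate.\n")

write.table(rates, "results/shuttling_rates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(as.data.frame(td$class_counts), "results/tdp_classes.tsv",
            sep = "\t", quote = FALSE)
cat("Wrote results/shuttling_rates.tsv and results/tdp_classes.tsv\n")
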