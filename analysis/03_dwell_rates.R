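#!/usr/bin/env Rscript
# Stage 3: dissociation kinetics and binding free energies.
#
# Simulates PIFE trajectories for the templating-base constructs and the
# AF ternary complex, segments binding events by thresholding the
# normalized PIFE at the unbound/bound midpoint, and estimates k_off by
# censored-exponential maximum likelihood. Rate ratios are converted to
# binding free-energy differences via dG = RT ln(k_ref / k_test).

library(polshuttle)
dir.create("results", showWarnings = FALSE)

# The PIFE-2.0 constructs separate from baseline by ~5 noise sd per raw
# frame, so no smoothing is needed; the ternary complex (PIFE 1.2) needs
# the five-point moving average, and its dead time is extended by one
# frame for the edge blurring the smoothing introduces. In both cases the
# left-truncated MLE removes the bias from binding events shorter than
# the detection floor.
koff_for <- function(nm, seed, window = NULL, dead_time = 0.10,
                     n_traces = 80, duration = 100) {
  sc <- make_preset(nm)
  ds <- generate_dataset(nm, n_traces = n_traces, duration = duration,
                         channel = "pife", seed = seed)
  thr <- mean(c(1, max(sc$pife)))   # unbound/bound midpoint
  segs <- lapply(ds$traces, segment_binding_events, threshold = thr,
                 min_frames = 2, window = window)
  fit_exponential_mle(extract_dwells(segs, "bound"), dead_time = dead_time)
}

ks <- list(
  unmodified = koff_for("unmodified_templating", 301),
  af = koff_for("af_templating", 302),
  aaf = koff_for("aaf_templating", 303),
  af_ternary = koff_for("af_ternary", 304, window = 5, dead_time = 0.15,
                        n_traces = 60)
)
tab <- data.frame(
  construct = names(ks),
  k_off_true = c(0.40, 0.10, 0.07, 2.5),
  k_off_fit = sapply(ks, function(e) round(e$value, 3)),
  stderr = sapply(ks, function(e) signif(e$stderr, 2)),
  n_events = sapply(ks, function(e) e$n_events))
print(tab, row.names = FALSE)

fc_af <- fold_change(ks$unmodified, ks$af)
fc_aaf <- fold_change(ks$unmodified, ks$aaf)
g_af <- delta_g(ks$unmodified, ks$af)
g_aaf <- delta_g(ks$unmodified, ks$aaf)
energies <- data.frame(
  comparison = c("unmodified_vs_af", "unmodified_vs_aaf"),
  fold_change = round(c(fc_af$value, fc_aaf$value), 2),
  ddG_kcal_mol = round(c(g_af$value, g_aaf$value), 2),
  ddG_stderr = round(c(g_af$stderr, g_aaf$stderr), 2))
print(energies, row.names = FALSE)
cat(sprintf(
  "\nTemplating-base adducts stabilize the binary complex by %.1f (AF) and %.1f (AAF) kcal/mol.\n",
  g_af$value, g_aaf$value))

write.table(tab, "results/koff_estimates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(energies, "results/free_energies.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Wrote results/koff_estimates.tsv and results/free_energies.tsv\n")
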