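#!/usr/bin/env Rscript
# Stage 2: population analysis (FRET/PIFE histograms + Gaussian mixtures).
#
# For each construct, simulates >100 trajectories at the measured kinetic
# parameters, pools bound-state frames (selected by generator ground
# truth), and fits Gaussian mixtures to the apparent-FRET and normalized
# PIFE distributions. The AAF-modified n+1 construct resolves two bound
# FRET populations (intermediate ~0.50 and exo ~0.63); every other
# construct is single-population.

library(polshuttle)
dir.create("results", showWarnings = FALSE)

analyze_preset <- function(nm, seed) {
  sc <- make_preset(nm)
  bound_states <- setdiff(sc$states, "unbound")
  n_comp <- if (nm == "aaf_n1") 2 else 1
  ds <- generate_dataset(nm, n_traces = 120, duration = 60, seed = seed)
  bound_fret <- unlist(lapply(seq_along(ds$traces), function(i) {
    occ <- frame_occupancy(ds$paths[[i]], 0.05, states = sc$states)
    f <- trace_fret(ds$traces[[i]])
    f[occ[, "unbound"] < 0.5]
  }))
  fit <- fit_population_mixture(bound_fret, n_comp, seed = 1)
  dsp <- generate_dataset(nm, n_traces = 120, duration = 60,
                          channel = "pife", seed = seed + 1)
  bound_pife <- unlist(lapply(seq_along(dsp$traces), function(i) {
    occ <- frame_occupancy(dsp$paths[[i]], 0.05, states = sc$states)
    z <- normalize_pife(dsp$traces[[i]]$intensity,
                        baseline = dsp$traces[[i]]$meta$baseline)
    z[occ[, "unbound"] < 0.5]
  }))
  data.frame(preset = nm,
             nominal_fret = paste(sprintf("%.2f", sc$fret[bound_states]),
                                  collapse = "/"),
             fitted_fret = paste(sprintf("%.3f", fit$means),
                                 collapse = "/"),
             nominal_pife = paste(sprintf("%.1f", sc$pife[bound_states]),
                                  collapse = "/"),
             fitted_pife = sprintf("%.2f", mean(bound_pife)),
             n_bound_frames = length(bound_fret))
}

presets <- c("unmodified_templating", "af_templating", "aaf_templating",
             "unmodified_n1", "af_n1", "aaf_n1", "double_mismatch",
             "single_mismatch")
tab <- do.call(rbind, lapply(seq_along(presets), function(i)
  analyze_preset(presets[i], seed = 200 + 2 * i)))
print(tab, row.names = FALSE)
write.table(tab, "results/population_fits.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# The fast-exchange control: if the ~0.50 FRET state were rapid pol/exo
# shuttling, PIFE would average pol (1.2) and exo (1.8) to ~1.5 — not the
# observed 1.9.
cat(sprintf("\nFast-exchange PIFE prediction (pol 1.2 / exo 1.8): %.2f\n",
            fast_exchange_average(c(1.2, 1.8), c(0.5, 0.5))))
cat("Wrote results/population_fits.tsv\n")
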