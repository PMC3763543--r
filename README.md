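# polshuttle

Single-molecule kinetics of DNA polymerase binding orientations on
carcinogen-adducted DNA.

## The problem

High-fidelity DNA polymerases such as the Klenow fragment (KF) of
*E. coli* DNA polymerase I stall at bulky carcinogenic adducts —
2-aminofluorene (AF-dG) and *N*-acetyl-2-aminofluorene (AAF-dG) at
guanine C8. Single-molecule FRET (Cy3 on the DNA template, Cy5 on the
polymerase; apparent efficiency E = I_A / (I_A + I_D)) and
protein-induced fluorescence enhancement (PIFE, Cy3 intensity normalized
to 1.0 for unbound DNA) report, frame by frame at ~50 ms resolution,
where and how long the polymerase binds a primer–template:

* pol site binding — FRET 0.59 / PIFE 2.0 with the adduct at the
  templating base; FRET 0.4 / PIFE 1.2 one position downstream,
* exo (proofreading) site binding — FRET ~0.60–0.63 / PIFE 1.8–1.9,
* an **intermediate site** — FRET ~0.50 / PIFE 1.9 — induced when an
  adduct (or a mismatch) sits across from the primer terminus.

`polshuttle` re-implements, as a tested R package plus a scripted
analysis, the quantitative machinery behind those findings:

* **Kinetic schemes and exact simulation** — continuous-time Markov
  chains over {unbound, pol, intermediate, exo} with per-state FRET/PIFE
  levels, realized by the Gillespie algorithm; a preset catalog carries
  the measured parameters of each DNA construct
  (`make_preset("aaf_n1")` etc.).
* **Camera model** — exposure-time integration over 50 ms frames,
  additive Gaussian detection noise calibrated to the ±0.02 FRET /
  ±0.1 PIFE experimental errors, optional photobleaching, and the
  5/7-point moving average.
* **Population analysis** — apparent-FRET / normalized-PIFE histograms
  and 1-D Gaussian-mixture EM (the AAF n+1 construct resolves two bound
  populations at 0.50 and 0.63).
* **Dwell-time kinetics** — threshold segmentation, censored- and
  left-truncated-exponential maximum likelihood for k_off, fold changes,
  and binding free energies ΔΔG = RT ln(k_fast / k_slow).
* **HMM idealization** — shared-emission Gaussian hidden Markov model
  (Baum–Welch in C++ via Rcpp), Viterbi decoding, transition density
  plots, and a resolution-corrected estimator for the
  intermediate ⇄ exo shuttling rates (k_exo = 2.1 s⁻¹,
  k_int = 4.3 s⁻¹).
* **Pathway inference** — pause-length distributions for exo-site
  association and dissociation, simulated through the full
  camera + idealization pipeline, and a grid search over the fraction of
  dissociations occurring directly from the exo site (the 60 % / 40 %
  split, via `add_direct_dissociation()` whose exo→unbound rate is set
  in closed form from the embedded-jump-chain branching ratios).

No experimental trace archive exists for this system, so the synthetic
generator *is* the data source: every analysis runs on traces simulated
at the published parameter values and is judged by parameter recovery.

## Worked example

Simulate the AAF-modified n+1 construct, idealize blind, and estimate
the shuttling rates:

```r
library(polshuttle)

ds   <- generate_dataset("aaf_n1", n_traces = 120, duration = 100, seed = 501)
obs  <- lapply(ds$traces, trace_fret)
init <- hmm_init_from_traces(obs, n_states = 3, seed = 1)
fit  <- fit_hmm(obs, n_states = 3, init = init, seed = 1)
fit
#> HMM fit: 3 states, 120 traces / 240000 frames, loglik 466138.5
#>         state       mean         sd
#>       unbound 0.01471101 0.02885232
#>  intermediate 0.50246126 0.02444347
#>           exo 0.62401227 0.02614956

ips <- lapply(obs, function(o) viterbi(fit, o))
rates_from_idealization(ips)$rates[c("intermediate", "exo"),
                                   c("intermediate", "exo")]
#>              intermediate      exo
#> intermediate     0.000000 2.104836
#> exo              4.218928 0.000000
```

The recovered emission means sit within ±0.02 of the generating levels
(0, 0.50, 0.63) and the exchange rates within a few percent of the
generating k_exo = 2.1 s⁻¹ and k_int = 4.3 s⁻¹. Free energies follow
directly from rate ratios:

```r
delta_g(0.40, 0.10, temperature = 295)
#> delta G = 0.813 +/- 0 kcal/mol at 295.00 K
```

The numbered drivers under `analysis/` run the complete workflow
(`01_simulate.R` … `05_pathway.R`), each printing what it finds and
writing its tables under `results/`.

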