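---
title: "Models and methods behind polshuttle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polshuttle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the kinetic model, the camera model, the estimators, and the numerical
and design choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The kinetic model

Polymerase–DNA binding is modeled as a continuous-time Markov chain over
a small set of states: unbound DNA plus one or more bound orientations
(pol site, proofreading exo site, and the intermediate site seen with
adducted or mismatched primer termini). Each state carries two
observables — an apparent FRET efficiency in [0, 1] and a PIFE level
normalized to 1.0 for unbound DNA. Dwell times are exponential; the dwell
in state *i* has rate equal to the sum of the outgoing rates, and the
jump destination is drawn in proportion to the individual rates
(`simulate_path()` is an exact Gillespie realization, truncated and
right-censored at the trace duration).

The preset catalog (`make_preset()`) encodes one scheme per DNA
construct with the measured emission levels and dissociation rates:
k_off = 0.40 s⁻¹ (unmodified templating base), 0.10 s⁻¹ (AF), 0.07 s⁻¹
(AAF), 2.5 s⁻¹ (AF ternary complex), and the AAF n+1 construct with
states {unbound, intermediate, exo}, FRET {0, 0.50, 0.63}, and exchange
rates k_exo = 2.1 s⁻¹ (intermediate→exo), k_int = 4.3 s⁻¹ (exo→intermediate).

Three parameters are not fixed by measurement and were set once:

* **Association rate, 0.5 s⁻¹** (pseudo-first-order; depends on enzyme
  concentration). The choice puts several binding events into a 100 s
  trace so that dwell and pathway statistics — the quantities of
  interest — accumulate; association kinetics themselves are never an
  analysis target.
* **Intermediate-site dissociation** uses the binary-complex k_off of
  the matching construct (e.g. 0.07 s⁻¹ for AAF n+1), since the dwell
  analysis pools bound time regardless of orientation.
* **n+1 presets omit unpopulated states**: the AF n+1 scheme has only
  the intermediate bound state and AAF n+1 has intermediate + exo,
  because no pol-site population is observed for those constructs.
  Whether the AF n+1 intermediate secretly exchanges with an optically
  identical exo state cannot be decided from the data; the preset
  exposes that variant through `af_n1_hidden_exo` (a two-rate argument
  adding a spectroscopically silent exo state) without privileging it.

### Direct dissociation in closed form

`add_direct_dissociation(scheme, f)` augments the three-state scheme
with an exo→unbound rate *d* such that a fraction *f* of dissociation
events terminates in the exo state. With a = k(I→X), b = k(X→I),
c = k(I→U), the embedded jump chain gives the terminal-exo probability
q = a d / ((a+c)(b+d) − a b), hence

d = f·b·c / (a − f·(a + c)),

valid for f < a/(a+c); larger targets are infeasible at finite *d* and
are rejected (with c = 0 only f = 1 is meaningful and *d* defaults to
*b*). A Monte-Carlo test verifies the closed form at f = 0.6.

One subtlety worth recording: the *pause-length distribution* conditions
on binding events that reach the exo site, so its zero-pause share is
f·(a+c)/a, slightly above *f* (for the AAF n+1 parameters, 0.62 vs
0.60). The unconditional terminal-exo fraction equals *f* exactly; both
are tested. Model fitting is unaffected because observed and simulated
distributions are conditioned identically.

## The camera model

Real traces are camera integrals: frame *j* reports the time-weighted
mean of the emission level over the half-open interval
[jΔt, (j+1)Δt), Δt = 50 ms by default; a partial final frame is
discarded (`integrate_frames()`). This single mechanism produces the
artifacts that motivate the simulation-based model comparison: dwells
shorter than a frame vanish, and transitions land on boundary frames as
spurious intermediate levels.

Detection noise is additive Gaussian per channel. The experimental
uncertainty statements (±0.02 FRET, ±0.1 PIFE) calibrate the defaults:
with total intensity *I* = 1000 counts/frame and channel noise σ, the
apparent FRET E = I_A/(I_A + I_D) has, to first order,
sd(E) = σ·sqrt(E² + (1−E)²)/I, so σ = 30 gives sd(E) ≈ 0.02 across the
relevant range; σ = 100 (10 % of the baseline) gives a normalized PIFE
sd of 0.1. Intensities are floored at zero — which makes the zero-FRET
population visibly non-Gaussian, a fact the HMM initialization must
respect (below). Photobleaching is exponential per fluorophore and off
by default; blinking and spectral crosstalk are out of scope (the PIFE
channel, insensitive to acceptor photophysics, is the experimental
control for them). The moving average (5 or 7 points) uses a centered
window that shrinks symmetrically at the edges so the output length
equals the input length — a requirement for feeding smoothed traces to
the HMM.

### What the generator does and does not emulate

It reproduces: exponential state dwells under a user-specified scheme,
exposure-time integration, calibrated Gaussian detection noise, optional
bleaching, and the moving average. It does not reproduce: intensity
fluctuations from laser drift or focus, Cy3/Cy5 blinking, non-Markovian
(e.g. stretched-exponential) kinetics, baseline drift, or
molecule-to-molecule heterogeneity in emission levels. Passing recovery
tests on generated data therefore demonstrates estimator correctness
under the stated model, not robustness to every instrumental pathology
of real data.

## Estimators

**Apparent FRET** is I_A/(I_A+I_D) with zero-total frames returned as
`NA` and excluded downstream, never imputed.

**Gaussian mixtures** (`fit_population_mixture()`) use 1-D EM with 10
restarts (k-means initialization first, perturbed restarts after),
relative log-likelihood tolerance 1e-8, a standard-deviation floor of
1e-4 × sd(data), and a monotone-likelihood assertion on every fit.
Close components (0.50 vs 0.63 at sd 0.02) are exactly the regime where
single-start EM sticks; restarts are cheap insurance. BIC
(−2·logL + p·log n, p = 3K−1) selects the component count when asked.

**Dwell-time rates** use the censored-exponential MLE
k = (uncensored events)/(total observed time), stderr k/√n. First and
last intervals of every trace are censored (entry or exit unobserved),
as are photobleach-terminated dwells — the standard survival treatment.
When a detection floor exists (events shorter than `min_frames` are
suppressed as noise), the left-truncated variant
k = n/Σ(τ − t_dead) over dwells ≥ t_dead is available
(`dead_time` argument); by memorylessness it is unbiased no matter how
many short events were missed.

**Free energies** are ΔΔG = RT·ln(k_fast/k_slow) with
R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹ and T = 295.15 K by default (room
temperature); standard errors propagate first-order from the rates.

**The HMM** (`fit_hmm()`) is a shared-emission Gaussian hidden Markov
model over all traces, fit by Baum–Welch (scaled forward–backward in
C++; tolerance 1e-6 relative log-likelihood, max 500 iterations, 5
restarts when no initialization is supplied, monotonicity asserted).
States are relabeled by ascending emission mean — a deterministic
tie-break that maps 3-state fits onto
{unbound, intermediate, exo}. Emission sds are floored at 1e-4 so
noiseless test data cannot collapse the likelihood. Rows of the
transition matrix that were never left become absorbing rather than
renormalized noise. `hmm_init_from_traces()` provides the recommended
blind initialization: because intensity flooring skews the zero-FRET
peak, a plain 3-component mixture tends to spend two components on it
and merge 0.50/0.63; the helper instead takes the unbound mean/sd from
frames below 0.25 (the midpoint between 0 and the lowest bound level)
and fits the mixture to bound frames only.

**Rates from idealized paths.** The plain estimator
k(i→j) = N(i→j)/T(i) on Viterbi segments (`method = "naive"`) is
substantially biased at 50 ms resolution for the AAF n+1 exchange: mean
dwells of 4.7 frames (exo) and 9 frames (intermediate) mean a large
fraction of visits falls below one or two frames, merging neighbouring
dwells. The default `method = "truncated"` therefore

1. estimates each state's total exit rate by the left-truncated MLE on
   its uncensored Viterbi dwells ≥ 2 frames,
2. splits it across destinations by the observed branching of those
   dwells, and
3. for reversible pairs whose forward/backward transition counts are
   statistically consistent with the stationary flux identity
   N(i→j) = N(j→i) (within 3√(N_ij+N_ji); pairs with net cycle flux,
   e.g. a direct-dissociation channel, are left alone), replaces the
   rate out of the state more exposed to merging — the one whose
   partners dwell briefly — by the flux-balanced value
   k(i→j) = k(j→i)·T_j/T_i, using Viterbi occupancy times, which are
   robust to missed events.

The matrix-logarithm estimator Q = logm(A)/Δt from the fitted
transition matrix is also implemented
(`rates_from_transition_matrix()`); it corrects discretization but not
emission-blur bias, and serves as a logged cross-check (the test suite
asserts the two routes agree within a loose band, and
`analysis/04_hmm_shuttling.R` prints all three side by side — the
measured bias of the naive estimator is exactly the artifact that makes
simulation-based model comparison necessary in the first place).

**Transition densities** bin, for every Viterbi segment boundary, the
pair (mean observed FRET before, after) on a 50×50 grid over [0,1]²,
and tally transitions by ordered state pair; the fraction of apparent
direct unbound⇄exo transitions comes from those tallies.

**Pause measurement.** For each binding bout (maximal run of non-unbound
segments) that reaches exo: the association pause is the intermediate
time between leaving unbound and first reaching exo; the dissociation
pause is the intermediate time after the last exo visit. Bouts truncated
by the trace start (association) or end (dissociation) are skipped.
Pauses are measured on idealized paths by default — the published
comparison is between simulated and experimental HMM output — with a
`ground_truth` mode retained as the analytic oracle (on exact paths the
obligatory model yields strictly positive association pauses with
conditional mean 1/(a+c)).

**Pathway fitting** (`fit_direct_fraction()`) scores each candidate
fraction on a 0–1 grid (step 0.05) by simulating the candidate scheme
through the same pipeline as the observed data and comparing normalized
pause histograms (bin width 0.1 s = two frames, zero pauses in the first
bin, overflow clamped at 5 s) by summed squared differences; a
Kolmogorov–Smirnov objective is available. The goodness-of-fit metric
was an open choice; least squares on histograms was selected as the
simplest objective that uses the full shape including the zero bin.
A local 0.01-resolution refinement pass exists but is off by default:
with a stochastic simulation objective at feasible per-point trace
counts, replicate noise exceeds a 0.01 step, so refinement adds cost and
argmin jitter without adding resolution. Grid values infeasible for the
scheme's branching ratios get `NA` objectives rather than poisoning the
argmin.

## Problem sizes

The analysis scripts and tests use: 120 traces × 100 s for population
and HMM work (>100 trajectories per histogram, 240k frames); a
10,000-trace × 40 s observed dataset and 2,000 traces per grid point
for the pathway fit in `scripts/acceptance.R` (the `analysis/05` driver
runs a 3,000/1,000 version for quick turnaround); 5,000 samples for
mixture recovery; 200 replicates for MLE bias/coverage. These sizes were
chosen so that sampling error sits comfortably below the tolerances
being tested while the full workflow remains a desk-scale computation on
one CPU.

## Known limitations

* Rate recovery through the pipeline is demonstrated for the parameter
  regime of this system (dwells ≥ ~4 frames after correction); for
  substantially faster exchange the truncated estimator, like any
  fixed-frame-rate method, will degrade.
* `normalize_pife()` cannot distinguish an all-unbound from an all-bound
  trace without absolute-intensity context; the optional
  `baseline_range` argument turns that ambiguity into an explicit error.
* The flux-balance refinement assumes stationarity within the pooled
  data and is automatically disabled for count-asymmetric (cyclic)
  pairs; it is not a general missed-event likelihood (à la full
  dead-time-corrected HMM likelihoods), which would be the next step in
  estimator sophistication.
* Emission levels are assumed homogeneous across molecules; real
  datasets show per-molecule level scatter that would broaden the fitted
  sds and, at some point, demand hierarchical emission models.
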