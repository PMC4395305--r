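---
title: "From BOLD-like time series to efficiency-performance models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From BOLD-like time series to efficiency-performance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braineff)
```

`braineff` studies a single scientific question: does the efficiency of
information transfer in a functional brain network account for individual
variability in working-memory performance, and does that relationship differ
between young and older adults? This vignette documents the model behind
each stage, the tunable parameters with their defaults and units, what the
synthetic generators do and do not emulate, and the numerical decisions made
where the method description left the design open.

## The analysis chain

One subject's data are (a) a node-by-frame time-series matrix (BOLD-like
arbitrary units, sampling interval `tr` seconds per frame), (b) a 6-column
rigid-body motion table (3 translations in mm, 3 rotations in radians), and
(c) a 2-back trial log. The chain is fixed and runs in this order:

1. **Band-pass filter** (`bandpass_filter`): 0.009–0.08 Hz, the band that
   carries resting-state connectivity signal, removing scanner drift below
   and physiological noise above.
2. **Nuisance regression** (`regress_nuisance`): the six motion parameters
   plus the global mean signal are projected out of every node's series.
3. **Motion scrubbing** (`scrub`): frames terminating a transition with
   framewise displacement (FD) above 0.5 mm *or* DVARS above 0.5% are
   removed; the count feeds the model as a per-subject control covariate.
4. **Network construction** (`correlation_matrix`,
   `threshold_to_density`): pairwise Pearson correlations, cut to a
   density-matched binary undirected network.
5. **Efficiency metrics** (`efficiency`): global and local efficiency by
   breadth-first search.
6. **Behavioural scoring** (`classify_trials`, `dprime`,
   `mean_correct_rt`): signal-detection d′ and the speed control.
7. **Modelling** (`stepwise_select`, `cohort_equations`): stepwise AIC
   regression of d′ on the covariates; deconstruction into per-cohort
   equations.

`run_subject()` composes stages 1–6 for one subject; `run_cohort()` runs a
whole simulated sample and fits the model.

## Network construction and density matching

Networks from different subjects are only comparable at equal edge density.
The matching rule is `N = K^S`: a network of `N` nodes is cut to average
degree `K = N^(1/S)`, i.e. an edge budget of `round(N * N^(1/S) / 2)`. The
default `S = 2.5` sits in the 2–3 range where functional brain networks
remain connected and reproducible; `target_degree()` exposes the rule.
Only positive correlations are candidate edges — negative functional
coupling is excluded rather than thresholded — and the cut is rank-based, so
any strictly monotone transform of the correlations yields the same network.

Three details are deliberate choices rather than consequences of the rule:

- **Ties at the cut value** are broken by `(i, j)` lexicographic order. Real
  correlation data has ties with probability zero, but synthetic fixtures hit
  them constantly; a deterministic tie-break keeps the edge budget exact and
  every run reproducible.
- **The edge budget uses round-half-to-even** (base R `round`), unbiased and
  deterministic.
- **Isolated nodes are kept.** A node disconnected by thresholding still
  contributes 0 to the efficiency sums; dropping it would silently change
  `N` between subjects, which is what density matching exists to prevent.

## Efficiency metrics

Global efficiency is the mean inverse shortest-path length over all ordered
pairs, `E_global = 1/(N(N-1)) * sum_{j != k} 1/L_{j,k}`, with `1/Inf = 0`
for disconnected pairs. Hop distances come from per-source breadth-first
search; ordered-pair summation with symmetric distances is algebraically
identical to unordered pairs normalised by `N(N-1)/2`.

Local efficiency of node *i* is the global efficiency of the subgraph
induced by the neighbours of *i* with *i* removed — paths are constrained to
stay inside the neighbourhood (the strict variant of the metric; allowing
detours through the rest of the graph gives systematically higher values).
Nodes of degree 0 or 1 have no neighbour pairs; their nodal value is defined
as 0 and they stay in the network-level average over all `N` nodes, rather
than being excluded from the mean. The alternative (averaging only nodes
with degree ≥ 2) would make the denominator density-dependent; keeping all
nodes makes `E_local = mean(nodal_local)` hold unconditionally.

Both metrics are validated in the test suite against an independent
Floyd–Warshall oracle (exact to 1e-12 on random graphs) and against
closed-form values: complete graphs score 1, the 3-node path scores 5/6
globally, cycles of length ≥ 4 score 0 locally, and the 4-clique minus one
edge scores 11/12 locally.

## Preprocessing parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| band edges | 0.009, 0.08 | Hz | must stay below Nyquist `1/(2*tr)` |
| filter | Butterworth order 2, zero-phase | — | `signal::filtfilt`, run forward and backward |
| FD threshold | 0.5 | mm | scrub cut-off |
| DVARS threshold | 0.5 | % of mean signal | scrub cut-off |
| rotation radius | 50 | mm | converts radians to arc displacement |
| scrub mask extension | 0 before, 0 after | frames | only the offending frame is removed |

Choices worth recording:

- **Zero-phase filtering.** A causal filter delays each series by a
  frequency-dependent lag, which distorts the correlations that define the
  network. Running the order-2 Butterworth forward and backward cancels the
  phase at the cost of squaring the magnitude response; the in-band/stop-band
  contract (≥ 80% variance retained at 0.05 Hz, ≤ 10% at 0.2 Hz with
  `tr = 2`) is asserted in the tests on the implemented filter.
- **FD formula.** `FD_t = sum |Δtranslation| + 50 mm * sum |Δrotation|` —
  the common summed-displacement form with rotations mapped to arc length on
  a 50 mm sphere (roughly the cortical distance from the head centre). The
  radius is configurable.
- **OR logic.** A frame is removed when *either* FD or DVARS exceeds its
  threshold — the conservative reading, and the one the scrubbing
  literature uses.
- **DVARS timing and normalisation.** DVARS is computed on the filtered,
  regressed data (the data the correlations will see) but expressed as a
  percentage of the *raw*-signal grand mean, because filtering leaves the
  cleaned data near zero-mean and a percentage of ~0 is meaningless.
  `compute_dvars()` takes the reference mean as `baseline_mean`;
  `run_subject()` passes the raw grand mean automatically.
- **Scrubbing scores only acquisition-adjacent transitions.** After frames
  are removed, the survivors' `frame_ids` record the gaps; transitions that
  span a gap are never scored against the thresholds (the frame-to-frame
  differences there do not estimate instantaneous motion). This makes
  scrubbing idempotent: scrubbing already-scrubbed data removes nothing.
- A subject with fewer than 3 surviving frames is rejected as unusable —
  below that no correlation is defined.

## Behavioural scoring

d′ = `qnorm(H) − qnorm(FA)`. Conventions:

- **Extreme rates**: a hit or false-alarm rate of exactly 0 or 1 makes the
  quantile infinite; the default correction replaces 0 with `1/(2N)` and 1
  with `1 − 1/(2N)` (`N` = trials of that type). The correction is
  pluggable (`correction = "none"` disables it).
- **Omissions count as incorrect**: no response on a target is a miss; no
  response on a non-target is a correct rejection (no false alarm occurred).
  This is a package convention, stated rather than inherited.
- **RT control**: mean RT over correct, responded trials after excluding
  RTs outside mean ± 3 SD in a *single* pass — the exclusion is not
  iterated to convergence.
- Trials 1 and 2 of a session can never be scored (no 2-back reference),
  and `classify_trials()` validates the stored target flags against the
  letter sequence before counting.

## The stepwise model

Candidates are every main effect of the supplied covariates, every pairwise
product, and the square of every continuous covariate (a 0/1 indicator's
square is itself and is dropped). With the standard five covariates — local
efficiency, global efficiency, mean RT, volumes removed, age group — that is
19 candidate terms. Covariates enter **raw (uncentred)**, so coefficients
and the deconstructed per-cohort equations read directly in original units;
the cost is high collinearity between a covariate and its square, which the
selection criterion, not the parametrisation, is left to handle.

The search is **backward-first with forward re-entry**: start from the full
model, evaluate every single-term drop and re-addition, apply the move that
most reduces AIC, stop when none does. The criterion is the
Gaussian-likelihood AIC on the RSS scale, `n*log(RSS/n) + 2*(p+2)` (`p`
slopes, plus intercept and error variance); AICc is available behind
`aicc = TRUE` for small samples. Exact AIC ties between moves are broken by
higher adjusted R², then by the smaller model, then by candidate order —
AIC is primary and adjusted R² is only a tie-break, a documented choice for
how the two criteria combine when they disagree. Control covariates (RT,
volumes removed) are ordinary candidates, not forced terms: a control that
carries no variance is allowed to leave the model. Hierarchy is not enforced
by default (an interaction may outlive its mains); `hierarchy = TRUE`
enables the strict rule.

One numerical guard matters: on noise-free data the full model fits exactly
and `log(RSS)` of a numerically-zero RSS is meaningless noise, making the
search nondeterministic. `ols_fit()` therefore floors RSS at
`1e-12 * TSS` inside the AIC only. All saturated models then share one AIC
and each superfluous term costs exactly its penalty of 2, so the search
deterministically strips every term the generating equation does not
contain. Reported R², residuals and coefficient tables always use the true
RSS.

`cohort_equations()` deconstructs a fit containing a 0/1 group indicator:
the group-0 equation keeps the intercept and plain slopes; the group-1
equation adds the group coefficient to the intercept and each
group-interaction coefficient to its partner's slope. Only two-way
interactions with the group are deconstructable; a three-way term is an
error.

## What the synthetic generators emulate

`generate_modular_timeseries()` draws each node as
`baseline + a*g + b*f_block + c*eps` with `a² + b² + c² = 1`, solving
`a² = rho_between` and `a² + b² = rho_within`, so expected pairwise
correlations equal the targets exactly — within-block 0.6 / between-block
0.1 at the defaults' scale reproduces the block-modular correlation
structure functional networks show. The baseline offset (default 1000
arbitrary units) gives the series the large positive mean real BOLD data
has, which the DVARS percentage needs. What is *not* emulated: hemodynamic
autocorrelation, spatial smoothness, physiological rhythms, scanner drift —
so passing tests demonstrate correctness of the downstream computations
given the assumed correlation structure, not robustness to every artefact of
real fMRI.

`generate_motion_trace()` keeps baseline jitter below 0.1 mm FD and injects
exact x-translation steps at chosen frames, so scrub tests can assert
removal counts exactly. `generate_nback_session()` forces 2-back matches at
the target rate (default 0.3 over a 100-letter session of 20 consonants) and
draws responses Bernoulli(hit rate / false-alarm rate) with log-normal RTs —
a subject whose sensitivity and speed are dialled in directly, with no model
of attention or learning.

`generate_subject_cohort()` produces the modelling substrate: covariates
within plausible ranges (local efficiency 0.35–0.50, global efficiency
0.15–0.35, RT 400–1500 ms, volumes removed 0–5 — stand-ins chosen to keep
predicted d′ in a realistic band, not estimates of any real sample), and d′
set by one linear equation per cohort (see `default_cohort_equations()`)
plus Gaussian noise. With `noise_sd = 0` the covariates are laid out on a
deterministic Halton sequence (prime bases 2, 3, 5, 7) instead of being
drawn: an RNG-free quasi-random layout spreads every covariate across its
range at any `n` and keeps the full 19-column candidate design full-rank,
which a periodic lattice does not (cyclic levels produce exact linear
dependencies among product columns). On such a cohort, refitting the
generating five-term model recovers its coefficients to machine precision —
the package's acceptance surface.

## Problem sizes and runtime envelope

The test suite and acceptance script are desk-scale by design: cohorts of
80 subjects, networks up to 50 nodes for the oracle equivalence (200 random
graphs), thresholding checked up to 2000 nodes, 1000 replicates for the
confidence-interval coverage property (nominal 95% within ±3%), and 200
replicates of null-model selection (13 independent candidates; median
selected size ≤ 2, the per-term AIC inclusion probability of ~0.157 at
work). These sizes make every property cheap to re-verify while leaving the
algebra identical to full-scale use.

## Known limitations

- Efficiency metrics are for binary undirected graphs only; no weighted or
  directed variants, no small-world statistics.
- The stepwise search is greedy; like all single-move searches it can stop
  in a local AIC optimum, and under heavy collinearity (raw quadratics) it
  retains correlated clusters more often than the orthogonal-candidate
  theory suggests.
- The per-cohort deconstruction handles one binary group factor; multi-level
  groups or three-way interactions are out of scope.
- The generators share no code with real fMRI preprocessing; conclusions
  about real data require the real upstream pipeline.
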