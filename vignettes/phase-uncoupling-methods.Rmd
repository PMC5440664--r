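---
title: "Testing coupled versus uncoupled phenotypic evolution across life-history phases"
author: "phasecouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing coupled versus uncoupled phenotypic evolution across life-history phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecouple)
```

# The scientific question

Organisms with complex life cycles — a tadpole that metamorphoses into a
frog — expose two very different phenotypes to selection. If the same genes
shape homologous structures in both phases ("phase-pleiotropy"), selection
on one phase drags the other along and we expect *coupled* evolution:
correlated rates of phenotypic change, regime shifts concentrated on the
same branches of the phylogeny, and morphology-related genes expressed in
both phases. If each phase is shaped by its own genes or its own regulation
("phase-polygeny"), the phases can climb different adaptive peaks
independently — *uncoupled* evolution.

`phasecouple` implements the full macroevolutionary side of this test for a
time-calibrated radiation scored for categorical morphology in each phase,
plus the expression-level classification, and a synthetic-data module that
generates every input with known truth so each stage can be validated
without external data.

# Pipeline and models

## From characters to phenotypic axes

Each phase contributes a species-by-character categorical matrix (NEXUS).
The morphological distance between two species is the number of character
state transformations summed over characters scored in both species:
`|i - j|` for ordered (mensural, continuum-coded) characters, 0/1 for
unordered ones, with pairwise deletion of missing data
(`pairwise_transformations()`). The raw count is the default; dividing by
the per-pair number of comparable characters is available for strongly
unequal missingness. The distance matrix is embedded in `k` dimensions by
non-metric MDS (`fit_nmds()`, Kruskal stress-1 with global monotone
regression via `vegan::monoMDS`), taking the best of 20 seeded random
starts plus a classical-scaling start. Ties are treated as *secondary*
(equal dissimilarities must receive equal fitted values): transformation
counts are small integers with massive ties, and the primary treatment
would let, e.g., three mutually equidistant species embed on a line with
zero stress. Axes are then ordered by variance
with a deterministic sign convention (`axis_variance_order()`). We use
`k = 4` axes for optimum analyses and the single highest-variance axis for
rate analyses. Because NMDS is only defined up to monotone distortion,
determinism-by-seed (not bit-reproduction of any particular other
implementation) is the contract.

## Is the radiation adaptive?

Two classic signatures are quantified:

* **Diversification.** Six birth–death models (constant or exponentially
  time-varying speciation `lambda(t) = lambda0 e^{a t}` and extinction
  `mu(t) = mu0 e^{b t}`, `t` in Myr before present) are fitted by maximum
  likelihood and ranked by AICc (`fit_bd_models()`, `selection_table()`).
  The reconstructed-tree likelihood is conditioned on the crown age and
  survival of both crown lineages; this conditioning is stated explicitly
  because absolute log-likelihoods depend on it. An early burst shows up
  as the exponential-speciation, no-extinction model winning with `a > 0`
  (rates increasing toward the past).
* **Disparity through time.** `dtt_curve()` plots, at each internal-node
  age, the mean relative disparity (average squared pairwise distance,
  the conventional metric) of the subclades crossing that age, against
  the median of 1000 Brownian-motion simulations at the ML rate. The MDI
  is the signed trapezoid area between observed and median simulated
  curves over relative time; negative MDI means morphospace was
  partitioned among subclades early — the adaptive-radiation signature.

## Rate heterogeneity and rate coupling

Branch-specific Brownian rates are sampled by reversible-jump MCMC
(`run_rjmcmc()`). A configuration is a set of shift branches; each branch
evolves at the rate of its nearest ancestral shift, so the painting is
always reconstructable from the shift set. Moves are a log-scale
sliding-window rate update (probability 0.4), a root-state update (0.1),
and shift birth/death (0.25/0.25) with the new rate drawn from its prior,
which reduces the dimension-jump acceptance ratio to the likelihood ratio
times `k_mean/(k+1)` (birth) or `k/k_mean` (death) — the combinatorial
factors of the Poisson(1) prior on the shift count, the uniform placement
prior and the proposal densities cancel (the algebra is unit-tested).

The class-rate prior is log-normal, centered on the single-rate ML estimate
with `sdlog = 6`. The width matters: the birth move's Occam factor — how
strongly an uninformative extra shift is penalized — scales with the prior
width, and at `sdlog = 6` a dataset simulated with a single rate yields
posterior `P(0 shifts) >= 0.5` in about 80% of replicates (the remainder
are datasets whose Brownian noise genuinely mimics a shift) while a
planted 10-fold rate clade is still recovered essentially always. Defaults mirror
the study design: 2 chains of 1e6 generations with 50% burn-in; the test
suite uses 2e4 generations, which the planted-shift simulations show is
already sufficient at `n = 64`.

Cross-phase coupling of rates is then scored by `compare_phase_rates()`
(Kruskal–Wallis on the two per-branch rate samples; Pearson correlation of
within-phase z-scored rates — "standardized" is interpreted as z-scoring
because the original description leaves it open) and by binning branch
rates into 4-Myr intervals anchored at the present (`bin_rates_by_time()`,
branch contributions weighted by the fraction of their length in each
interval) followed by `interval_correlation()`.

## Selective optima and their shifts

Multi-optimum Ornstein–Uhlenbeck evolution is fitted with a stepwise
search (`surface_forward()`): starting from one regime, the shift whose
addition most decreases the summed-across-axes AICc is accepted until no
candidate improves it, with ties broken to the earliest branch in
preorder. All `k` axes share the painting; `alpha` and `sig2` are per axis,
optimized on `log alpha` with `theta` profiled out by GLS and `sig2`
analytic. The root state sits at the root-regime optimum. The AICc
parameter count is `n_regimes * k + 2k + n_shifts` on an effective sample
of `n_tips * k`; the count includes the shift placements so that adding a
shift is never free. Shifts on terminal branches are allowed (the source
analysis does not say either way; excluding them would silently cap the
number of detectable optima). `surface_backward()` then collapses regime
pairs whose shared optimum lowers AICc; the number of regimes lost is the
convergence measure.

Like any threshold-free stepwise AICc search, the forward phase admits a
few *weak* spurious shifts even on single-regime data (accepted spurious
steps typically gain under 10 AICc units, versus tens of units for
genuine strong shifts, but the two distributions overlap). Shift counts
should therefore be read against a simulation null — which is exactly
what `convergence_pvalue()` provides for the convergence statistic, and
what the shift-concordance randomizations provide for cross-phase
comparisons: both are robust to a shared false-positive floor in the two
phases.

`convergence_pvalue()` calibrates that measure against a null of
*non-convergent* evolution: datasets are simulated under the forward fit's
shift structure, `alpha` and `sig2`, but each regime's optimum offset is
redrawn as Gaussian with the RMS fitted step size. Redrawing is essential:
simulating from the fitted optima verbatim would reproduce the very
convergence being tested (fitted optima of convergent data are nearly
equal) and destroy the test's power. The p-value is
`(1 + #(sim >= obs))/(nrep + 1)` with 100 replicates by default.
Phylogenetic half-lives are reported as `ln(2)/alpha` Myr.

## Concordance of shifts between phases

A shift's *node* is the parent of its branch; its *direction* is the child
lineage that carries the new optimum. `node_concordance_test()` compares
the shared-node fraction `|A ∩ B| / max(|A|, |B|)` (the published rule —
divide by the phase with more shifts — generalized symmetrically) with
shifts placed uniformly at random, independently per phase. The eligible
set defaults to internal non-root nodes: shift nodes are parents of
branches and hence always internal, and a null that also occupies tips
cannot be attained by any empirical shift set (measured type-I error 0.275
with the tip-inclusive null versus 0.0275 with the internal null under
uncoupled shifts at the study's shift counts of 15 and 17). The
tip-inclusive variant remains available via `eligible = "all"`.
`direction_concordance_test()` restricts to shared nodes and redraws each
phase's descendant lineage uniformly among the node's children. Both use
the `(1 + #(null >= obs))/(nreps + 1)` convention so 1000 randomizations
can resolve p = 0.001 and p is never zero. Note that both statistics are
discrete, so their randomization p-values are *super-uniform*
(conservative) rather than exactly uniform under the null — the test suite
checks exactly this property.

## Correlated evolution of character pairs

For every adult-by-tadpole character pair (binarized 0 vs > 0 — the
robustness of binary coding was part of the original study design, and the
dependent/independent contrast is defined for binary pairs), `pair_lrt()`
fits the 4-rate independent and 8-rate dependent joint Markov models by
maximum likelihood (pruning over the 4 joint states; one eigendecomposition
of the rate matrix supplies all branch propagators; the root is weighted by
the stationary distribution of the fitted matrix) and refers
`2 (logL_dep - logL_indep)` to chi-square with 4 df. The original analysis
used a Bayesian engine whose exact decision statistic is not recoverable
from the text; the ML likelihood-ratio version implements the same
dependent-vs-independent contrast, and measured type-I error at `n = 64`
is within [0.01, 0.10] with null p-values indistinguishable from uniform.
`summarize_pairs()` reports the percentage of significant pairs (one
decimal) and appends BH-FDR q-values, since the original multiplicity
handling is unstated.

## Expression classification

`classify_phase_bias()` applies the published FPKM ratio thresholds
(adult/tadpole > 1.6 adult-biased, < 0.4 tadpole-biased) exactly as
printed — deliberately not reciprocal — with a 1-FPKM floor: genes under
the floor in both phases are unclassifiable, and genes under it in exactly
one phase are assigned to the other phase's class rather than forming a
ratio against ~0. `keyword_flag()` reproduces the annotation text-mining
step (case-insensitive substring match of morphology-associated GO terms),
and `proportion_ztest()` the two-sided pooled-proportion z-tests.

# The synthetic-data module

`simulate_tree()` draws birth–death trees conditioned on the tip count by
forward Gillespie simulation with generalized sampling: the observation
time is drawn uniformly from the periods with exactly `n` lineages (chosen
proportionally to their length), extinct lineages are pruned, and under
pure birth the mean crown age matches the closed form
`sum_{k=2..n} 1/(lambda k)` (verified to < 1% over 500 replicates).
Histories with extinction are capped at `4n` lineages, which truncates
rare late returns to `n`; speciation decline is parametrized forward from
the crown origin and restricted to non-negative decline (the early-burst
case under study).

`simulate_phase_traits()` plants OU regime shifts with optima stepping
`effect` stationary SDs (default 4, the "strong shift" condition) away
from the parent regime, on disjoint clades of at least 4 tips so recovery
is well defined; `coupled` mode shares shift branches between phases,
`uncoupled` places them independently. The default shift counts, 15 and
17, mirror the adult and tadpole shift counts of the mantellid radiation.
`simulate_mk()`/`simulate_dependent_pair()` generate categorical
characters (symmetric k-state chains; exact Gillespie for dependent binary
pairs), and `simulate_expression()` log-normal FPKM tables with planted
biased fractions and class-specific morphology-flag enrichment (defaults
24.8%/54.5%/16.3%, the published morphology-gene fractions). The default
per-phase measurement noise (`sdlog = 0.15`) is set so that unbiased
genes cross the 1.6/0.4 ratio thresholds in under 5% of cases — the
calibration the ratio rule presumes; noisier libraries can be emulated by
raising it.

What the generator deliberately does **not** emulate: correlated
characters within a phase, heterotachy beyond the planted shifts,
measurement error in FPKM, or phylogenetic signal in expression. Passing
tests therefore demonstrate correctness of the estimators under their own
model assumptions and calibrated behavior under realistic sizes — not
robustness to model misspecification in real data.

# Numerical choices

* Ultrametricity tolerance `1e-6 * T` on reading; depths renormalized so
  tips sit at age exactly 0. Node ages run backwards from the present.
* Birth–death survival integrals: closed-form rate integrals plus
  cumulative-trapezoid quadrature on a 4096-point grid that includes every
  node age (relative error well under 1e-8 for the exponential-rate
  family); optimization from 10 Latin-hypercube starts within
  `lambda0 in (1e-6, 10)`, `mu0 in [0, 10)`, `a, b in (-2, 2)`, with each
  nested model's solution seeding its supersets so the fitted
  log-likelihoods respect nesting by construction.
* OU `alpha` is searched on `log alpha in [log 1e-5, log 50]` with
  tolerance 0.01 (resolving AICc to well under 0.1); the forward search
  accepts only strict AICc decreases, and the first-best (preorder)
  candidate wins ties.
* NMDS: 20 restarts, `monoMDS` convergence at stress ratio 0.999999,
  maximum 500 iterations; degenerate all-zero distance matrices are
  rejected.
* Polymorphic (bracketed) NEXUS entries are treated as missing — the
  source data description is silent on polymorphism — and state symbols
  are restricted to the digits 0–9.
* Randomization p-values use `(1 + k)/(n + 1)` throughout.

Problem sizes in the test suite (64-tip trees, 2e4 MCMC generations,
200–500 randomization replicates, 1000-simulation DTT envelopes) were
chosen as the smallest at which the calibration targets stabilize;
the same code runs the full-size analyses by changing the arguments.

# Known limitations

* The OU machinery assumes an ultrametric tree (stationary-start
  covariance); non-ultrametric trees are rejected rather than mishandled.
* One painting is shared across axes, per-axis `alpha`/`sig2`/`theta`;
  per-regime `alpha` variants are out of scope.
* The dependent-model LRT handles binary characters; multistate dependent
  models are not implemented.
* `pairwise_lrt_all()` is quadratic in the number of characters; the
  full 43 x 117 study-scale grid takes hours on one core, so exploratory
  analyses should subset characters first.
* The diversification models ignore incomplete taxon sampling; fits to
  sparsely sampled trees will be biased toward apparent slowdowns.
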