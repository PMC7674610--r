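---
title: "Threshold models of germination and seedling development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold models of germination and seedling development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedthresholds)
```

## The models

Threshold ("cardinal") models describe germination timing as progress
accumulated above a threshold. In the thermal-time model a seed at
constant temperature $T$ above the base temperature $T_b$ germinates when
it has accumulated its thermal-time requirement $\theta_T$ (°C h), so its
germination rate is

$$GR(T) = \frac{1}{t_{50}} = \frac{T - T_b}{\theta_T},
\qquad T_b \le T \le T_o,$$

linear in $T$ on the sub-optimal range. The hydrotime model is its
water-potential analogue at fixed temperature: above the base water
potential $\Psi_b$ (MPa),

$$GR(\psi) = \frac{\psi - \Psi_b}{\theta_H}.$$

Both are inverted by ordinary least squares on (treatment, rate) pairs:
the base is the x-intercept $-b/a$ and the time constant the reciprocal
slope $1/a$. These identities hold *exactly* for every returned
`threshold_fit`, and on noiseless collinear input the estimates are exact
to numerical precision. The same machinery serves the later
seed-to-seedling transition (cotyledon opening), giving stage-specific
parameters $T_{bS}$, $\theta_{TS}$, $\Psi_{bS}$, $\theta_{HS}$ next to the
germination-stage $T_{bG}$, $\theta_{TG}$, $\Psi_{bG}$, $\theta_{HG}$.

Optimum temperatures $T_o$ are estimated differently: final percentages
(on the viable-seed basis) are fitted with a concave quadratic and the
vertex $-b/(2a)$ is reported, clamped (and flagged) when it falls outside
the tested range. Percentages, not rates, are used because the optimum is
a statement about how *complete* germination is, while rates describe how
*fast* it is.

## t50: which 50%?

"Time to 50% germination" is ambiguous whenever a dish plateaus below
100%. The package fits the Boltzmann sigmoid

$$f(t) = A_2 + \frac{A_1 - A_2}{1 + e^{(t - x_0)/d_x}}$$

to each dish (lower asymptote fixed at $A_1 = 0$ by default; a switch
frees it) and offers two definitions:

* **`"fraction"` (default)** — the time at which the *fitted curve*
  crosses 50% of the normalising population (viable seeds for
  germination; germinated seeds for the seedling stage). If the plateau
  $A_2$ never reaches 50%, t50 is undefined and the treatment drops out
  of rate regressions.
* **`"midpoint"`** — the fitted midpoint $x_0$, i.e. half of the dish's
  *own* plateau.

The default matters. Threshold theory defines $GR_{50}$ on the population
percentile: under a population-threshold model the seed at the median of
the $\Psi_b$ distribution germinates at exactly
$t = \theta_H/(\psi - \Psi_{b(50)})$, so percentile-based rates are linear
in $\psi$ through the median base potential. The midpoint definition
instead tracks the median of the *germinating subpopulation*, which at
stressful treatments (where part of the population never germinates) is
systematically faster than the population median; rate regressions built
on it extrapolate to a base potential that is too negative by roughly a
tenth of an MPa under the default simulation scenario. Parameter-recovery
experiments with the package's own generators (below) show the percentile
definition recovers the generating $\Psi_{b}$ and $T_b$ without that
bias, which is why it is the default; the midpoint remains available for
comparability with curve-centric summaries.

Numerical details of the sigmoid fit: Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with starting values read off the empirical curve
(plateau = maximum observed fraction; $x_0$ = linear-interpolated
half-crossing; $d_x$ = interquartile width / 2.2), box constraints
($A_2 \le 1.05$, $d_x > 0$), and up to five deterministic perturbed
restarts of $(x_0, d_x)$ when the optimizer fails. Dishes whose final
germination is below 10% of viable seeds (configurable) are flagged and
excluded from rate estimation — midpoints of near-flat curves are not
identifiable — but still contribute to percentage outputs. Observation
times carry the scoring resolution; raw counts are never interpolated
before fitting.

## The viable-seed basis

All percentages use only viable seeds: final germinated plus the
ungerminated seeds classified alive at the end-of-test cut test. Dead
seeds never enter a denominator. Seedling conversion is expressed as a
percentage of germinated seeds. Every ingested dish must satisfy the
accounting identity
`max(cumulative) + viable_ungerminated + dead == sown`, enforced at
construction, and the basis is scale-free (doubling all counts changes no
percentage). Dead/viable classification is taken as given in the input —
the cut test is a wet-lab step — and seeds dead at the cut test are not
removed from the seedling-conversion denominator, which per the
definition above is *germinated* seeds.

## Sub-optimal range selection

The thermal regression must stop at the optimum; which temperatures are
"sub-optimal" is itself an estimate. The default takes all temperatures
up to and including the warmest temperature attaining the maximum mean
rate. This handles both a species whose rate peaks inside the tested
range and one whose rate still rises at the warmest treatment (where all
temperatures enter), and makes flat rate profiles fail loudly with a
non-positive-slope error rather than silently extrapolating. The choice
is overridable per run (`suboptimal_max`). For the hydro regression,
zero-rate treatments are censoring artifacts (no seed crossed the stage
within the test) and are excluded; only treatments with germination carry
information about the slope.

Parameters are estimated per replicate experiment — the scoring schema
carries a `replicate` column, one dish per treatment per replicate — and
averaged to accession means; both levels are returned.

## Exact Spearman probabilities

Rank correlations on ten accessions per species sit far outside t-approximation
comfort. The package computes the ties-adjusted coefficient (Pearson
correlation of mid-ranks) and a two-sided permutation p-value
$P(|\rho^*| \ge |\rho|)$:

* $n \le 7$: full enumeration of all $n!$ pairings (ties included);
* $7 < n \le$ `exact_n_max` (default 10), untied data: an exact dynamic
  program over subsets computes the full permutation distribution of
  $S = \sum d_i^2$ — identical to enumerating all $10! = 3{,}628{,}800$
  pairings, at a cost of $2^n n \cdot S_{max}$ — so p-values at $n = 10$
  are exact probabilities, not approximations;
* $7 < n \le$ `exact_n_max`, tied data: seeded Monte-Carlo permutation
  (99,999 draws by default);
* larger $n$: the usual $t$ approximation.

`exact_n_max = 10` was chosen because ten accessions per species is the
design the package targets, and because the $t$ approximation is visibly
anticonservative there: in the package's own null calibration (500
independent trait tables of 20 traits × 10 accessions, run by the test
suite and the acceptance script) the exact method holds the 5% level
while the $t$ approximation exceeds it. The subset-DP is verified against
brute-force enumeration in the tests.

## The trait network

Edges are the significant correlations ($p \le \alpha$, default 0.05, raw
p-values by default with an optional Benjamini–Hochberg switch), with two
structural exclusions applied *before* thresholding: no
geography–geography and no geography–climate edges, since those pairs
correlate trivially and would swamp the physiological signal. Edge weight
is $-\log_{10} p$; weights are display attributes only — edge betweenness
and modularity use the unweighted graph. Community detection removes the
highest-betweenness edge, recomputes, and keeps the partition maximising
Newman modularity of the original graph (`igraph`'s edge-betweenness
clustering); isolated traits stay outside the partition. Tests verify
edge betweenness against explicit shortest-path counting and the
community partition against exhaustive modularity maximisation on small
fixtures.

## What the generators emulate — and what they do not

`simulate_thermal()` places between-seed variation on the thermal time
(lognormal, default CV 15%); `simulate_hydro()` places it on the base
water potential (normal, default SD 0.15 MPa) — the standard
population-threshold formulations. Defaults mirror the targeted
laboratory design: 3 replicate dishes × 50 seeds, 5–30 °C in 5 °C steps,
potentials 0 to −1.0 MPa in 0.2 MPa steps at 15 °C, twice-daily
germination scoring to 840 h (daily for osmoticum), seedling checks every
3 days, a small non-viable fraction (5%), and an optional dormant
fraction (default 0) scored as viable-ungerminated. Germination times are
rounded *up* to the scoring grid and censored at test end, reproducing
the interval-censored character of real scoring. Default generating
parameters ($T_b = 4$ °C, $\theta_T = 800$ °C h, $\Psi_{b50} = -0.9$ MPa,
$\theta_H = 40$ MPa h) are deliberately not equal to any published
estimate, so recovery tests are independent of reported values.

The generators do *not* emulate: between-dish environmental scatter
(binomial seed sampling is the only noise source), after-ripening or
stratification dynamics, temperature-by-potential interaction (potentials
are crossed with a single temperature), or seed lots with shifting
viability. Passing recovery tests therefore show the estimator chain is
consistent for the stated model, not that real dishes obey it.

Two generator features are worth knowing when reading outputs. First,
recovered thermal time carries a small (~1%) downward bias because the
median of a lognormal lies below its mean; this is inherent to
percentile-based rates and well inside the recovery tolerance. Second,
the quadratic optimum from the thermal scenario is nearly invariant
across seeds (≈21.5 °C under the defaults): percentages saturate at 100%
for 10–30 °C, and the OLS vertex then barely depends on the single
sub-saturated point. Quadratic optima are only informative when the
tested range brackets a real percentage decline.

## Problem sizes and reproducibility

The recovery studies run 20 seeded replicates of each default scenario
(18 + 36 dishes per replicate) and the null calibration 500 trait tables;
these sizes give Monte-Carlo error comfortably below the tolerances being
checked while keeping the whole suite fast. Every stochastic routine
takes an explicit seed and restores the caller's RNG state;
`run_pipeline()` fans one global seed out to stage seeds by fixed
offsets and writes a manifest of MD5 checksums, so a configuration plus
seed reproduces every artifact byte for byte.

## Known limitations

* No probit/repeated-probit hydrothermal fitting across percentiles, and
  no ceiling-temperature estimation; the rate regressions use one
  percentile (the median) per dish.
* No interval-censored survival likelihoods: the Boltzmann fit treats
  the cumulative curve as a regression target, which is standard
  practice but understates uncertainty at coarse scoring grids.
* The network stage thresholds raw p-values by default (the BH switch is
  off), so at $\alpha = 0.05$ across ~150 admissible pairs a handful of
  false edges is expected; community structure should be read
  accordingly.
* Trait classes are fixed at physiological/climate/geographical; the
  exclusion rule is not configurable beyond that taxonomy.
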