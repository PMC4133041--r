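---
title: "Single-locus evolutionary rescue: model, theory, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-locus evolutionary rescue: model, theory, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorescue)
```

## The model

A haploid population of size $N_0$ experiences a sudden environmental change
at generation 0. The wildtype allele now has absolute fitness $1 - r$
($0 < r < 1$), so wildtype numbers decline geometrically and, unchecked, the
population goes extinct. A beneficial allele with fitness $1 + s - r$
($s > r$; the product $s\,r$ is assumed negligible) can rescue the
population. It is either already present as $k$ rare copies of standing
variation (frequency $p_0 = k/N_0$) or arises recurrently by mutation at
per-gamete rate $u$. Generations are discrete and non-overlapping; each
individual leaves an independent, Poisson-distributed number of offspring
with the fitness as its mean; growth is exponential until a ceiling $K$
(default $N_0$). There is no dominance (haploids), no population structure,
and no clonal interference.

All analytic results are branching-process approximations for *rare*
beneficial alleles and use Haldane's establishment probability $2(s - r)$
for a single copy; `establishment_probability()` also exposes the refined
form $1 - e^{-2(s-r)}$ and the exact probability-generating-function (PGF)
fixed point for the chosen offspring law, which is the simulator's
correctness oracle.

## Rescue probabilities and the dominant source

With per-copy establishment probability $2(s - r)$,

* new mutation: $P_{\mathrm{new}} = 1 - \exp\{-2 N_0 u (s - r)/r\}$ — the
  factor $N_0 u / r$ is the expected cumulative number of mutant copies
  produced before extinction;
* standing variation: $P_{\mathrm{sta}} = 1 - \exp\{-2 N_0 p_0 (s - r)\}$ —
  each of the $k = N_0 p_0$ copies has an independent fate;
* either: $P = 1 - (1 - P_{\mathrm{new}})(1 - P_{\mathrm{sta}})$, exact
  under the exponential forms.

Comparing exponents shows that standing variation is the likelier source of
rescue precisely when $p_0 > u/r$, independent of $s$ and $N_0$
(`dominant_rescue_source()`). If the allele segregated at
mutation–selection balance before the change ($p_0 = u/s_d$), standing
variation dominates exactly when $s_d < r$.

## The rescue-conditioned trajectory and the oversampling correction

The expected population size conditional on rescue is the sum of a
deterministic wildtype decline $N_0 e^{-rt}$ and a conditional mutant
component. Naively one would write $k\,e^{(s-r)t}$ for the mutant term, but
conditioning on rescue changes it qualitatively when $k$ is small: lineages
that survive drift are disproportionately those that drifted high early, so
conditional on rescue the sweep behaves as if it started from
$1/(2(s-r))$ copies rather than $k$ (the oversampling effect). The
corrected standing-variation curve is

$$E[N(t)] = N_0 e^{-rt} + \frac{e^{(s-r)t}}{2(s-r)},$$

independent of $k$ for small $k$ (conditional on rescue, the descendants of
a single lucky copy sweep). For $k$ not small the package offers a
general-$k$ mode that replaces $1/(2(s-r))$ by
$k/(1 - (1 - 2(s-r))^k)$ (`effective_initial_copies()`); its rebound
quantities are computed numerically from the curve rather than from the
small-$k$ closed forms. Under rescue by new mutation the mutant component
carries an extra factor $r/s$, the price of waiting for a successful
mutation to arise; a finite-time convolution against the waiting-time
density (adding a factor $1 - e^{-st}$) is available via
`form = "convolution"` and is evaluated by adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-8}$). Conditional on rescue
and once $t$ is appreciable, mutant copy numbers are approximately
exponential, so the variance of the total size is the squared conditional
mutant mean (`population_size_variance()`); the approximation is expected
to be poor at small $t$.

Closed forms for the rebound follow directly
(continuous time): $t_{\min} = \ln(2N_0r)/s$ (standing) or
$\ln(2N_0s)/s$ (new mutation, independent of $r$); the minimum expected
size is the curve at $t_{\min}$; the mutant/wildtype ratio there is
$r/(s-r)$ exactly; and recovery to $N_0$ takes
$\ln(2N_0(s-r))/(s-r)$, plus $\ln(s/r)/(s-r)$ under new mutation. These
assume the wildtype is negligible at recovery, an unchanged carrying
capacity, and exponential growth throughout.

### Time conventions

The analytic default is continuous time ($e^{-rt}$), matching the closed
forms above. A discrete convention ($(1-r)^t$, $(1+s-r)^t$) is provided so
curves can be compared generation-by-generation with the simulator; the two
differ by $O(r^2 t)$ in the exponent, which is invisible on the scale of
the curves but measurable with tens of thousands of conditioned
realizations. Validation tests that compare ensemble means against the
theory at 3 standard errors therefore use the discrete convention; with the
continuous curve the convention gap itself (about 1% at
$t \approx 2/r$) would be flagged. Closed-form rebound quantities switch to
the numeric argmin of the discrete curve automatically.

## Waiting times for the successful mutation

The origin generation of the mutation that rescues the population has,
to first approximation, the geometric (exponential) density with rate $r$:
the mutational supply declines with the wildtype, so rescue is more likely
early than late. The improved form treats origins of *establishing*
mutations as an inhomogeneous Poisson process with intensity
$\lambda(t) = 2u(s-r)N_0e^{-rt}$ and uses the conditional first-arrival
density $\lambda(t)e^{-\Lambda(t)}/(1 - e^{-\Lambda(\infty)})$; its
normalizer is exactly $P_{\mathrm{new}}$, which ties the two results
together. The improved density concentrates earlier whenever rescue is
appreciable and converges to the geometric one as $u \to 0$.

The distinction matters for how the simulator attributes rescue. If one
credits the *first lineage to reach the establishment threshold*, then in
replicates with a single establishing arrival — the vast majority when
rescue is not too likely — the credited origin is simply a random
establishing arrival, whose density is the geometric form by construction.
The theory's waiting time is instead the *earliest* establishing arrival.
The engine's default attribution (`attribute = "earliest"`) therefore waits,
after establishment, for any still-alive earlier-origin lineage to die or
cross the threshold, and credits the minimum origin among crossers;
`"first_cross"` is available for comparison. Under the earliest rule the
simulated origin distribution is fit better by the improved density, as it
should be.

## The simulator

`simulate_trajectory()` is a transparent single-population implementation
(per-lineage bookkeeping, runs to true demographic extinction);
`run_ensemble()` is the vectorized engine used for everything quantitative.
Design choices:

* **Offspring law.** Independent per-individual Poisson offspring with the
  stated means (default); a binomial alternative (at most two offspring,
  mean preserved) probes sensitivity to the offspring variance. The
  establishment frequency of a single copy is checked against the PGF fixed
  point of the *chosen* law, not merely Haldane's approximation.
* **Standing copies as one class.** The $k$ standing copies are tracked as
  one aggregate count: sums of independent Poisson draws are Poisson, so
  class totals are exact. New mutations are tracked per lineage (origin
  generation, counts) for attribution and waiting-time studies.
* **Mutation timing.** Applied to wildtype offspring at birth
  (binomially, probability $u$ per offspring), so $u$ is a per-gamete rate;
  several mutations may arise in one generation.
* **Establishment threshold.** A lineage (or the standing aggregate)
  counts as established at $\lceil 10/(2(s-r))\rceil$ copies, making the
  subsequent loss probability below $e^{-10}$; misclassification is
  negligible. Unresolved runs are censored at $t_{\max} = \lceil 20/(s-r)
  \rceil$ generations (censoring is counted and reported; in practice it is
  essentially zero). Both are configurable.
* **Regulation.** When the total exceeds $K$, the population is downsampled
  multinomially to exactly $K$ across classes, preserving expected
  proportions.
* **Classification with `u = 0`.** Loss of every beneficial copy makes
  extinction certain, so such replicates are classified extinct immediately
  rather than simulated to demographic extinction; with $u > 0$ a replicate
  fails only when empty.
* **Reproducibility.** One R RNG stream, seeded once from the master seed,
  with batches processed sequentially: ensembles are bit-identical given
  the seed. The package does not parallelize; a parallel implementation
  would need per-replicate streams.
* **Memory.** Per-generation states are stored only for replicates that are
  still unresolved, and full curves are reconstructed only for rescued
  replicates, so ensembles of a million replicates fit comfortably in
  memory.

## Conditioning and the rebound estimator

`conditional_moments()` averages only replicates that were ultimately
rescued (no re-weighting), on the common grid $0..\mathrm{horizon}$.
`empirical_rebound()` smooths the mean total curve with a centered moving
average (window 5 generations by default — enough to suppress
generation-level noise without displacing the minimum; the raw argmin is
reported alongside) and reads off the minimum's location, value, and the
mutant/wildtype ratio there. Standard errors come from a nonparametric
bootstrap over rescued replicates, which captures the argmin-location
uncertainty that a delta method at fixed $t$ would miss. A minimum on the
grid boundary raises an error rather than returning a boundary artifact.

### The rebound experiments run without the ceiling

The rebound theory describes unregulated decline and regrowth. With
$K = N_0$ and a shallow decline (e.g. $r = 0.001$), the exponential spread
of conditional sweep sizes means a nontrivial fraction of rescued
replicates reach the ceiling well before the *mean* curve's minimum;
regulation then erodes their wildtype class and inflates the measured
mutant/wildtype ratio (we measure 0.072 rather than ~0.053 in that
configuration). The published observed ratios match ceiling-free theory, so
the package's rebound experiments (acceptance script and validation tests)
disable regulation (`K = Inf`) — one protocol for all design points, chosen
to match the regime the theory describes. Rescue *probabilities* are
insensitive to this choice, since establishment happens far below any
plausible ceiling.

## Problem sizes and what the tests show

The validation experiments use 20,000 rescued realizations per rebound
design point (bootstrap standard errors on the ratio of 0.002–0.016), 5,000
for the U-curve band test, 6,000 for waiting-time comparisons, and $10^5$
replicates for establishment frequencies — sizes at which every
Monte-Carlo band is a few per mil to a few percent wide and the whole suite
runs in a few minutes on one core. The simulated rebound ratios land within
about 2–7% of the published observed values; note that the three published
observations corresponding to the *same* theoretical ratio 0.333 scatter by
about ±5% among themselves, so agreement much tighter than that is not an
attainable target for any reimplementation.

The generator emulates exactly the model above — it is the model. Passing
tests therefore demonstrate internal consistency of theory and simulation
and correct implementation of both, not realism of the model itself: real
rescued populations have overlapping generations, demographic and
environmental stochasticity beyond Poisson reproduction, density regulation
subtler than a hard ceiling, diploid genetics, multiple loci, and changing
carrying capacities. The theory is also explicitly asymptotic: conditional
means are accurate once $t$ is appreciable (the variance approximation
"is less good early on"), and all closed forms assume $s - r$ small enough
for the establishment approximations.

## Known limitations

* Haploid, single-locus, abrupt environmental change only; no gradual
  change, no diploid dominance schemes, no interference among beneficial
  lineages.
* The new-mutation curve's default asymptotic form slightly overstates the
  mutant component at very small $t$ (use the convolution form there).
* The improved waiting-time density uses Haldane's establishment
  probability inside its intensity; at large $s - r$ the PGF fixed point
  should replace it.
* `rescue_summary()` reports `NA` for rebound quantities when no interior
  minimum exists ($2N_0r \le 1$), rather than extrapolating.
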