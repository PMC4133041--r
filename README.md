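# evorescue

Theory and exact forward simulation of **evolutionary rescue** at a single
haploid locus after a sudden environmental change — for population
geneticists, conservation modelers, and experimental-evolution researchers
who need the quantitative anatomy of the U-shaped population-size curve:
how likely rescue is, where it comes from, how far the population falls,
and when it rebounds.

## The model

At generation 0 the environment changes: the wildtype allele's absolute
fitness drops to `1 - r`, so a population of size `N0` declines
geometrically toward extinction. A beneficial allele with fitness
`1 + s - r` (`s > r`) is either present as `k` rare standing copies
(frequency `p0 = k/N0`) or arises recurrently by mutation at per-gamete
rate `u`. Growth is exponential up to a ceiling `K`. The package provides,
in closed form,

- rescue probabilities, with per-copy establishment probability
  `2(s - r)` (Haldane):
  `P_new = 1 - exp(-2 N0 u (s-r)/r)`,
  `P_standing = 1 - exp(-2 N0 p0 (s-r))`, and their exact composition;
- the condition for standing variation to be the likelier source of
  rescue, `p0 > u/r`;
- the rescue-conditioned expected trajectory with the *oversampling
  correction*: conditional on rescue, a rare allele sweeps as if it started
  from `1/(2(s-r))` copies, so
  `E[N(t)] = N0 exp(-r t) + exp((s-r) t) / (2(s-r))`
  (times `r/s` in the mutant term under new mutation), plus its variance;
- rebound time `ln(2 N0 r)/s` (standing) or `ln(2 N0 s)/s` (new mutation),
  the minimum expected size, the mutant/wildtype ratio `r/(s-r)` at the
  rebound, and the recovery time `ln(2 N0 (s-r))/(s-r)`;
- waiting-time densities (geometric and improved) for the origin of the
  mutation that rescues the population.

Every analytic result is validated by an exact, vectorized forward Monte
Carlo simulator (`run_ensemble()`) whose ensembles are conditioned on
rescue; the simulator itself is checked against the numeric fixed point of
its offspring-law generating function. See the methods vignette
(`vignettes/evolutionary-rescue.Rmd`) for assumptions, conventions, and
design choices.

## Worked example

```r
library(evorescue)

p <- rescue_params(N0 = 1e4, r = 0.01, s = 0.02, k = 1)
rescue_summary(p)
#>   p_rescue_new p_rescue_standing p_rescue_total   source t_min N_min
#> 1            0            0.0198         0.0198 standing 264.9  1414
#>   ratio_at_tmin t_recovery dominant_source
#> 1             1      529.8        standing
```

One standing copy rescues with probability ~0.0198 (the exact
establishment probability of a single copy; Haldane's approximation gives
0.02). Conditional on rescue the population is expected to bottom out
around generation 265 at ~1414 individuals — mutants and wildtypes then
equally common (`ratio_at_tmin = 1`, since `r/(s-r) = 1` here) — and to
regain its initial size around generation 530.

The simulator reproduces this conditionally on rescue (regulation disabled,
the regime the rebound theory describes):

```r
ens <- run_ensemble(rescue_params(1e4, 0.01, 0.02, k = 1, K = Inf),
                    n_successes = 2000, seed = 1)
ens
#> <rescue_ensemble> 104673 runs (until_successes): 2000 rescued, 102673 extinct, 0 censored
#>   rescued-run curves recorded on generations 0..567
empirical_rebound(ens, boot = 50)
#>   t_min_hat t_min_raw N_min_hat ratio_hat se_t_min se_ratio
#> 1       261       261      1384     0.917     2.61   0.0528
```

2000 rescued realizations put the empirical rebound at generation 261 with
a mutant/wildtype ratio of 0.92 ± 0.05 — on top of the analytic 265 and
1.00. `autoplot(ens)` overlays the conditional mean on the corrected and
naive analytic curves (the classic U-curve contrast), and
`plot_waiting_times()` compares simulated origin times of successful
mutations with both analytic densities.

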