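# repsecr

Density estimation from spatially replicated capture–recapture arrays.

Wildlife surveys of wide-ranging species increasingly use *clustered*
spatially explicit capture–recapture (SECR) designs: many small, widely
separated arrays of proximity detectors (baited hair corrals, camera
traps), each treated as an independent replicate within a large region
of interest. Pooling data across replicates and assuming common
detectability is tempting — but when detectability actually varies in
space, pooled SECR density estimates are biased low by 20–30%.
`repsecr` implements the alternative: estimate detectability and
density *locally* on each array by maximizing the SECR conditional
likelihood, then combine the replicates with design-based estimators of
average density and its variance.

## What it computes

For binary proximity-detector data with half-normal detection
`g(d) = g0 exp(−d²/2σ²)`:

* **Local fits** (`fit_secr`): MLE of `(g0, σ)` on the link scale by
  conditional likelihood over a discretized habitat mask; effective
  sampling area `â = Σ p·(x) ΔA` with delta-method variance; density
  `D̂ = n/â` (per 100 km²) with Poisson variance
  `D̂²(1/n + var(â)/â²)` and lognormal 95% CI. Replicates can also be
  fitted jointly with constant, additive, or fully array-specific
  ("interactive") detection parameters; the interactive joint model
  reproduces the independent fits.
* **Regional combination** (`region_estimate`): mean of array-specific
  densities `D̂_region = J⁻¹ Σ n_j/â_j`, with an analytic (Poisson)
  variance `D̂²(n/n² + Σvar(â_j)/Â²)` and an empirical variance that
  replaces `var(n) = n` with the across-array sample variance
  `J/(J−1) Σ (n_j − n/J)²`.
* **Simulation study** (`make_scenario`, `run_study`): a 200 × 300 km
  region in three bands sampled by six 5 × 8 detector arrays at 2-km
  spacing over 6 occasions, with four scenarios crossing constant /
  band-varying density (12 vs 6/18/12 per 100 km²) and detectability
  (g0 0.30 vs 0.25/0.30/0.35; σ 1500 vs 1000/2000/3000 m), summarized
  as bias (MPRB), precision (MRSE) and CI coverage of local and
  regional estimates.

## Worked example

```r
library(repsecr)
sc    <- make_scenario(1)                      # homogeneous base scenario
pop   <- sample_population(sc, seed = 101)     # Poisson activity centres
capts <- simulate_captures(pop, sc, seed = 102)

fit_secr(capts[[1]], sc$design[[1]])           # one array, fitted alone
#> Half-normal SECR fit (conditional likelihood)
#>   sharing: independent; arrays: G1
#>   G1: n = 24, g0 = 0.3123, sigma = 1474.6 m, a = 250.6 km2,
#>       D = 9.58 (6.39-14.36) per 100 km2
#>   logLik = -354.934, params = 2, AICc = 714.440

fits <- fit_secr(capts, sc$design, sharing = "independent")
region_estimate(fits)
#> Regional density over 6 arrays (mean estimator)
#>   D = 10.911 per 100 km2
#>   Poisson:   SE 0.872 (RSE 8.0%), 95% CI 9.331-12.758
#>   empirical: SE 0.425 (RSE 3.9%), 95% CI 10.110-11.775
```

The single-array fit recovers the generating parameters (true g0 0.30,
σ 1500 m) and estimates local density 9.6 per 100 km² (truth 12; the
lognormal CI covers it). Averaging the six replicate arrays gives a
regional density of 10.9 per 100 km² with an 8% relative SE under the
Poisson variance. A full bias/precision/coverage table for any scenario
comes from `run_study(scenario_id, iterations, seed)`.

A command-line interface wrapping the same functions is in
`inst/cli/repsecr` (subcommands `simulate`, `fit`, `combine`, `study`).

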