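# gaspread

Quantifying the regional spread of gamma-band activation in task MEG.

During a sustained grip, gamma (30–48 Hz) and high-gamma (52–80 Hz)
oscillations show brief, focal cortical activations, while beta
(13–30 Hz) power desynchronises with movement. In amyotrophic lateral
sclerosis (ALS), impaired inhibitory interneuronal control is thought
to let gamma activation spread over far more of the cortex than in
healthy controls — and the degree of spread tracks how fast the disease
progresses. `gaspread` implements that analysis end to end for
parcellated source-space MEG epochs, together with a synthetic cohort
generator so every stage is validated without access to patient data.

## The statistic

For participant *p*, region *r*, band *b* and 100 ms time bin *t*, let
`x[r,b,t]` be the trial-averaged, baseline-corrected (percent-change)
band power. Thresholds are calibrated on the healthy-control (HC) group
per region × band:

    upper[r,b] = mean_HC(x[r,b,·]) + 2 · sd_HC(x[r,b,·])
    lower[r,b] = mean_HC(x[r,b,·]) − 2 · sd_HC(x[r,b,·])

pooling values over participants and all bins of the epoch. A region is
*activated* in bin *t* when `x > upper`, *deactivated* when `x < lower`.
The spread time course counts activated (and deactivated) regions per
bin, and the **gamma activation spread** is its mean over the tonic
grip window:

    GAS = mean over bins with centers in [1 s, 3 s] of #{r : x[r,gamma,t] > upper[r,gamma]}

Group contrasts (ALS vs HC per band × bin, plus the GAS scalars) and
clinical associations (`score ~ GAS + age + sex` within ALS) use OLS
with Freedman–Lane permutation inference and max-|t| family-wise error
correction across the whole tested family. Behavioural summaries are
compared with Welch's t test, Bonferroni-corrected.

## Worked example

A small simulated cohort (5 HC + 5 ALS, 52 regions, 10 trials each,
gamma band) through the full pipeline:

```r
library(gaspread)

cfg <- gas_config(
  sim  = sim_config(n_hc = 5, n_als = 5, n_regions = 52,
                    n_trials = 10, fs = 200, seed = 8),
  bands = "gamma", n_perm = 500, seed = 8,
  clinical_outcomes = "progression_rate", video = FALSE)
res <- run_pipeline(cfg, "gas_run")

aggregate(gas_gamma ~ group, res$gas, mean)
#>   group gas_gamma
#> 1   ALS     28.66
#> 2    HC      7.90

gs <- res$group_stats
gs[gs$measure == "gas", c("element", "beta", "t", "p_uncorrected", "p_fwe")]
#>             element     beta        t p_uncorrected       p_fwe
#> gas_gamma gas_gamma 19.46471 9.453102   0.001996008 0.003992016
```

The generator plants ~20 active gamma regions per trial in ALS against
~7 in HC; the pipeline recovers a group GAS difference of ~19 regions
(`beta`), significant after correction across all 122 tested elements
(`p_fwe ≈ 0.004` at 500 permutations). `gas_run/` now contains the
per-participant GAS table, threshold table, statistics CSVs, a spread
time-course figure and a manifest with checksums; reruns with the same
config and seed reproduce every CSV byte for byte.

Summary-statistic Welch tests work directly on published cohort tables:

```r
welch_from_summaries(61.76, 16.42, 33, 61.02, 12.65, 42)
#> Welch t = 0.214, df = 58.8, p = 0.8314 (Bonferroni m = 1: 0.8314)
```

A full simulated-cohort run from the shell:

```sh
Rscript scripts/run_pipeline.R --out gas_run --seed 1 [--config my_config.yaml]
```

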