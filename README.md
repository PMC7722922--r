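# noveltag

Behavioral tagging predicts that a salient, unrelated experience — such as
exploring a **novel** environment — can rescue the consolidation of a weak
memory formed shortly before. `noveltag` implements the full analysis
pipeline for studies that test this effect in a 2×2 factorial design
(diagnosis: ADHD vs. typically developing × environment: familiar vs.
novel), where memory consolidation is measured by the retention score

```
retention = LTM hits / STM hits × 100
```

the percentage of words recalled immediately after learning (STM, out of
20) that are still recalled 24 h later (LTM). The package is aimed at
researchers analysing free-recall counts together with virtual-environment
telemetry (avatar positions logged every 100 ms in Minecraft block units).

## What it computes

* **Bayesian linear models of retention** with the design's conventions:
  `retention ~ novelty × diagnosis` (main model) and
  `retention ~ covariate × diagnosis × novelty` for each control variable
  (novelty seeking, immersion, exploration), covariates z-scored so slopes
  are per 1 SD. Priors: Student-t(3, 50, 30) on the intercept,
  half-Student-t(3, 0, 10) on the residual SD, flat on all other
  coefficients. Sampling uses the package's own Metropolis-within-Gibbs
  sampler (4 chains × 2000 draws, 1000 warm-up) with split-R̂ and ESS
  diagnostics.
* **HDI + ROPE decisions.** Each group contrast or slope is summarised by
  its posterior mean *b*, 95% highest density interval, and the share of
  the posterior outside the region of practical equivalence [−5, 5] %
  retention (one word out of twenty). A verdict is *significant* when
  ≥ 95% of the posterior lies outside the ROPE, *practically zero* when
  ≥ 95% lies inside, *undecided* otherwise.
* **Group posteriors and contrasts** rebuilt draw-by-draw from the
  dummy-coded coefficients, so every reported quantity is invariant to the
  reference-cell choice.
* **Exploration metrics**: unique 2×2-block tiles visited per session from
  raw position logs, and novel-vs-familiar occupancy difference maps.
* **Classical control analyses**: two-way factorial ANOVAs (Type III,
  sum-to-zero coding) with partial η².
* **A synthetic cohort and trajectory generator** reproducing the study's
  structure (Binomial(20, p) recall, STM-matched condition assignment,
  bounded persistent random walks at 10 Hz) for parameter-recovery testing
  without any data download.

## Worked example

```r
library(noveltag)

sim <- generate_cohort(synth_cohort_config(seed = 42))
fit <- fit_main_model(sim$cohort, config = sampler_config(base_seed = 42))
print(fit)
```

```
Main model: retention ~ novelty x diagnosis, n = 68
  ADHD-familiar  mean 55.07, 95% HDI [49.27, 61.27]
  ADHD-novel     mean 66.57, 95% HDI [60.65, 72.36]
  TD-familiar    mean 71.45, 95% HDI [65.31, 77.38]
  TD-novel       mean 72.71, 95% HDI [66.66, 78.78]
Contrasts (ROPE [ -5 , 5 ]):
  ADHD-familiar vs TD-familiar b = -16.38, HDI [-24.06,  -7.67],  99.50% outside -> significant
  ADHD-novel vs TD-novel       b =  -6.14, HDI [-14.51,   2.61],  62.50% outside -> undecided
  ADHD-novel vs ADHD-familiar  b =  11.50, HDI [  2.86,  19.55],  93.30% outside -> undecided
  TD-novel vs TD-familiar      b =   1.25, HDI [ -7.34,   9.84],  27.30% outside -> undecided
```

Read: in this simulated cohort, patients who explored a familiar
environment retained 16.4 percentage points less than typically developing
peers, and ≥ 95% of that contrast's posterior lies outside [−5, 5], so the
impairment is declared significant; the within-patient novelty benefit
(b = 11.5) leaves 93.3% outside the ROPE — suggestive but short of the 95%
bar, hence *undecided* at n = 17 per cell.

The control-variable ANOVA on the same cohort:

```r
two_way_anova(sim$cohort$exploration_tiles, sim$cohort$diagnosis, sim$cohort$novelty)
#>             effect        ss df    F       p partial_eta_sq
#>          diagnosis 135013.24  1 3.80 0.05580          0.056
#>            novelty 304716.24  1 8.57 0.00474          0.118
#>  diagnosis:novelty  31004.47  1 0.87 0.35400          0.013
```

An end-to-end run (cohort → models → ANOVAs → report files) is
`run_pipeline(pipeline_config(out_dir = "report", seed = 7))`, or from a
shell via `inst/scripts/run_pipeline.R`.

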