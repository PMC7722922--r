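---
title: "Models and methods behind noveltag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind noveltag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noveltag)
```

# The scientific question and the response variable

Behavioral tagging holds that weakly encoded memories can be consolidated
if a salient unrelated event — here, exploring a *novel* virtual
environment — occurs within a critical window around learning. The design
crosses diagnosis (ADHD vs. typically developing, TD) with environment
novelty (familiar vs. novel), n ≈ 17 per cell. Memory consolidation is the
retention score, `LTM / STM × 100`: the percentage of words recalled
immediately (out of 20) that survive a 24 h delay. Retention is always
recomputed from the hit counts; a participant with zero STM hits has no
defined retention and is excluded with a warning rather than imputed.
Values above 100 (hypermnesia) are arithmetically valid and retained —
the formula imposes no cap and clipping would bias group means downward.

# The Bayesian retention models

The main model is Gaussian linear regression on dummy-coded factors,

$$\text{retention}_i \sim \mathcal{N}(\mathbf{x}_i^\top\beta,\ \sigma^2),
\qquad \mathbf{x}_i = (1,\ \text{novel}_i,\ \text{TD}_i,\
\text{novel}_i\,\text{TD}_i),$$

with priors chosen to be weakly informative on the quantities with a
natural scale and agnostic on the effects:

* intercept: Student-t(df 3, location 50, scale 30) — prior knowledge
  that patients typically retain about half of the learned words;
* residual SD: half-Student-t(df 3, scale 10);
* all other coefficients: flat over the real line, giving positive and
  negative effects (and zero) equal prior weight.

Flat coefficient priors are improper, so the sampler requires more rows
than columns (posterior propriety); this is enforced as a precondition.
The three control-variable models replace the factorial formula by the
full three-way interaction `retention ~ covariate × diagnosis × novelty`
(eight terms), with the covariate z-scored — centred and scaled by the
n−1 sample SD **pooled over all rows entering the model**, not per group.
Pooled standardisation is what makes "change in retention per 1 SD"
comparable across the four cells; per-group scaling would silently give
each cell its own unit. Listwise deletion is per model: the main model
keeps every participant with valid counts, each covariate model drops
only rows missing that covariate.

## Group posteriors, contrasts and slopes

Dummy coding expresses coefficients relative to a reference cell
(default ADHD-familiar; configurable). No reported quantity depends on
that choice: per-cell posteriors are rebuilt draw-by-draw as the sum of
the intercept and the coefficient draws selected by the cell's dummy
pattern, contrasts are elementwise differences of those cell draws, and
per-cell covariate slopes are the covariate main effect plus its selected
interaction draws. Reference invariance is verified by tests that refit
under the opposite coding. Because contrasts are formed draw-wise, they
are exactly consistent with each other (the triangle identity
`(AN−AF) + (AF−TF) = AN−TF` holds per draw, not just in expectation).

# The sampler

No MCMC backend is assumed; the package carries its own sampler, designed
around the model's partial conjugacy so that the default budget of
4 chains × 2000 draws (first 1000 discarded as warm-up, 4000 pooled
retained draws) yields effectively independent draws:

1. **σ update.** A draw from the conjugate inverse-gamma conditional
   implied by a flat prior on log σ (`σ² = SSR/χ²_n`), accepted by a
   Metropolis ratio that corrects for the half-t prior. The correction
   ratio `half-t(σ*)σ* / half-t(σ)σ` is slowly varying, so acceptance is
   near 1; under a flat σ prior the step is exact Gibbs.
2. **Intercept update.** An independence proposal from the intercept's
   *marginal* conditional likelihood given σ (the flat-prior coefficients
   integrated out analytically), accepted by the Student-t prior ratio
   alone — the Gaussian factors cancel.
3. **Remaining coefficients.** An exact draw from their conditional
   multivariate normal given intercept and σ (flat priors are conjugate).

Steps 2–3 together are a joint block draw of β given σ, so the only
serial dependence left runs through σ, which at n ≫ p is nearly
independent of β. Observed ESS is close to the nominal 4000 and split-R̂
sits at 1.000–1.002. Chains are seeded `base_seed + chain`, initialised
at the least-squares solution (residual SD for σ) with per-chain jitter,
and runs are bit-reproducible given the seed. Under fully flat priors the
scheme reduces to exact Gibbs for classical Bayesian regression, whose β
marginal is multivariate-t — the closed form used as the test oracle.
A prior-only mode switches the likelihood off and samples the (proper)
intercept and σ priors through the same prior-density code by adaptive
random walk; it is restricted to intercept-only designs because flat
coefficient priors have no distribution to sample.

An earlier implementation used a preconditioned random-walk block for all
coefficients; it was correct but mixed marginally (R̂ ≈ 1.02 at the
default budget) and was replaced by the conjugacy-based scheme above.

## Convergence diagnostics

`rhat()` implements split-R̂ (each chain halved; between/within variance
ratio) and an autocorrelation-based ESS with Geyer's initial-positive-
sequence truncation. Convergence is declared when every split-R̂ < 1.01;
model fits warn, and the pipeline records, when it is not.

# HDI + ROPE decisions

The 95% HDI is estimated as the shortest contiguous window of the sorted
draws containing `ceil(0.95 n)` draws — deterministic given the draws, no
density smoothing; ties go to the smallest lower bound. At least 100
draws are required (fewer gives an unstable estimate). The ROPE defaults
to [−5, 5] percent retention: with 20 words, a 5-point difference is one
word, the smallest effect of interest. Draws exactly on a ROPE boundary
count as inside (closed interval; immaterial at 4000 continuous draws).
The primary decision statistic is the share of the pooled posterior
outside the ROPE — *significant* at ≥ 95% outside, *practically zero* at
≥ 95% inside, *undecided* otherwise; both thresholds are closed, matching
the "at least 95%" rule. The HDI-containment flags are reported alongside
because both phrasings of the rule are in common use; for unimodal
posteriors "HDI fully outside" is the stricter of the two and never
disagrees in direction.

**Power at this design size.** With a true contrast of 15, residual SD 13
and 17 per cell, the contrast posterior SD is ≈ 13·√(2/17) ≈ 4.5, so a
*significant* verdict needs a realized sample difference ≥ 5 + 1.645·4.5
≈ 12.3 — the analytic probability is only ≈ 0.7, and the count
discretisation described below shaves a further point or two off.
Simulations at this n therefore show verdict rates near that boundary,
and equivalence (≥ 95% inside a 10-unit ROPE against a ≈ 4.5-SD
posterior) is essentially out of reach: null cohorts come out *undecided*,
not *practically zero*. This is a property of the decision rule at this
sample size, not of the implementation.

# Classical control analyses

The two-way ANOVAs for novelty seeking, immersion and exploration use
`car::Anova` with sum-to-zero contrasts and Type III sums of squares —
identical to sequential sums in balanced designs and the conventional
choice for the mildly unbalanced cells that listwise exclusions leave
(Type II is available for sensitivity). Partial η² is
`SS_effect / (SS_effect + SS_residual)`. Both degrees of freedom are
always reported. The independent test oracle is the textbook balanced
two-way decomposition computed from cell means, plus a 1000-replicate
type-I calibration at α = 0.05.

# Telemetry

Position logs are 10 Hz samples `(t_ms, x, y, z)` in block units.
Exploration is the number of unique tiles entered, with tiles of
2×2 blocks anchored at the world origin: sample → tile
`(⌊x/2⌋, ⌊z/2⌋)`. Tiles are computed in 2-D on the horizontal (x, z)
plane, ignoring altitude — the multi-floor mansion could alternatively be
stratified by floor, which would change absolute counts but not the
contract; an optional y-band filter supports per-floor views. No
resampling or path interpolation is applied: at 10 Hz and walking speed
(4.3 blocks/s, 0.43 blocks per sample) no 2-block tile can be skipped
between samples. Occupancy difference maps count, per tile, the distinct
participants of each group who entered it (0/1 per participant), and are
exactly antisymmetric in the group order.

# The synthetic cohort generator

The generator is the package's stand-in for the study cohort and defines
the conditions under which the pipeline is validated:

* STM ~ Binomial(20, p), p = 0.42 (ADHD) / 0.55 (TD), redrawn on zero —
  anchored to the "about half the words" intercept rationale;
* latent retention ~ Normal(cell mean + Σ slope · z(covariate), SD 13);
  cell means default to 52 / 67 / 75 / 71 (ADHD-fam / ADHD-nov / TD-fam /
  TD-nov), whose pairwise differences equal the reported group contrasts
  up to rounding; the absolute anchor (TD-familiar = 75) is a simulation
  convention, since only differences are identified;
* LTM = `round(STM · retention / 100)` clamped to 0..20, and the cohort's
  retention is recomputed from these counts. This discretisation is
  deliberate: it reproduces the granularity a real word-list study has
  (≈ 100/STM percent per word), which widens the effective retention SD
  from 13 to ≈ 13.4 at ADHD-level STM scores and slightly truncates at
  the 20-word ceiling;
* covariates ~ Normal(cell mean, cell SD) with the observed per-cell
  summaries as defaults (immersion truncated to its ±30 scale,
  exploration rounded to a count). Generator slopes are expressed per SD
  of the configured *cell* SD; because the fitted models standardise
  pooled, the `SyntheticTruth` object also stores the implied
  per-pooled-SD slopes (using the realized pooled SD) as the oracle for
  recovery tests.

Condition assignment in the real study matched participants on STM
performance; `pseudo_random_match()` reproduces the intent with a
documented stand-in (the exact algorithm is unreported): rank by STM,
random tie-breaks, split consecutive pairs one-to-each condition, odd
leftover at random. Condition sizes differ by at most one and baseline
STM distributions are near-identical by construction.

What the generator does **not** emulate: environment geometry (rooms,
floors, two distinct worlds), recognition memory, questionnaire item
structure, or any non-Gaussian features of real retention distributions.
Passing recovery tests therefore validates the estimation machinery under
the model's own assumptions, not the model's adequacy for any particular
real dataset.

## Trajectories

Sessions are persistent random walks at the game's nominal 4.3 blocks/s
inside a 120×120-block arena, reflected at the walls, sampled every
100 ms, with duration uniform on 10–20 min. Turning noise has SD
`(1 − persistence)·π` radians per step. Exploration propensity is a
revisit-avoidance dial: every 5th sample (≈ once per traversed tile),
with the configured probability, the walker checks the tile 3 blocks
ahead and, if already visited, turns by the gentlest of ±45/90/135/180°
that points at an unvisited tile, preferring a sticky side (rare random
flips) so it sweeps the frontier of the visited region instead of
oscillating. Coverage is monotone in the dial, which a naive
"turn away at random" rule is not — random large turns destroy
persistence and *reduce* coverage. Defaults (persistence 0.7, avoidance
0.5) were calibrated once so that study-scale sessions produce unique-
tile counts in the observed range (means ≈ 640–990; the generator's
default mean is ≈ 850); they shape realism only and are not an
estimation target.

# Numerical and design choices

* File formats: comma-separated UTF-8 with header, decimal point
  regardless of locale; empty string = missing. Trajectory CSVs are
  `t_ms,x,y,z`. Round trips are exact for integers and far below 1e-9
  for reals.
* Degenerate inputs: constant responses collapse the σ posterior toward
  zero without crashing (σ draws stay positive); rank-deficient designs
  and empty factorial cells are errors naming the offending columns or
  cells; non-monotone trajectory timestamps are dropped with warnings.
* Reported precision follows the field convention: effects b and ROPE
  percentages to two decimals.
* Suite sizing: replicate-based checks use 100–200 replicates per
  condition and 40k draws for the closed-form sampler oracle; these sizes
  put Monte-Carlo error well inside the asserted tolerances while keeping
  the default test run in minutes.
* The pipeline is end-to-end seedable: one seed pins cohort generation,
  chain seeds and report content; reports carry a config hash that
  changes exactly when an analysis-relevant setting changes.

# Known limitations

* The sampler's near-iid efficiency relies on the specific prior
  structure (proper priors only on intercept and σ); dense proper priors
  on all coefficients would need a different scheme.
* The HDI estimator assumes a unimodal posterior, which holds for these
  linear-model quantities but would mis-summarise multimodal draws.
* Tile metrics are 2-D; multi-floor environments conflate floors unless
  the y-band filter is used per floor.
* The decision rule's power analysis above shows that at 17 per cell the
  framework rarely reaches *practically zero*; absence of evidence
  against the ROPE should not be read as evidence of equivalence at this
  sample size.
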