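---
title: "Methods: bioindication, climatic debt and its determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioindication, climatic debt and its determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climdebt)
```

## The climatic debt

Community composition responds to climate warming with delay. When plant
assemblages are used as a bioindicator of temperature, that delay becomes
measurable: the *floristically reconstructed temperature* (FrT) of a survey —
the temperature its species composition indicates — falls short of the
*climatically reconstructed temperature* (CrT) actually observed at the
survey's location and year. The gap

$$dT = CrT - FrT$$

is the **climatic debt**: positive values mean the assemblage lags behind
warming. `climdebt` estimates this debt, constructs the abiotic, biotic and
anthropogenic covariates suspected to drive it, and fits a bootstrapped,
spatially thinned, observation-weighted partial least squares (PLS)
regression of the debt on those covariates.

Because the floristic and climate databases this kind of analysis uses are
restricted, the package ships a first-class synthetic-data generator that
plants a *known* debt and *known* covariate effects, so every stage can be
validated end to end by recovery experiments.

## The transfer function

FrT comes from a two-stage transfer function calibrated on surveys where the
response is known:

1. **Weighted-averaging PLS (WA-PLS).** Component 1 is classical weighted
   averaging on presence/absence data: species optima
   $u_k = \sum_i y_{ik} x_i / \sum_i y_{ik}$, site scores
   $s_i = \sum_k y_{ik} u_k / \sum_i y_{ik}$, followed by *classical linear
   deshrinking* (ordinary regression of observed on inferred — the default of
   the WA-PLS formulation we follow). Components $h \ge 2$ repeat the
   optimum/score cycle on the residuals of the previous fit, with scores
   orthogonalised against the earlier components under site-total weights.
2. **Random-forest residual stage.** A 500-tree random forest (the `ranger`
   implementation, seeded) is trained on the presence/absence columns with
   the WA-PLS calibration residuals as target; it captures nonlinear and
   interaction structure among species occurrences. The hybrid prediction is
   WA-PLS + forest.

The number of WA-PLS components is chosen by 10-fold cross-validated RMSD
(the source method is silent on this; CV is standard transfer-function
practice). Unknown species at prediction time are dropped silently but
counted in a per-survey diagnostic, since survey pools differ between
calibration and application periods. The same machinery calibrates any
bioindicated variable — we use it for temperature, soil pH and inverse C:N.

Calibration data pass an iterative filter first: surveys need at least 5
co-occurring species and species at least 5 occurrences, re-checked until
both thresholds hold.

## Species niche indices

**Tolerance ranges** (`TO_T`, degrees C; `TO_W`, mm) are the max-minus-min of
baseline-period climate at the species' occupied localities.

**Schoener's D**, $D = 1 - \tfrac12\sum_b |p_b - q_b|$, measures overlap of
two binned occupancy distributions. Bins are fixed-width — 0.5 °C for
temperature, 50 mm for precipitation, 0.5 units for C:N — spanning the pooled
range of the distributions compared; the width is a configuration knob
recorded in outputs.

**Distribution conservatism** (DC) asks whether a species kept its former
spatial distribution despite climate change; **niche conservatism** (NC)
whether its occupied climates track its former niche. Both are ratios
$D_{obs}/D_{ref}$ of overlaps with the past niche $N_0$. The "matched"
samples they need are drawn by histogram-matched subsampling: per-bin draws,
without replacement, proportional to the target distribution at the target's
sample size, replicated (100 times by default) and averaged. This equalises
both the size and the shape of the compared samples, which is what makes
niches comparable across periods with similar accuracy. Sampling noise can
push $D_{obs}$ marginally above $D_{ref}$; we clip at $D_{ref}$ so the index
respects its documented upper bound of 1.

A consequence of this matching worth knowing: DC is driven by how well the
current occupied climates can *reproduce the expected niche*. A species
displaced to cells climatically alien to its expected niche collapses the
index, while displacement to cells that happen to resemble the old niche does
not lower it — any sample drawn from such candidates overlaps $N_0$ at least
as well as the expected niche does. NC, whose matching target is $N_0$
itself, behaves the opposite way: staying put under warming (occupied
climates disjoint from $N_0$) drives it to 0, and perfect tracking keeps it
at 1.

## Landscape and human-pressure covariates

- `THET`: the sample standard deviation of fine-grid (nested) temperatures
  within the survey's 1-km cell; the range is available as an alternative
  statistic.
- Potential habitat: forest cells whose period-mean temperature lies within
  the species' thermal limits. `HP` (past habitat proximity) is
  $1/(d + \text{cell size})$ with $d$ the distance to the nearest
  past-habitat cell centre — the one-cell offset keeps the index finite and
  strictly monotone at $d = 0$.
- The aggregation index is `AI = e / e_max` with rook-adjacency shared edges
  and the largest-square-packing maximum; a single cell gets `AI = 0` by
  convention (no aggregation measurable). `dHA` is the current-minus-past AI
  within 10 km of the survey.
- `road_prox` is a plain point-to-polyline Euclidean minimum; `HPD` sums the
  population raster over cell centres within 10 km.
- Water and nutrient competition (`C_W`, `C_N`) average pairwise niche
  differentiation ($1 - D$ along the precipitation and C:N gradients) over
  the co-occurring species. A community-assembly null model (2,500
  richness-preserving uniform draws from the regional pool, two-sided
  add-one rank p-value) checks that observed differentiation is not a random
  sampling artefact; the add-one convention means p-values are never 0.

## The inference engine

Each of the (by default 5,000) subsample draws:

1. **Thins** surveys to a 10-km minimum pairwise distance by random-order
   greedy acceptance, suppressing spatial autocorrelation.
2. **Weights** observations by the inverse of their year's survey count, so
   each year contributes equal total weight.
3. **Standardizes** response and covariates to weighted mean 0 / sd 1
   *within the draw* — coefficients are then comparable standardized slopes.
   (Whether the source analysis standardized globally or per subsample is
   unstated; per-draw standardization is the choice consistent with
   comparing slopes within draws.)
4. **Extracts** the full set of weighted PLS components (weighted NIPALS:
   weight vectors maximise weighted covariance with the response, scores are
   orthogonal under the weighted inner product, the design is deflated per
   component).
5. **Selects** components by a weighted regression of the response on all
   scores, keeping those whose slope passes a t-test at
   $\alpha / (\text{components tested})$ (Bonferroni). The retained set may
   be non-contiguous. The divisor is always computed from the number of
   components actually tested: with the year term the standard determinant
   set has 20 predictor columns, giving the 0.05/20 = 0.0025 threshold.
6. **Back-transforms** the retained-component regression to per-variable
   standardized coefficients (exact for any retained subset via the rotation
   $R = W(P'W)^{-1}$), records the weighted $R^2$ and the per-variable
   variance shares $\text{share}_j = \sum_h Rd(y, t_h)\, w^{*2}_{jh}$, which
   sum to $R^2$ exactly because the weight vectors are unit-norm.

Draw-level failures (no component retained) are recorded and excluded from
summaries, with the failure rate reported. Coefficient significance uses the
bootstrap sign test: significant positive (negative) when at least 99 % of
draws lie above (below) zero. Percentile 2.5/97.5 intervals summarise the
draw distributions.

One honesty note on step 5: the first extracted score is *chosen* to
maximise covariance with the response, so its t-test is optimistic under a
null of no association (the expected score $R^2$ is of order $p/n$). On
pure-noise responses the procedure retains a component more often than the
nominal level, though rarely more than one. We implement the procedure as
described by its source; the inferential guarantee the package relies on is
the bootstrap sign test on coefficients, which is unaffected.

**Model variants.** `PLS0` fits the 19 standard determinants plus the year
term on all surveys; `PLS1` the same on the later period (from 1993);
`PLS2` adds canopy temperature buffering and the three disturbance
indicators (consumed as supplied covariates); `PLS3`/`PLS4` split the later
period into disturbed/undisturbed subsets, disturbance being the presence of
any of the silvicultural, disturbance or exotic flags.

**Measurement error.** `error_propagation()` re-runs the whole pipeline with
per-draw Gaussian perturbation of each covariate at its stated error sd
(never the response), so attenuation under measurement error is visible in
the coefficient distributions.

**Spatial diagnostics.** Moran's I per 10-km distance class (up to 150 km by
default; the source's classes are unstated), with subsample bootstrap CIs.
We reproduce the conventional fixed I = 0.05 flag for comparability and
report a 199-permutation p-value per class alongside, because a fixed
threshold is not a calibrated test.

## The synthetic generator

`sim_config()` describes a landscape (a smooth south–north temperature
gradient plus random smooth structure, 1-km cells), two climate periods (a
stationary baseline; a study period warmed by a linear trend reaching
`warming_total` at its last year, optionally spatially modulated), a species
pool with Gaussian niches on temperature, precipitation and soil pH, and
clustered survey placement (Poisson-cluster process) with deliberately
uneven yearly counts — so the 10-km thinning and the per-year weights have
real work to do.

The planted debt is phenomenological: occupancy is sampled from suitability
at the *effective* temperature
$T_{\text{eff}} = T_{\text{baseline}} + (1 - \lambda)\,\Delta T$, so the
community tracks only a fraction $1 - \lambda$ of the warming and
`true_debt` $= \lambda \Delta T$ exactly. No demography or dispersal is
simulated; the lag is imposed, not emergent. Defaults emulate the conditions
the package is meant to reproduce: ~1 °C total warming, a 760-species pool,
niche breadths of a few degrees, survey-level richness of a few dozen.

`simulate_predictor_table()` plants *effects*: covariates come from a
one-factor Gaussian model whose common factor is a smooth spatial field
(inducing both covariate and spatial correlation), and the response is a
linear combination with chosen standardized coefficients plus noise whose
variance is set to $1 - \beta'\Sigma\beta$ so the response has unit
variance — the planted coefficients then live on exactly the scale the
regression estimates.

What the generator does *not* emulate: real species' asymmetric and
multimodal niches, abundance information, observer and identification error,
non-stationary precipitation, and spatially structured disturbance. Passing
recovery tests therefore demonstrates the correctness of the machinery, not
the field accuracy of the original estimates.

## Problem sizes and numerical choices

The test-suite and acceptance runs use scaled-down study sizes chosen to
keep recovery experiments sharp while remaining quick: a 40 × 40 km
landscape, a 400-species pool, ~440 calibration and ~1,570 study surveys for
debt recovery, and 500 bootstrap draws (of the default 5,000) for effect
recovery — percentile CIs are correspondingly wider, which the tests
account for. Tolerances: exact identities at 1e-8; the planted-debt
recovery band is ±0.15 °C and planted-coefficient recovery ±0.1, both
inherited from the recovery experiment design.

Degenerate cases are explicit errors rather than silent NAs: constant
responses, zero-variance covariate columns within a draw, species with no
occurrences, empty forest masks, surveys sharing no species with a
calibration, zero-variance Moran fields, pools smaller than the community.
Random streams all derive from one master seed per run via a stream-hash, so
every stage is reproducible independently.

## Known limitations

- WA-PLS transfer functions attenuate compositional shifts near the
  calibration margins; end-to-end debt recovery is accurate to roughly a
  tenth of a degree at the sizes above, not exact.
- PLS coefficients under heavy component truncation are biased toward the
  retained subspace; the recovery experiments quantify this at the default
  settings.
- The conservatism indices inherit the matched-sampling interpretation
  documented above; alternative matchings (e.g. quantile matching) would
  shift their sensitivity.
- The null model assumes richness-preserving uniform assembly from the
  regional pool; frequency-weighted sampling is not implemented.
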