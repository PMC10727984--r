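---
title: "Modelling crop-yield responses to agricultural input shocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crop-yield responses to agricultural input shocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Industrial crop production depends on off-farm inputs — synthetic N, P and K
fertilizer, machinery, pesticides — whose supply can be disrupted. This
package estimates how proportional reductions ("shocks") of those inputs
would change crop yields and production on a gridded cropland map. The
method is purely statistical: within strata of similar climate, it learns
the observed cross-sectional relationship between input use and yield, then
asks what yield the model predicts when a cell's inputs are reduced to the
level other cells in the same stratum actually use.

Because real global input/yield rasters are large external datasets, the
package ships a synthetic-world generator with the same statistical
structure *and a known ground-truth yield response*, so every step of the
pipeline — and its counterfactual predictions — can be verified against
truth rather than merely inspected.

## Pipeline

1. **Climate binning.** Per-cell growing degree days (GDD) are accumulated
   daily: a day at temperature $T$ contributes $\min(T, T_{cut}) - T_{base}$
   when $T > T_{base}$, else 0; annual sums are averaged over the years of
   record (21 by default). Annual precipitation is the mean of annual sums.
   Over the cropland cells of the crop, both climatologies are split into
   rank-based quintiles and a cell's bin is the pair
   $b = 5(q_{GDD}-1) + q_{precip} \in \{1..25\}$. Marginal quintile counts
   are $N/5$ up to rounding; joint counts are only approximately equal
   unless the two climatologies are independent, so the package asserts
   equality on the marginals only. Ties are broken by first appearance in
   row-major cell order, making the assignment deterministic; an
   all-constant climatology is an explicit error. The phrase "summing the
   temperature" in the degree-day literature admits two readings — summing
   $T$ itself or $T - T_{base}$ on qualifying days; both are implemented
   behind `contribution=`, with the standard degree-day reading
   ($T - T_{base}$, capped) as the default. The default base (8 °C) and
   cutoff (30 °C) describe a temperate cereal and are this package's own
   choice; real applications should set crop-specific values.

2. **Input processing.** Pesticide high/low rate estimates are averaged,
   each pesticide layer is divided by its global 97.5th-percentile rate over
   cropland (type-7 linear-interpolation quantile, fixed so the worked
   examples are stable) and capped at 1, and the rescaled layers are summed
   into four groups (herbicides, insecticides, fungicides, others), giving
   group indices in $[0, 4]$ that preserve the weight of low-dose active
   ingredients. Country-level machinery (hp per 1,000 ha) missing for a
   country is filled with the unweighted mean of its continent. Irrigated
   and total harvested area become a percentage share (0 where no area).
   Topsoil density layers (hg/m³) convert to stocks as
   $\mathrm{t\,ha^{-1}} = \mathrm{density} \times \mathrm{depth\,[m]}$ (the
   unit factors cancel), with fine cells mean-aggregated into coarse cells.
   The final model covariates are the 14 enumerated by
   `model_covariates()`: N, P, K rates, non-mineral fertilizer, machinery,
   labour, the four pesticide groups, irrigation share, and soil N, P and
   organic carbon.

3. **Per-bin forests.** One random-forest regressor per climate bin, yield
   on the 14 covariates, with 1,000 trees, minimum terminal node 5, and 2
   candidate split variables by default — the last follows the stated
   practice for this analysis even though $p/3$ is the usual regression
   convention; it is configurable. Train/test splits are spatial: a coarse
   grid of 12×12-cell blocks (1° at 5-arcmin resolution; ragged at edges)
   is imposed and whole blocks are assigned to training
   ($\lfloor 0.75\,n_{blocks} \rfloor$, deterministic under seed) or
   testing, so spatially autocorrelated neighbours never straddle the
   split. Fitting and prediction repeat over 25 independent splits; all
   seeds derive deterministically from one master seed. Bins with fewer
   than 50 training rows (configurable) are skipped with a warning rather
   than fitted unreliably. Forests are fitted with `ranger`; an independent
   implementation (`randomForest`) serves as a cross-check in the tests.

4. **Scenarios.** Seven families — N, P, K, machinery, pesticide (all four
   groups at once), all fertilizers, all inputs — each at 25/50/75 %
   severity, plus a control with every shockable input at zero. A shock
   multiplies the shocked covariate columns by $(1-s)$; non-mineral
   fertilizer, labour, irrigation and soils are frozen. Scenario predictions
   reuse each iteration's fitted forests — no refitting under shock — so a
   severity-0 scenario reproduces the baseline bit-exactly.

5. **Aggregation and evaluation.** Production is yield × harvested area per
   cell, summed to countries and the globe; changes are percentages of the
   baseline, counting increases and decreases alike. Per-bin impact extent
   is the harvested-area-weighted share of cells losing at least 10 % of
   baseline yield (cell-count weighting behind a flag — the area weighting
   is this package's choice). Model skill is Nash–Sutcliffe efficiency on
   held-out blocks, classified very good (NSE > 0.75), good (0.65–0.75] or
   below; baseline country-mean yields are validated against the
   generator's noise-free truth by a production-weighted $R^2$; and
   prediction uncertainty is the per-cell coefficient of variation (sample
   SD / mean) of baseline predictions across the 25 iterations.

## The synthetic world

`generate_world()` draws, from a single seed and in a fixed order so worlds
are bit-reproducible:

* daily temperature with a latitudinal mean, latitude-dependent seasonal
  cycle and weather noise; patchy annual precipitation statistically
  independent of the temperature gradient (so all 25 joint bins stay
  populated and no climate quintile aliases with the 12-cell blocking
  grid);
* spatially autocorrelated input rates (box-smoothed Gaussian fields,
  correlation length a few cells) sharing a common "fertility" latent
  field, which induces the positive N–P–K–pesticide cross-correlations seen
  in intensification gradients;
* countries as contiguous rectangular blocks grouped into continents, with
  machinery and labour constant within each country (100 countries by
  default, so country-constant covariates vary within the 12×12 evaluation
  blocks);
* harvested area on ~90 % of cells, zero elsewhere (the cropland mask).

The true yield response is Mitscherlich-type saturation per shockable
input $i$:

$$Y = Y_{pot}\; \prod_i \left[f_i + (1-f_i)\left(1 - e^{-k_i x_i (1 + \gamma\, I/100)}\right)\right]\; g(\mathrm{SOC})\; \varepsilon$$

with response floors $f_i > 0$ (an absent input does not zero the yield —
other agronomic pathways persist), an irrigation interaction $\gamma$ (the
same input does more on irrigated land), a monotone soil-organic-carbon
multiplier $g(\mathrm{SOC}) = 1 - 0.25\,e^{-\mathrm{SOC}/40}$, and
multiplicative lognormal noise $\varepsilon$ with $E[\varepsilon] = 1$ and
CV 0.10 by default. The realized noise field is stored, so
`true_counterfactual()` re-evaluates the response under shocked inputs with
the *same* noise — the baseline/scenario difference is purely the
deterministic input effect. Rate scales and $k_i$ are set so the saturating
factors span roughly 0.5–0.97 across the map: shocks have leverage, but no
input is fully saturated. These constants were calibrated once so that the
default world meets its design target (below) and then frozen.

What the generator does **not** emulate: real geography and crop calendars,
measurement error structure of survey-derived rasters, price- or
trade-mediated adaptation, within-country input heterogeneity for
machinery/labour, and long-run soil nutrient dynamics. Passing tests on
this world show the pipeline recovers a known saturating response under
realistic spatial correlation and noise — not that the paper-scale global
numbers are reproduced.

## Numerical choices

* Quantiles (pesticide ceiling, quintile edges) use R's type-7
  linear-interpolation definition, stated so worked examples are exact.
* Quintile ties break by (value, row-major cell index); degenerate
  (all-equal) climatologies error out rather than produce arbitrary bins.
* Per-iteration NSE is recorded only when a bin's test set has ≥ 10 rows:
  below that the variance denominator is close to degenerate and the score
  is meaningless (RMSE is always recorded). The headline per-bin score
  pools all iterations' test pairs into a single NSE; the mean of
  per-iteration scores is exported alongside. At this problem size a
  bin-iteration test set holds only tens of cells, and the mean-of-scores
  estimator is dominated by denominator noise — pooling estimates the same
  quantity stably.
* Across-iteration means (baseline and scenario predictions) are taken over
  the iterations in which the cell's bin had a model; cells whose bin never
  fitted are NA and propagate as nodata.
* Forest predictions are means of leaf means, hence bounded by the training
  yield range. This is why the all-inputs-zero control still predicts an
  appreciable yield, and why *relative* counterfactual changes are
  compressed where the true change is deep: the model cannot predict below
  what it has seen. Recovery of the counterfactual is therefore measured on
  absolute per-cell yield change (t/ha), where the default world reaches a
  correlation of ~0.9 with truth; the relative-change correlation is much
  weaker for exactly this extrapolation reason.

## Problem sizes and what the checks show

The standard study conditions are the default configuration: a 50×50-cell
grid (2,250 cropland cells, ~90 per bin), 21 years of daily climate, noise
CV 0.10, 25 iterations, with forests scaled to 200 trees for the recovery
runs (results at 1,000 trees are indistinguishable on this data size; the
200-tree runs are flagged as scaled down). Under these conditions, with the
fixed study seed, ≥ 90 % of non-skipped bins reach pooled held-out
NSE > 0.65, the absolute counterfactual-change correlation under the 50 %
all-inputs shock exceeds 0.7, the median per-cell prediction CV is below
0.10, and global production change is monotone in severity. The NSE share
varies by roughly ±10 percentage points across generator seeds; the other
properties are stable. Unit tests run on smaller worlds (25–30 cells a
side, 1–2 years of climate) where the same contracts hold.

## Known limitations

* The 25-bin stratification controls climate coarsely; residual within-bin
  climate gradients load onto correlated inputs.
* With ~65 training rows per bin, forests underfit relative to what the
  paper-scale data (10⁴–10⁵ rows per bin) would support; skill bounds are
  set accordingly.
* Scenario predictions are short-run and adaptation-free: no reallocation
  of crops or labour, no soil-stock buffering, no price response.
* The pesticide treatment (97.5th-percentile rescaling, four summed
  groups) retains each ingredient's weight but ignores chemistry and
  crop-specific registration.
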