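---
title: "Attributing groundfish stock status to management tactics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing groundfish stock status to management tactics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(stocktactics)
```

## The question the package addresses

Managed groundfish fisheries report a small set of snapshot quantities that
summarise how a stock is doing relative to what its managers intended: the
ratio of catch to the total allowable catch (TAC), the ratio of the realized
exploitation rate to its target (F:F~target~), the ratio of biomass to its
target (B:B~target~), and the proportion of the catch discarded at sea.
Management agencies differ widely in the tactics they use — harvest control
rules with limit reference points, seasonal closures, permanent spatial
closures, bycatch caps, individual quotas (catch shares), gear mix — and a
natural question is which of these tactics, if any, is associated with
better adherence to targets.

`stocktactics` implements that analysis end to end as a tested pipeline:

1. a **synthetic fleet generator** producing multi-stock datasets with the
   statistical structure the analysis assumes and *known* ground truth;
2. **Schaefer reference points** for stocks whose assessments publish time
   series but no targets;
3. **ten performance measures** per stock over a recent 5-year window,
   including a downside-risk semi-deviation;
4. a from-scratch **bagged regression-tree ensemble** (random-forest style)
   with out-of-bag error, permutation importance, partial dependence, and
   categorical marginal means, used to attribute variation in each measure
   to the management covariates;
5. **collinearity screening** (pairwise correlations, generalized variance
   inflation factors);
6. a **foregone-revenue** analysis of the gap between catch and TAC;
7. **status plots** with kernel-density contours.

Because every stage is exercised against synthetic fleets with injected
effects of known sign and size, the pipeline's ability to recover (or
refuse to invent) management effects is itself a tested property.

## Population model and harvest control rule

Each synthetic stock follows Schaefer (logistic surplus-production)
dynamics with multiplicative process noise:

$$B_{t+1} = \left(B_t + rB_t\Bigl(1 - \frac{B_t}{K}\Bigr) - C_t\right)\,
\varepsilon_t, \qquad \varepsilon_t \sim
\mathrm{Lognormal}\!\left(-\tfrac{\sigma_p^2}{2},\, \sigma_p\right),$$

so the noise deviate has mean one. `r` is the intrinsic growth rate (per
year), `K` the carrying capacity (tonnes), and the exploitation rate F is the
annual fraction caught, `C_t / B_t` — not an instantaneous rate. The MSY
reference points are the closed forms `MSY = rK/4`, `B_MSY = K/2`,
`F_MSY = r/2`.

The TAC is set each year by a 40–10-style harvest control rule: the full
target exploitation rate at or above 40% of K, declining linearly to zero at
10% of K (the limit reference point below which directed fishing stops). The
ramp shape is a package choice — agencies describe rules with a lower limit
without mandating a shape, and the 40–10 ramp is the most common published
form. Two error sources separate intention from outcome:

* **assessment error** — the rule sees an estimated biomass
  (`assessment_sd`, default 0.15 lognormal), which decouples realized
  F:F~target~ from catch:TAC;
* **implementation (outcome) error** — realized catch is the TAC times
  `exp(mu_catch_tac)` (the systematic tendency to land less than the TAC;
  default `log(0.65)`) times a mean-one lognormal deviate
  (`implementation_sd`, default 0.15), truncated below the available
  biomass.

An effort ramp over the first years of each fishery produces a development
phase in landings, so the "year of fishery development" covariate (first
year landings reach 25% of the historic maximum) is informative. The discard
fraction decreases logistically with ex-vessel price, mirroring the dominant
price effect reported for real groundfish fleets.

Management targets are set more conservatively than MSY
(`f_target_mult = 0.75` of F~MSY~; `b_target_frac = 0.40` of K, a B40%-style
proxy). Under these defaults the fleet equilibrates with catches below TACs,
exploitation below target and biomass above target — the "conservatively
managed" regime in which the analysis is meant to operate.

## Study conditions and injected ground truth

`fleet_config()` defaults define the study conditions: 85 stocks across
three regions (Alaska 36%, British Columbia 40%, U.S. West Coast 24%), each
a mix of rockfish (35%, low `r`, late maturity) and other groundfish.
Regional covariate distributions encode the broad contrasts seen in real
fleets: near-universal individual quotas and seasonal closures in B.C.,
roughly tenfold larger and cheaper catches in Alaska developing about a
decade later, higher prices and lower spatial-closure coverage on the U.S.
West Coast, and harvest control rules with limit reference points common in
the two U.S. regions.

Three effects are injected by default, each acting on the generating
parameters (never on the computed metrics):

| covariate | affected measure | mechanism | magnitude |
|---|---|---|---|
| ex-vessel price | mean ln(catch:TAC) | shifts the implementation bias | +0.30 per SD of log price |
| ex-vessel price | discard proportion | logistic linear predictor | −1.5 per SD of log price |
| % catch in IQs | SD of ln(catch:TAC) | scales the implementation SD | ×exp(−1.1·z) |

All injections use z-scored covariates so magnitudes are comparable across
covariates; `GroundTruth` records every realized generating value. Two
covariates — total catch and year of development — are *derived from the
simulated series* exactly as they would be from real data, and are therefore
structurally associated with the catch:TAC family of responses. Effect-recovery
checks treat them as confounded-by-construction rather than as null
covariates.

The generating distribution of real status ratios is not known; lognormal
interannual variation is an assumption of the generator, and passing tests
show that the pipeline recovers structure *of that kind*. They cannot show
robustness to features the generator does not emulate: age-structured
dynamics, autocorrelated recruitment regimes, assessment bias that trends
over time, or spatially structured fleets.

## Performance measures

For each stock, each metric is computed over the most recent run of five
consecutive years with usable data *for that metric* (coverage differs, so
windows may differ across metrics). If a listed management change falls
inside the candidate window, the window steps back to end before the change
year. Stocks are excluded — each with exactly one primary reason — when data
end before 2000, when they have little or no commercial value, when they
were under a rebuilding plan during the window, or when co-caught with
rebuilding stocks.

Ratios are treated in log space. For each of the three status ratios the
package reports the 5-year mean, the sample standard deviation (n − 1), and
the downside **semi-deviation**

$$\delta = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n} d_i^2}, \qquad
d_i = \begin{cases} \ln(x_i/\mathrm{target}) & \text{on the undesirable side}\\
0 & \text{otherwise,}\end{cases}$$

with the undesirable side being *above* the target for catch:TAC and
F:F~target~ and *below* it for B:B~target~. The root-mean-square form (with
denominator n, the window length) is the standard downside-risk
semi-deviation; a mean-absolute variant is available via
`semideviation(..., method = "mean_abs")`. The statistic is zero exactly
when every year is at or more conservative than the target, strictly
increases with any undesirable excursion, and obeys the log symmetry
`semidev(x, t, upper) = semidev(1/x, 1/t, lower)`.

```{r}
x <- c(1.1, 0.9, 1.35, 1.0, 0.8)
semideviation(x, target = 1, side = "upper")
semideviation(x, target = 1, side = "lower")
```

The tenth measure is the discard proportion, pooled over the window
(total discards / total catch) rather than averaged across annual rates, so
near-zero-catch years cannot dominate. The catch:TAC ratio uses the per-year
TAC as its target; `screen_catch_tac()` restricts catch to the components a
TAC actually covers when scopes differ.

## The tree ensemble

The attribution engine is a bagged regression-tree ensemble written for this
package (C++ core): n-out-of-n bootstrap per tree with stocks weighted
equally, `mtry` covariates sampled without replacement at each node, splits
maximizing the sum-of-squares reduction with numeric cutpoints at midpoints
between sorted distinct values, recursion stopping at `min_node_size = 5`
in-bag rows or zero variance. Equal-quality splits are broken by lowest
covariate index then smallest cutpoint, so a fit is a pure function of
(data, seed): all randomness flows from R's RNG through a single
`set.seed()`, and fits are bit-reproducible. Tests verify the root split and
full-tree predictions against an exhaustive brute-force CART oracle, and the
forest against the independent `randomForest` implementation.

Defaults mirror the analysis the package reimplements: 10,000 trees and
`mtry = 5` for the 11-predictor key run (close to the p/3 ≈ 3.67 and
√p ≈ 3.32 rules of thumb; `mtry_diagnostic()` plots out-of-bag MSE over
candidate values). Simulation-style checks in the tests use 100–500 trees —
at stock-level sample sizes the OOB error stabilises well below 10,000 trees,
and the smaller forests keep the default test run fast without changing any
conclusion.

* **Out-of-bag error** (`oob_mse`) is the cross-validation accuracy: each
  stock predicted only by trees whose bootstrap omitted it.
* **Permutation importance** is the loss of prediction accuracy from
  removing a predictor: per tree, the increase in OOB MSE after permuting
  that predictor's OOB values, averaged over trees. Null covariates score
  about zero (positive or negative — values are not truncated).
* **Partial dependence** forces a covariate to a grid value for all stocks
  and averages the predictions (51 grid points over the observed range;
  the two levels for booleans). Per-group curves (region × taxa) average
  over subgroup rows under the *same* shared forest — regions differ in
  their covariate values, which is what makes separate marginal curves
  informative. Deciles and the middle-80% band of the covariate accompany
  every curve; plots shade the sparse 10% tails and draw the overall curve
  with thickness proportional to importance.
* **Marginal means** for two-level covariates are the partial-dependence
  values at the two levels; the relative difference is expressed as a
  percentage of the span of the central 95% interval (2.5–97.5 percentiles,
  pooled over all stocks) of the observed response. The percentile reading
  of "95% interval of all data" is a package choice; a normal-theory span
  would differ little at these sample sizes.

Missing predictor values are imputed by column medians (numeric) or modal
levels (boolean) before fitting, with the missingness mask retained.

A note on one tempting-but-false identity: averaging the partial-dependence
curve over the covariate's own empirical distribution is a double average
over forced rows, not the plain mean prediction, so the two are close only
for near-additive fits; the package does not assert it.

## Reference-point estimation

For stocks supplying biomass and catch series but no published targets,
`fit_schaefer()` estimates `r`, `K` and the first-year biomass by minimizing
the sum of squared log residuals between observed and projected biomass — an
observation-error estimator, chosen because assessments provide biomass
*estimates* and the analysis treats ratios in log space. `B_start` is free
(bounded by (0, 2K]) because first-year depletion is unknown. A coarse
multistart grid (r ∈ {0.05…1.5}, K ∈ {1…5}×max B) precedes bounded
quasi-Newton refinement with a final small-step polish; `converged = FALSE`
(never an error) marks solutions on a bound or non-identifiable fits — e.g.
constant biomass under negligible catch, detected when several starts reach
the same SSE with widely different `r`. Noise-free self-generated series are
recovered to ~1e-10 relative error; under 5% lognormal observation noise on
a series with real contrast (depletion then rebuild), median relative errors
of `r` and `K` are about 2%. Identifiability is poor — as it genuinely is —
when the series shows little biomass contrast.

## Collinearity screening and sensitivity scenarios

Before attribution, `colinearity_report()` computes pairwise Pearson
correlations among the numeric covariates (flagging |r| ≥ 0.5) and
generalized variance inflation factors across all predictors (flagging
GVIF ≥ 2.5), with `GVIF = det(R_j)·det(R_{-j})/det(R)` on the correlation
matrix of the encoded design; a categorical predictor's indicator columns
form one group, which is what makes the statistic "generalized". For a
single column this reduces to the classical 1/(1 − R²), cross-checked in
tests against direct regression.

Five sensitivity scenarios rerun the attribution on modified data:
(a) drop stocks with >50% recreational catch, (b) drop weakly targeted
stocks (window-mean catch:TAC < 0.5), (c) drop secondary targets, (d) add a
3-level region predictor, (e) add maximum length. The engine encodes region
as a single integer-coded column (ordered splits), giving p = 12; exhaustive
categorical subset splits are not implemented, a deliberate simplification
at three levels.

## Economics and status plots

`economics_report()` multiplies ex-vessel price by the 5-year mean catch,
TAC and (when available) ABC of each stock, ranks stocks by catch value
within each region, and accumulates value along the ranking; the percent
loss of potential revenue at each rank is
`100 × (cumulative TAC value / cumulative catch value − 1)`. Currency passes
through without deflation; total catch value is used in the denominator.
The final per-region loss is invariant to ranking — only the path of the
curve depends on it.

`status_panel()` draws B:B~target~ against F:F~target~ per category with
target cross-hairs at 1 and 2-D Gaussian kernel-density contours. The
kernel standard deviation (bandwidth, default 2) applies on the ratio scale
on both axes, on a 101×101 grid padded by three bandwidths — over that grid
the density integrates to 1 within 2% (a tested property). The KDE is a
direct ~15-line product-kernel computation so that "bandwidth" means the
kernel SD, with no library-specific rescaling. Every figure is written with
a companion CSV of the plotted coordinates, which round-trips exactly.

## Orchestration and reproducibility

`run_analysis(run_config(...))` chains the stages and writes delimited
artifacts plus a manifest (seeds, sample sizes per metric, exclusion
counts). One master seed drives everything; stage seeds are derived by a
stable hash of (master seed, stage name), so any stage can be rerun in
isolation. Forests are grown serially from that single RNG stream — the
package trades parallel tree growth for an uncomplicated bit-reproducibility
contract.

```{r, eval = FALSE}
cfg <- run_config(mode = "synthetic",
                  fleet = fleet_config(n_stocks = 85),
                  seed = 1, n_trees = 2000, scenario = "key",
                  out_dir = "run1")
res <- run_analysis(cfg)
res$attribution$mean_catch_tac$importance
```

A thin command-line wrapper (`exec/stocktactics`) exposes `simulate`,
`refpoints`, `metrics`, `diagnose`, `attribute`, `economics` and `run`
subcommands over the same functions.

## Numerical choices and known limitations

* Lognormal noise everywhere a ratio is analysed in log space; deviates are
  bias-corrected to mean 1 so that configured biases are exact in the
  noise-free limit (a tested invariant).
* Biomass projections floor at a small positive epsilon; persistent
  overharvest flags a collapse rather than raising an error.
* Catch:TAC years with zero TAC and positive catch are flagged and dropped
  from the log ratio; zero-catch windows leave the discard proportion
  undefined rather than zero.
* The semi-deviation denominator is the window length n (not the count of
  excursions); the display in the source literature is ambiguous, and the
  RMS-over-n form matches the downside-risk literature it cites.
* Tree splits are axis-aligned midpoints; no surrogate splits (missingness
  is imputed upstream), no proximity measures, no classification mode.
* The generator is not age-structured and has no spatial dynamics or
  multispecies technical interactions beyond a scalar bycatch-constraint
  covariate; effects injected on B:B~target~ family responses are not
  supported (the biomass pathway is indirect through the control rule).
* Real compiled assessment datasets are not shipped; analyses of real
  fleets enter through the delimited-table mode with the documented schema.
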