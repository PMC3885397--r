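---
title: "Estimating population maturity ogives for a migratory tuna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population maturity ogives for a migratory tuna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maturogive)
```

## The problem

The maturity ogive — the proportion of females mature as a function of fork
length (FL) — feeds directly into spawning-stock-biomass calculations, so a
biased ogive propagates straight into stock assessment. For a migratory
species such as South Pacific albacore the standard pooled estimate is
biased whenever mature and immature fish occupy different places at
different times of the year and sampling effort is not proportional to
abundance. Albacore mature fish move toward northern spawning latitudes
(roughly 10–25°S) during the austral spring/summer (October–March), while
similar-sized immature fish stay south. Samples taken on the spawning
ground over-represent mature fish at a given length; the apparent length at
50% maturity (L50) drops, even though nothing about individual fish has
changed.

`maturogive` implements the full analysis chain for this situation:

1. a deterministic histological rule engine mapping ovary features to a
   development class and a maturity call;
2. binomial logit mixed models of maturity with spline/factor covariates
   and a fishing-set random intercept;
3. AICc multi-model inference over a candidate covariate grid;
4. an abundance-weighted population ogive with a delta-method variance; and
5. a synthetic-data generator that reproduces the sampling structure the
   method assumes, so every stage is testable without confidential fishery
   data.

## Histological classification

Ovaries are scored on four features: the most advanced group of oocytes
(MAGO), postovulatory follicles (POFs), alpha/beta-stage atresia of yolked
oocytes, and "maturity markers" (gamma/delta atresia — brown bodies — or
residual hydrated oocytes). Eight development classes follow (C1 immature,
C2 developing, C3 spawning capable, C4 spawning, C5 regressing, C6a/C6b
regressed, C7 regenerating); C1–C2 are immature, C3–C4 mature and active,
the rest mature but inactive. The markers matter because they persist
through the non-spawning season, letting mature-but-regenerating females be
distinguished from immature ones year-round.

Rules are evaluated most-advanced-evidence first (C4, C3, C5, C6a, C6b, C7,
C2, C1). Three readings were genuinely open and are fixed as follows:

* "<50% alpha atresia" for the active classes includes zero atresia;
* C4 fires on migratory-nucleus/hydrated MAGO **or** POFs ("and/or");
* a fully atretic clutch (100% alpha) is represented as `alpha = "full"`
  with an unyolked/early-yolked MAGO, since no intact advanced oocytes
  remain; an advanced clutch overtaken by ≥50% atresia is regressing (C5).

Atresia is a 4-level ordinal (`none`, `lt50`, `ge50`, `full`) because the
classification uses only those cut points. The rules are verified by
enumeration over the complete feature grid: every valid snapshot receives
exactly one class, and maturity is equivalent to advanced-clutch evidence,
POFs, atresia, or markers. Females below 70 cm FL may be classed immature
on macroscopic examination alone; at or above 70 cm a missing histology
class is an error, not a default.

```{r}
classify_ovary(ovary_snapshot("unyolked", FALSE, "none", FALSE, TRUE))
assign_maturity("C7", 88)
```

## The maturity model

Maturity (1 = mature) is binomial with a logit link. Fork length (or age),
latitude and longitude enter linearly or as cubic regression splines with
knots at equally spaced quantiles of the observed data; season is a factor
with two levels (Oct–Mar, Apr–Sep; reference Apr–Sep) or four quarters
(reference Jan–Mar); fishing set is a Gaussian random intercept, because
fish caught together are not independent.

**Spline family.** The df accounting here is "df = node count − 1". A
*natural* cubic spline with `df` columns has exactly `df − 1` interior knots
at equally spaced quantiles plus two boundary knots — `df + 1` nodes — and
is the only cubic spline family for which a 2-df fit (the best-supported
length term) exists at all. `spline_basis()` therefore wraps
`splines::ns()`, stores the knots, and re-evaluates predictions on the
training knots; `df = 1` is the plain centred linear term.

**Estimation.** The marginal likelihood integrates each set's random
intercept out of the conditional Bernoulli likelihood. With a single
Gaussian intercept the Laplace approximation is accurate and fast: each
set's integrand is expanded around its posterior mode, found by damped
Newton iterations (tolerance 1e-10, at most 50 steps with step-halving).
The outer optimisation over fixed effects and the set-level SD uses
`nlminb` with the SD box-constrained at zero; at the boundary the fit
collapses exactly to plain logistic regression. Starting values come from
an unpenalised GLM; complete separation is detected from a perfectly
classifying linear predictor and reported with the offending covariate.
The fixed-effect covariance is the inverse observed information,
differentiated numerically at the optimum. An independent adaptive
Gauss–Hermite quadrature evaluation (21+ nodes, mode-centred, log-sum-exp)
validates the Laplace value on small problems; on the test fixtures the two
agree to well under 1%, and the optimum matches `lme4::glmer` to about five
decimals.

**Predictions** are conditional on a typical set (random effect = 0), the
common convention for mixed-model ogives; a population-averaged alternative
(Gauss–Hermite marginalisation over the set effect) is available via
`predict_proportion(..., population_averaged = TRUE)`. Intervals are Wald
intervals on the logit scale, back-transformed, so they respect [0, 1] and
bracket the point estimate.

## Model selection

Candidates are compared with AICc, `-2 logLik + 2k + 2k(k+1)/(n−k−1)`,
where `k` counts fixed effects plus one for the random-intercept variance
and `n` is the number of fish (conditional-likelihood counting; both
choices are configurable). AICc is refused when `n ≤ k + 2`, where the
correction term's denominator reaches 1. Akaike weights renormalise
`exp(−Δ/2)` after subtracting the minimum, which makes them numerically
stable and invariant to constant shifts. The default grid crosses predictor
df {1, 2, 6}, latitude {absent, 2-df spline}, longitude {absent, linear},
seasons {2, 4}, and each interaction on/off — 54 candidates. Length-vs-age
comparisons refit the identical structure on the subset with both
measurements. L50-by-latitude curves are obtained by root-finding the first
upward 0.5-crossing of the predicted curve within the observed length span
(to 0.01 cm); a non-monotone spline ogive can cross more than once, and the
first upward crossing is the reproducible choice that matches the
biological reading.

## The weighted ogive

For discrete areas the best continuous-latitude structure is refitted with
latitude as a three-band factor (<23°S, 23–29°S, ≥29°S — chosen to match
the areas for which CPUE-based relative abundance exists). With
area-and-season curves \(\hat p_{las}\) at 5-cm class midpoints, the
population ogive in season \(s\) is

\[
\hat P_{ls} = \sum_a W_{las}\,\hat p_{las}, \qquad
W_{las} = \frac{N_{as}\,p_{las}\,f_{las}}{\sum_a N_{as}\,p_{las}\,f_{las}},
\]

where \(N_{as}\) is relative abundance (both sexes; only the relative scale
matters), \(p_{las}\) the within-area length composition and \(f_{las}\)
the proportion female. This is the law of total probability over areas:
with weights that reflect the population, the weighted average recovers the
population proportion mature at length regardless of how sampling effort
was distributed — that is the entire point of the estimator. Treating the
weights as known,

\[
\mathrm{Var}(\hat P_{ls}) = \sum_a W_{las}^2\,\mathrm{Var}(\hat p_{las}),
\]

with prediction variances carried on the proportion scale via the delta
method (the printed reduced formula operates on proportions; a logit-scale
alternative would differ only in the delta step). The resulting intervals
deliberately exclude uncertainty in \(N\), \(p\) and \(f\) and are flagged
as such. Length classes are closed 5-cm intervals ("46–50", "51–55", …)
with predictions at midpoints (48, 53, …); a boundary length belongs to
the lower class. Cells with no data in any area are undefined and propagate
as missing; cells missing in some areas drop those areas and renormalise
the weights. L50 interpolates linearly between the midpoints bracketing the
first upward 0.5-crossing; "length at 100% maturity" is operationalised as
the smallest class reaching 0.99, because fitted curves approach 1 only
asymptotically (threshold configurable).

## What the generator emulates — and what it does not

`simulate_population()` builds a latent population of fish clusters
(schools): month; home latitude uniform on 10–40°S; a set-level intercept
(SD 0.5 on the logit scale); Poisson cluster sizes (mean 10). Lengths
follow the latitudinal size gradient `FL ~ N(105 − 0.9·lat, 8)` cm, so
average size increases toward the equator. True maturity is Bernoulli with
logit `0.25·(FL − L50(lat, season)) + b_cluster` and `L50 = 87` cm by
default, constant over space and season — the apparent latitudinal
variation in the default scenario is produced entirely by movement, not by
a spatially varying maturation schedule. The slope 0.25/cm makes the
5%-to-95% transition span roughly 74–94 cm, the observed transitional size
range. In season 1 a fraction (0.75) of mature fish migrate 8° north
(partial migration: mature fish are still found in the south in summer, as
observed) and join existing schools near their destination; fishing sets
are then an effort-weighted sample of clusters, with season-1 effort skewed
toward the spawning ground (fleets follow the fish). The sample is
deliberately *not* the population: the attached census plays the role of
the CPUE abundance index, and the gap between sample composition and
population abundance is exactly what creates — and what the weighted
estimator corrects — the season-1 bias. Sex is assigned with
`logit P(F) = 2.5 − 0.03·FL`, so females thin out among the largest fish.
Ages, when requested, invert a von Bertalanffy curve (Linf 104 cm, K 0.4,
t0 −0.5 y) with 0.5 y noise.

The generator reproduces clustered sampling, the size gradient, spawning
migration, effort bias and the length-dependent sex ratio. It does not
attempt oceanographic realism, longitude-dependent growth, multi-year
dynamics, ageing error structure, or misclassified histology — so passing
tests demonstrate the estimator's statistical behaviour under the assumed
sampling structure, not robustness to classification error or to abundance
indices that are themselves biased.

`true_weighted_ogive()` gives the exact population curve (latitude by
trapezoid integration on a 201-point grid, the random effect by 40-node
Gauss–Hermite); it is the recovery target in the tests, since migration
moves fish around without changing who is mature at a given length.

## Numerical choices and problem sizes

Tests and the acceptance script run the recovery and bias checks at about
20,000 fish in 1,000 sets (census four times larger), the L50
coverage study at 200 replicates of ~1,500 fish in 150 sets (the study's
sampling scale), and the quadrature cross-checks at 5–30 sets where the
oracle is exact enough to judge the Laplace value. Quadrature uses
Golub–Welsch Gauss–Hermite nodes; all log-likelihoods use the stable
`y·η − softplus(η)` form; Akaike weights subtract the minimum before
exponentiating; weighted-average denominators of zero propagate as missing
rather than dividing.

## Known limitations

* Ogive CIs omit weight uncertainty (abundance, composition, sex ratio);
  propagating it would need variance estimates for the CPUE index.
* Conditional (typical-set) predictions are slightly attenuated relative to
  population-averaged curves when the set-level SD is large; with SD ≈ 0.5
  the effect on L50 is well under half a centimetre.
* A single Gaussian random intercept only; no crossed or nested grouping,
  no non-logit links, no penalised smoothness selection.
* The discrete-latitude refit assumes every band-season stratum contains
  data and errors otherwise.
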