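# maturogive

Maturity-ogive estimation for fish stocks in which mature and immature fish
are distributed differently in space and season — the situation of South
Pacific albacore tuna, where mature fish migrate to northern spawning
latitudes (≈10–25°S) in October–March while similar-sized immature fish
remain further south. A pooled logistic fit to samples taken under such
conditions is biased whenever sampling effort is not proportional to
abundance; on the spawning ground it over-represents mature fish and pulls
the apparent length at 50% maturity (L50) down.

The package is aimed at fisheries reproductive-biology and stock-assessment
analysts. It provides:

* **Histological classification** — a deterministic rule engine mapping
  ovary features (most advanced group of oocytes, postovulatory follicles,
  alpha/beta atresia, maturity markers) to development classes C1–C7 and a
  mature/immature, active/inactive call, with a <70 cm macroscopic-immature
  rule. Verified by enumeration over the complete feature grid.
* **Spline logistic mixed models** — maturity as a binomial logit response
  with cubic-spline (quantile-knot) or linear terms for length/age,
  latitude, longitude, a 2- or 4-level season factor, interactions, and a
  fishing-set Gaussian random intercept. Fitting maximises the
  Laplace-approximate marginal likelihood (nested Newton per-set modes);
  an adaptive Gauss–Hermite quadrature oracle cross-checks it.
* **AICc multi-model inference** — candidate grids over the covariate axes,
  ΔAICc and Akaike weights, and length-versus-age head-to-head comparison.
* **The abundance-weighted population ogive.** With area/season curves
  p̂(l,a,s) from a discrete-latitude refit, the population curve is

      P(l,s) = Σₐ W(l,a,s) · p̂(l,a,s),
      W(l,a,s) ∝ N(a,s) · p(l,a,s) · f(l,a,s),

  where N is relative abundance (CPUE-scale), p the within-area 5-cm length
  composition, f the proportion female. Treating the weights as known,
  Var(P) = Σₐ W² · Var(p̂). This is the law of total probability over
  areas: with population weights, the weighted average recovers the
  population proportion mature at length regardless of where the samples
  came from.
* **A synthetic-data generator** reproducing the sampling structure the
  method assumes: latitudinal size gradient, partial spawning migration,
  clustered fishing-set sampling with effort that follows the fish, and a
  length-dependent sex ratio — with the exact population ogive available as
  a recovery target.

## Worked example

Simulate an albacore-like scenario (≈4,500 fish in 300 sets; true L50 =
87 cm, set-effect SD 0.5, migration on), tabulate abundance from the
attached census, and estimate the weighted ogive:

```r
library(maturogive)

params <- population_params(n_sets = 300, fish_per_set_mean = 15, seed = 42)
pop       <- simulate_population(params)
females   <- pop[pop$sex == "F", ]
census    <- attr(pop, "population")
abundance   <- derive_abundance_inputs(census)$abundance
composition <- derive_abundance_inputs(pop)$composition

wo <- weighted_ogive(females, abundance, composition)
subset(as.data.frame(wo$ogive), season == 1 & midpoint >= 78 & midpoint <= 98)
#>    midpoint season estimate variance ci_low ci_high n_areas
#> 7        78      1   0.0894 0.000548 0.0436   0.135       3
#> 8        83      1   0.2708 0.001732 0.1893   0.352       3
#> 9        88      1   0.6208 0.000932 0.5610   0.681       3
#> 10       93      1   0.8648 0.000250 0.8338   0.896       3
#> 11       98      1   0.9479 0.000166 0.9226   0.973       3

length_at_quantile(wo$ogive, 0.5, season = 1)   # 86.27 cm
length_at_quantile(wo$ogive, 0.5, season = 2)   # 87.37 cm
fit_unweighted(females, season = 1)$l50         # 85.29 cm
```

The weighted estimates sit at the true 87 cm in both seasons (sampling
noise aside), while the unweighted season-1 fit — which ignores the
migration-driven spatial structure — is biased a centimetre low; at the
full study scale the same contrast appears with tighter error. Each row of
the ogive table is a 5-cm length class (midpoint shown) with the weighted
proportion mature, its variance (weights treated as known, so CIs exclude
abundance/composition/sex-ratio uncertainty), and the number of areas
contributing.

`run_pipeline(pipeline_config(...))` orchestrates the same analysis from
delimited input files (fish table + abundance table) through model
comparison, the discrete-latitude refit, weighting, and the L50/L100
summary, writing all artifacts plus a reproducibility record (seed, config
hash, package version). A thin command-line wrapper with `simulate`,
`classify`, `compare`, `ogive` and `run` subcommands ships in
`inst/cli/maturogive.R`. See `vignettes/maturity-ogives.Rmd` for the model,
its assumptions, and every numerical choice.

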