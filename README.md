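# agedose

Exposure–response (E–R) relationships in children can differ between age
groups: maturation shifts both the baseline response and how strongly a
given drug exposure moves it.  `agedose` is an R toolkit for

1. **estimating how E–R model parameters vary over the continuous age
   range 0–18 years**, by three routes —
   * a benchmark linear model with pre-specified categorical age groups
     (ICH E11 boundaries) and group-by-exposure interactions,
   * model-based recursive partitioning over age (MOB), including
     PALM-style global covariate effects and bootstrap aggregation of
     the tree fits into smooth age–parameter curves,
   * Bayesian penalised B-splines: quadratic splines with a
     regulatory-informed knot recipe (J = 26 basis functions) and
     first-order random-walk smoothing priors, fitted by MCMC; and
2. **deriving age-grouped dosing rules**: age boundaries and per-group
   target exposures chosen to keep the expected response close to a
   clinical target `Y*`, scored by an objective `G` that averages the
   absolute dosing error within fixed reference age bands (NICHD-style)
   so narrow infant bands weigh as much as wide adolescent ones.  The
   number of groups `K*` is the smallest `K` whose further refinement
   improves `G` by less than 25%.

Both linear and sigmoid Emax E–R models are supported, along with a
seeded synthetic-data module (eleven linear scenarios plus a fixed-panel
Emax design) and a simulation-evaluation layer (Simpson-integrated
absolute bias / empirical SD / MSE of parameter curves, expected-response
surfaces and dosing-rule accuracy).

The package is aimed at pharmacometricians and trial statisticians
planning paediatric development programmes; "dose" here always means
*target exposure* — mapping exposures to administered doses needs a
separate PK model and is out of scope.

## Worked example

Simulate a study (25 subjects per ICH E11 age group, log-normal trough
concentrations, a four-group truth), fit a partition tree, then derive a
dosing rule from bootstrap-aggregated curves:

```r
library(agedose)

scn <- linear_scenario(1)              # sharply separated four-group truth
d   <- generate_dataset(scn, seed = 42)

tree <- fit_palm(d)                    # single tree (no covariates -> MOB)
print(tree$tree)
#> Model-based partition tree (linear node model)
#> + split at age 1.947 (supLM p = 5e-05)
#>   + split at age 0.08008 (supLM p = 5e-05)
#>     * leaf (0, 0.08008], n = 25: intercept = 4.345, slope = -0.1382
#>     * leaf (0.08008, 1.947], n = 24: intercept = 4.969, slope = -0.1956
#>   + split at age 11.91 (supLM p = 5e-05)
#>     * leaf (1.947, 11.91], n = 26: intercept = 5.518, slope = -0.2232
#>     * leaf (11.91, 18], n = 25: intercept = 6.226, slope = -0.3034

agg <- bootstrap_aggregate(d, B = 200, seed = 43)
drs <- derive_dosing_rule(as_aggregated_spec(agg),
                          dosing_target(log(60)),   # 50% seizure reduction
                          rule_search_config(boundary_step = 0.5))
print(drs)
#> Optimal dosing rules, K = 1..6
#>   G*: 1.5561, 0.56441, 0.27284, 0.12829, 0.11544, 0.10606
#>   selected K* = 4
#>
#> Dosing rule with K = 4 age group(s), G = 0.12829
#>   (0, 0.07671] years: target exposure 1.78445
#>   (0.07671, 2] years: target exposure 4.47984
#>   (2, 11.5] years: target exposure 6.45323
#>   (11.5, 18] years: target exposure 6.89972
```

The tree recovers splits essentially at the generating boundaries
(28/365, 2 and 12 years).  The `G*` sequence drops steeply until four
groups and flattens afterwards, so the 25% rule selects `K* = 4`; the
recovered boundaries and exposures then define the rule.  Newborns need
far lower target exposures (1.8) than adolescents (6.9) because both the
intercept and the slope of the E–R relationship change with age.

The Bayesian route does the same job with credible bands:

```r
fit <- fit_bspline_linear(d, seed = 1)          # Gibbs, 3 x 3000 draws
max(rhat(fit))                                  # convergence check
bands <- posterior_curve_quantiles(fit, "slope")
spec <- as_posterior_spec(fit)                  # posterior-mean curves
derive_dosing_rule(spec, dosing_target(log(60)))
```

A thin command-line interface wrapping these functions lives at
`inst/cli/agedose.R` (subcommands `simulate`, `fit`, `dose-rule`,
`study`).

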