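# amcgc — adaptive mixture categorization and g-computation

`amcgc` estimates the joint effect of a mixture of continuous exposures
(trace elements, pollutants, …) on a health outcome.  Instead of cutting
each exposure at fixed quantiles, it searches for the categorization that
best separates the exposure's distributional components, then applies
g-computation to the categorized terms.  It is written for environmental
epidemiologists and biostatisticians analysing exposure-mixture data, and
for methodologists who want a self-contained simulation bench for
categorization-based mixture methods.

## The method

**Categorization.**  For one exposure split into `k` ordered categories,
the loss is the reciprocal of the one-way ANOVA F statistic

```
L = (SS_within / (n - k)) / (SS_between / (k - 1)) = 1 / F ,
```

so minimizing `L` shrinks within-category variation while preserving
between-category variation.  The search is incremental: every boundary
found so far is kept and one more is placed wherever it most reduces the
loss (`k (n - 1)` candidate evaluations instead of the exhaustive
`choose(n - 1, k - 1)`).  `k` can be fixed (`k_fixed`) or chosen adaptively
by tracking the F-test p-value with df `(k - 1, n - k)` up to `k_max = 10`;
see the vignette for why the adaptive rule is anti-conservative on
continuous data and when to prefer a fixed `k`.

**G-computation.**  Categories enter a GLM as ordinal scores `0..k-1` or as
dummy indicators (reference = lowest category, allowing inverted-U shaped
effects).  The joint mixture effect is the sum of exposure-term
coefficients,

```
psi = sum_j beta_j ,        OR = exp(psi)  (logistic outcome),
```

with covariates adjusted for but excluded from `psi`.  Per-term weights are
the coefficients normalized within their direction — positive weights sum
to `1`, negative weights to `-1`.  Confidence intervals come from a
percentile bootstrap that re-runs the entire pipeline (categorization
included) on each resample of individuals.

## Worked example

Categorize a 4-component mixture, then run the non-monotonic
variable-selection pipeline:

```r
library(amcgc)
set.seed(1)
x <- rnorm(200, mean = sample(1:4, 200, TRUE, c(.4, .3, .2, .1)), sd = 0.33)
amc_categorize(x, amc_config(k_fixed = 4))
#> Categorization (amc): k = 4, n = 200
#>   thresholds: 1.41073, 2.26689, 3.20823
#>   counts:     66, 63, 41, 30
#>   loss = 0.00119837, F = 834.465, p = 2.57e-111
```

The thresholds land in the gaps between the latent components (true
component means 1, 2, 3, 4), and the category counts track the state
probabilities (0.4, 0.3, 0.2, 0.1).

```r
sc  <- sim_scenario(n = 500, m = 10, alpha = c(.4, .3, .2, .1),
                    effect_model = "nonmonotonic")
d   <- generate_dataset(sc, seed = 7)
fit <- amc_gcomp(d$exposures, d$outcome, coding = "dummy", family = "linear",
                 config = amc_config(k_fixed = 4))
round(sort(fit$weights, decreasing = TRUE)[1:5], 3)
#>  X3_1  X1_1  X2_1  X5_1  X8_3
#> 0.188 0.158 0.142 0.127 0.119
round(sort(fit$weights)[1:5], 3)
#>   X4_2   X2_2   X3_2   X1_2   X5_3
#> -0.212 -0.154 -0.142 -0.114 -0.089
truth <- selection_truth(sc)
c(tpr = compute_tpr(fit$weights, truth), fpr = compute_fpr(fit$weights, truth))
#>  tpr  fpr
#> 0.80 0.10
```

In this draw the level-1 terms of causal exposures X1, X2, X3, X5 (true
effect +1) fill four of the top five weights and the level-2 terms (true
effect -1) fill four of the bottom five, giving a true positive rate of
0.80: 8 of the 10 causal dummy terms were ranked where they belong.

The full application recipe (LOD/2 imputation, log transform, AMC `k = 3`
with a 10% minimum category share, dummy coding, covariate-adjusted
logistic fit, bootstrap CIs) runs on a synthetic case-control fixture:

```r
fx  <- make_application_fixture(265, 353, seed = 1)
app <- run_application(fx, n_boot = 200, seed = 1)
app$weights[app$weights$element == "zinc", ]
#>   element  level     weight       lower     upper
#> 5    zinc medium 0.13332266  0.00498446 0.2375353
#> 6    zinc   high 0.03461938 -0.11630947 0.1182902
```

The fixture plants an inverted-U zinc effect (+0.8 log-odds medium vs.
low, -0.1 high vs. low): the medium-level zinc weight is positive with a
bootstrap interval excluding 0, while the high-level weight is near zero —
the planted shape.  (All numbers above are the actual output of the code
shown, at these seeds.)

A command-line surface wraps the same workflows
(`categorize`, `fit`, `simulate-bias`, `simulate-tpr`, `application`):

```sh
Rscript -e 'amcgc::amc_cli()' simulate-tpr --mode nonmonotonic \
    --n 500 --m 10 --reps 200 --seed 1 -o tpr.csv
```

## Simulation studies

`run_bias_study()` and `run_tpr_study()` reproduce the two benchmark
experiments: bias of `psi` under four latent-state scenarios, and true/false
positive rates of weight-based variable selection under monotonic and
non-monotonic effects, for both the AMC and the fixed-quartile arm.
`tests/testthat/test-acceptance.R` runs them at reduced replicate counts
(200 for the TPR tables, 1000 for bias) against the reference operating
characteristics.

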