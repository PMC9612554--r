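# boostmec

Boosted variable selection and estimation for binary-response regression
when **both** the response and the predictors are measured with error —
the situation of, say, a disease label that is sometimes recorded as the
wrong subtype, regressed on thousands of noisy gene-expression values with
`p >> n`.

## What it does

Two binary-response models are supported, logistic and probit (no implicit
intercept):

    P(Y = 1 | X) = expit(X'b)        P(Y = 1 | X) = Phi(X'b)

Estimation works through averaged estimating functions `g(b)` (the
negative average score of the corresponding likelihood).  Two error
processes are corrected *inside* those functions:

- **Response misclassification.**  With known probabilities
  `pi10 = P(Y* = 1 | Y = 0, x)` and `pi01 = P(Y* = 0 | Y = 1, x)`, the
  surrogate label is replaced by the corrected response
  `Y** = (Y* - pi10) / (1 - pi10 - pi01)`, which satisfies
  `E(Y** | Y, x) = Y` and may lie outside `[0, 1]`.
- **Classical additive predictor error** `X* = X + e`,
  `e ~ N(0, Sigma_eps)`.  The logistic model substitutes the
  beta-dependent sufficient statistic `X** = X* + Y** Sigma_eps b`; the
  probit model substitutes the regression-calibration predictor
  `X** = mu + (S - Sigma_eps)' S^{-1} (X* - mu)` computed once from the
  sample moments.

The corrected (or naive — both error corrections are individually
switchable) estimating function drives a thresholded boosting loop:
starting from `b = 0`, each of `T` iterations updates only the coordinates
whose component of `g` is within a factor `tau` of the largest, by a step
`-eta * g_j`.  Coordinates never updated stay exactly zero, so the fit
selects predictors and estimates their coefficients in one pass.

The package also ships the matching synthetic-data generator
(`simulate_me_binary()`), a replicated simulation-study driver with
L1/L2 estimation errors and inclusion/exclusion rates
(`run_simulation_study()`), a sensitivity-analysis workflow over posited
error variances (`run_sensitivity()`), cross-validated threshold selection
(`choose_threshold()`), and tidyverse-style accessors (`tidy()`,
`glance()`, `autoplot()`).  A thin command-line wrapper lives in
`inst/cli/boostmec.R`.

## Worked example

Simulate moderately contaminated data (18% misclassification both ways,
predictor-noise variance 0.3) with three truly informative predictors out
of 30, then compare the naive and the fully corrected fit:

```r
library(boostmec)
library(dplyr)

sim <- simulate_me_binary(
  n = 400, p = 30, beta_true = c(rep(1, 3), rep(0, 27)),
  sigma_eps = 0.3, gamma10 = c(-1.5, rep(0, 30)), seed = 42
)
sim
#> <me_sim> logistic model, n = 400, p = 30, 3 truly informative predictors
#>   observed P(y* = 1) = 0.51, mean pi10 = 0.182, mean pi01 = 0.182

naive <- me_boost(sim$data, iterations = 200, threshold = 0.8,
                  learn_rate = 0.05, correct_x = FALSE, correct_y = FALSE)
corrected <- me_boost(sim$data, iterations = 200, threshold = 0.8,
                      learn_rate = 0.05, probs = sim$probs, sigma_eps = 0.3)
corrected
#> <me_boost> logistic model, n = 400, p = 30
#>   corrections: response on, predictors on
#>   200 iterations, 5 predictors selected
#>   selected: 1, 2, 3, 8, 29

tidy(corrected) |> filter(selected)
#> # A tibble: 5 × 4
#>   term  index estimate selected
#>   <chr> <int>    <dbl> <lgl>
#> 1 1         1    0.718 TRUE
#> 2 2         2    0.853 TRUE
#> 3 3         3    1.09  TRUE
#> 4 8         8    0.154 TRUE
#> 5 29       29   -0.107 TRUE
```

The corrected fit recovers the three informative predictors with
coefficients near their true value 1 (plus two small spurious terms),
while the naive fit selects 21 predictors with attenuated signal
estimates.  The evaluation helpers make the contrast explicit:

```r
bind_rows(estimation_errors(coef(naive), sim$truth$beta),
          estimation_errors(coef(corrected), sim$truth$beta))
#> # A tibble: 2 × 3      (rows: naive, corrected)
#>      l1    l2
#>   <dbl> <dbl>
#> 1 2.98  1.27
#> 2 0.782 0.380

selection_rates(corrected$selected, truth = 1:3, p = 30)
#> # A tibble: 1 × 2
#>     spe   sen
#>   <dbl> <dbl>
#> 1     1 0.926
```

Here `spe` is the fraction of truly informative predictors included and
`sen` the fraction of truly unimportant ones excluded.

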