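---
title: "Boosted variable selection under misclassified responses and error-prone predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted variable selection under misclassified responses and error-prone predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boostmec)
```

## The problem

Binary-outcome regression on high-dimensional continuous predictors -- the
canonical example being a disease label regressed on thousands of gene
expression levels with $p \gg n$ -- faces two error sources at once:

* **Response misclassification.** The recorded label $Y^*_i$ may differ from
  the true label $Y_i$ (e.g. one leukemia subtype recorded as the other).
* **Classical additive predictor error.** The recorded expression values
  $X^*_i = X_i + \epsilon_i$ carry instrument noise,
  $\epsilon_i \sim N(0, \Sigma_\epsilon)$, independent of $X_i$.

Ignoring either source biases both the coefficient estimates and -- more
insidiously -- the *selection* of which predictors matter.  `boostmec`
corrects both error sources inside the estimating function and couples the
corrected function to a thresholded boosting loop that performs selection
and estimation simultaneously.

## Models and estimating functions

Two binary-response models are supported, neither with an implicit
intercept (prepend a ones column if you want one):

* logistic: $P(Y_i = 1 \mid X_i) = \mathrm{expit}(X_i^\top\beta)$,
* probit: $P(Y_i = 1 \mid X_i) = \Phi(X_i^\top\beta)$.

Estimation is driven by averaged estimating functions, written with a
leading minus sign (the negative average score of the corresponding
log-likelihood):

$$
g_{LR}(\beta) = -\tfrac1n \sum_i X_i\{Y_i - \mathrm{expit}(X_i^\top\beta)\},
\qquad
g_{PM}(\beta) = -\tfrac1n \sum_i X_i\,\phi(X_i^\top\beta)
\left\{\tfrac{Y_i}{\Phi(X_i^\top\beta)} - \tfrac{1-Y_i}{1-\Phi(X_i^\top\beta)}\right\}.
$$

Both are implemented exactly in this form (`score_logistic()`,
`score_probit()`) and are linear in $Y$ -- deliberately so, because the
misclassification-corrected response below is real-valued.

## Correcting the response

Misclassification is described by per-observation probabilities
$\pi_{i10} = P(Y^*=1 \mid Y=0, X_i)$ and $\pi_{i01} = P(Y^*=0 \mid Y=1, X_i)$,
forming a $2\times 2$ misclassification matrix assumed invertible
($\pi_{i10} + \pi_{i01} \ne 1$).  Inverting it yields the corrected
response

$$
Y^{**}_i = \frac{Y^*_i - \pi_{i10}}{1 - \pi_{i10} - \pi_{i01}},
$$

which satisfies $E(Y^{**}_i \mid Y_i, X_i) = Y_i$ whatever the outcome
model.  $Y^{**}$ may fall outside $[0,1]$; with severe misclassification
($\pi_{10} + \pi_{01} > 1$) the denominator is negative and the corrected
values flip sign relative to the surrogate -- both are handled, only an
exactly singular matrix (denominator within $10^{-12}$ of zero) is an
error, reported with the offending row.

## Correcting the predictors

Two strategies, matched to the two models:

* **Sufficient-statistic substitution (logistic).**  Each row is replaced
  by $X^{**}_i = X^*_i + Y^{**}_i\,\Sigma_\epsilon\beta$ inside the
  estimating function.  Because the substitute depends on $\beta$, it is
  re-evaluated at the current iterate in every boosting iteration.
* **Regression calibration (probit).**  Each row is replaced by the
  moment-estimated best linear predictor
  $\hat E(X_i \mid X^*_i) = \hat\mu + (\hat\Sigma - \Sigma_\epsilon)^\top
  \hat\Sigma^{-1}(X^*_i - \hat\mu)$, computed once before iterating
  ($\hat\Sigma$ uses the $n-1$ denominator).  When $\hat\Sigma$ is singular
  -- always for $p \ge n$ -- and $\Sigma_\epsilon$ is diagonal, the same
  formula is applied coordinatewise with per-column sample variances; a
  full-matrix $\Sigma_\epsilon$ with singular $\hat\Sigma$ is an error
  rather than a silent pseudo-inverse.

The four combinations of the two correction flags (`correct_y`,
`correct_x`) give the four analysis settings used throughout: 1 = naive,
2 = response corrected, 3 = predictors corrected, 4 = both.  When
`correct_x = TRUE` but `correct_y = FALSE`, the surrogate $Y^*$ is used as
the multiplier inside the sufficient statistic -- the setting is defined by
not touching the response.

## The boosting loop

Starting at $\beta^{(0)} = 0_p$, iteration $t$ computes
$\Delta^{(t-1)} = g^{**}(\beta^{(t-1)})$ for the configured (corrected)
estimating function, forms the active set

$$
J_{t-1} = \{ j : |\Delta_j^{(t-1)}| \ge \tau \max_{j'} |\Delta_{j'}^{(t-1)}| \},
$$

and updates $\beta_j^{(t)} \leftarrow \beta_j^{(t-1)} - \eta\,\Delta_j^{(t-1)}$
for $j \in J_{t-1}$.  Coordinates never entering the active set stay
exactly zero, so the nonzero set of the final iterate is the selection.

Two sign conventions collide here: the estimating functions carry a leading
minus, and the update must drive them toward their root, i.e. *ascend* the
likelihood.  The update therefore subtracts $\eta\,\Delta_j$ (equivalently,
adds $\eta$ times the score).  Adding $\eta\,\Delta_j$ with the leading-minus
convention would descend the likelihood; we treat that combination as
inconsistent and resolve it in favour of the direction that recovers
positive true coefficients on simulated data.  The update uses
$\eta\,\Delta_j$ itself, not its sign, so $\tau = 0$ is a plain gradient
method -- a property the tests exploit by checking the whole iterate
sequence against an independently coded loop.

Tuning parameters, all dimensionless:

* `iterations` ($T$): the dominant regularizer.  Finite $T$ matters beyond
  overfitting control here -- see Limitations.
* `threshold` ($\tau \in [0,1]$, default 0.9): sparsity control; ties at
  the cutoff are kept; an all-zero signal stops the loop immediately.
* `learn_rate` ($\eta > 0$): step size on the scale of the *averaged*
  estimating function; useful values depend on $n$ and the predictor
  scale.
* `stop_tol` ($\xi$, off by default): early stopping when
  $\lVert g(\beta^{(t)}) - g(\beta^{(t-1)}) \rVert_2 < \xi$.  The norm is
  the L2 norm (the rule's norm is otherwise unspecified); fixed-$T$ runs
  are the reference behaviour, so the rule is opt-in.
* `choose_threshold()` picks $\tau$ from a grid by k-fold cross-validation
  on the held-out negative log-likelihood, with responses corrected before
  scoring (the loss is linear in $Y^{**}$); ties break toward the largest,
  sparsest $\tau$; folds whose training part lacks a response class are
  re-drawn (at most five times) from a shifted seed.

Reported selections are 1-based column indices of the predictor matrix.

## The synthetic-data generator

`simulate_me_binary()` draws, in order: $X_i \sim N(0, I_p)$; $Y_i$ from
the chosen outcome model at `beta_true` (default $(1,1,1,0,\dots)$);
misclassification probabilities from a logistic (or probit) model
$\pi = \mathrm{link}(\gamma_0 + X_i^\top\gamma)$ -- the default
intercept 1 with zero slopes gives the constant severe rate
$\pi_{10} = \pi_{01} = \mathrm{expit}(1) \approx 0.731$ for every
observation; $Y^*_i$ through the misclassification channel; and
$X^*_i = X_i + \epsilon_i$ with variance `sigma_eps` (default 0.15) per
coordinate.  One master seed makes the whole bundle bitwise reproducible;
the study driver derives replicate $r$'s seed as `seed + r - 1`.

These defaults *are* the package's reference study conditions, used by the
replicated study driver (`run_simulation_study()`, default 100 replicates
with Monte Carlo standard errors) and the acceptance script.  What the
generator deliberately does not emulate: correlated predictor designs,
non-normal or differential predictor error, and misclassification
depending on unobserved covariates.  Passing tests on these synthetic
conditions therefore say nothing about, e.g., correlated expression
blocks.

## Numerical choices

* Probit probabilities are clipped to $[10^{-10}, 1 - 10^{-10}]$ before
  division; the boundary behaviour of the probit score is otherwise
  undefined and raw division overflows.
* Misclassification-matrix invertibility is enforced with a $10^{-12}$
  guard on the denominator.
* `standardize()` uses the population ($n$) denominator, matching the
  usual z-score preprocessing convention; `regression_calibration()` uses
  the $n-1$ covariance.  The mismatch is intentional and documented in
  both places.
* The iteration loop is compiled (RcppArmadillo); a plain-R reference loop
  in the test suite serves as its oracle.
* A non-finite estimating function aborts the fit with an explicit error
  (this is reachable: see Limitations) rather than returning garbage.

## Limitations

* **The corrected logistic equation need not have a root.**  With a
  *binary* response and predictor error only, the sufficient-statistic
  construction is the classical conditional-score estimator and has a
  stable root near the truth.  With a real-valued corrected response
  $Y^{**}$ in the exponent multiplier, the equation loses that structure:
  along the true-coefficient direction the score can keep pushing outward,
  and unboundedly large iterates (with step sizes large enough to follow
  them) diverge.  Finite $T$ and a small $\eta$ are then not merely
  overfitting control but the de facto definition of the estimator.  The
  package surfaces divergence as an error suggesting a smaller
  `learn_rate`.
* **Severe misclassification destroys selection information.**  Under the
  default generator conditions ($\pi_{10} = \pi_{01} \approx 0.731$,
  constant), the surrogate retains correlation
  $|1 - \pi_{10} - \pi_{01}| \approx 0.46$ with the truth; at $n = 100$,
  $p = 1000$ the marginal signal of a truly informative predictor then
  sits *below* the maximum of a thousand null signals, and no estimator --
  corrected or not -- can reliably single out the informative set.  The
  response correction restores unbiasedness of the estimating function,
  not the lost information.  Unit tests therefore validate the correction
  machinery where it is mathematically guaranteed (zero-error reductions,
  conditional unbiasedness, oracle equivalences, error-free consistency
  against `glm()`), while the study driver reports whatever the reference
  conditions actually deliver.
* **Step-size scale.**  With the averaged estimating function, the total
  coefficient movement is bounded by $T\,\eta\,\max_t\lVert
  \Delta^{(t)}\rVert_\infty$; at the reference tuning
  ($T = 1000$, $\eta = 10^{-5}$) this is of order $10^{-3}$, so the
  reference fits are deliberately heavily regularized and their value lies
  in the *selection* behaviour, not the coefficient magnitudes.
* No inference (standard errors, p-values) is provided for the selected
  coefficients, and $\Sigma_\epsilon$ and $\pi$ are taken as known (or
  posited via `run_sensitivity()`), not estimated from replicates or
  validation data.

## Problem sizes used by the tests and scripts

The bundled checks run the reference design at $n = 100$, $p = 1000$ with
100 replicates (25 replicates at $p = 5000$), which completes in about a
minute; the error-free consistency check uses $n = 2000$, $p = 5$.  These
sizes are the package's chosen defaults for its own validation and can be
scaled up by the user.
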