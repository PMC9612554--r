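#' Mean response of a binary-regression model
#'
#' Evaluates the success probability `P(Y = 1 | x)` of a logistic or probit
#' model at each row of a predictor matrix: `expit(x'beta)` for the logistic
#' link and `Phi(x'beta)` (standard normal CDF) for the probit link.  Neither
#' model carries an implicit intercept; callers that want one prepend a
#' column of ones.
#'
#' @param x Numeric predictor matrix (n x p) or a single predictor row.
#' @param beta Numeric coefficient vector of length p.
#' @param model `"logistic"` or `"probit"`.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row of `x`.
#' @examples
#' mean_response(matrix(c(1, 0), 1), c(0, 0), "logistic")  # 0.5
#' mean_response(matrix(1.959964, 1), 1, "probit")         # 0.975
#' @export
mean_response <- function(x, beta, model = c("logistic", "probit")) {
  model <- match.arg(model)
  x <- as_predictor_matrix(x, length(beta))
  eta <- drop(x %*% beta)
  if (model == "logistic") plogis(eta) else pnorm(eta)
}

#' Logistic-regression estimating function
#'
#' The averaged estimating function whose root is the logistic maximum
#' likelihood estimate, returned with a leading minus sign:
#' `g(beta) = -(1/n) sum_i x_i (y_i - expit(x_i' beta))`.
#' It is the negative average score of the Bernoulli log-likelihood, and is
#' linear in `y`, so real-valued (misclassification-corrected) responses can
#' be passed through the same code path.
#'
#' @param beta Numeric coefficient vector of length p.
#' @param x Numeric predictor matrix (n x p).
#' @param y Numeric response vector of length n; need not be 0/1.
#' @return Numeric vector of length p.
#' @seealso [score_probit()], [corrected_score_logistic()]
#' @export
score_logistic <- function(beta, x, y) {
  x <- as_predictor_matrix(x, length(beta))
  y <- as_response(y, nrow(x))
  g <- lin_score(x, y - plogis(drop(x %*% beta)))
  assert_finite_score(g)
  g
}

#' Probit-regression estimating function
#'
#' The averaged probit estimating function, with a leading minus sign:
#' `g(beta) = -(1/n) sum_i x_i phi(x_i' beta) * (y_i / Phi_i - (1 - y_i) / (1 - Phi_i))`
#' where `phi` and `Phi` are the standard normal density and CDF and
#' `Phi_i = Phi(x_i' beta)`.  `Phi_i` is clipped into
#' `[1e-10, 1 - 1e-10]` before division, so extreme linear predictors do not
#' overflow.  Like [score_logistic()], the function is linear in `y`.
#'
#' @inheritParams score_logistic
#' @return Numeric vector of length p.
#' @export
score_probit <- function(beta, x, y) {
  x <- as_predictor_matrix(x, length(beta))
  y <- as_response(y, nrow(x))
  g <- lin_score(x, probit_weight(drop(x %*% beta), y))
  assert_finite_score(g)
  g
}

# shared kernel: g = -(1/n) X'w ; every (corrected) score funnels through this
# so that zero-error corrections reduce to the naive scores bitwise
lin_score <- function(x, w) {
  -drop(crossprod(x, w)) / nrow(x)
}

# per-observation probit weight phi(eta) * (y/Phi - (1-y)/(1-Phi)),
# with Phi clipped away from {0, 1}
probit_weight <- function(eta, y) {
  p <- clip_prob(pnorm(eta))
  dnorm(eta) * (y / p - (1 - y) / (1 - p))
}

PROB_CLIP <- 1e-10

clip_prob <- function(p) {
  pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)
}

as_predictor_matrix <- function(x, p = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.numeric(x)) {
    abort("predictor matrix must be numeric")
  }
  if (anyNA(x) || !all(is.finite(x))) {
    abort("predictor matrix contains missing or non-finite entries")
  }
  if (!is.null(p) && ncol(x) != p) {
    abort(sprintf(
      "dimension mismatch: %d predictor columns but %d coefficients",
      ncol(x), p
    ))
  }
  x
}

as_response <- function(y, n) {
  y <- as.numeric(y)
  if (length(y) != n) {
    abort(sprintf("response length %d does not match %d rows", length(y), n))
  }
  if (anyNA(y) || !all(is.finite(y))) {
    abort("response contains missing or non-finite values")
  }
  y
}

assert_finite_score <- function(g) {
  if (!all(is.finite(g))) {
    abort("estimating function is non-finite; the fit has diverged")
  }
  invisible(g)
}
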