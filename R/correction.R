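#' Correct a misclassified binary response
#'
#' Inverts the 2x2 misclassification matrix linking the surrogate response
#' `Y*` to the latent truth `Y`.  With `pi10 = P(Y* = 1 | Y = 0, x)` and
#' `pi01 = P(Y* = 0 | Y = 1, x)`, the corrected response is
#' `Y** = (Y* - pi10) / (1 - pi10 - pi01)`.
#' `Y**` is real-valued -- it can be negative or exceed 1 -- but satisfies
#' `E(Y** | Y, x) = Y`, so it can replace `Y` inside any estimating function
#' that is linear in the response.  The denominator may be negative (severe
#' misclassification, `pi10 + pi01 > 1`); only a (near-)zero denominator, a
#' non-invertible misclassification matrix, is an error.
#'
#' @param y_star Binary (0/1) surrogate response vector.
#' @param probs Misclassification probabilities: a data frame with columns
#'   `pi10` and `pi01` (one row per observation, or a single row that is
#'   recycled), or a 2-column matrix in that column order.
#' @return Numeric vector of corrected responses.
#' @examples
#' correct_response(c(1, 0), data.frame(pi10 = 0.1, pi01 = 0.2))
#' @export
correct_response <- function(y_star, probs) {
  y_star <- as_response(y_star, length(y_star))
  if (!all(y_star %in% c(0, 1))) {
    abort("`y_star` must contain only 0 and 1")
  }
  probs <- as_misclass_probs(probs, length(y_star))
  (y_star - probs$pi10) / (1 - probs$pi10 - probs$pi01)
}

#' Sufficient-statistic substitute for error-prone predictors
#'
#' Builds the corrected predictor rows used by the corrected logistic
#' estimating function: `x** = x* + y** * (Sigma_eps %*% beta)`.  Because the
#' substitute depends on `beta`, it is re-evaluated at the current iterate
#' inside every boosting iteration.
#'
#' @param x_star Observed predictor matrix (n x p) or a single row.
#' @param y_corrected Real-valued (corrected) response vector, length n.
#' @param sigma_eps Measurement-error covariance: a scalar (`sigma2 * I`), a
#'   length-p vector of diagonal entries, or a full p x p matrix.
#' @param beta Coefficient vector of length p.
#' @return An n x p matrix of corrected predictor rows.
#' @export
sufficient_statistic <- function(x_star, y_corrected, sigma_eps, beta) {
  x_star <- as_predictor_matrix(x_star, length(beta))
  y_corrected <- as_response(y_corrected, nrow(x_star))
  sb <- me_cov_mult(as_me_cov(sigma_eps, ncol(x_star)), beta)
  x_star + outer(y_corrected, sb)
}

#' Corrected logistic estimating function
#'
#' The logistic estimating function with both error sources corrected:
#' [score_logistic()] evaluated with each predictor row replaced by its
#' sufficient-statistic substitute ([sufficient_statistic()]) and the
#' response replaced by the corrected response ([correct_response()]).
#' With `sigma_eps = 0` it reduces, bitwise, to the naive
#' [score_logistic()] on the same inputs.
#'
#' @inheritParams sufficient_statistic
#' @param beta Coefficient vector of length p.
#' @return Numeric vector of length p.
#' @export
corrected_score_logistic <- function(beta, x_star, y_corrected, sigma_eps) {
  x_star <- as_predictor_matrix(x_star, length(beta))
  y_corrected <- as_response(y_corrected, nrow(x_star))
  me <- as_me_cov(sigma_eps, ncol(x_star))
  g <- corrected_logistic_kernel(beta, x_star, y_corrected, me)
  assert_finite_score(g)
  g
}

# shared arithmetic for the corrected logistic score; written so the
# sigma = 0 case reproduces score_logistic() exactly (adding a zero vector
# and subtracting a zero correction are bitwise identities)
corrected_logistic_kernel <- function(beta, x, y, me) {
  sb <- me_cov_mult(me, beta)
  lin <- drop(x %*% beta) + y * sum(sb * beta)
  w <- y - plogis(lin)
  lin_score(x, w) - sb * (sum(y * w) / nrow(x))
}

#' Corrected probit estimating function
#'
#' The probit estimating function evaluated on regression-calibrated
#' predictors and corrected responses: [score_probit()] applied to
#' `(x**, y**)`, where `x**` comes from [predict.rc_calibration()] and
#' `y**` from [correct_response()].  The calibration map does not depend on
#' `beta`, so it is computed once before iterating.
#'
#' @inheritParams score_logistic
#' @param x_calibrated Calibrated predictor matrix (n x p).
#' @return Numeric vector of length p.
#' @export
corrected_score_probit <- function(beta, x_calibrated, y_corrected) {
  score_probit(beta, x_calibrated, y_corrected)
}

#' Regression calibration for classical additive measurement error
#'
#' Estimates the best linear predictor `E(X | X*)` by the method of moments:
#' `x** = mu_hat + t(Sigma_hat - Sigma_eps) %*% solve(Sigma_hat) %*% (x - mu_hat)`
#' with `mu_hat` the column means and `Sigma_hat` the empirical covariance
#' (denominator `n - 1`) of the observed predictors.  When `Sigma_hat` is
#' singular -- always the case for p >= n -- and `Sigma_eps` is diagonal, the
#' map is applied coordinatewise using per-column sample variances, which is
#' the same formula restricted to diagonal matrices.  A full-matrix
#' `Sigma_eps` with singular `Sigma_hat` is an error.
#'
#' @param x_star Observed predictor matrix (n x p), `n >= 2`.
#' @inheritParams sufficient_statistic
#' @return An object of class `"rc_calibration"` with elements `mu` (column
#'   means), `method` (`"full"` or `"diagonal"`), and the fitted affine map;
#'   apply it with [predict.rc_calibration()].
#' @examples
#' cal <- regression_calibration(matrix(c(0, 2, 4), 3), sigma_eps = 3)
#' predict(cal, matrix(c(0, 2, 4), 3))  # 1.5, 2.0, 2.5
#' @export
regression_calibration <- function(x_star, sigma_eps) {
  x_star <- as_predictor_matrix(x_star)
  n <- nrow(x_star)
  p <- ncol(x_star)
  if (n < 2) abort("regression calibration needs at least two observations")
  me <- as_me_cov(sigma_eps, p)
  mu <- colMeans(x_star)

  full_ok <- p <= n - 1
  if (full_ok) {
    sigma_hat <- cov(x_star)
    full_ok <- is.finite(rcond_sym(sigma_hat)) && rcond_sym(sigma_hat) > 1e-12
  }
  if (me$type == "full" || full_ok) {
    if (!full_ok) {
      abort(paste(
        "empirical covariance of the observed predictors is singular;",
        "full-matrix calibration needs p < n and a well-conditioned",
        "covariance (supply a scalar or diagonal `sigma_eps` for the",
        "coordinatewise fallback)"
      ))
    }
    amat <- t(sigma_hat - me_cov_dense(me)) %*% solve(sigma_hat)
    out <- list(mu = mu, method = "full", amat = amat)
  } else {
    s2 <- apply(x_star, 2, var)
    if (any(s2 <= 0)) {
      abort("constant predictor column; cannot calibrate")
    }
    out <- list(mu = mu, method = "diagonal", scale = (s2 - me_cov_diag(me)) / s2)
  }
  structure(out, class = "rc_calibration")
}

#' Apply a fitted calibration map
#'
#' @param object An `"rc_calibration"` fit from [regression_calibration()].
#' @param newdata Predictor matrix (n x p) to calibrate.
#' @param ... Unused.
#' @return The calibrated matrix, same shape as `newdata`.
#' @export
predict.rc_calibration <- function(object, newdata, ...) {
  x <- as_predictor_matrix(newdata, length(object$mu))
  centred <- sweep(x, 2, object$mu)
  out <- if (object$method == "full") {
    centred %*% t(object$amat)
  } else {
    sweep(centred, 2, object$scale, `*`)
  }
  sweep(out, 2, object$mu, `+`)
}

#' @export
print.rc_calibration <- function(x, ...) {
  cat(sprintf(
    "<rc_calibration> %s map on %d predictors\n",
    x$method, length(x$mu)
  ))
  invisible(x)
}

# ---- measurement-error covariance handling ---------------------------------

# internal canonical form for Sigma_eps: scalar sigma2*I, diagonal, or full
as_me_cov <- function(sigma, p) {
  if (inherits(sigma, "me_cov")) {
    if (sigma$p != p) abort("`sigma_eps` dimension does not match predictors")
    return(sigma)
  }
  if (is.null(sigma)) sigma <- 0
  if (is.matrix(sigma)) {
    if (nrow(sigma) != p || ncol(sigma) != p) {
      abort(sprintf("`sigma_eps` must be %d x %d", p, p))
    }
    if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
      abort("`sigma_eps` must be symmetric")
    }
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(1, max(abs(ev)))) {
      abort("`sigma_eps` must be positive semidefinite")
    }
    out <- list(type = "full", p = p, full = sigma)
  } else if (length(sigma) == 1L) {
    if (!is.finite(sigma) || sigma < 0) abort("scalar `sigma_eps` must be >= 0")
    out <- list(type = "scalar", p = p, scalar = as.numeric(sigma))
  } else if (length(sigma) == p) {
    if (any(!is.finite(sigma)) || any(sigma < 0)) {
      abort("diagonal `sigma_eps` entries must be finite and >= 0")
    }
    out <- list(type = "diagonal", p = p, diag = as.numeric(sigma))
  } else {
    abort("`sigma_eps` must be a scalar, a length-p vector, or a p x p matrix")
  }
  structure(out, class = "me_cov")
}

me_cov_mult <- function(me, beta) {
  switch(me$type,
    scalar   = me$scalar * beta,
    diagonal = me$diag * beta,
    full     = drop(me$full %*% beta)
  )
}

me_cov_diag <- function(me) {
  switch(me$type,
    scalar   = rep(me$scalar, me$p),
    diagonal = me$diag,
    full     = diag(me$full)
  )
}

me_cov_dense <- function(me) {
  switch(me$type,
    scalar   = diag(me$scalar, me$p),
    diagonal = diag(me$diag, me$p),
    full     = me$full
  )
}

me_cov_is_zero <- function(me) {
  switch(me$type,
    scalar   = me$scalar == 0,
    diagonal = all(me$diag == 0),
    full     = all(me$full == 0)
  )
}

rcond_sym <- function(m) {
  suppressWarnings(tryCatch(rcond(m), error = function(e) 0))
}

# ---- misclassification probabilities ---------------------------------------

as_misclass_probs <- function(probs, n) {
  if (is.matrix(probs)) {
    if (ncol(probs) != 2) abort("misclassification matrix must have 2 columns")
    probs <- tibble(pi10 = probs[, 1], pi01 = probs[, 2])
  }
  if (!is.data.frame(probs) || !all(c("pi10", "pi01") %in% names(probs))) {
    abort("`probs` must be a data frame with columns `pi10` and `pi01`")
  }
  probs <- as_tibble(probs)[c("pi10", "pi01")]
  if (nrow(probs) == 1L && n > 1L) {
    probs <- probs[rep(1L, n), ]
  }
  if (nrow(probs) != n) {
    abort(sprintf(
      "misclassification probabilities have %d rows but there are %d observations",
      nrow(probs), n
    ))
  }
  bad <- !is.finite(probs$pi10) | !is.finite(probs$pi01) |
    probs$pi10 < 0 | probs$pi10 > 1 | probs$pi01 < 0 | probs$pi01 > 1
  if (any(bad)) {
    abort(sprintf(
      "misclassification probabilities outside [0, 1] at row %d",
      which(bad)[1]
    ))
  }
  den <- 1 - probs$pi10 - probs$pi01
  if (any(abs(den) < 1e-12)) {
    abort(sprintf(
      "misclassification matrix is not invertible at row %d (pi10 + pi01 = 1)",
      which(abs(den) < 1e-12)[1]
    ))
  }
  probs
}
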