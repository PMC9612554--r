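#' Generate latent (error-free) binary-regression data
#'
#' Predictor rows are i.i.d. standard multivariate normal `N(0, I_p)`; the
#' binary response is drawn from the logistic or probit model at
#' `beta_true`.
#'
#' @param n,p Sample size and number of predictors.
#' @param beta_true Coefficient vector of length p.
#' @param model `"logistic"` or `"probit"`.
#' @param seed Optional integer seed (applied locally).
#' @return A list with `x` (n x p matrix, columns named `"1"..."p"`) and
#'   `y` (0/1 vector).
#' @export
generate_true <- function(n, p, beta_true = c(rep(1, 3), rep(0, p - 3)),
                          model = c("logistic", "probit"), seed = NULL) {
  model <- match.arg(model)
  if (n < 1 || p < 1) abort("`n` and `p` must be >= 1")
  if (length(beta_true) != p) abort("`beta_true` must have length p")
  with_optional_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, as.character(seq_len(p))))
    y <- rbinom(n, 1, mean_response(x, beta_true, model))
    list(x = x, y = y)
  })
}

#' Misclassification probabilities from a regression model
#'
#' Computes per-observation misclassification probabilities
#' `pi10 = P(Y* = 1 | Y = 0, x)` and `pi01 = P(Y* = 0 | Y = 1, x)` from a
#' logistic or probit model on the (latent) predictors:
#' `pi = link(intercept + x' slopes)`.  Each `gamma` is given as the
#' concatenation `c(intercept, slopes)`; the default
#' `c(1, 0, ..., 0)` gives the constant rate `plogis(1) = 0.731` for every
#' observation, for both probabilities.
#'
#' @param x Predictor matrix (n x p).
#' @param gamma10,gamma01 Numeric vectors of length `p + 1`
#'   (intercept first) for `pi10` and `pi01`.
#' @param link `"logistic"` or `"probit"`.
#' @return A tibble with columns `pi10`, `pi01`.  It is an error if any row
#'   yields `pi10 + pi01 = 1` (a non-invertible misclassification matrix).
#' @export
misclass_probs <- function(x, gamma10 = c(1, rep(0, ncol(x))),
                           gamma01 = gamma10,
                           link = c("logistic", "probit")) {
  link <- match.arg(link)
  x <- as_predictor_matrix(x)
  p <- ncol(x)
  if (length(gamma10) != p + 1 || length(gamma01) != p + 1) {
    abort("`gamma10` and `gamma01` must have length p + 1 (intercept first)")
  }
  lp <- function(g) g[1] + drop(x %*% g[-1])
  fun <- if (link == "logistic") plogis else pnorm
  probs <- tibble(pi10 = fun(lp(gamma10)), pi01 = fun(lp(gamma01)))
  as_misclass_probs(probs, nrow(x))
}

#' Misclassify a binary response
#'
#' Draws the surrogate response through the misclassification channel:
#' `P(Y* = 1 | Y = 1) = 1 - pi01` and `P(Y* = 1 | Y = 0) = pi10`.
#'
#' @param y_true 0/1 response vector.
#' @param probs Misclassification probabilities (see [correct_response()]).
#' @param seed Optional integer seed (applied locally).
#' @return 0/1 vector of surrogate responses.
#' @export
misclassify <- function(y_true, probs, seed = NULL) {
  y_true <- as_response(y_true, length(y_true))
  if (!all(y_true %in% c(0, 1))) abort("`y_true` must be 0/1")
  probs <- as_misclass_probs(probs, length(y_true))
  with_optional_seed(seed, {
    rbinom(length(y_true), 1, ifelse(y_true == 1, 1 - probs$pi01, probs$pi10))
  })
}

#' Add classical additive measurement error to predictors
#'
#' Returns `x* = x + e` with `e ~ N(0, Sigma_eps)` independent across rows
#' and independent of `x`.
#'
#' @param x_true Predictor matrix (n x p).
#' @inheritParams sufficient_statistic
#' @param seed Optional integer seed (applied locally).
#' @return Matrix of observed, error-prone predictors.
#' @export
add_classical_error <- function(x_true, sigma_eps, seed = NULL) {
  x_true <- as_predictor_matrix(x_true)
  n <- nrow(x_true)
  p <- ncol(x_true)
  me <- as_me_cov(sigma_eps, p)
  with_optional_seed(seed, {
    eps <- switch(me$type,
      scalar = matrix(rnorm(n * p, 0, sqrt(me$scalar)), n, p),
      diagonal = matrix(rnorm(n * p), n, p) %*% diag(sqrt(me$diag), p),
      full = matrix(rnorm(n * p), n, p) %*% chol_psd(me$full)
    )
    x_true + eps
  })
}

# upper Cholesky factor tolerating semidefinite matrices
chol_psd <- function(m) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(r)) return(r)
  e <- eigen(m, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m)) %*% t(e$vectors))
}

#' Simulate error-prone binary-regression data
#'
#' One-stop generator bundling [generate_true()], [misclass_probs()],
#' [misclassify()] and [add_classical_error()].  The defaults reproduce the
#' package's reference simulation design: `beta_true = (1, 1, 1, 0, ...)`,
#' standard-normal predictors, logistic response, misclassification
#' probabilities from a logistic model with intercept 1 and zero slopes
#' (`pi10 = pi01 = 0.731` for every observation), and independent additive
#' predictor noise with variance `sigma_eps` per coordinate.
#'
#' @inheritParams generate_true
#' @inheritParams sufficient_statistic
#' @inheritParams misclass_probs
#' @param seed Optional integer seed making the whole bundle reproducible.
#' @return An object of class `"me_sim"`: a list with
#'   \describe{
#'     \item{`data`}{tibble of observed data -- response column `y` and
#'       error-prone predictor columns `"1"..."p"`.}
#'     \item{`probs`}{tibble of misclassification probabilities
#'       (`pi10`, `pi01`).}
#'     \item{`truth`}{list with the latent `x`, `y` and `beta`.}
#'     \item{`model`, `link`, `sigma_eps`, `seed`}{the configuration.}
#'   }
#' @examples
#' sim <- simulate_me_binary(n = 50, p = 10, seed = 7)
#' sim$data
#' @export
simulate_me_binary <- function(n = 100, p = 1000,
                               beta_true = c(rep(1, min(3, p)), rep(0, max(0, p - 3))),
                               model = c("logistic", "probit"),
                               sigma_eps = 0.15,
                               gamma10 = c(1, rep(0, p)),
                               gamma01 = gamma10,
                               link = c("logistic", "probit"),
                               seed = NULL) {
  model <- match.arg(model)
  link <- match.arg(link)
  with_optional_seed(seed, {
    latent <- generate_true(n, p, beta_true, model)
    probs <- misclass_probs(latent$x, gamma10, gamma01, link)
    y_obs <- misclassify(latent$y, probs)
    x_obs <- add_classical_error(latent$x, sigma_eps)
    data <- dplyr::bind_cols(tibble(y = y_obs), as_tibble(x_obs))
    structure(
      list(
        data = data,
        probs = probs,
        truth = list(x = latent$x, y = latent$y, beta = beta_true),
        model = model,
        link = link,
        sigma_eps = sigma_eps,
        seed = seed
      ),
      class = "me_sim"
    )
  })
}

#' @export
print.me_sim <- function(x, ...) {
  cat(sprintf(
    "<me_sim> %s model, n = %d, p = %d, %d truly informative predictors\n",
    x$model, nrow(x$data), ncol(x$data) - 1L, sum(x$truth$beta != 0)
  ))
  cat(sprintf(
    "  observed P(y* = 1) = %.2f, mean pi10 = %.3f, mean pi01 = %.3f\n",
    mean(x$data$y), mean(x$probs$pi10), mean(x$probs$pi01)
  ))
  invisible(x)
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
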