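#' Thresholded boosting with measurement-error correction
#'
#' Fits a sparse logistic or probit regression by boosting a (corrected)
#' estimating function.  Starting from `beta = 0`, each iteration evaluates
#' the configured estimating function `g` at the current iterate, forms the
#' active set of coordinates whose `|g_j|` is within a factor `threshold` of
#' the largest, and moves those coordinates by `learn_rate * |g_j|` toward
#' the root of `g`.  Predictors whose coefficient is never moved stay exactly
#' zero, so the fit selects variables and estimates coefficients at once.
#'
#' The four correction settings are controlled by two flags:
#' `correct_y` replaces the surrogate response by the misclassification-
#' corrected response ([correct_response()]); `correct_x` corrects the
#' error-prone predictors -- through the sufficient-statistic substitution
#' inside the estimating function for the logistic model
#' ([corrected_score_logistic()]), and through a one-off regression
#' calibration of the predictor matrix for the probit model
#' ([regression_calibration()]).  With both flags off the naive estimating
#' function is boosted as-is.  When `correct_x` is on but `correct_y` is
#' off, the surrogate response is used as the multiplier inside the
#' sufficient statistic.
#'
#' @param data Data frame holding the binary response column and numeric
#'   predictor columns.
#' @param response Name of the response column (default `"y"`).
#' @param model `"logistic"` or `"probit"`.
#' @param iterations Maximum number of boosting iterations `T`.
#' @param threshold Active-set threshold `tau` in `[0, 1]`; `tau = 0` updates
#'   every coordinate (a plain gradient method), `tau = 1` only the largest.
#' @param learn_rate Step size `eta > 0`.
#' @param stop_tol Optional early-stopping tolerance `xi`: iteration stops
#'   once the L2 change of the estimating function between consecutive
#'   iterates falls below `xi`.  `NULL` (default) runs all `iterations`.
#' @param correct_x,correct_y Logical correction flags (see Details).
#' @param probs Misclassification probabilities (`pi10`, `pi01` columns);
#'   required when `correct_y = TRUE`.
#' @param sigma_eps Measurement-error covariance (scalar, length-p diagonal,
#'   or p x p matrix); required when `correct_x = TRUE`.
#' @return An object of class `"me_boost"`: a list with `beta` (named
#'   estimate vector), `selected` (1-based indices of nonzero coefficients),
#'   `n_selected`, `iterations_run`, `stopped_early`, `score_norm_trace`,
#'   and the fitting configuration.  [tidy()] returns the per-term table,
#'   [glance()] the one-row fit summary.
#' @examples
#' sim <- simulate_me_binary(n = 80, p = 5, sigma_eps = 0.1, seed = 1)
#' fit <- me_boost(sim$data,
#'   iterations = 50, threshold = 0.5, learn_rate = 0.01,
#'   probs = sim$probs, sigma_eps = 0.1
#' )
#' tidy(fit)
#' @export
me_boost <- function(data,
                     response = "y",
                     model = c("logistic", "probit"),
                     iterations = 1000,
                     threshold = 0.9,
                     learn_rate = 1e-5,
                     stop_tol = NULL,
                     correct_x = TRUE,
                     correct_y = TRUE,
                     probs = NULL,
                     sigma_eps = NULL) {
  model <- match.arg(model)
  xy <- split_response(data, response)
  fit <- me_boost_engine(
    x = xy$x, y = xy$y, model = model,
    iterations = iterations, threshold = threshold,
    learn_rate = learn_rate, stop_tol = stop_tol,
    correct_x = correct_x, correct_y = correct_y,
    probs = probs, sigma_eps = sigma_eps
  )
  fit$response <- response
  fit
}

# matrix-level engine shared by me_boost(), choose_threshold() and the
# study drivers (which already hold x/y)
me_boost_engine <- function(x, y, model,
                            iterations, threshold, learn_rate, stop_tol,
                            correct_x, correct_y, probs, sigma_eps) {
  x <- as_predictor_matrix(x)
  y <- as_response(y, nrow(x))
  if (!all(y %in% c(0, 1))) {
    abort("the observed response must be binary 0/1")
  }
  if (!is.numeric(iterations) || iterations < 1) abort("`iterations` must be >= 1")
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1]")
  if (!is.numeric(learn_rate) || learn_rate <= 0) abort("`learn_rate` must be > 0")
  if (!is.null(stop_tol) && stop_tol <= 0) abort("`stop_tol` must be > 0")
  if (correct_y && is.null(probs)) {
    abort("`correct_y = TRUE` needs misclassification probabilities (`probs`)")
  }
  if (correct_x && is.null(sigma_eps)) {
    abort("`correct_x = TRUE` needs a measurement-error covariance (`sigma_eps`)")
  }
  p <- ncol(x)

  y_use <- if (correct_y) correct_response(y, probs) else y

  me <- if (correct_x) as_me_cov(sigma_eps, p) else NULL
  use_ss <- correct_x && model == "logistic"
  x_use <- x
  if (correct_x && model == "probit") {
    x_use <- predict(regression_calibration(x, me), x)
  }

  sig_type <- 0L
  sig_scalar <- 0
  sig_diag <- numeric(0)
  sig_full <- matrix(0, 0, 0)
  if (use_ss) {
    sig_type <- switch(me$type, scalar = 1L, diagonal = 2L, full = 3L)
    if (sig_type == 1L) sig_scalar <- me$scalar
    if (sig_type == 2L) sig_diag <- me$diag
    if (sig_type == 3L) sig_full <- me$full
  }

  res <- boost_engine_cpp(
    x_use, y_use, if (model == "logistic") 0L else 1L,
    use_ss, sig_type, sig_scalar, sig_diag, sig_full,
    as.integer(iterations), threshold, learn_rate,
    if (is.null(stop_tol)) -1 else stop_tol
  )
  if (isTRUE(res$diverged)) {
    abort("estimating function became non-finite; reduce `learn_rate`")
  }

  beta <- drop(res$beta)
  names(beta) <- colnames(x) %||% as.character(seq_len(p))
  selected <- which(beta != 0)
  structure(
    list(
      beta = beta,
      selected = as.integer(selected),
      n_selected = length(selected),
      iterations_run = res$iterations_run,
      stopped_early = res$stopped_early,
      score_norm_trace = drop(res$score_norm),
      model = model,
      n = nrow(x),
      p = p,
      config = list(
        iterations = iterations, threshold = threshold,
        learn_rate = learn_rate, stop_tol = stop_tol,
        correct_x = correct_x, correct_y = correct_y
      )
    ),
    class = "me_boost"
  )
}

#' Active set of a thresholded boosting iteration
#'
#' Indices whose estimating-function component is within a factor `tau` of
#' the largest absolute component: `{ j : |delta_j| >= tau * max |delta| }`.
#' Ties at the cutoff are included.  The set is empty exactly when all
#' components are zero.
#'
#' @param delta Numeric vector of estimating-function components.
#' @param tau Threshold in `[0, 1]`.
#' @return Integer vector of 1-based indices.
#' @examples
#' active_set(c(0.5, -0.4, 0.1), 0.9)  # 1
#' @export
active_set <- function(delta, tau) {
  if (tau < 0 || tau > 1) abort("`tau` must be in [0, 1]")
  if (anyNA(delta) || !all(is.finite(delta))) abort("`delta` must be finite")
  m <- max(abs(delta))
  if (m == 0) return(integer(0))
  which(abs(delta) >= tau * m)
}

#' Choose the boosting threshold by cross-validation
#'
#' Evaluates each candidate threshold by k-fold cross-validation and returns
#' the one minimising the mean held-out negative log-likelihood.  Held-out
#' responses are corrected for misclassification (when `correct_y = TRUE`)
#' before scoring, so the loss is linear in the corrected response:
#' `-(1/n) sum y** log mu + (1 - y**) log(1 - mu)` with `mu` clipped away
#' from 0 and 1.  Ties are broken toward the largest (sparsest) threshold.
#' Folds are drawn deterministically from `seed`; a fold whose training part
#' contains a single response class is re-drawn with a shifted seed, at most
#' five times.
#'
#' @inheritParams me_boost
#' @param tau_grid Candidate thresholds in `[0, 1]`.
#' @param k_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return The selected threshold (a scalar), with the per-threshold mean
#'   losses attached as attribute `"cv_loss"`.
#' @export
choose_threshold <- function(data,
                             response = "y",
                             tau_grid = seq(0.5, 0.95, by = 0.05),
                             k_folds = 5,
                             seed = 1,
                             model = c("logistic", "probit"),
                             iterations = 1000,
                             learn_rate = 1e-5,
                             stop_tol = NULL,
                             correct_x = TRUE,
                             correct_y = TRUE,
                             probs = NULL,
                             sigma_eps = NULL) {
  model <- match.arg(model)
  if (length(tau_grid) < 1 || any(tau_grid < 0 | tau_grid > 1)) {
    abort("`tau_grid` must be a non-empty subset of [0, 1]")
  }
  xy <- split_response(data, response)
  n <- nrow(xy$x)
  if (k_folds < 2 || k_folds > n) abort("`k_folds` must be in [2, n]")
  probs_tbl <- if (!is.null(probs)) as_misclass_probs(probs, n) else NULL

  folds <- NULL
  for (attempt in 0:4) {
    cand <- withr::with_seed(seed + attempt, sample(rep_len(seq_len(k_folds), n)))
    ok <- all(vapply(seq_len(k_folds), function(k) {
      length(unique(xy$y[cand != k])) == 2L
    }, logical(1)))
    if (ok) {
      folds <- cand
      break
    }
  }
  if (is.null(folds)) {
    abort("could not build folds with both response classes in every training set")
  }

  loss <- vapply(tau_grid, function(tau) {
    fold_losses <- vapply(seq_len(k_folds), function(k) {
      tr <- folds != k
      fit <- me_boost_engine(
        xy$x[tr, , drop = FALSE], xy$y[tr],
        model = model, iterations = iterations, threshold = tau,
        learn_rate = learn_rate, stop_tol = stop_tol,
        correct_x = correct_x, correct_y = correct_y,
        probs = if (!is.null(probs_tbl)) probs_tbl[tr, ] else NULL,
        sigma_eps = sigma_eps
      )
      te <- !tr
      y_te <- if (correct_y) {
        correct_response(xy$y[te], probs_tbl[te, ])
      } else {
        xy$y[te]
      }
      mu <- clip_prob(mean_response(xy$x[te, , drop = FALSE], fit$beta, model))
      -mean(y_te * log(mu) + (1 - y_te) * log(1 - mu))
    }, numeric(1))
    mean(fold_losses)
  }, numeric(1))

  best <- max(tau_grid[loss <= min(loss) + 1e-12])
  structure(best, cv_loss = stats::setNames(loss, tau_grid))
}

split_response <- function(data, response) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  if (!response %in% names(data)) {
    abort(sprintf("response column `%s` not found in `data`", response))
  }
  x <- as.matrix(data[setdiff(names(data), response)])
  storage.mode(x) <- "double"
  list(x = as_predictor_matrix(x), y = as_response(data[[response]], nrow(data)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- methods ----------------------------------------------------------------

#' @export
print.me_boost <- function(x, ...) {
  cat(sprintf(
    "<me_boost> %s model, n = %d, p = %d\n", x$model, x$n, x$p
  ))
  cat(sprintf(
    "  corrections: response %s, predictors %s\n",
    if (x$config$correct_y) "on" else "off",
    if (x$config$correct_x) "on" else "off"
  ))
  cat(sprintf(
    "  %d iterations%s, %d predictors selected\n",
    x$iterations_run,
    if (x$stopped_early) " (stopped early)" else "",
    x$n_selected
  ))
  if (x$n_selected > 0 && x$n_selected <= 10) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.me_boost <- function(object, ...) object$beta

#' Tidy a boosted measurement-error fit
#'
#' @param x An `"me_boost"` object.
#' @param all Return all terms (`TRUE`, default) or only selected ones.
#' @param ... Unused.
#' @return A tibble with columns `term`, `index`, `estimate`, `selected`.
#' @export
tidy.me_boost <- function(x, all = TRUE, ...) {
  out <- tibble(
    term = names(x$beta),
    index = seq_along(x$beta),
    estimate = unname(x$beta),
    selected = x$beta != 0
  )
  if (!all) out <- dplyr::filter(out, .data$selected)
  out
}

#' One-row summary of a boosted measurement-error fit
#'
#' @param x An `"me_boost"` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.me_boost <- function(x, ...) {
  tibble(
    model = x$model,
    n = x$n,
    p = x$p,
    n_selected = x$n_selected,
    iterations_run = x$iterations_run,
    stopped_early = x$stopped_early,
    final_score_norm = utils::tail(x$score_norm_trace, 1)
  )
}

#' Plot a boosted measurement-error fit
#'
#' Lollipop plot of the nonzero coefficient estimates (left) is the default;
#' `type = "trace"` shows the L2 norm of the estimating function across
#' iterations instead.
#'
#' @param object An `"me_boost"` object.
#' @param type `"coefficients"` or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.me_boost <- function(object, type = c("coefficients", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    d <- tibble(
      iteration = seq_along(object$score_norm_trace),
      score_norm = object$score_norm_trace
    )
    return(
      ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$score_norm)) +
        ggplot2::geom_line() +
        ggplot2::labs(
          x = "iteration", y = "||g||2",
          title = "Estimating-function norm along the boosting path"
        )
    )
  }
  d <- dplyr::filter(tidy(object), .data$selected)
  if (nrow(d) == 0) {
    d <- tibble(term = character(), index = integer(), estimate = numeric())
  }
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$index), .data$estimate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = factor(.data$index), yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "predictor index", y = "estimate",
      title = "Selected predictors"
    )
}
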