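#' Estimation error of a coefficient estimate
#'
#' L1 and L2 norms of `beta_hat - beta_true`.
#'
#' @param beta_hat,beta_true Numeric vectors of equal length.
#' @return A one-row tibble with columns `l1` and `l2` (`l2 <= l1` always).
#' @examples
#' estimation_errors(c(0.5, 0, 1, 0.2, 0), c(1, 1, 1, 0, 0))  # 1.7, 1.136
#' @export
estimation_errors <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true)) {
    abort("`beta_hat` and `beta_true` must have the same length")
  }
  d <- beta_hat - beta_true
  tibble(l1 = sum(abs(d)), l2 = sqrt(sum(d^2)))
}

#' Variable-selection rates
#'
#' Inclusion and exclusion rates of a selected index set against the truly
#' informative set:
#' `spe` = correctly included / number truly informative, and
#' `sen` = correctly excluded / number truly unimportant.
#' (These names follow the convention of the sensitivity/specificity pair as
#' used for this selection problem in the measurement-error boosting
#' literature, which is the reverse of the usual classification convention;
#' they are kept as-is so reported tables line up.)
#'
#' @param selected Integer indices of selected predictors (may be empty).
#' @param truth Integer indices of the truly informative predictors
#'   (non-empty).
#' @param p Total number of predictors; must exceed `length(truth)` so the
#'   exclusion rate is defined.
#' @return A one-row tibble with columns `spe` and `sen`, both in `[0, 1]`.
#' @examples
#' selection_rates(c(1, 3, 4), 1:3, p = 5)  # 2/3, 1/2
#' @export
selection_rates <- function(selected, truth, p) {
  truth <- as.integer(truth)
  selected <- as.integer(selected)
  if (length(truth) == 0) abort("`truth` must be non-empty")
  if (!all(truth %in% seq_len(p)) || !all(selected %in% seq_len(p))) {
    abort("`selected` and `truth` must be subsets of 1..p")
  }
  if (p == length(truth)) {
    abort("all predictors are informative; the exclusion rate is undefined")
  }
  null_set <- setdiff(seq_len(p), truth)
  tibble(
    spe = length(intersect(selected, truth)) / length(truth),
    sen = length(setdiff(null_set, selected)) / length(null_set)
  )
}

setting_flags <- function(setting) {
  if (!setting %in% 1:4) abort("`settings` must be in 1..4")
  list(
    correct_x = setting %in% c(3, 4),
    correct_y = setting %in% c(2, 4)
  )
}

#' Replicated simulation study of the boosted measurement-error fits
#'
#' Runs the full factorial of `models` x `p_values` x `sigma_values` x
#' correction `settings`.  For every cell, `reps` datasets are drawn from
#' [simulate_me_binary()] (each replicate's data are shared across the
#' settings, so setting contrasts are paired) and fitted with [me_boost()];
#' per-replicate L1/L2 estimation errors and selection rates
#' ([estimation_errors()], [selection_rates()]) are averaged, with Monte
#' Carlo standard errors.
#'
#' Settings map to correction flags as: 1 = no correction, 2 = response
#' corrected, 3 = predictors corrected, 4 = both corrected.
#'
#' @param models Character vector from `c("logistic", "probit")`; each model
#'   both generates its data and is fitted.
#' @param p_values,sigma_values Numeric vectors of dimensions and
#'   measurement-error variances to cross.
#' @param settings Integer subset of 1:4.
#' @param n Sample size per replicate.
#' @param reps Number of replicates per cell.
#' @param n_signal Number of leading unit coefficients in the true
#'   coefficient vector `(1, ..., 1, 0, ..., 0)`.
#' @param misclass_intercept Intercept of the (zero-slope) logistic
#'   misclassification model used by the generator, for both `pi10` and
#'   `pi01`.
#' @param iterations Boosting iterations; `NULL` uses 1000 for logistic and
#'   2000 for probit fits.
#' @param threshold,learn_rate,stop_tol Passed to [me_boost()].
#' @param seed Master integer seed; replicate r uses `seed + r - 1`.
#' @return A tibble of class `"me_study"`, one row per cell, with mean
#'   metrics (`l1`, `l2`, `spe`, `sen`), their standard errors (`*_se`),
#'   `n_reps` and `n_failed`.  Per-replicate detail (including each
#'   replicate's selected set) is attached as attribute `"replicates"`.
#' @export
run_simulation_study <- function(models = "logistic",
                                 p_values = 1000,
                                 sigma_values = 0.15,
                                 settings = 1:4,
                                 n = 100,
                                 reps = 100,
                                 n_signal = 3,
                                 misclass_intercept = 1,
                                 iterations = NULL,
                                 threshold = 0.9,
                                 learn_rate = 1e-5,
                                 stop_tol = NULL,
                                 seed = 1) {
  models <- match.arg(models, c("logistic", "probit"), several.ok = TRUE)
  if (reps < 1) abort("`reps` must be >= 1")
  lapply(settings, setting_flags)

  grid <- tidyr::expand_grid(model = models, p = p_values, sigma_eps = sigma_values)
  detail <- vector("list", nrow(grid))

  for (i in seq_len(nrow(grid))) {
    model <- grid$model[i]
    p <- grid$p[i]
    s2 <- grid$sigma_eps[i]
    iters <- iterations %||% if (model == "logistic") 1000 else 2000
    beta_true <- c(rep(1, n_signal), rep(0, p - n_signal))
    truth <- seq_len(n_signal)

    rows <- purrr::map(seq_len(reps), function(r) {
      sim <- simulate_me_binary(
        n = n, p = p, beta_true = beta_true, model = model,
        sigma_eps = s2,
        gamma10 = c(misclass_intercept, rep(0, p)),
        seed = seed + r - 1
      )
      purrr::map(settings, function(s) {
        fl <- setting_flags(s)
        res <- tryCatch(
          {
            fit <- me_boost(
              sim$data,
              model = model, iterations = iters,
              threshold = threshold, learn_rate = learn_rate,
              stop_tol = stop_tol,
              correct_x = fl$correct_x, correct_y = fl$correct_y,
              probs = sim$probs, sigma_eps = s2
            )
            dplyr::bind_cols(
              estimation_errors(fit$beta, beta_true),
              selection_rates(fit$selected, truth, p),
              tibble(
                n_selected = fit$n_selected,
                selected = list(fit$selected),
                failed = FALSE
              )
            )
          },
          error = function(e) {
            warn(sprintf(
              "replicate %d, setting %d failed: %s", r, s, conditionMessage(e)
            ))
            tibble(
              l1 = NA_real_, l2 = NA_real_, spe = NA_real_, sen = NA_real_,
              n_selected = NA_integer_, selected = list(integer(0)),
              failed = TRUE
            )
          }
        )
        dplyr::bind_cols(
          tibble(model = model, p = p, sigma_eps = s2, setting = s, rep = r),
          res
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    detail[[i]] <- rows
  }

  detail <- purrr::list_rbind(detail)
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0

  report <- detail |>
    dplyr::group_by(.data$model, .data$p, .data$sigma_eps, .data$setting) |>
    dplyr::summarise(
      n_failed = sum(.data$failed),
      dplyr::across(
        c("l1", "l2", "spe", "sen"),
        list(mean = ~ mean(.x, na.rm = TRUE), se = ~ se(.x[!is.na(.x)]))
      ),
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rename(l1 = "l1_mean", l2 = "l2_mean", spe = "spe_mean", sen = "sen_mean") |>
    dplyr::relocate("n_failed", .after = "n_reps")

  flagged <- dplyr::filter(report, .data$n_failed > 0.1 * .data$n_reps)
  if (nrow(flagged) > 0) {
    warn(sprintf("%d cell(s) had more than 10%% failed replicates", nrow(flagged)))
  }

  structure(
    report,
    replicates = detail,
    seed = seed,
    class = c("me_study", class(report))
  )
}

#' Per-replicate detail of a simulation study
#'
#' @param study An `"me_study"` report from [run_simulation_study()].
#' @return The per-replicate tibble (one row per replicate x setting), with
#'   each replicate's selected index set as a list column.
#' @export
study_replicates <- function(study) {
  attr(study, "replicates")
}

#' Plot a simulation-study report
#'
#' @param object An `"me_study"` report.
#' @param ... Unused.
#' @return A ggplot object: mean metrics against the error variance, one
#'   panel per metric, coloured by correction setting.
#' @export
autoplot.me_study <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object),
    c("l1", "l2", "spe", "sen"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(.data$sigma_eps, .data$value,
      colour = factor(.data$setting), group = factor(.data$setting)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      ggplot2::vars(.data$metric),
      ggplot2::vars(.data$model, .data$p),
      scales = "free_y"
    ) +
    ggplot2::labs(
      x = "measurement-error variance", y = NULL, colour = "setting"
    )
}

#' Sensitivity analysis over the measurement-error variance
#'
#' Refits one observed dataset over a grid of assumed error variances and
#' correction settings, reporting each fit's selected predictors and, per
#' setting, the predictors commonly selected across the whole grid (the set
#' intersection).  This is the workflow for data where `Sigma_eps` is not
#' estimable and must be posited.
#'
#' @inheritParams me_boost
#' @param sigma_grid Numeric vector of error variances to assume.
#' @param probs Misclassification probabilities: a single table used for all
#'   grid points, or a function of the error variance returning one.
#' @param settings Integer subset of 1:4 (see [run_simulation_study()]).
#' @return A tibble of class `"me_sensitivity"` with one row per
#'   (setting, sigma) pair: `n_selected`, list columns `selected` and
#'   `estimates`.  The per-setting common selections are attached as
#'   attribute `"common"` and returned by [common_selection()].
#' @export
run_sensitivity <- function(data,
                            response = "y",
                            sigma_grid,
                            probs = NULL,
                            settings = 1:4,
                            model = c("logistic", "probit"),
                            iterations = NULL,
                            threshold = 0.9,
                            learn_rate = 1e-5,
                            stop_tol = NULL) {
  model <- match.arg(model)
  if (length(sigma_grid) < 1) abort("`sigma_grid` must be non-empty")
  iters <- iterations %||% if (model == "logistic") 1000 else 2000

  rows <- purrr::map(settings, function(s) {
    fl <- setting_flags(s)
    purrr::map(sigma_grid, function(s2) {
      pr <- if (is.function(probs)) probs(s2) else probs
      fit <- me_boost(
        data,
        response = response, model = model, iterations = iters,
        threshold = threshold, learn_rate = learn_rate, stop_tol = stop_tol,
        correct_x = fl$correct_x, correct_y = fl$correct_y,
        probs = pr, sigma_eps = s2
      )
      tibble(
        setting = s, sigma_eps = s2,
        n_selected = fit$n_selected,
        selected = list(fit$selected),
        estimates = list(fit$beta[fit$selected])
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  common <- rows |>
    dplyr::group_by(.data$setting) |>
    dplyr::summarise(
      common = list(Reduce(intersect, .data$selected)),
      .groups = "drop"
    )

  structure(rows, common = common, class = c("me_sensitivity", class(rows)))
}

#' Predictors commonly selected across a sensitivity grid
#'
#' @param x An `"me_sensitivity"` result.
#' @return A tibble with one row per setting and the list column `common`
#'   holding the indices selected at every grid point.
#' @export
common_selection <- function(x) {
  attr(x, "common")
}
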