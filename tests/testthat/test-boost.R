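test_that("active set keeps ties and empties only on a zero signal", {
  expect_equal(active_set(c(0.5, -0.4, 0.1), 0.9), 1L)
  expect_equal(active_set(c(0.5, -0.5, 0.1), 1), c(1L, 2L))
  expect_equal(active_set(c(0.5, -0.4, 0.1), 0), 1:3)
  expect_equal(active_set(c(0, 0, 0), 0.5), integer(0))
  expect_error(active_set(c(1, NA), 0.5), "finite")
  expect_error(active_set(1, 1.5), "\\[0, 1\\]")
})

test_that("one iteration at tau = 0 is a single full-gradient step", {
  inst <- small_instance(n = 10, p = 3, seed = 21)
  d <- data.frame(y = inst$y, inst$x)
  eta <- 0.05
  fit <- me_boost(d,
    model = "logistic", iterations = 1, threshold = 0,
    learn_rate = eta, correct_x = FALSE, correct_y = FALSE
  )
  oracle <- -eta * score_logistic(rep(0, 3), inst$x, inst$y)
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-12)
})

test_that("tau = 0 boosting matches an independently coded gradient loop", {
  inst <- small_instance(n = 20, p = 3, seed = 31)
  d <- data.frame(y = inst$y, inst$x)
  for (model in c("logistic", "probit")) {
    fit <- me_boost(d,
      model = model, iterations = 200, threshold = 0,
      learn_rate = 0.05, correct_x = FALSE, correct_y = FALSE
    )
    ref <- reference_boost(inst$x, inst$y, 200, 0, 0.05, model = model)
    expect_equal(unname(coef(fit)), ref, tolerance = 1e-10)
  }
})

test_that("the corrected fits match the independent loop too", {
  withr::with_seed(41, {
    n <- 40
    x <- matrix(rnorm(n * 4), n, 4)
    y <- rbinom(n, 1, expit(drop(x %*% c(1, -1, 0, 0))))
    pr <- data.frame(pi10 = rep(0.15, n), pi01 = rep(0.1, n))
    ys <- misclassify(y, pr)
    d <- data.frame(y = ys, x)
    fit_lr <- me_boost(d,
      model = "logistic", iterations = 150, threshold = 0.6,
      learn_rate = 0.05, probs = pr, sigma_eps = 0.2
    )
    ref_lr <- reference_boost(x, ys, 150, 0.6, 0.05,
      model = "logistic",
      correct_x = TRUE, correct_y = TRUE, probs = pr, sigma2 = 0.2
    )
    expect_equal(unname(coef(fit_lr)), ref_lr, tolerance = 1e-10)

    fit_pm <- me_boost(d,
      model = "probit", iterations = 150, threshold = 0.6,
      learn_rate = 0.05, probs = pr, sigma_eps = 0.2
    )
    ref_pm <- reference_boost(x, ys, 150, 0.6, 0.05,
      model = "probit",
      correct_x = TRUE, correct_y = TRUE, probs = pr, sigma2 = 0.2
    )
    expect_equal(unname(coef(fit_pm)), ref_pm, tolerance = 1e-10)
  })
})

test_that("threshold sets are nested: the tau = 1 selection is contained in any lower one", {
  withr::with_seed(51, {
    sim <- simulate_me_binary(n = 60, p = 30, sigma_eps = 0.1, seed = 13)
    sels <- lapply(c(1, 0.9, 0.5, 0), function(tau) {
      me_boost(sim$data,
        iterations = 40, threshold = tau, learn_rate = 0.02,
        probs = sim$probs, sigma_eps = 0.1
      )$selected
    })
    for (k in 2:4) expect_true(all(sels[[1]] %in% sels[[k]]))
  })
})

test_that("error-free boosting converges to the maximum-likelihood estimate", {
  withr::with_seed(61, {
    n <- 2000
    p <- 5
    b0 <- c(1, 1, 1, 0, 0)
    x <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, expit(drop(x %*% b0)))
    d <- data.frame(y = y, x)
    fit <- me_boost(d,
      model = "logistic", iterations = 3000, threshold = 0,
      learn_rate = 0.5, correct_x = FALSE, correct_y = FALSE
    )
    mle <- glm(y ~ . - 1, data = d, family = binomial())
    expect_lt(max(abs(coef(fit) - coef(mle))), 0.15)
    expect_lt(max(abs(coef(fit) - b0)), 0.3)
  })
})

test_that("degenerate configurations stop cleanly", {
  # no movement possible: all-equal responses at beta = 0 still give a signal,
  # but a zero design matrix gives none and the loop exits at once
  d <- data.frame(y = c(0, 1), x1 = c(0, 0), x2 = c(0, 0))
  fit <- me_boost(d,
    iterations = 50, threshold = 0.9, learn_rate = 0.1,
    correct_x = FALSE, correct_y = FALSE
  )
  expect_true(fit$stopped_early)
  expect_equal(fit$n_selected, 0)
  expect_equal(unname(coef(fit)), c(0, 0))
})

test_that("the xi stopping rule halts once the score stabilises", {
  inst <- small_instance(n = 30, p = 3, seed = 71)
  d <- data.frame(y = inst$y, inst$x)
  fit <- me_boost(d,
    iterations = 5000, threshold = 0, learn_rate = 0.3,
    stop_tol = 1e-6, correct_x = FALSE, correct_y = FALSE
  )
  expect_true(fit$stopped_early)
  expect_lt(fit$iterations_run, 5000)
})

test_that("correction flags demand their inputs", {
  d <- data.frame(y = c(0, 1, 1), x1 = c(0.1, -0.2, 0.5))
  expect_error(me_boost(d, correct_x = FALSE, correct_y = TRUE), "probs")
  expect_error(me_boost(d, correct_x = TRUE, correct_y = FALSE), "sigma_eps")
  expect_error(
    me_boost(data.frame(y = c(0, 2, 1), x1 = 1:3),
      correct_x = FALSE, correct_y = FALSE
    ),
    "binary"
  )
})

test_that("cross-validated threshold selection is deterministic with sane tie-breaks", {
  sim <- simulate_me_binary(n = 60, p = 8, sigma_eps = 0.1, seed = 5)
  # a single candidate is returned untouched
  expect_equal(
    as.numeric(choose_threshold(sim$data,
      tau_grid = 0.7, k_folds = 3, seed = 2,
      iterations = 20, learn_rate = 0.01,
      probs = sim$probs, sigma_eps = 0.1
    )),
    0.7
  )
  # learn_rate so small that every tau gives an all-zero fit: identical losses,
  # the largest (sparsest) threshold wins
  tie <- choose_threshold(sim$data,
    tau_grid = c(0.5, 0.8, 0.9), k_folds = 3, seed = 2,
    iterations = 1, learn_rate = 1e-12,
    correct_x = FALSE, correct_y = FALSE
  )
  expect_equal(as.numeric(tie), 0.9)
  # determinism
  a <- choose_threshold(sim$data,
    tau_grid = c(0.6, 0.9), k_folds = 3, seed = 7,
    iterations = 20, learn_rate = 0.01,
    probs = sim$probs, sigma_eps = 0.1
  )
  b <- choose_threshold(sim$data,
    tau_grid = c(0.6, 0.9), k_folds = 3, seed = 7,
    iterations = 20, learn_rate = 0.01,
    probs = sim$probs, sigma_eps = 0.1
  )
  expect_identical(a, b)
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_me_binary(n = 40, p = 6, sigma_eps = 0.1, seed = 3)
  fit <- me_boost(sim$data,
    iterations = 30, threshold = 0.5, learn_rate = 0.02,
    probs = sim$probs, sigma_eps = 0.1
  )
  td <- tidy(fit)
  expect_named(td, c("term", "index", "estimate", "selected"))
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$selected), fit$n_selected)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_selected, fit$n_selected)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "trace"), "ggplot")
})
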