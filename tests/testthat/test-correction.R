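test_that("response correction matches hand values and the identity case", {
  expect_equal(correct_response(c(1, 0), data.frame(pi10 = 0, pi01 = 0)), c(1, 0))
  pr <- data.frame(pi10 = 0.1, pi01 = 0.2)
  expect_equal(correct_response(1, pr), 0.9 / 0.7, tolerance = 1e-7)
  expect_equal(correct_response(0, pr), -0.1 / 0.7, tolerance = 1e-7)
})

test_that("non-invertible misclassification matrices are rejected by row", {
  pr <- data.frame(pi10 = c(0.1, 0.5), pi01 = c(0.2, 0.5))
  expect_error(correct_response(c(1, 0), pr), "row 2")
  expect_error(correct_response(c(1), data.frame(pi10 = 1.2, pi01 = 0)), "\\[0, 1\\]")
})

test_that("a negative denominator (severe misclassification) is handled", {
  pr <- data.frame(pi10 = 0.731, pi01 = 0.731)
  ycc <- correct_response(c(1, 0), pr)
  expect_equal(ycc, c((1 - 0.731) / (1 - 1.462), (0 - 0.731) / (1 - 1.462)),
    tolerance = 1e-12
  )
  expect_true(ycc[1] < 0 && ycc[2] > 1) # corrected values leave [0, 1]
})

test_that("corrected response has conditional mean equal to the true response", {
  # E(Y** | Y, X) = Y: average the correction over the misclassification draw
  n_draws <- 1e5
  for (cfg in list(
    list(y = 1, pi10 = 0.1, pi01 = 0.25),
    list(y = 0, pi10 = 0.2, pi01 = 0.15),
    list(y = 1, pi10 = 0.731, pi01 = 0.731) # negative denominator
  )) {
    pr <- data.frame(pi10 = rep(cfg$pi10, n_draws), pi01 = rep(cfg$pi01, n_draws))
    y_star <- misclassify(rep(cfg$y, n_draws), pr, seed = 42)
    expect_equal(mean(correct_response(y_star, pr)), cfg$y, tolerance = 0.01)
  }
})

test_that("sufficient statistic matches the printed formula", {
  expect_equal(
    sufficient_statistic(c(1, 2), 1.25, 0.2, c(1, -1)),
    matrix(c(1.25, 1.75), 1),
    ignore_attr = TRUE
  )
  # zero error or zero multiplier leave the row unchanged
  expect_equal(sufficient_statistic(c(1, 2), 1.25, 0, c(1, -1)),
    matrix(c(1, 2), 1),
    ignore_attr = TRUE
  )
  expect_equal(sufficient_statistic(c(1, 2), 0, 0.2, c(1, -1)),
    matrix(c(1, 2), 1),
    ignore_attr = TRUE
  )
})

test_that("regression calibration reproduces the univariate hand example", {
  cal <- regression_calibration(matrix(c(0, 2, 4), 3), sigma_eps = 3)
  expect_equal(drop(predict(cal, matrix(c(0, 2, 4), 3))), c(1.5, 2, 2.5),
    tolerance = 1e-12
  )
})

test_that("calibration is the identity at zero error and fixes the mean", {
  withr::with_seed(11, {
    x <- matrix(rnorm(60), 20, 3)
    cal0 <- regression_calibration(x, sigma_eps = 0)
    expect_equal(predict(cal0, x), x, tolerance = 1e-10)
    cal <- regression_calibration(x, sigma_eps = 0.3)
    mu <- matrix(colMeans(x), 1)
    expect_equal(predict(cal, mu), mu, tolerance = 1e-12)
  })
})

test_that("p >= n falls back to coordinatewise calibration for diagonal error", {
  withr::with_seed(12, {
    x <- matrix(rnorm(5 * 20), 5, 20)
    cal <- regression_calibration(x, sigma_eps = 0.1)
    expect_identical(cal$method, "diagonal")
    # coordinatewise map agrees with the univariate formula per column
    s2 <- apply(x, 2, var)
    mu <- colMeans(x)
    manual <- sweep(sweep(sweep(x, 2, mu), 2, (s2 - 0.1) / s2, `*`), 2, mu, `+`)
    expect_equal(predict(cal, x), manual, tolerance = 1e-12)
    # a full matrix cannot be calibrated when the covariance is singular
    expect_error(
      regression_calibration(x, sigma_eps = diag(0.1, 20)),
      "singular"
    )
  })
})

test_that("corrected scores reduce bitwise to naive scores at zero error", {
  inst <- small_instance(n = 15, p = 4, seed = 3)
  b <- withr::with_seed(8, rnorm(4, sd = 0.4))
  expect_identical(
    corrected_score_logistic(b, inst$x, inst$y, sigma_eps = 0),
    score_logistic(b, inst$x, inst$y)
  )
  expect_identical(
    corrected_score_probit(b, inst$x, inst$y),
    score_probit(b, inst$x, inst$y)
  )
})

test_that("corrected logistic score equals its compositional definition", {
  inst <- small_instance(n = 10, p = 3, seed = 6)
  pr <- data.frame(pi10 = rep(0.1, 10), pi01 = rep(0.2, 10))
  ycc <- correct_response(inst$y, pr)
  b <- c(0.5, -0.25, 0.1)
  sig <- c(0.2, 0.1, 0.3) # diagonal
  direct <- corrected_score_logistic(b, inst$x, ycc, sig)
  composed <- score_logistic(b, sufficient_statistic(inst$x, ycc, sig, b), ycc)
  expect_equal(direct, composed, tolerance = 1e-12)
})

test_that("corrected logistic score matches the single-observation hand value", {
  g <- corrected_score_logistic(c(0, 0), matrix(c(1, 0), 1), 1.2857143,
    sigma_eps = 0.2
  )
  expect_equal(g, c(-(1.2857143 - 0.5), 0), tolerance = 1e-7)
})

test_that("corrected probit score matches the single-observation hand value", {
  g <- corrected_score_probit(0, matrix(1, 1), 1.2857143)
  expect_equal(g, -dnorm(0) * (1.2857143 / 0.5 + 0.2857143 / 0.5),
    tolerance = 1e-7
  )
  expect_equal(g, -1.2538186, tolerance = 1e-6)
})

test_that("corrected logistic score is linear in the corrected response", {
  # doubling y** changes the score exactly as the formula dictates
  x <- matrix(c(0.5, -1, 2, 0.3), 2, 2)
  sig <- 0.2
  b <- c(0.4, -0.6)
  y1 <- c(1.2857143, -0.1428571)
  g1 <- corrected_score_logistic(b, x, y1, sig)
  manual <- function(y) {
    sb <- sig * b
    xs <- x + outer(y, sb)
    mu <- expit(drop(xs %*% b))
    -drop(crossprod(xs, y - mu)) / 2
  }
  expect_equal(g1, manual(y1), tolerance = 1e-12)
  expect_equal(
    corrected_score_logistic(b, x, 2 * y1, sig), manual(2 * y1),
    tolerance = 1e-12
  )
})

test_that("sigma_eps is accepted as scalar, diagonal vector, or full matrix", {
  x <- matrix(c(1, 2, -1, 0.5), 2, 2)
  b <- c(0.3, -0.2)
  y <- c(1.1, -0.1)
  g_scalar <- corrected_score_logistic(b, x, y, 0.2)
  g_diag <- corrected_score_logistic(b, x, y, c(0.2, 0.2))
  g_full <- corrected_score_logistic(b, x, y, diag(0.2, 2))
  expect_equal(g_scalar, g_diag, tolerance = 1e-14)
  expect_equal(g_scalar, g_full, tolerance = 1e-14)
  expect_error(corrected_score_logistic(b, x, y, matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(
    corrected_score_logistic(b, x, y, matrix(c(1, 2, 2, 1), 2)),
    "positive semidefinite"
  )
})
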