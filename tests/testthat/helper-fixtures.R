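# small deterministic fixtures shared across test files

expit <- function(z) 1 / (1 + exp(-z))

# random small instance with binary response
small_instance <- function(n = 12, p = 3, seed = 1, model = "logistic") {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p, sd = 0.5)
    eta <- drop(x %*% beta)
    pr <- if (model == "logistic") expit(eta) else pnorm(eta)
    list(x = x, y = rbinom(n, 1, pr), beta = beta)
  })
}

# central finite difference of a scalar function
fd_grad <- function(f, beta, h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- replace(numeric(length(beta)), j, h)
    (f(beta + e) - f(beta - e)) / (2 * h)
  }, numeric(1))
}

# plain-R reference of the boosting loop (the oracle for the compiled engine);
# written independently of the package internals on purpose
reference_boost <- function(x, y, iterations, tau, eta,
                            model = "logistic",
                            correct_x = FALSE, correct_y = FALSE,
                            probs = NULL, sigma2 = 0) {
  n <- nrow(x)
  p <- ncol(x)
  yv <- if (correct_y) (y - probs$pi10) / (1 - probs$pi10 - probs$pi01) else y
  xv <- x
  if (correct_x && model == "probit") {
    mu <- colMeans(x)
    if (p < n) {
      S <- cov(x)
      amat <- t(S - diag(sigma2, p)) %*% solve(S)
      xv <- sweep(sweep(x, 2, mu) %*% t(amat), 2, mu, `+`)
    } else {
      s2 <- apply(x, 2, var)
      xv <- sweep(sweep(sweep(x, 2, mu), 2, (s2 - sigma2) / s2, `*`), 2, mu, `+`)
    }
  }
  beta <- rep(0, p)
  for (t in seq_len(iterations)) {
    if (model == "logistic") {
      sb <- if (correct_x) sigma2 * beta else rep(0, p)
      lin <- drop(xv %*% beta) + yv * sum(sb * beta)
      r <- yv - expit(lin)
      g <- -(drop(crossprod(xv, r)) + sb * sum(yv * r)) / n
    } else {
      lin <- drop(xv %*% beta)
      P <- pmin(pmax(pnorm(lin), 1e-10), 1 - 1e-10)
      w <- dnorm(lin) * (yv / P - (1 - yv) / (1 - P))
      g <- -drop(crossprod(xv, w)) / n
    }
    m <- max(abs(g))
    if (m == 0) break
    a <- abs(g) >= tau * m
    beta[a] <- beta[a] - eta * g[a]
  }
  beta
}
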