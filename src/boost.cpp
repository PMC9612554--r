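// Thresholded boosting over a (corrected) binary-regression estimating
// function.  The estimating function g is the averaged score with a leading
// minus sign; the update moves against g (likelihood ascent):
//   beta_j <- beta_j - eta * g_j   for j in the active set
//   active set = { j : |g_j| >= tau * max_j |g_j| }.
// For the logistic model with predictor-error correction the sufficient
// statistic x* + y** * Sigma_eps beta is rebuilt every iteration (it depends
// on the current iterate); probit calibration happens once, in R, before
// this loop runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PROB_CLIP = 1e-10;

// [[Rcpp::export]]
Rcpp::List boost_engine_cpp(const arma::mat& X,
                            const arma::vec& y,
                            const int model,        // 0 logistic, 1 probit
                            const bool use_ss,      // sufficient-statistic correction
                            const int sigma_type,   // 0 none, 1 scalar, 2 diag, 3 full
                            const double sigma_scalar,
                            const arma::vec& sigma_diag,
                            const arma::mat& sigma_full,
                            const int iterations,
                            const double tau,
                            const double eta,
                            const double xi)        // < 0: early stopping off
{
  const uword n = X.n_rows, p = X.n_cols;
  vec beta(p, fill::zeros);
  vec g(p), prev_g(p);
  vec score_norm(iterations, fill::zeros);
  int iterations_run = 0;
  bool stopped_early = false;
  bool diverged = false;

  for (int t = 1; t <= iterations; ++t) {
    vec lin = X * beta;
    vec w(n);
    vec sb(p, fill::zeros);

    if (use_ss) {
      switch (sigma_type) {
        case 1: sb = sigma_scalar * beta; break;
        case 2: sb = sigma_diag % beta; break;
        case 3: sb = sigma_full * beta; break;
        default: break;
      }
      lin += y * dot(sb, beta);
    }

    if (model == 0) {
      w = y - 1.0 / (1.0 + exp(-lin));
    } else {
      vec P = clamp(normcdf(lin), PROB_CLIP, 1.0 - PROB_CLIP);
      w = normpdf(lin) % (y / P - (1.0 - y) / (1.0 - P));
    }

    g = -(X.t() * w) / double(n);
    if (use_ss && sigma_type != 0) {
      g -= sb * (dot(y, w) / double(n));
    }

    if (!g.is_finite()) { diverged = true; break; }

    score_norm(t - 1) = norm(g, 2);

    if (t > 1 && xi >= 0.0 && norm(g - prev_g, 2) < xi) {
      stopped_early = true;
      break;
    }

    double m = max(abs(g));
    if (m == 0.0) { stopped_early = true; break; }

    uvec active = find(abs(g) >= tau * m);
    beta(active) -= eta * g(active);
    iterations_run = t;
    prev_g = g;
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("iterations_run") = iterations_run,
    Rcpp::Named("stopped_early") = stopped_early,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("score_norm") = score_norm.head(std::max(iterations_run, 1))
  );
}
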