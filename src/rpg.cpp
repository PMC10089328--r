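// Exact Polya-Gamma PG(1, z) sampling by the alternating-series rejection
// method (Devroye-type), used for the logistic data augmentation.  All
// randomness goes through R's RNG so seeded runs are reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;  // series/inverse-Gaussian split point

// Probability of proposing from the truncated exponential branch.
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC).
static double rtigauss(double z) {
  double t = TRUNC;
  double X = t + 1.0;
  double mu = 1.0 / z;
  if (mu > t) {
    double alpha = 0.0;
    while (R::runif(0.0, 1.0) > alpha) {
      double E1 = R::exp_rand();
      double E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * z * z * X);
    }
  } else {
    while (X > t) {
      double Y = R::norm_rand();
      Y = Y * Y;
      double mu_Y = mu * Y;
      X = mu + 0.5 * mu * mu_Y -
          0.5 * mu * std::sqrt(4.0 * mu_Y + mu_Y * mu_Y);
      if (R::runif(0.0, 1.0) > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// n-th term of the alternating series for the J*(1, .) density.
static double aterm(int n, double x, double t) {
  double f = std::log(M_PI) + std::log(n + 0.5);
  if (x <= t)
    f += 1.5 * (std::log(2.0 / M_PI) - std::log(x)) -
         2.0 * (n + 0.5) * (n + 0.5) / x;
  else
    f += -0.5 * x * M_PI * M_PI * (n + 0.5) * (n + 0.5);
  return std::exp(f);
}

// One PG(1, z) draw.
static double sample_pg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  for (;;) {
    double X;
    if (R::runif(0.0, 1.0) < mass_texpon(z))
      X = TRUNC + R::exp_rand() / fz;
    else
      X = rtigauss(z);
    double S = aterm(0, X, TRUNC);
    double Y = R::runif(0.0, 1.0) * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= aterm(n, X, TRUNC);
        if (Y <= S) return 0.25 * X;
      } else {
        S += aterm(n, X, TRUNC);
        if (Y > S) break;
      }
    }
  }
}

//' Polya-Gamma PG(1, z) random draws
//'
//' One draw per element of `z`, using R's RNG stream (so results are
//' reproducible under `set.seed()`).  The PG(1, z) law is the mixing
//' distribution that renders logistic-regression full conditionals
//' Gaussian under data augmentation.
//'
//' @param z Numeric vector of tilting parameters (the linear predictor).
//' @return Numeric vector of PG(1, z) draws, same length as `z`.
//' @examples
//' set.seed(1); mean(rpg_devroye(rep(0, 1e4)))  # about 1/4
//' @export
// [[Rcpp::export]]
NumericVector rpg_devroye(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_pg1(z[i]);
  return out;
}
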