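// Fused ZINB negative log-likelihood + gradients and decoder head
// activations. These run once per training step over an n x m matrix, so
// they are written as single-pass loops to avoid R-level temporaries.

#include <Rcpp.h>
using namespace Rcpp;

static const double PI_EPS = 1e-8;
static const double PAR_LO = 1e-4;
static const double PAR_HI = 1e4;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Mean-per-entry NLL of the ZINB model and its gradients with respect to
// pi, mu and theta (already divided by the entry count).
// [[Rcpp::export(name = ".zinbLossGradCpp")]]
List zinbLossGradCpp(NumericMatrix x, NumericMatrix pi, NumericMatrix mu,
                     NumericMatrix theta) {
  R_xlen_t n = x.size();
  NumericMatrix dpi(x.nrow(), x.ncol());
  NumericMatrix dmu(x.nrow(), x.ncol());
  NumericMatrix dth(x.nrow(), x.ncol());
  double loss = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    double p = clampd(pi[i], PI_EPS, 1.0 - PI_EPS);
    double m = clampd(mu[i], PAR_LO, PAR_HI);
    double t = clampd(theta[i], PAR_LO, PAR_HI);
    double tm = t + m;
    double lth = std::log(t);
    double ltm = std::log(tm);
    double lr0 = t * (lth - ltm);          // NB log pmf at x = 0
    if (xi == 0.0) {
      double a = std::exp(lr0);            // NB(0)
      double lik0 = p + (1.0 - p) * a;
      loss -= std::log(lik0);
      dpi[i] = -(1.0 - a) / lik0;
      double dLda = -(1.0 - p) / lik0;
      dmu[i] = dLda * (-a * t / tm);
      dth[i] = dLda * a * (lth + 1.0 - ltm - t / tm);
    } else {
      double ratio = (t + xi) / tm;
      double ll = std::log1p(-p) + R::lgammafn(xi + t) - R::lgammafn(t) -
                  R::lgammafn(xi + 1.0) + lr0 + xi * (std::log(m) - ltm);
      loss -= ll;
      dpi[i] = 1.0 / (1.0 - p);
      dmu[i] = -(xi / m - ratio);
      dth[i] = -(R::digamma(xi + t) - R::digamma(t) + lth + 1.0 - ltm -
                 ratio);
    }
  }
  double inv = 1.0 / (double)n;
  for (R_xlen_t i = 0; i < n; ++i) {
    dpi[i] *= inv; dmu[i] *= inv; dth[i] *= inv;
  }
  return List::create(_["loss"] = loss * inv, _["dpi"] = dpi,
                      _["dmu"] = dmu, _["dtheta"] = dth);
}

// Head activations: pi = sigmoid(spi) clamped, mu = sf * exp(smu) clamped,
// theta = exp(sth) clamped, plus the clamp masks used by backprop.
// sf is the per-cell (row) size factor.
// [[Rcpp::export(name = ".zinbHeadsCpp")]]
List zinbHeadsCpp(NumericMatrix spi, NumericMatrix smu, NumericMatrix sth,
                  NumericVector sf) {
  int nr = spi.nrow(), nc = spi.ncol();
  NumericMatrix pi(nr, nc), mu(nr, nc), th(nr, nc);
  NumericMatrix muMask(nr, nc), thMask(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double p = 1.0 / (1.0 + std::exp(-spi(i, j)));
      pi(i, j) = clampd(p, PI_EPS, 1.0 - PI_EPS);
      double mraw = sf[i] * std::exp(std::min(smu(i, j), 50.0));
      mu(i, j) = clampd(mraw, PAR_LO, PAR_HI);
      muMask(i, j) = (mraw > PAR_LO && mraw < PAR_HI) ? 1.0 : 0.0;
      double traw = std::exp(std::min(sth(i, j), 50.0));
      th(i, j) = clampd(traw, PAR_LO, PAR_HI);
      thMask(i, j) = (traw > PAR_LO && traw < PAR_HI) ? 1.0 : 0.0;
    }
  }
  return List::create(_["pi"] = pi, _["mu"] = mu, _["theta"] = th,
                      _["muMask"] = muMask, _["thMask"] = thMask);
}
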