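#include <Rcpp.h>
using namespace Rcpp;

// One-step-ahead log-likelihood of a deck-choice sequence under one model of
// the 18-model factorial space (utility x updating x choice rule).
//
// choice: 1-based deck indices (A=1..D=4); gain/loss: nonnegative dollars.
// utility: 0=EU, 1=PU, 2=PU2; updating: 0=delta, 1=decay-reinforcement,
// 2=mixed; choicerule: 0=trial-dependent theta, 1=trial-independent theta.
// pars: canonical order (utility pars, updating pars, c).
// tdc_predicted: 1 -> theta for the prediction of trial t+1 uses index t+1,
// 0 -> uses index t.
//
// Expectancies start at zero; the choice on trial 1 contributes no term.
// Softmax is computed with max-subtraction and exponent arguments floored at
// -700 so that decay-reinforcement expectancies (unbounded in magnitude)
// cannot overflow.
// [[Rcpp::export]]
double cpp_osa_loglik(IntegerVector choice, NumericVector gain,
                      NumericVector loss, int utility, int updating,
                      int choicerule, NumericVector pars, int tdc_predicted) {
  const int T = choice.size();
  double E[4] = {0.0, 0.0, 0.0, 0.0};

  double W = 0.0, alpha = 0.0, lam = 0.0, A = 0.0, D = 0.0, c = 0.0;
  int i = 0;
  if (utility == 0) {
    W = pars[i++];
  } else {
    alpha = pars[i++];
    lam = pars[i++];  // loss-aversion multiplier (lambda for PU, gamma for PU2)
  }
  if (updating == 2) {
    D = pars[i++];
    A = pars[i++];
  } else {
    A = pars[i++];
  }
  c = pars[i++];

  double theta = 0.0;
  if (choicerule == 1) theta = std::pow(3.0, c) - 1.0;

  double ll = 0.0;
  for (int t = 0; t < T - 1; ++t) {
    const int j = choice[t] - 1;
    const double w = gain[t], l = loss[t];

    double u;
    if (utility == 0) {
      u = (1.0 - W) * w - W * l;
    } else if (utility == 1) {
      const double x = w - l;
      u = (x >= 0.0) ? std::pow(x, alpha) : -lam * std::pow(-x, alpha);
    } else {
      u = std::pow(w, alpha) - lam * std::pow(l, alpha);
    }
    if (!R_finite(u)) stop("non-finite utility at trial %d", t + 1);

    if (updating == 0) {
      E[j] += A * (u - E[j]);
    } else if (updating == 1) {
      for (int m = 0; m < 4; ++m) E[m] *= A;
      E[j] += u;
    } else {
      for (int m = 0; m < 4; ++m) E[m] *= (1.0 - D);
      E[j] += A * (u - E[j]);
    }
    for (int m = 0; m < 4; ++m)
      if (!R_finite(E[m])) stop("non-finite expectancy at trial %d", t + 1);

    if (choicerule == 0) {
      const double idx = tdc_predicted ? (double)(t + 2) : (double)(t + 1);
      theta = std::pow(idx / 10.0, c);
    }
    if (!R_finite(theta)) stop("non-finite sensitivity at trial %d", t + 2);

    double z[4], zmax = R_NegInf;
    for (int m = 0; m < 4; ++m) {
      z[m] = theta * E[m];
      if (z[m] > zmax) zmax = z[m];
    }
    if (!R_finite(zmax))
      stop("non-finite weighted expectancy at trial %d", t + 2);

    double denom = 0.0;
    for (int m = 0; m < 4; ++m) {
      double a = z[m] - zmax;
      if (a < -700.0) a = -700.0;
      denom += std::exp(a);
    }
    const int nj = choice[t + 1] - 1;
    double an = z[nj] - zmax;
    if (an < -700.0) an = -700.0;
    ll += an - std::log(denom);
  }
  return ll;
}
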