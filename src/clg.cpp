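#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Upper bound on the logistic curvature p(1-p) over the interval
// |eta - eta0| <= delta (Zhang-Oles bound used by the CLG algorithm).
static inline double curvBound(double eta, double delta) {
  double a = std::fabs(eta);
  if (a <= delta) return 0.25;
  double d = a - delta;
  // 1 / (2 + exp(d) + exp(-d))
  return 1.0 / (2.0 + std::exp(d) + std::exp(-d));
}

static inline double objective(const NumericVector& y,
                               const std::vector<double>& eta,
                               const std::vector<double>& beta,
                               double k, double penaltyFactor) {
  const int n = y.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    double sp = (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e)));
    ll += y[i] * e - sp;
  }
  double pen = 0.0;
  for (size_t j = 0; j < beta.size(); ++j) pen += beta[j] * beta[j];
  return -ll + 0.5 * penaltyFactor * k * pen;
}

// Cyclic coordinate descent (CLG) for ridge logistic regression.
// Minimises -logLik + (penaltyFactor/2) * k * sum(beta^2) over
// (intercept, beta); the intercept is unpenalised.  Each coordinate
// takes a damped Newton step clipped to a per-coordinate trust region,
// with the linear predictor maintained incrementally (O(n) per update).
// [[Rcpp::export(name = ".clgFit")]]
List clgFit(NumericMatrix X, NumericVector y, double k,
            int maxSweeps, double tol, double deltaInit,
            double curvFloor, double penaltyFactor,
            NumericVector betaInit, double interceptInit) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(p);
  for (int j = 0; j < p; ++j) beta[j] = betaInit[j];
  double b0 = interceptInit;
  std::vector<double> eta(n), delta(p + 1, deltaInit);
  // linear predictors at entry (non-zero when warm-started)
  for (int i = 0; i < n; ++i) {
    double e = b0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
    eta[i] = e;
  }
  std::vector<double> objTrace;
  bool converged = false;
  int sweep = 0;
  const double ck = penaltyFactor * k;
  for (sweep = 1; sweep <= maxSweeps; ++sweep) {
    double absChange = 0.0;
    // intercept coordinate (j = -1), then each penalised coordinate
    for (int j = -1; j < p; ++j) {
      double g = 0.0, curv = 0.0;
      double dj = delta[j + 1];
      if (j < 0) {
        for (int i = 0; i < n; ++i) {
          double pi = 1.0 / (1.0 + std::exp(-eta[i]));
          g += (pi - y[i]);
          curv += curvBound(eta[i], dj);
        }
      } else {
        for (int i = 0; i < n; ++i) {
          double x = X(i, j);
          if (x == 0.0) continue;
          double pi = 1.0 / (1.0 + std::exp(-eta[i]));
          g += x * (pi - y[i]);
          curv += x * x * curvBound(eta[i], dj * std::fabs(x));
        }
        g += ck * beta[j];
        curv += ck;
      }
      if (curv < curvFloor) curv = curvFloor;
      double step = -g / curv;
      if (step > dj) step = dj; else if (step < -dj) step = -dj;
      if (step != 0.0) {
        if (j < 0) b0 += step; else beta[j] += step;
        if (j < 0) {
          for (int i = 0; i < n; ++i) eta[i] += step;
          absChange += std::fabs(step) * n;
        } else {
          double s = 0.0;
          for (int i = 0; i < n; ++i) {
            eta[i] += step * X(i, j);
            s += std::fabs(step * X(i, j));
          }
          absChange += s;
        }
      }
      double ad = std::fabs(step);
      delta[j + 1] = std::max(2.0 * ad, dj / 2.0);
    }
    objTrace.push_back(objective(y, eta, beta, k, penaltyFactor));
    double etaAbs = 0.0;
    for (int i = 0; i < n; ++i) etaAbs += std::fabs(eta[i]);
    if (absChange / (1.0 + etaAbs) < tol) { converged = true; break; }
  }
  if (sweep > maxSweeps) sweep = maxSweeps;
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = b0,
                      _["eta"] = NumericVector(eta.begin(), eta.end()),
                      _["sweeps"] = sweep,
                      _["objective"] = NumericVector(objTrace.begin(), objTrace.end()),
                      _["converged"] = converged);
}
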