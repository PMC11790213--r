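// State-dependent speciation-extinction (SSE) likelihood on a rooted
// ultrametric tree: the extinction probabilities E_i(t) and conditional
// likelihoods D_i(t) are integrated along every branch with an adaptive
// Cash-Karp Runge-Kutta scheme, combined at nodes with the state's
// speciation rate, and summed at the root under a state prior, optionally
// conditioned on the survival of both root daughter lineages.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct SSEPars {
  int S;
  std::vector<double> lambda, mu, rowq;  // rowq_i = sum_j q_ij
  // sparse off-diagonal transitions, CSR-like
  std::vector<int> qptr, qcol;
  std::vector<double> qval;
  // integration workspace (reused across branches)
  std::vector<double> k1, k2, k3, k4, k5, k6, yt, y5, y4;
};

// y = (E_1..E_S, D_1..D_S)
static void sse_deriv(const SSEPars& p, const double* y, double* dy) {
  const int S = p.S;
  const double* E = y;
  const double* D = y + S;
  for (int i = 0; i < S; ++i) {
    double qe = 0.0, qd = 0.0;
    for (int k = p.qptr[i]; k < p.qptr[i + 1]; ++k) {
      qe += p.qval[k] * E[p.qcol[k]];
      qd += p.qval[k] * D[p.qcol[k]];
    }
    double out = p.lambda[i] + p.mu[i] + p.rowq[i];
    dy[i] = p.mu[i] - out * E[i] + p.lambda[i] * E[i] * E[i] + qe;
    dy[S + i] = -out * D[i] + 2.0 * p.lambda[i] * E[i] * D[i] + qd;
  }
}

// Cash-Karp RK45 with step-size control
static bool integrate_branch(SSEPars& p, std::vector<double>& y,
                             double t0, double t1, double rtol, double atol) {
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                      b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double d1 = 2825.0 / 27648.0, d3 = 18575.0 / 48384.0,
                      d4 = 13525.0 / 55296.0, d5 = 277.0 / 14336.0,
                      d6 = 1.0 / 4.0;

  const int n = (int)y.size();
  double t = t0;
  double span = t1 - t0;
  if (span <= 0) return true;
  double h = span / 4.0;
  std::vector<double>&k1 = p.k1, &k2 = p.k2, &k3 = p.k3, &k4 = p.k4,
      &k5 = p.k5, &k6 = p.k6, &yt = p.yt, &y5 = p.y5, &y4 = p.y4;
  int iter = 0;
  while (t < t1) {
    if (++iter > 1000000) return false;
    if (t + h > t1) h = t1 - t;
    sse_deriv(p, y.data(), k1.data());
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * b21 * k1[i];
    sse_deriv(p, yt.data(), k2.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    sse_deriv(p, yt.data(), k3.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    sse_deriv(p, yt.data(), k4.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                          b54 * k4[i]);
    sse_deriv(p, yt.data(), k5.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                          b64 * k4[i] + b65 * k5[i]);
    sse_deriv(p, yt.data(), k6.data());
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      y5[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      y4[i] = y[i] + h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                          d6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      std::copy(y5.begin(), y5.end(), y.begin());
      double grow = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      h *= std::min(grow, 5.0);
    } else {
      h *= std::max(0.9 * std::pow(errmax, -0.25), 0.1);
      if (h < 1e-14 * span) return false;
    }
    for (int i = 0; i < n; ++i)
      if (!R_finite(y[i])) return false;
  }
  return true;
}

// edge: 2-column (parent, child) in 1-based ape indexing, postorder.
// heights: per-node time before present (tips ~ 0).  tipD: ntip x S.
// [[Rcpp::export(name = ".sse_loglik_cpp")]]
double sse_loglik_cpp(IntegerMatrix edge, NumericVector heights,
                      NumericMatrix tipD, int ntip,
                      NumericVector lambda, NumericVector mu,
                      NumericMatrix Qm, NumericVector root_prior,
                      bool condition_survival, double rtol) {
  const int S = lambda.size();
  SSEPars p;
  p.S = S;
  p.lambda.assign(lambda.begin(), lambda.end());
  p.mu.assign(mu.begin(), mu.end());
  p.rowq.assign(S, 0.0);
  p.qptr.assign(S + 1, 0);
  for (int i = 0; i < S; ++i) {
    for (int j = 0; j < S; ++j)
      if (i != j && Qm(i, j) != 0.0) {
        p.qcol.push_back(j);
        p.qval.push_back(Qm(i, j));
        p.rowq[i] += Qm(i, j);
      }
    p.qptr[i + 1] = (int)p.qcol.size();
  }
  p.k1.resize(2 * S); p.k2.resize(2 * S); p.k3.resize(2 * S);
  p.k4.resize(2 * S); p.k5.resize(2 * S); p.k6.resize(2 * S);
  p.yt.resize(2 * S); p.y5.resize(2 * S); p.y4.resize(2 * S);

  const int nnode = heights.size();
  const int root = ntip;  // ape: root = ntip + 1 (1-based)
  std::vector<std::vector<double>> prodD(nnode), Eatnode(nnode);
  std::vector<int> nchild(nnode, 0);
  for (int v = 0; v < nnode; ++v) prodD[v].assign(S, 1.0);
  double logcomp = 0.0;
  const double atol = rtol * 1e-2;

  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0) - 1, chi = edge(e, 1) - 1;
    std::vector<double> y(2 * S, 0.0);
    if (chi < ntip) {
      for (int i = 0; i < S; ++i) y[S + i] = tipD(chi, i);
    } else {
      // finalize internal child: node combination with speciation rate
      for (int i = 0; i < S; ++i) {
        y[i] = Eatnode[chi][i];
        y[S + i] = prodD[chi][i] * p.lambda[i];
      }
    }
    if (!integrate_branch(p, y, heights[chi], heights[par], rtol, atol))
      return R_NegInf;
    double s = 0.0;
    for (int i = 0; i < S; ++i) s += y[S + i];
    if (!(s > 0.0) || !R_finite(s)) return R_NegInf;
    for (int i = 0; i < S; ++i) {
      prodD[par][i] *= y[S + i] / s;
      }
    logcomp += std::log(s);
    Eatnode[par] = std::vector<double>(y.begin(), y.begin() + S);
    nchild[par] += 1;
  }

  // root: D_i = lambda_i * prod of children, weighted by the prior
  double lik = 0.0;
  for (int i = 0; i < S; ++i) {
    double d = prodD[root][i] * p.lambda[i];
    if (condition_survival) {
      double surv = 1.0 - Eatnode[root][i];
      double denom = p.lambda[i] * surv * surv;
      d = denom > 0 ? d / denom : 0.0;
    }
    lik += root_prior[i] * d;
  }
  if (!(lik > 0.0) || !R_finite(lik)) return R_NegInf;
  return std::log(lik) + logcomp;
}
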