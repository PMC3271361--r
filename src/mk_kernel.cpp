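#include <Rcpp.h>
using namespace Rcpp;

// Pruning (post-order message passing) likelihood for a 2-state CTMC with
// instantaneous rates fw (0->1) and bw (1->0) and equilibrium root
// frequencies pi = (bw, fw)/(fw+bw).
//
// `edge` must be in post-order (children before parents), 1-indexed in the
// ape convention: tips 1..ntip, root ntip+1. `tip0`/`tip1` hold per-tip
// conditional likelihoods (ntip x nchar); a missing observation is (1,1).
// Returns the sum over characters of the natural-log likelihood.

// [[Rcpp::export]]
double C_mk_loglik(const IntegerMatrix edge,
                   const NumericVector elen,
                   const int ntip,
                   const int nnode,
                   const NumericMatrix tip0,
                   const NumericMatrix tip1,
                   const double fw,
                   const double bw,
                   const int root1) {
  const int nchar = tip0.ncol();
  const int ntot = ntip + nnode;
  const int nedge = edge.nrow();
  const double s = fw + bw;

  std::vector<double> up0(ntot * nchar), up1(ntot * nchar);
  std::vector<double> logscale(nchar, 0.0);

  for (int j = 0; j < nchar; ++j) {
    for (int i = 0; i < ntip; ++i) {
      up0[i * nchar + j] = tip0(i, j);
      up1[i * nchar + j] = tip1(i, j);
    }
    for (int i = ntip; i < ntot; ++i) {
      up0[i * nchar + j] = 1.0;
      up1[i * nchar + j] = 1.0;
    }
  }

  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1;
    const int c = edge(e, 1) - 1;
    if (p < 0 || p >= ntot || c < 0 || c >= ntot) {
      stop("edge matrix refers to a node outside 1..(ntip + nnode)");
    }
    const double t = elen[e];
    const double ex = std::exp(-s * t);
    const double p00 = (bw + fw * ex) / s;
    const double p01 = 1.0 - p00;
    const double p11 = (fw + bw * ex) / s;
    const double p10 = 1.0 - p11;
    for (int j = 0; j < nchar; ++j) {
      const double c0 = up0[c * nchar + j];
      const double c1 = up1[c * nchar + j];
      const double m0 = p00 * c0 + p01 * c1;
      const double m1 = p10 * c0 + p11 * c1;
      double v0 = up0[p * nchar + j] * m0;
      double v1 = up1[p * nchar + j] * m1;
      const double mx = (v0 > v1) ? v0 : v1;
      if (mx > 0.0 && mx < 1e-280) {
        v0 /= mx;
        v1 /= mx;
        logscale[j] += std::log(mx);
      }
      up0[p * nchar + j] = v0;
      up1[p * nchar + j] = v1;
    }
  }

  const int root = root1 - 1;
  if (root < 0 || root >= ntot) stop("root index out of range");
  const double pi0 = bw / s;
  const double pi1 = fw / s;
  double ll = 0.0;
  for (int j = 0; j < nchar; ++j) {
    const double lik = pi0 * up0[root * nchar + j] + pi1 * up1[root * nchar + j];
    if (lik <= 0.0 || !std::isfinite(lik)) return R_NegInf;
    ll += std::log(lik) + logscale[j];
  }
  return ll;
}
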