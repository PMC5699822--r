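#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 4x4 transition probability P(t) = A diag(exp(lambda t)) B for a reversible
// rate matrix decomposed as Q = A diag(lambda) B (A = D^{-1/2} U,
// B = U^T D^{1/2}, D = diag(pi)). P stored row-major: P[4*i + j].
static inline void pmat(const double* A, const double* B,
                        const double* lambda, double t, double* P) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(lambda[k] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += A[i + 4 * k] * e[k] * B[k + 4 * j];
      P[4 * i + j] = s < 0.0 ? 0.0 : s;
    }
}

// Felsenstein pruning log-likelihood over compressed site patterns with
// discrete-gamma rate categories. Edges must be in postorder (children
// before parents); node indexing follows ape (tips 1..ntip, root ntip+1).
// tipstates: ntip x npat, values 0..3 or >=4 for missing. Partial
// likelihoods are pattern-major ([4*pat + state]) with per-node,
// per-pattern rescaling against underflow.
// [[Rcpp::export]]
double cpp_pruning_loglik(IntegerMatrix edge, NumericVector elen, int ntip,
                          IntegerMatrix tipstates, NumericVector weights,
                          NumericVector pi, NumericVector lambda,
                          NumericMatrix A, NumericMatrix B,
                          NumericVector catrates) {
  const int nedge = edge.nrow();
  const int npat = tipstates.ncol();
  const int ncat = catrates.size();
  int nnode = ntip;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }
  const size_t slab = (size_t)4 * npat;          // one category of one node
  std::vector<double> L((size_t)nnode * ncat * slab);
  std::vector<double> lsc((size_t)nnode * ncat * npat, 0.0);
  std::vector<char> init(nnode, 0);
  const double* Ap = REAL(A);
  const double* Bp = REAL(B);
  const double* lam = REAL(lambda);
  const int* tips = INTEGER(tipstates);
  double P[16];

  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chd = edge(e, 1) - 1;
    double* Lpar = &L[(size_t)par * ncat * slab];
    double* spar = &lsc[(size_t)par * ncat * npat];
    if (!init[par]) {
      std::fill(Lpar, Lpar + ncat * slab, 1.0);
      std::fill(spar, spar + (size_t)ncat * npat, 0.0);
      init[par] = 1;
    }
    for (int c = 0; c < ncat; ++c) {
      pmat(Ap, Bp, lam, elen[e] * catrates[c], P);
      double* Lp = Lpar + (size_t)c * slab;
      double* sp = spar + (size_t)c * npat;
      if (chd < ntip) {                      // tip child: column-indicator
        for (int p = 0; p < npat; ++p) {
          const int s = tips[chd + (size_t)ntip * p];
          if (s >= 4) continue;              // missing: all-ones partial
          double* Lq = Lp + 4 * p;
          Lq[0] *= P[s];
          Lq[1] *= P[4 + s];
          Lq[2] *= P[8 + s];
          Lq[3] *= P[12 + s];
        }
      } else {                               // internal child
        const double* Lc = &L[(size_t)chd * ncat * slab + (size_t)c * slab];
        const double* sc = &lsc[(size_t)chd * ncat * npat + (size_t)c * npat];
        for (int p = 0; p < npat; ++p) {
          const double* v = Lc + 4 * p;
          double* Lq = Lp + 4 * p;
          double mx = 0.0;
          for (int i = 0; i < 4; ++i) {
            const double* Pr = P + 4 * i;
            const double s =
              Pr[0] * v[0] + Pr[1] * v[1] + Pr[2] * v[2] + Pr[3] * v[3];
            Lq[i] *= s;
            if (Lq[i] > mx) mx = Lq[i];
          }
          sp[p] += sc[p];
          if (mx > 0.0 && mx < 1e-200) {     // rescale to avoid underflow
            for (int i = 0; i < 4; ++i) Lq[i] /= mx;
            sp[p] += std::log(mx);
          }
        }
      }
    }
  }
  const int root = edge(nedge - 1, 0) - 1;
  const double* Lr = &L[(size_t)root * ncat * slab];
  const double* sr = &lsc[(size_t)root * ncat * npat];
  double lnL = 0.0;
  std::vector<double> lv(ncat);
  for (int p = 0; p < npat; ++p) {
    double mx = R_NegInf;                    // log-sum-exp over categories
    for (int c = 0; c < ncat; ++c) {
      const double* v = Lr + (size_t)c * slab + 4 * p;
      const double s =
        pi[0] * v[0] + pi[1] * v[1] + pi[2] * v[2] + pi[3] * v[3];
      lv[c] = (s > 0.0 ? std::log(s) : R_NegInf) + sr[(size_t)c * npat + p];
      if (lv[c] > mx) mx = lv[c];
    }
    if (!R_FINITE(mx)) return R_NegInf;
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c) acc += std::exp(lv[c] - mx);
    lnL += weights[p] * (mx + std::log(acc / ncat));
  }
  return lnL;
}
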