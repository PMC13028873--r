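// Compiled kernels for the inner PPI message-passing loops. Feature
// matrices travel in transposed layout (d1 x nT*B, herb blocks along
// columns). All relations' transforms are stacked into one (d1*R x d1)
// matrix so each layer costs a single well-shaped GEMM; neighbor
// aggregation then reads the relation's contiguous 16-row stripe of the
// product. The per-relation products are cached for the backward pass, so
// attention-scalar gradients reduce to elementwise dots. Sparse operators
// arrive as dgCMatrix slots (row-normalized in-neighbor averaging, see
// .meanOperator); the self-loop relation is the last entry and carries no
// matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct SpOp {
  IntegerVector i, p;
  NumericVector x;
  bool self;
  std::vector<int> src;   // columns with outgoing edges
};

std::vector<SpOp> unpackOps(const List& A) {
  std::vector<SpOp> ops;
  for (int r = 0; r < A.size(); ++r) {
    SpOp op;
    if (Rf_isNull(A[r])) {
      op.self = true;
    } else {
      S4 m = A[r];
      op.i = m.slot("i");
      op.p = m.slot("p");
      op.x = m.slot("x");
      op.self = false;
      for (int u = 0; u + 1 < op.p.size(); ++u)
        if (op.p[u + 1] > op.p[u]) op.src.push_back(u);
    }
    ops.push_back(op);
  }
  return ops;
}

}  // namespace

// Ht: d1 x (nT*B). Wstack: list over steps of (d1*R) x d1 stacked
// transforms (relation r occupies rows r*d1 .. r*d1+d1-1). alpha: B x
// (R*layerI), column (i-1)*R + r. Returns the intermediate states (input
// first) and the cached stacked products, one per step.
// [[Rcpp::export(name = ".innerForwardCpp")]]
List innerForwardCpp(const arma::mat& Ht, const List& Wstack, const List& A,
                     const arma::mat& alpha, int nT, int B,
                     bool needP = true) {
  std::vector<SpOp> ops = unpackOps(A);
  const int R = ops.size();
  const int layerI = Wstack.size();
  const int d = Ht.n_rows;
  const int N = Ht.n_cols;
  List states(layerI + 1), Pcache(layerI);
  arma::mat H = Ht;
  states[0] = H;
  for (int i = 0; i < layerI; ++i) {
    arma::mat Ws = as<arma::mat>(Wstack[i]);   // (d*R) x d
    arma::mat P = Ws * H;                      // (d*R) x N, one GEMM
    arma::mat S(d, N, arma::fill::zeros);
    for (int r = 0; r < R; ++r) {
      const int stripe = r * d;
      if (ops[r].self) {
        for (int b = 0; b < B; ++b) {
          const double a = alpha(b, i * R + r);
          const int off = b * nT;
          for (int v = 0; v < nT; ++v) {
            double* sv = S.colptr(off + v);
            const double* pv = P.colptr(off + v) + stripe;
            for (int j = 0; j < d; ++j) sv[j] += a * pv[j];
          }
        }
      } else {
        for (int b = 0; b < B; ++b) {
          const double a = alpha(b, i * R + r);
          const int off = b * nT;
          for (int u : ops[r].src) {
            const double* pu = P.colptr(off + u) + stripe;
            for (int k = ops[r].p[u]; k < ops[r].p[u + 1]; ++k) {
              double* sv = S.colptr(off + ops[r].i[k]);
              const double w = a * ops[r].x[k];
              for (int j = 0; j < d; ++j) sv[j] += w * pu[j];
            }
          }
        }
      }
    }
    S.transform([](double v) { return v > 0.0 ? v : 0.0; });
    H = std::move(S);
    states[i + 1] = H;
    if (needP) Pcache[i] = P;
  }
  return List::create(Named("states") = states, Named("P") = Pcache);
}

// Backward. dHt: gradient at the final state. Returns the input-state
// gradient, the stacked per-step weight gradients ((d1*R) x d1, same
// stripe layout) and the attention gradients (B x R*layerI).
// [[Rcpp::export(name = ".innerBackwardCpp")]]
List innerBackwardCpp(const arma::mat& dHt, const List& states,
                      const List& Pcache, const List& Wstack, const List& A,
                      const arma::mat& alpha, int nT, int B) {
  std::vector<SpOp> ops = unpackOps(A);
  const int R = ops.size();
  const int layerI = Wstack.size();
  const int d = dHt.n_rows;
  const int N = dHt.n_cols;
  arma::mat dH = dHt;
  List gW(layerI);
  arma::mat dAlpha(B, R * layerI, arma::fill::zeros);
  for (int i = layerI - 1; i >= 0; --i) {
    arma::mat Hout = as<arma::mat>(states[i + 1]);
    arma::mat Hin = as<arma::mat>(states[i]);
    arma::mat P = as<arma::mat>(Pcache[i]);
    arma::mat Ws = as<arma::mat>(Wstack[i]);
    arma::mat dS = dH % (Hout > 0);
    // V: stacked gradients wrt the pre-aggregation products; stripe r of
    // column off+u collects alpha-scaled transposed-edge contributions
    arma::mat V(d * R, N, arma::fill::zeros);
    for (int r = 0; r < R; ++r) {
      const int stripe = r * d;
      if (ops[r].self) {
        for (int b = 0; b < B; ++b) {
          const double a = alpha(b, i * R + r);
          const int off = b * nT;
          double dal = 0.0;
          for (int v = 0; v < nT; ++v) {
            const double* dv = dS.colptr(off + v);
            const double* pv = P.colptr(off + v) + stripe;
            double* vv = V.colptr(off + v) + stripe;
            double s = 0.0;
            for (int j = 0; j < d; ++j) {
              s += dv[j] * pv[j];
              vv[j] = a * dv[j];
            }
            dal += s;
          }
          dAlpha(b, i * R + r) += dal;
        }
      } else {
        for (int b = 0; b < B; ++b) {
          const double a = alpha(b, i * R + r);
          const int off = b * nT;
          for (int u : ops[r].src) {
            double* vu = V.colptr(off + u) + stripe;
            for (int k = ops[r].p[u]; k < ops[r].p[u + 1]; ++k) {
              const double* dv = dS.colptr(off + ops[r].i[k]);
              const double w = a * ops[r].x[k];
              for (int j = 0; j < d; ++j) vu[j] += w * dv[j];
            }
          }
          // dAlpha over this block: <V stripe, P stripe> / alpha; the V
          // stripe is nonzero only at source columns
          double dal = 0.0;
          for (int u : ops[r].src) {
            const double* vc = V.colptr(off + u) + stripe;
            const double* pc = P.colptr(off + u) + stripe;
            double s = 0.0;
            for (int j = 0; j < d; ++j) s += vc[j] * pc[j];
            dal += s;
          }
          dAlpha(b, i * R + r) += dal / a;
        }
      }
    }
    gW[i] = arma::mat(V * Hin.t());     // (d*R) x d, one GEMM
    dH = Ws.t() * V;                    // d x N, one GEMM
  }
  return List::create(Named("dH") = dH, Named("gW") = gW,
                      Named("dAlpha") = dAlpha);
}
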