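// Batched per-gene dense layers.  Inputs use the unit-major layout:
// an N x (h * M) matrix whose column (i - 1) * M + m holds hidden unit i of
// gene m, which viewed column-major is an (N * M) x h array indexed by
// (cell, gene) rows.  Weights are (M, h_out, h_in) arrays, biases (M, h_out).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_gene_linear_fwd(const NumericMatrix& X,
                                  const NumericVector& W,
                                  const NumericVector& b,
                                  int n, int M, int h_in, int h_out,
                                  bool has_bias) {
  NumericMatrix out(n, h_out * M);
  const double* x = X.begin();
  const double* w = W.begin();
  const double* bp = b.begin();
  double* o = out.begin();
  const R_xlen_t nm = (R_xlen_t)n * M;
  for (int j = 0; j < h_out; ++j) {
    double* oj = o + j * nm;
    for (int m = 0; m < M; ++m) {
      double* om = oj + (R_xlen_t)m * n;
      const double bias = has_bias ? bp[m + (R_xlen_t)j * M] : 0.0;
      for (int c = 0; c < n; ++c) om[c] = bias;
      for (int i = 0; i < h_in; ++i) {
        const double wj = w[m + (R_xlen_t)j * M + (R_xlen_t)i * M * h_out];
        const double* xm = x + i * nm + (R_xlen_t)m * n;
        for (int c = 0; c < n; ++c) om[c] += wj * xm[c];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_gene_linear_bwd(const NumericMatrix& G,
                         const NumericMatrix& X,
                         const NumericVector& W,
                         int n, int M, int h_in, int h_out,
                         bool want_da, bool want_dw, bool want_db) {
  const double* g = G.begin();
  const double* x = X.begin();
  const double* w = W.begin();
  const R_xlen_t nm = (R_xlen_t)n * M;
  NumericMatrix da(want_da ? n : 1, want_da ? h_in * M : 1);
  NumericVector dw(want_dw ? (R_xlen_t)M * h_out * h_in : 1);
  NumericMatrix db(want_db ? M : 1, want_db ? h_out : 1);
  if (want_da) {
    double* d = da.begin();
    for (int i = 0; i < h_in; ++i) {
      double* di = d + i * nm;
      for (int m = 0; m < M; ++m) {
        double* dm = di + (R_xlen_t)m * n;
        for (int c = 0; c < n; ++c) dm[c] = 0.0;
        for (int j = 0; j < h_out; ++j) {
          const double wj = w[m + (R_xlen_t)j * M + (R_xlen_t)i * M * h_out];
          const double* gm = g + j * nm + (R_xlen_t)m * n;
          for (int c = 0; c < n; ++c) dm[c] += wj * gm[c];
        }
      }
    }
  }
  if (want_dw) {
    double* d = dw.begin();
    for (int j = 0; j < h_out; ++j) {
      for (int i = 0; i < h_in; ++i) {
        for (int m = 0; m < M; ++m) {
          const double* gm = g + j * nm + (R_xlen_t)m * n;
          const double* xm = x + i * nm + (R_xlen_t)m * n;
          double s = 0.0;
          for (int c = 0; c < n; ++c) s += gm[c] * xm[c];
          d[m + (R_xlen_t)j * M + (R_xlen_t)i * M * h_out] = s;
        }
      }
    }
  }
  if (want_db) {
    double* d = db.begin();
    for (int j = 0; j < h_out; ++j) {
      for (int m = 0; m < M; ++m) {
        const double* gm = g + j * nm + (R_xlen_t)m * n;
        double s = 0.0;
        for (int c = 0; c < n; ++c) s += gm[c];
        d[m + (R_xlen_t)j * M] = s;
      }
    }
  }
  return List::create(Named("da") = want_da ? (SEXP)da : R_NilValue,
                      Named("dW") = want_dw ? (SEXP)dw : R_NilValue,
                      Named("db") = want_db ? (SEXP)db : R_NilValue);
}
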