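#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Blocked update of a ring-buffered symmetric relationship/kinship window.
//
// K is column-major, W x W. A batch of nn new individuals occupies the
// contiguous column range [newbase, newbase + nn - 1] (1-based). Each new
// individual t is a linear combination of older individuals ("parents"):
// row(new_t) = sum_p coef(t, p) * row(par(t, p)), with par 0-padded.
// Parents must all have been written in earlier calls (never in this
// batch). live_start/live_len give the currently valid column ranges of
// the window (excluding the new block). diagval holds the new diagonal
// entries, computed by the caller from pre-call reads.
//
// The within-batch block is filled from the same linear combination and
// is symmetric because all parents are older and the new individuals'
// Mendelian terms are mutually independent.
// [[Rcpp::export]]
void row_update_block(NumericMatrix K, IntegerMatrix par,
                      NumericMatrix coef, int newbase,
                      IntegerVector live_start, IntegerVector live_len,
                      NumericVector diagval) {
  const int W = K.nrow();
  const int nn = par.nrow();
  const int pmax = par.ncol();
  const int nb = newbase - 1;
  if (nn == 0) return;
  // compact per-row parent lists (drop 0-padding, keep counts)
  std::vector<const double*> pp((size_t)nn * pmax, (const double*)0);
  std::vector<double> pc((size_t)nn * pmax, 0.0);
  std::vector<int> np(nn, 0);
  for (int t = 0; t < nn; ++t) {
    int k = 0;
    for (int p = 0; p < pmax; ++p) {
      const int idx = par(t, p);
      if (idx > 0) {
        pp[(size_t)t * pmax + k] = &K(0, idx - 1);
        pc[(size_t)t * pmax + k] = coef(t, p);
        ++k;
      }
    }
    np[t] = k;
  }
  const int TILE = 128;
  std::vector<double> tmp((size_t)TILE * nn);
  for (int r = 0; r < live_start.size(); ++r) {
    const int j0 = live_start[r] - 1;
    const int len = live_len[r];
    for (int jt = 0; jt < len; jt += TILE) {
      const int jl = std::min(TILE, len - jt);
      const int joff = j0 + jt;
      for (int t = 0; t < nn; ++t) {
        const double** P = &pp[(size_t)t * pmax];
        const double* C = &pc[(size_t)t * pmax];
        double* out = &tmp[t];
        switch (np[t]) {
        case 0: {
          for (int j = 0; j < jl; ++j) out[(size_t)j * nn] = 0.0;
          break;
        }
        case 1: {
          const double* a = P[0] + joff; const double c0 = C[0];
          for (int j = 0; j < jl; ++j) out[(size_t)j * nn] = c0 * a[j];
          break;
        }
        case 2: {
          const double* a = P[0] + joff; const double* b = P[1] + joff;
          const double c0 = C[0], c1 = C[1];
          for (int j = 0; j < jl; ++j)
            out[(size_t)j * nn] = c0 * a[j] + c1 * b[j];
          break;
        }
        default: {
          const int k = np[t];
          for (int j = 0; j < jl; ++j) {
            double v = 0.0;
            for (int p = 0; p < k; ++p) v += C[p] * P[p][joff + j];
            out[(size_t)j * nn] = v;
          }
        }
        }
      }
      // rows of the new block in old columns
      for (int j = 0; j < jl; ++j) {
        double* col = &K(0, j0 + jt + j);
        const double* src = &tmp[(size_t)j * nn];
        for (int t = 0; t < nn; ++t) col[nb + t] = src[t];
      }
      // symmetric: old rows in the new columns
      for (int t = 0; t < nn; ++t) {
        double* col = &K(0, nb + t);
        const double* src = &tmp[t];
        for (int j = 0; j < jl; ++j) col[j0 + jt + j] = src[(size_t)j * nn];
      }
    }
  }
  // within-batch block: K(new_j, new_t) = sum_p coef(t,p) K(par_p, new_j)
  for (int t = 0; t < nn; ++t) {
    double* out = &K(nb, nb + t);
    for (int j = 0; j < nn; ++j) out[j] = 0.0;
    const double** P = &pp[(size_t)t * pmax];
    const double* C = &pc[(size_t)t * pmax];
    for (int p = 0; p < np[t]; ++p) {
      const double* cp = P[p] + nb;
      const double c = C[p];
      for (int j = 0; j < nn; ++j) out[j] += c * cp[j];
    }
  }
  for (int t = 0; t < nn; ++t) K(nb + t, nb + t) = diagval[t];
}

// Symmetric in-place addition K[i, j] += x, K[j, i] += x for index pairs
// (1-based); used for same-father sibling corrections.
// [[Rcpp::export]]
void add_pairs_sym(NumericMatrix K, IntegerVector i, IntegerVector j,
                   NumericVector x) {
  const int n = i.size();
  for (int t = 0; t < n; ++t) {
    K(i[t] - 1, j[t] - 1) += x[t];
    if (i[t] != j[t]) K(j[t] - 1, i[t] - 1) += x[t];
  }
}
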