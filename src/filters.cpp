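#include <Rcpp.h>
using namespace Rcpp;

// One pass of a direct-form-I IIR filter with zero initial conditions:
// y[n] = sum_j b[j] x[n-j] - sum_{i>=1} a[i] y[n-i], a[0] assumed 1.
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     const double* x, double* y, const int n) {
  const int nb = b.size(), na = a.size();
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const int jb = i < nb - 1 ? i : nb - 1;
    for (int j = 0; j <= jb; ++j) acc += b[j] * x[i - j];
    const int ja = i < na - 1 ? i : na - 1;
    for (int j = 1; j <= ja; ++j) acc -= a[j] * y[i - j];
    y[i] = acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  NumericVector y(n);
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  iir_pass(bv, av, x.begin(), y.begin(), n);
  return y;
}

// Zero-phase filtering with odd-symmetric edge padding of `npad` samples:
// pad, filter forward, filter backward, trim. Equivalent to the R-level
// pad/filter/rev/filter/rev sequence but in one allocation.
// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector b, NumericVector a, NumericVector x,
                           int npad) {
  const int n = x.size();
  if (npad > n - 1) npad = n - 1;
  const int m = n + 2 * npad;
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  std::vector<double> ext(m), tmp(m), out(m);
  for (int i = 0; i < npad; ++i) ext[i] = 2.0 * x[0] - x[npad - i];
  for (int i = 0; i < n; ++i) ext[npad + i] = x[i];
  for (int i = 0; i < npad; ++i) ext[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  iir_pass(bv, av, ext.data(), tmp.data(), m);
  std::reverse(tmp.begin(), tmp.end());
  iir_pass(bv, av, tmp.data(), out.data(), m);
  std::reverse(out.begin(), out.end());
  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = out[npad + i];
  return y;
}

// Terminal-node energies of a full wavelet packet decomposition with
// periodic extension, all channels at once. `x` is samples x channels; the
// node order matches the R-level tree traversal (level order, low-pass child
// first). Returns a (2^level) x channels energy matrix.
// [[Rcpp::export]]
NumericMatrix cpp_wpd_energy(NumericMatrix x, NumericVector lo, NumericVector hi,
                             int level) {
  const int n = x.nrow(), nch = x.ncol(), L = lo.size();
  const int nnodes = 1 << level;
  NumericMatrix energy(nnodes, nch);
  std::vector<double> flo(lo.begin(), lo.end()), fhi(hi.begin(), hi.end());
  for (int ch = 0; ch < nch; ++ch) {
    // nodes of the current level, concatenated (all have equal length)
    std::vector<double> cur(x.column(ch).begin(), x.column(ch).end());
    int nlen = n, nnode = 1;
    std::vector<double> nxt;
    for (int lev = 0; lev < level; ++lev) {
      const int half = nlen / 2;
      nxt.assign(2 * nnode * half, 0.0);
      for (int nd = 0; nd < nnode; ++nd) {
        const double* src = cur.data() + nd * nlen;
        double* dst_lo = nxt.data() + 2 * nd * half;
        double* dst_hi = dst_lo + half;
        for (int k = 0; k < half; ++k) {
          double acc_lo = 0.0, acc_hi = 0.0;
          const int base = 2 * k;
          for (int m = 0; m < L; ++m) {
            int idx = base + m;
            if (idx >= nlen) idx -= nlen;
            const double v = src[idx];
            acc_lo += flo[m] * v;
            acc_hi += fhi[m] * v;
          }
          dst_lo[k] = acc_lo;
          dst_hi[k] = acc_hi;
        }
      }
      cur.swap(nxt);
      nlen = half;
      nnode *= 2;
    }
    for (int nd = 0; nd < nnodes; ++nd) {
      double e = 0.0;
      const double* src = cur.data() + nd * nlen;
      for (int k = 0; k < nlen; ++k) e += src[k] * src[k];
      energy(nd, ch) = e;
    }
  }
  return energy;
}

// Per-row min and max of a matrix in one contiguous pass (column-major
// traversal); returns a 2 x nrow matrix (row 1 = min, row 2 = max).
// [[Rcpp::export]]
NumericMatrix cpp_row_range(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(2, nr);
  for (int i = 0; i < nr; ++i) { out(0, i) = R_PosInf; out(1, i) = R_NegInf; }
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    for (int i = 0; i < nr; ++i) {
      const double v = col[i];
      if (v < out(0, i)) out(0, i) = v;
      if (v > out(1, i)) out(1, i) = v;
    }
  }
  return out;
}
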