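#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reflective ("symmetric") index: ... c b a | a b c ... | c b a ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

//' @name conv2_reflect
//' @title 2-D convolution with reflective boundary
//' @description True convolution (kernel flipped) of a matrix with an
//'   odd-sized kernel under symmetric boundary extension.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix conv2_reflect(NumericMatrix x, NumericMatrix k) {
  int nr = x.nrow(), nc = x.ncol();
  int kr = k.nrow(), kc = k.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = -hc; dj <= hc; ++dj) {
        int jj = reflect_idx(j - dj, nc);
        for (int di = -hr; di <= hr; ++di) {
          int ii = reflect_idx(i - di, nr);
          acc += x(ii, jj) * k(di + hr, dj + hc);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Separable filtering with a symmetric 1-D kernel (rows then columns),
// reflective boundary.  For symmetric kernels convolution == correlation.
// [[Rcpp::export]]
NumericMatrix conv2_sep_reflect(NumericMatrix x, NumericVector k) {
  int nr = x.nrow(), nc = x.ncol();
  int kl = k.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  int h = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *kp = k.begin();
  const double *xp = x.begin();
  double *tp = tmp.begin();
  // vertical pass (contiguous within a column)
  for (int j = 0; j < nc; ++j) {
    const double *col = xp + (size_t)j * nr;
    double *tcol = tp + (size_t)j * nr;
    int lo = std::min(h, nr), hi = std::max(nr - h, lo);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int d = -h; d <= h; ++d)
        acc += col[reflect_idx(i - d, nr)] * kp[d + h];
      tcol[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double *c0 = col + i - h;
      for (int d = 0; d < kl; ++d) acc += c0[kl - 1 - d] * kp[d];
      tcol[i] = acc;
    }
    for (int i = hi; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -h; d <= h; ++d)
        acc += col[reflect_idx(i - d, nr)] * kp[d + h];
      tcol[i] = acc;
    }
  }
  // horizontal pass: accumulate column-by-column to keep accesses contiguous
  double *op = out.begin();
  std::fill(op, op + (size_t)nr * nc, 0.0);
  for (int j = 0; j < nc; ++j) {
    double *ocol = op + (size_t)j * nr;
    for (int d = -h; d <= h; ++d) {
      const double *scol = tp + (size_t)reflect_idx(j - d, nc) * nr;
      double kv = kp[d + h];
      for (int i = 0; i < nr; ++i) ocol[i] += scol[i] * kv;
    }
  }
  return out;
}

// Minimum distance from every pixel centre (row, col, 0-based) to a
// sampled polyline.  Used by the phantom rasteriser.
// [[Rcpp::export]]
NumericMatrix polyline_dist(int nrow, int ncol, NumericVector pr, NumericVector pc) {
  int np = pr.size();
  if (np != pc.size()) stop("point vectors must have equal length");
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int p = 0; p + 1 < np; ++p) {
    double ar = pr[p], ac = pc[p];
    double br = pr[p + 1], bc = pc[p + 1];
    double dr = br - ar, dc = bc - ac;
    double len2 = dr * dr + dc * dc;
    for (int j = 0; j < ncol; ++j) {
      for (int i = 0; i < nrow; ++i) {
        double t = 0.0;
        if (len2 > 0) {
          t = ((i - ar) * dr + (j - ac) * dc) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
        }
        double er = i - (ar + t * dr), ec = j - (ac + t * dc);
        double d = std::sqrt(er * er + ec * ec);
        if (d < out(i, j)) out(i, j) = d;
      }
    }
  }
  if (np == 1) {
    for (int j = 0; j < ncol; ++j)
      for (int i = 0; i < nrow; ++i) {
        double er = i - pr[0], ec = j - pc[0];
        out(i, j) = std::sqrt(er * er + ec * ec);
      }
  }
  return out;
}
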