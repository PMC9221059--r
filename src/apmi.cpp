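#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adaptive-partitioning mutual information on copula-transformed data.
// The unit square is split recursively at cell midpoints into four
// quadrants; a cell is split only while the chi-square statistic against
// local uniformity exceeds `chi2_crit` and the cell holds at least
// `min_points` points. Leaf cells contribute the plug-in term
// (n/N) * log[(n/N) / area]. MI is in nats and floored at zero.

static double apmi_rec(const double *x, const double *y,
                       std::vector<int> &idx, std::vector<int> &buf,
                       int lo, int hi,
                       double xlo, double xhi, double ylo, double yhi,
                       int N, double chi2_crit, int min_points,
                       bool root) {
  const int n = hi - lo;
  if (n == 0) return 0.0;

  const double xm = 0.5 * (xlo + xhi);
  const double ym = 0.5 * (ylo + yhi);

  int cnt[4] = {0, 0, 0, 0};
  for (int k = lo; k < hi; ++k) {
    const int i = idx[k];
    const int q = (x[i] > xm ? 1 : 0) + (y[i] > ym ? 2 : 0);
    ++cnt[q];
  }
  const double e = n / 4.0;
  double x2 = 0.0;
  for (int q = 0; q < 4; ++q) {
    const double d = cnt[q] - e;
    x2 += d * d / e;
  }

  // The root cell is always split: the copula transform balances its
  // margins exactly, which degenerates the chi-square test there.
  if (n >= min_points && (x2 > chi2_crit || root)) {
    // stable 4-way partition of idx[lo:hi) by quadrant
    int off[4];
    off[0] = lo;
    off[1] = off[0] + cnt[0];
    off[2] = off[1] + cnt[1];
    off[3] = off[2] + cnt[2];
    int pos[4] = {off[0], off[1], off[2], off[3]};
    for (int k = lo; k < hi; ++k) buf[k] = idx[k];
    for (int k = lo; k < hi; ++k) {
      const int i = buf[k];
      const int q = (x[i] > xm ? 1 : 0) + (y[i] > ym ? 2 : 0);
      idx[pos[q]++] = i;
    }
    double s = 0.0;
    s += apmi_rec(x, y, idx, buf, off[0], off[0] + cnt[0], xlo, xm, ylo, ym,
                  N, chi2_crit, min_points, false);
    s += apmi_rec(x, y, idx, buf, off[1], off[1] + cnt[1], xm, xhi, ylo, ym,
                  N, chi2_crit, min_points, false);
    s += apmi_rec(x, y, idx, buf, off[2], off[2] + cnt[2], xlo, xm, ym, yhi,
                  N, chi2_crit, min_points, false);
    s += apmi_rec(x, y, idx, buf, off[3], off[3] + cnt[3], xm, xhi, ym, yhi,
                  N, chi2_crit, min_points, false);
    return s;
  }

  const double p = (double)n / (double)N;
  const double area = (xhi - xlo) * (yhi - ylo);
  return p * std::log(p / area);
}

static double apmi_one(const double *x, const double *y, int N,
                       double chi2_crit, int min_points) {
  std::vector<int> idx(N), buf(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  double mi = apmi_rec(x, y, idx, buf, 0, N, 0.0, 1.0, 0.0, 1.0,
                       N, chi2_crit, min_points, true);
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
double apmi_cpp(NumericVector x, NumericVector y,
                double chi2_crit, int min_points) {
  const int N = x.size();
  if (y.size() != N) stop("x and y must have the same length");
  return apmi_one(REAL(x), REAL(y), N, chi2_crit, min_points);
}

// All unordered pairs (i < j) of rows of `mat` (proteins x samples),
// returned in row-major pair order: (1,2), (1,3), ..., (n-1,n).
// [[Rcpp::export]]
NumericVector allpairs_mi_cpp(NumericMatrix mat,
                              double chi2_crit, int min_points) {
  const int n = mat.nrow(), N = mat.ncol();
  std::vector<std::vector<double>> rows(n, std::vector<double>(N));
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < N; ++s) rows[i][s] = mat(i, s);
  NumericVector out((double)n * (n - 1) / 2);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      out[k++] = apmi_one(rows[i].data(), rows[j].data(), N,
                          chi2_crit, min_points);
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Pool of null MI values: repeatedly pick two distinct rows of `mat`,
// shuffle one of them, and compute MI. Uses R's RNG so results are
// reproducible under set.seed() from the caller.
// [[Rcpp::export]]
NumericVector null_mi_pool_cpp(NumericMatrix mat, int n_perm,
                               double chi2_crit, int min_points) {
  const int n = mat.nrow(), N = mat.ncol();
  if (n < 2) stop("need at least two rows");
  std::vector<std::vector<double>> rows(n, std::vector<double>(N));
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < N; ++s) rows[i][s] = mat(i, s);
  NumericVector out(n_perm);
  std::vector<double> perm(N);
  GetRNGstate();
  for (int t = 0; t < n_perm; ++t) {
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    int j = i;
    while (j == i) {
      j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
    }
    for (int s = 0; s < N; ++s) perm[s] = rows[j][s];
    for (int s = N - 1; s > 0; --s) {  // Fisher-Yates
      int r = (int)(unif_rand() * (s + 1));
      if (r > s) r = s;
      std::swap(perm[s], perm[r]);
    }
    out[t] = apmi_one(rows[i].data(), perm.data(), N, chi2_crit, min_points);
    if (t % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return out;
}
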