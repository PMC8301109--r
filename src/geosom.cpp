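#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of Geo-SOM training. Samples arrive transposed (variables x
// samples) so each sample is a contiguous column; weights are kept
// transposed the same way (variables x nodes).

// lattice distance between nodes a and b (0-based indices),
// Chebyshev on the rectangular lattice, cube distance on the hexagonal
// (odd-r offset) lattice
static inline int lattice_dist(const int* rows, const int* cols, int a,
                               int b, bool hex) {
  int ra = rows[a], ca = cols[a];
  int rb = rows[b], cb = cols[b];
  if (!hex) {
    int dr = std::abs(ra - rb), dc = std::abs(ca - cb);
    return dr > dc ? dr : dc;
  }
  int qa = ca - (ra - (ra & 1)) / 2;
  int qb = cb - (rb - (rb & 1)) / 2;
  int dq = qa - qb, dr = ra - rb;
  int ds = -dq - dr;
  int ad = std::abs(dq), adr = std::abs(dr), ads = std::abs(ds);
  int m = ad > adr ? ad : adr;
  return m > ads ? m : ads;
}

// two-phase geographically tolerant BMU search for the sample at column
// `x` (length p); Wt is p x n (column per node); ties break low index
static int find_bmu_one(const double* Wt, int n, int p, const double* x,
                        const int* geo, int ng, const int* rows,
                        const int* cols, int k, bool hex) {
  int geo_winner = 0;
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    const double* w = Wt + (size_t)i * p;
    double d = 0.0;
    for (int j = 0; j < ng; ++j) {
      double diff = x[geo[j]] - w[geo[j]];
      d += diff * diff;
    }
    if (d < best) { best = d; geo_winner = i; }
  }
  int bmu = -1;
  best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (lattice_dist(rows, cols, i, geo_winner, hex) > k) continue;
    const double* w = Wt + (size_t)i * p;
    double d = 0.0;
    for (int j = 0; j < p; ++j) {
      double diff = x[j] - w[j];
      d += diff * diff;
    }
    if (d < best) { best = d; bmu = i; }
  }
  return bmu;
}

// [[Rcpp::export]]
IntegerVector cpp_bmu_map(const NumericMatrix& Wt,
                          const IntegerVector& node_row,
                          const IntegerVector& node_col,
                          const NumericMatrix& Xt,
                          const IntegerVector& geo_idx, int k, bool hex) {
  int n = Wt.ncol(), p = Wt.nrow(), ns = Xt.ncol();
  IntegerVector out(ns);
  for (int s = 0; s < ns; ++s) {
    out[s] = find_bmu_one(&Wt(0, 0), n, p, &Xt(0, s), &geo_idx[0],
                          geo_idx.size(), &node_row[0], &node_col[0],
                          k, hex) + 1;  // 1-based
  }
  return out;
}

// one full sequential training pass: for each sample (in the given
// 0-based order) find the geo-tolerant BMU and apply the bubble update
//   w <- w + eta * (x - w)  for nodes within `radius` of the BMU
// [[Rcpp::export]]
NumericMatrix cpp_som_pass(const NumericMatrix& Wt_in,
                           const IntegerVector& node_row,
                           const IntegerVector& node_col,
                           const NumericMatrix& Xt,
                           const IntegerVector& order0,
                           const IntegerVector& geo_idx,
                           int k, double eta, double radius, bool hex) {
  NumericMatrix Wt = clone(Wt_in);
  int n = Wt.ncol(), p = Wt.nrow();
  double* W = &Wt(0, 0);
  const int* rows = &node_row[0];
  const int* cols = &node_col[0];
  int irad = (int)std::floor(radius);
  for (int t = 0; t < order0.size(); ++t) {
    const double* x = &Xt(0, order0[t]);
    int bmu = find_bmu_one(W, n, p, x, &geo_idx[0], geo_idx.size(),
                           rows, cols, k, hex);
    for (int i = 0; i < n; ++i) {
      if (lattice_dist(rows, cols, i, bmu, hex) > irad) continue;
      double* w = W + (size_t)i * p;
      for (int j = 0; j < p; ++j) {
        w[j] += eta * (x[j] - w[j]);
      }
    }
  }
  return Wt;
}

// mean over samples of sqrt(summed squared distance to the BMU)
// [[Rcpp::export]]
double cpp_quantization_error(const NumericMatrix& Wt,
                              const IntegerVector& node_row,
                              const IntegerVector& node_col,
                              const NumericMatrix& Xt,
                              const IntegerVector& geo_idx, int k,
                              bool hex) {
  int n = Wt.ncol(), p = Wt.nrow(), ns = Xt.ncol();
  if (ns == 0) return 0.0;
  const double* W = &Wt(0, 0);
  double total = 0.0;
  for (int s = 0; s < ns; ++s) {
    const double* x = &Xt(0, s);
    int bmu = find_bmu_one(W, n, p, x, &geo_idx[0], geo_idx.size(),
                           &node_row[0], &node_col[0], k, hex);
    const double* w = W + (size_t)bmu * p;
    double d = 0.0;
    for (int j = 0; j < p; ++j) {
      double diff = x[j] - w[j];
      d += diff * diff;
    }
    total += std::sqrt(d);
  }
  return total / ns;
}
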