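#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimum Euclidean distance from each query point to any atom, plus the
// index (1-based) of the nearest atom. Brute force; both inputs are n x 3.
// [[Rcpp::export]]
List cpp_min_dist(NumericMatrix pts, NumericMatrix atoms) {
  const int n = pts.nrow(), m = atoms.nrow();
  NumericVector dist(n);
  IntegerVector nearest(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - atoms(j, 0);
      const double dy = py - atoms(j, 1);
      const double dz = pz - atoms(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; arg = j; }
    }
    dist[i] = std::sqrt(best);
    nearest[i] = arg + 1;
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

// Accumulate per-atom sums of Gaussians onto a voxel lattice.
// coords: n x 3 atom positions (Angstrom).
// pref, expo: n x 5 matrices; the contribution of atom a at squared
// distance r2 is sum_i pref(a,i) * exp(-expo(a,i) * r2), truncated at
// r > cutoff (inclusive at exactly cutoff).
// origin: centre of voxel (1,1,1); spacing/dim: per-axis.
// [[Rcpp::export]]
NumericVector cpp_scatter_density(NumericMatrix coords,
                                  NumericMatrix pref, NumericMatrix expo,
                                  NumericVector origin, NumericVector spacing,
                                  IntegerVector dim, double cutoff) {
  const int n = coords.nrow();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double c2 = cutoff * cutoff;
  for (int a = 0; a < n; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    // voxel index window covering the cutoff sphere
    int i0 = (int)std::ceil((ax - cutoff - origin[0]) / spacing[0]);
    int i1 = (int)std::floor((ax + cutoff - origin[0]) / spacing[0]);
    int j0 = (int)std::ceil((ay - cutoff - origin[1]) / spacing[1]);
    int j1 = (int)std::floor((ay + cutoff - origin[1]) / spacing[1]);
    int k0 = (int)std::ceil((az - cutoff - origin[2]) / spacing[2]);
    int k1 = (int)std::floor((az + cutoff - origin[2]) / spacing[2]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing[2] - az;
      const double dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing[1] - ay;
        const double dyz2 = dy * dy + dz2;
        if (dyz2 > c2) continue;
        const R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing[0] - ax;
          const double r2 = dx * dx + dyz2;
          if (r2 > c2) continue;
          double v = 0.0;
          for (int g = 0; g < 5; ++g)
            v += pref(a, g) * std::exp(-expo(a, g) * r2);
          out[base + i] += v;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Kraskov-Stoegbauer-Grassberger estimator 1 of mutual information between
// two scalar samples (max-norm in the joint space, k-th neighbour excluding
// self; marginal counts strictly inside the k-th neighbour distance).
// Ties should be broken upstream by a tiny jitter. Returns nats, clipped at 0.
// [[Rcpp::export]]
double cpp_ksg_mi(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (n <= k + 1) stop("need more than k + 1 samples");
  std::vector<double> eps(n);
  std::vector<double> knnd(k);
  for (int i = 0; i < n; ++i) {
    // distances to all others under the Chebyshev (max) metric
    int filled = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double d = std::max(std::fabs(x[i] - x[j]), std::fabs(y[i] - y[j]));
      if (filled < k) {
        knnd[filled++] = d;
        if (filled == k) std::make_heap(knnd.begin(), knnd.end());
      } else if (d < knnd[0]) {
        std::pop_heap(knnd.begin(), knnd.end());
        knnd[k - 1] = d;
        std::push_heap(knnd.begin(), knnd.end());
      }
    }
    eps[i] = knnd[0]; // k-th smallest
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[i] - x[j]) < eps[i]) ++nx;
      if (std::fabs(y[i] - y[j]) < eps[i]) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi > 0.0 ? mi : 0.0;
}
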