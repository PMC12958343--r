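#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

// Residue-residue contact matrix between two bodies.
// A, B: atom coordinate matrices (nAtoms x 3), resA/resB: 1-based atom->residue
// maps, L: cubic box edge (<=0 disables periodic wrap), cutoff: strict "<".
// [[Rcpp::export]]
LogicalMatrix residue_contact_cpp(NumericMatrix A, NumericMatrix B,
                                  IntegerVector resA, IntegerVector resB,
                                  int nResA, int nResB,
                                  double L, double cutoff) {
  const int na = A.nrow(), nb = B.nrow();
  const double cut2 = cutoff * cutoff;
  LogicalMatrix M(nResA, nResB);
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    const int ri = resA[i] - 1;
    for (int j = 0; j < nb; ++j) {
      const int rj = resB[j] - 1;
      if (M(ri, rj)) continue;
      const double dx = min_image(ax - B(j, 0), L);
      const double dy = min_image(ay - B(j, 1), L);
      const double dz = min_image(az - B(j, 2), L);
      if (dx * dx + dy * dy + dz * dz < cut2) M(ri, rj) = true;
    }
  }
  return M;
}

// Overall minimum-image distance between any atom of A and any atom of B.
// [[Rcpp::export]]
double min_interbody_dist_cpp(NumericMatrix A, NumericMatrix B, double L) {
  const int na = A.nrow(), nb = B.nrow();
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = min_image(ax - B(j, 0), L);
      const double dy = min_image(ay - B(j, 1), L);
      const double dz = min_image(az - B(j, 2), L);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Shrake-Rupley solvent-accessible surface area, per atom.
// Test points are a deterministic golden-section spiral on the unit sphere.
// [[Rcpp::export]]
NumericVector shrake_rupley_cpp(NumericMatrix X, NumericVector radii,
                                double probe, int n_points) {
  const int n = X.nrow();
  // golden-spiral sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }
  NumericVector area(n);
  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double Rj = radii[j] + probe;
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double dz = X(i, 2) - X(j, 2);
      if (dx * dx + dy * dy + dz * dz < (Ri + Rj) * (Ri + Rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double sx = X(i, 0) + Ri * px[k];
      const double sy = X(i, 1) + Ri * py[k];
      const double sz = X(i, 2) + Ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double Rj = radii[j] + probe;
        const double dx = sx - X(j, 0);
        const double dy = sy - X(j, 1);
        const double dz = sz - X(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * acc / n_points;
  }
  return area;
}
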