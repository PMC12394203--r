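#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley point test: per-atom accessible area given expanded radii
// (van der Waals + probe) and a fixed unit-sphere point set.
// [[Rcpp::export]]
NumericVector sasa_points_cpp(NumericMatrix xyz, NumericVector r,
                              NumericMatrix pts) {
  const int n = xyz.nrow();
  const int np = pts.nrow();
  NumericVector area(n);
  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double lim = r[i] + r[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      double px = xyz(i, 0) + r[i] * pts(p, 0);
      double py = xyz(i, 1) + r[i] * pts(p, 1);
      double pz = xyz(i, 2) + r[i] * pts(p, 2);
      bool free_pt = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < r[j] * r[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * r[i] * r[i] * acc / np;
  }
  return area;
}
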