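#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Cell-list search for inter-set atom pairs closer than `threshold`.
// Contractually identical to the all-pairs computation: every (a, b) pair
// with (minimum-image, if use_pbc) Euclidean distance strictly below the
// threshold is returned exactly once.
//
// a, b: (n x 3) coordinate matrices in Angstrom. box: 3 edge lengths.
// With use_pbc the cell grid spans the box with cells no smaller than the
// threshold; per-axis minimum-image separation is valid because the
// threshold is required to be <= half the shortest box edge.

static inline double wrap0(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L;
  if (w < 0) w = 0;
  return w;
}

// [[Rcpp::export]]
List contact_pairs_cell(NumericMatrix a, NumericMatrix b, NumericVector box,
                        double threshold, bool use_pbc) {
  const int na = a.nrow(), nb = b.nrow();
  if (threshold <= 0) stop("threshold must be > 0");
  for (int d = 0; d < 3; ++d) {
    if (!(box[d] > 0) || !std::isfinite(box[d])) stop("box lengths must be finite and > 0");
  }
  if (use_pbc) {
    double half = std::min(box[0], std::min(box[1], box[2])) / 2.0;
    if (threshold > half)
      stop("contact threshold exceeds half the shortest box edge; per-axis minimum image is invalid");
  }
  for (int i = 0; i < na; ++i)
    for (int d = 0; d < 3; ++d)
      if (!std::isfinite(a(i, d))) stop("non-finite coordinate");
  for (int i = 0; i < nb; ++i)
    for (int d = 0; d < 3; ++d)
      if (!std::isfinite(b(i, d))) stop("non-finite coordinate");

  // Grid origin/extent: the box itself under PBC, else the bounding box of
  // both sets (padded so every atom bins in range).
  double lo[3], span[3];
  int ncell[3];
  for (int d = 0; d < 3; ++d) {
    if (use_pbc) {
      lo[d] = 0.0;
      span[d] = box[d];
    } else {
      double mn = R_PosInf, mx = R_NegInf;
      for (int i = 0; i < na; ++i) { mn = std::min(mn, a(i, d)); mx = std::max(mx, a(i, d)); }
      for (int i = 0; i < nb; ++i) { mn = std::min(mn, b(i, d)); mx = std::max(mx, b(i, d)); }
      if (na + nb == 0) { mn = 0; mx = 1; }
      lo[d] = mn;
      span[d] = std::max(mx - mn, 1e-9);
    }
    ncell[d] = std::max(1, (int)std::floor(span[d] / threshold));
  }

  std::vector<int> head((size_t)ncell[0] * ncell[1] * ncell[2], -1);
  std::vector<int> nxt(nb, -1);
  std::vector<int> cb(3 * (size_t)std::max(nb, 1));

  auto cell_of = [&](double x, int d) {
    double xx = use_pbc ? wrap0(x - lo[d], span[d]) : (x - lo[d]);
    int c = (int)std::floor(xx / span[d] * ncell[d]);
    if (c >= ncell[d]) c = ncell[d] - 1;
    if (c < 0) c = 0;
    return c;
  };

  for (int j = 0; j < nb; ++j) {
    int cx = cell_of(b(j, 0), 0), cy = cell_of(b(j, 1), 1), cz = cell_of(b(j, 2), 2);
    cb[3 * j] = cx; cb[3 * j + 1] = cy; cb[3 * j + 2] = cz;
    size_t idx = ((size_t)cx * ncell[1] + cy) * ncell[2] + cz;
    nxt[j] = head[idx];
    head[idx] = j;
  }

  // Unique neighbor cell indices per axis (wrapping can alias when a grid
  // axis has fewer than 3 cells).
  auto neighbors = [&](int c, int d, std::vector<int> &out) {
    out.clear();
    for (int o = -1; o <= 1; ++o) {
      int v = c + o;
      if (use_pbc) {
        v = (v % ncell[d] + ncell[d]) % ncell[d];
      } else {
        if (v < 0 || v >= ncell[d]) continue;
      }
      if (std::find(out.begin(), out.end(), v) == out.end()) out.push_back(v);
    }
  };

  const double t2 = threshold * threshold;
  std::vector<int> pi, pj;
  std::vector<double> pd;
  std::vector<int> nx, ny, nz;

  for (int i = 0; i < na; ++i) {
    int cx = cell_of(a(i, 0), 0), cy = cell_of(a(i, 1), 1), cz = cell_of(a(i, 2), 2);
    neighbors(cx, 0, nx); neighbors(cy, 1, ny); neighbors(cz, 2, nz);
    for (int ux : nx) for (int uy : ny) for (int uz : nz) {
      size_t idx = ((size_t)ux * ncell[1] + uy) * ncell[2] + uz;
      for (int j = head[idx]; j != -1; j = nxt[j]) {
        double d2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          double dx = a(i, d) - b(j, d);
          if (use_pbc) dx -= box[d] * std::nearbyint(dx / box[d]);
          d2 += dx * dx;
        }
        if (d2 < t2) {
          pi.push_back(i + 1);
          pj.push_back(j + 1);
          pd.push_back(std::sqrt(d2));
        }
      }
    }
  }

  return List::create(
    _["i"] = wrap(pi), _["j"] = wrap(pj), _["distance"] = wrap(pd)
  );
}
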