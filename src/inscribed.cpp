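#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// f: squared distances along one dimension; returns lower envelope of parabolas.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance from every cell of an (nr x nc) grid to the nearest
// obstacle cell, where the grid is surrounded by a virtual ring of obstacles
// one pixel outside the frame. obstacle: 1 = obstacle, 0 = free.
static void dist_sq_grid(const std::vector<int>& obstacle, int nr, int nc,
                         std::vector<double>& out) {
  const double INF = 1e18;
  // pad by 1 on each side with obstacles
  int pr = nr + 2, pc = nc + 2;
  std::vector<double> g(pr * pc);
  for (int j = 0; j < pc; ++j)
    for (int i = 0; i < pr; ++i) {
      bool ring = (i == 0 || j == 0 || i == pr - 1 || j == pc - 1);
      bool obs = ring ? true : obstacle[(size_t)(i - 1) + (size_t)nr * (j - 1)] != 0;
      g[(size_t)i + (size_t)pr * j] = obs ? 0.0 : INF;
    }
  std::vector<double> f(std::max(pr, pc)), d(std::max(pr, pc));
  // transform along columns (vary row index)
  for (int j = 0; j < pc; ++j) {
    for (int i = 0; i < pr; ++i) f[i] = g[(size_t)i + (size_t)pr * j];
    dt1d(f, d, pr);
    for (int i = 0; i < pr; ++i) g[(size_t)i + (size_t)pr * j] = d[i];
  }
  // transform along rows (vary column index)
  for (int i = 0; i < pr; ++i) {
    for (int j = 0; j < pc; ++j) f[j] = g[(size_t)i + (size_t)pr * j];
    dt1d(f, d, pc);
    for (int j = 0; j < pc; ++j) g[(size_t)i + (size_t)pr * j] = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out[(size_t)i + (size_t)nr * j] = g[(size_t)(i + 1) + (size_t)pr * (j + 1)];
}

//' Squared-distance transform of a binary grid (internal)
//'
//' @param obstacle integer matrix, 1 = obstacle, 0 = free; the frame border
//'   acts as an obstacle ring one pixel outside the image.
//' @return numeric matrix of squared Euclidean distances between pixel
//'   centers to the nearest obstacle (virtual ring included).
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix dist_sq_transform(IntegerMatrix obstacle) {
  int nr = obstacle.nrow(), nc = obstacle.ncol();
  std::vector<int> obs(obstacle.begin(), obstacle.end());
  std::vector<double> out((size_t)nr * nc);
  dist_sq_grid(obs, nr, nc, out);
  NumericMatrix res(nr, nc);
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

//' Greedy maximum-inscribed-circle sequence (internal)
//'
//' Repeatedly places the largest circle that fits in the free region
//' (obstacles and the frame border excluded), removes the covered pixels
//' (strictly inside the circle; tangency allowed), and loops until the next
//' circle's diameter falls below \code{stop_diameter}. Ties in the distance
//' maximum are broken by the smallest (row, col).
//'
//' @param free integer matrix, 1 = free region, 0 = obstacle.
//' @param stop_diameter stop when the largest remaining diameter is below
//'   this value (pixels).
//' @return matrix with columns row, col (1-based centers) and diameter (px).
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix max_inscribed_circles_cpp(IntegerMatrix free_region, double stop_diameter) {
  int nr = free_region.nrow(), nc = free_region.ncol();
  size_t n = (size_t)nr * nc;
  std::vector<int> obstacle(n);
  for (size_t k = 0; k < n; ++k) obstacle[k] = free_region[k] != 0 ? 0 : 1;
  std::vector<double> dsq(n);
  dist_sq_grid(obstacle, nr, nc, dsq);
  std::vector<double> rows, cols, diams;
  const double INF = 1e18;
  std::vector<double> loc, f, d;
  for (;;) {
    double best = -1.0;
    int bi = -1, bj = -1;
    // lexicographic (row, col) tie-break: scan rows outer, cols inner
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        size_t k = (size_t)i + (size_t)nr * j;
        if (obstacle[k]) continue;
        if (dsq[k] > best) { best = dsq[k]; bi = i; bj = j; }
      }
    if (bi < 0) break;                 // no free pixel left
    double diam = 2.0 * std::sqrt(best);
    if (diam < stop_diameter) break;
    rows.push_back(bi + 1);
    cols.push_back(bj + 1);
    diams.push_back(diam);
    // remove pixels strictly inside the circle; they become obstacles so
    // later circles may touch but not overlap this one
    double r = std::sqrt(best);
    int rad = (int)std::ceil(r);
    for (int i = std::max(0, bi - rad); i <= std::min(nr - 1, bi + rad); ++i)
      for (int j = std::max(0, bj - rad); j <= std::min(nc - 1, bj + rad); ++j) {
        double dd = (i - (double)bi) * (i - (double)bi) + (j - (double)bj) * (j - (double)bj);
        if (dd < best) obstacle[(size_t)i + (size_t)nr * j] = 1;
      }
    // incremental distance update: the new obstacles are the removed disk's
    // pixels; since dsq <= best everywhere (the circle was the global max),
    // distances can only change within 2r of the center.  Run a local
    // transform seeded by the removed pixels on that window and take the
    // pointwise minimum with the existing field.
    int R = (int)std::ceil(2.0 * r) + 1;
    int i0 = std::max(0, bi - R), i1 = std::min(nr - 1, bi + R);
    int j0 = std::max(0, bj - R), j1 = std::min(nc - 1, bj + R);
    int wr = i1 - i0 + 1, wc = j1 - j0 + 1;
    loc.assign((size_t)wr * wc, INF);
    for (int i = std::max(i0, bi - rad); i <= std::min(i1, bi + rad); ++i)
      for (int j = std::max(j0, bj - rad); j <= std::min(j1, bj + rad); ++j) {
        double dd = (i - (double)bi) * (i - (double)bi) + (j - (double)bj) * (j - (double)bj);
        if (dd < best) loc[(size_t)(i - i0) + (size_t)wr * (j - j0)] = 0.0;
      }
    int m = std::max(wr, wc);
    f.resize(m); d.resize(m);
    for (int j = 0; j < wc; ++j) {
      for (int i = 0; i < wr; ++i) f[i] = loc[(size_t)i + (size_t)wr * j];
      dt1d(f, d, wr);
      for (int i = 0; i < wr; ++i) loc[(size_t)i + (size_t)wr * j] = d[i];
    }
    for (int i = 0; i < wr; ++i) {
      for (int j = 0; j < wc; ++j) f[j] = loc[(size_t)i + (size_t)wr * j];
      dt1d(f, d, wc);
      for (int j = 0; j < wc; ++j) loc[(size_t)i + (size_t)wr * j] = d[j];
    }
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j) {
        size_t k = (size_t)i + (size_t)nr * j;
        double v = loc[(size_t)(i - i0) + (size_t)wr * (j - j0)];
        if (v < dsq[k]) dsq[k] = v;
      }
  }
  NumericMatrix out(rows.size(), 3);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k];
    out(k, 1) = cols[k];
    out(k, 2) = diams[k];
  }
  colnames(out) = CharacterVector::create("row", "col", "diameter");
  return out;
}

//' Connected-component labeling with 8-connectivity (internal)
//'
//' @param mask integer matrix, non-zero = foreground.
//' @return integer matrix of labels (0 = background), labeled in raster order.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int a = p.first + di, b = p.second + dj;
            if (a < 0 || b < 0 || a >= nr || b >= nc) continue;
            if (mask(a, b) != 0 && lab(a, b) == 0) {
              lab(a, b) = next;
              stack.push_back(std::make_pair(a, b));
            }
          }
      }
    }
  return lab;
}
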