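#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// Labels are renumbered 1..n in row-major order of first occurrence,
// so the result is deterministic for a given mask.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  // pass 1: row-major scan (by row), look at already-visited neighbours
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int best = 0;
      int neigh[4][2] = {{i, j - 1}, {i - 1, j}, {i - 1, j - 1}, {i - 1, j + 1}};
      int nn = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < nn; ++k) {
        int r = neigh[k][0], c = neigh[k][1];
        if (r < 0 || c < 0 || c >= nc) continue;
        int l = lab(r, c);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
      }
    }
  }

  // pass 2: resolve + renumber by first occurrence
  std::vector<int> renum(next, 0);
  int nlab = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (lab(i, j) > 0) {
        int r = uf_find(parent, lab(i, j));
        if (renum[r] == 0) renum[r] = ++nlab;
        lab(i, j) = renum[r];
      }
  lab.attr("n_objects") = nlab;
  return lab;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance from every pixel to the nearest TRUE pixel of `mask`,
// in pixel units. Returns +Inf everywhere if the mask is empty.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix distance_to_mask_cpp(LogicalMatrix mask) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);

  // column pass: 1D distance (in rows) to the nearest mask pixel of the
  // column, via forward/backward scans; squared for the row pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    double dist = INF;
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j)) dist = 0; else if (dist < INF) dist += 1;
      out(i, j) = dist;
    }
    dist = INF;
    for (int i = nr - 1; i >= 0; --i) {
      if (mask(i, j)) dist = 0; else if (dist < INF) dist += 1;
      if (dist < out(i, j)) out(i, j) = dist;
    }
    for (int i = 0; i < nr; ++i)
      if (out(i, j) < INF) out(i, j) = out(i, j) * out(i, j);
  }
  // row pass (squared distances propagate even through Inf columns)
  for (int i = 0; i < nr; ++i) {
    bool allinf = true;
    for (int j = 0; j < nc; ++j) {
      f[j] = out(i, j);
      if (f[j] < INF) allinf = false;
    }
    if (allinf) continue;
    // dt1d assumes finite parabola roots; replace Inf by a huge finite value
    double big = 1e30;
    for (int j = 0; j < nc; ++j) if (f[j] == INF) f[j] = big;
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j] >= big ? INF : d[j];
  }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (out(i, j) < INF) out(i, j) = std::sqrt(out(i, j));
  return out;
}
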