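#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---- convolution support -------------------------------------------------
// Images are R arrays dim c(H, W, C), column-major. im2col rows follow the
// output grid in column-major order (row index fastest); columns are ordered
// (ki, kj, c) with ki fastest. Zero padding.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  const double *px = x.begin();
  double *po = out.begin();
  int nrow = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + kj * k + c * k * k;
        double *dst = po + (R_xlen_t)col * nrow;
        for (int jo = 0; jo < Wo; ++jo) {
          int jin = jo * stride - pad + kj;
          bool jok = (jin >= 0 && jin < W);
          const double *src = px + (R_xlen_t)c * H * W + (R_xlen_t)jin * H;
          for (int io = 0; io < Ho; ++io) {
            int iin = io * stride - pad + ki;
            double v = 0.0;
            if (jok && iin >= 0 && iin < H) v = src[iin];
            dst[io + jo * Ho] = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)H * W * C);
  const double *pc = cols.begin();
  double *po = out.begin();
  int nrow = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + kj * k + c * k * k;
        const double *src = pc + (R_xlen_t)col * nrow;
        for (int jo = 0; jo < Wo; ++jo) {
          int jin = jo * stride - pad + kj;
          if (jin < 0 || jin >= W) continue;
          double *dst = po + (R_xlen_t)c * H * W + (R_xlen_t)jin * H;
          for (int io = 0; io < Ho; ++io) {
            int iin = io * stride - pad + ki;
            if (iin < 0 || iin >= H) continue;
            dst[iin] += src[io + jo * Ho];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// ---- connected components (union-find, 4- or 8-connectivity) -------------

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int cur = 0;
      // scan previously-visited neighbours (column-major order)
      int di[4] = {-1, -1, 0, 1};
      int dj[4] = {0, -1, -1, -1};
      int nn = (connectivity == 8) ? 4 : 2;
      int use[4] = {0, 1, 2, 3};
      if (connectivity != 8) { use[0] = 0; use[1] = 2; }
      for (int t = 0; t < nn; ++t) {
        int ii = i + di[use[t]], jj = j + dj[use[t]];
        if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
        int l = lab(ii, jj);
        if (l) {
          if (!cur) cur = l; else unite(cur, l);
        }
      }
      if (!cur) { cur = ++next; parent.push_back(cur); }
      lab(i, j) = cur;
    }
  }
  // flatten and relabel densely in scan order
  std::vector<int> remap(next + 1, 0);
  int out = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j)) {
        int r = find(lab(i, j));
        if (!remap[r]) remap[r] = ++out;
        lab(i, j) = remap[r];
      }
  return lab;
}

// ---- Zhang-Suen thinning -------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int, int>> kill;
  bool changed = true;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= H || j >= W) return 0;
    return img(i, j) ? 1 : 0;
  };
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!img(i, j)) continue;
          int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int ring[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int t = 0; t < 8; ++t) if (ring[t] == 0 && ring[t + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t) img(kill[t].first, kill[t].second) = 0;
    }
  }
  return img;
}

// ---- gray-level co-occurrence statistics ---------------------------------
// Symmetric GLCM at 1-px offset for 4 orientations (0, 45, 90, 135 degrees),
// statistics averaged across orientations. gray holds levels 0..L-1; cells
// with level < 0 are ignored (outside the object).

// [[Rcpp::export]]
NumericVector glcm_stats_cpp(IntegerMatrix gray, int L) {
  int H = gray.nrow(), W = gray.ncol();
  int off[4][2] = { {0, 1}, {-1, 1}, {-1, 0}, {-1, -1} };
  double contrast = 0, correlation = 0, energy = 0, homogeneity = 0;
  int used = 0;
  std::vector<double> P((size_t)L * L);
  for (int o = 0; o < 4; ++o) {
    std::fill(P.begin(), P.end(), 0.0);
    double n = 0;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int a = gray(i, j);
        if (a < 0) continue;
        int ii = i + off[o][0], jj = j + off[o][1];
        if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
        int b = gray(ii, jj);
        if (b < 0) continue;
        P[(size_t)a * L + b] += 1; P[(size_t)b * L + a] += 1; n += 2;
      }
    }
    if (n == 0) continue;
    ++used;
    double con = 0, ene = 0, hom = 0, mi = 0, vi = 0;
    for (int a = 0; a < L; ++a)
      for (int b = 0; b < L; ++b) {
        double p = P[(size_t)a * L + b] / n;
        con += p * (a - b) * (a - b);
        ene += p * p;
        hom += p / (1.0 + std::abs(a - b));
      }
    for (int a = 0; a < L; ++a) {
      double pa = 0;
      for (int b = 0; b < L; ++b) pa += P[(size_t)a * L + b] / n;
      mi += a * pa;
    }
    for (int a = 0; a < L; ++a) {
      double pa = 0;
      for (int b = 0; b < L; ++b) pa += P[(size_t)a * L + b] / n;
      vi += (a - mi) * (a - mi) * pa;
    }
    double cor = 0;
    if (vi > 1e-12) {
      for (int a = 0; a < L; ++a)
        for (int b = 0; b < L; ++b) {
          double p = P[(size_t)a * L + b] / n;
          cor += p * (a - mi) * (b - mi);
        }
      cor /= vi;
    } else {
      cor = 1.0; // constant image: perfectly correlated by convention
    }
    contrast += con; correlation += cor; energy += ene; homogeneity += hom;
  }
  if (used == 0) return NumericVector::create(0.0, 0.0, 0.0, 0.0);
  return NumericVector::create(contrast / used, correlation / used,
                               energy / used, homogeneity / used);
}

// ---- random forest (gini CART, bootstrap, sqrt mtry) ---------------------

struct Tree {
  std::vector<int> feat, left, right, pred;
  std::vector<double> thr;
};

static void grow_node(const NumericMatrix &X, const IntegerVector &y, int K,
                      std::vector<int> &idx, int lo, int hi, int depth,
                      int mtry, int min_split, int max_depth, Tree &T) {
  int node = (int)T.feat.size();
  T.feat.push_back(-1); T.thr.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1); T.pred.push_back(0);
  std::vector<double> cnt(K, 0.0);
  for (int t = lo; t < hi; ++t) cnt[y[idx[t]]] += 1;
  int best_c = 0; double best_n = -1;
  for (int c = 0; c < K; ++c) if (cnt[c] > best_n) { best_n = cnt[c]; best_c = c; }
  T.pred[node] = best_c;
  int n = hi - lo;
  double imp = 1.0;
  for (int c = 0; c < K; ++c) imp -= (cnt[c] / n) * (cnt[c] / n);
  if (n < min_split || depth >= max_depth || imp <= 1e-12) return;

  int p = X.ncol();
  double best_gain = 1e-12; int bf = -1; double bt = 0;
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  // partial Fisher-Yates with R RNG
  for (int t = 0; t < mtry && t < p; ++t) {
    int r = t + (int)std::floor(unif_rand() * (p - t));
    if (r >= p) r = p - 1;
    std::swap(feats[t], feats[r]);
  }
  std::vector<std::pair<double, int>> v(n);
  std::vector<double> lc(K);
  for (int t = 0; t < std::min(mtry, p); ++t) {
    int f = feats[t];
    for (int q = 0; q < n; ++q) v[q] = std::make_pair(X(idx[lo + q], f), y[idx[lo + q]]);
    std::sort(v.begin(), v.end());
    std::fill(lc.begin(), lc.end(), 0.0);
    double parent = 0;
    for (int c = 0; c < K; ++c) parent += cnt[c] * cnt[c];
    parent /= n;
    for (int q = 0; q < n - 1; ++q) {
      lc[v[q].second] += 1;
      if (v[q].first == v[q + 1].first) continue;
      int nl = q + 1, nr = n - nl;
      double sl = 0, sr = 0;
      for (int c = 0; c < K; ++c) {
        sl += lc[c] * lc[c];
        double rcnt = cnt[c] - lc[c];
        sr += rcnt * rcnt;
      }
      double gain = sl / nl + sr / nr - parent;
      if (gain > best_gain) {
        best_gain = gain; bf = f; bt = 0.5 * (v[q].first + v[q + 1].first);
      }
    }
  }
  if (bf < 0) return;
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], bf) <= bt) std::swap(idx[mid++], idx[t]);
  if (mid == lo || mid == hi) return;
  T.feat[node] = bf; T.thr[node] = bt;
  T.left[node] = (int)T.feat.size();
  grow_node(X, y, K, idx, lo, mid, depth + 1, mtry, min_split, max_depth, T);
  T.right[node] = (int)T.feat.size();
  grow_node(X, y, K, idx, mid, hi, depth + 1, mtry, min_split, max_depth, T);
}

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int K, int ntree,
                  int mtry, int min_split, int max_depth) {
  int n = X.nrow();
  List forest(ntree);
  RNGScope scope;
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) {
      int r = (int)std::floor(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[t] = r;
    }
    Tree T;
    grow_node(X, y, K, idx, 0, n, 0, mtry, min_split, max_depth, T);
    forest[b] = List::create(_["feat"] = wrap(T.feat), _["thr"] = wrap(T.thr),
                             _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                             _["pred"] = wrap(T.pred));
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X, int K) {
  int n = X.nrow(), B = forest.size();
  NumericMatrix votes(n, K);
  for (int b = 0; b < B; ++b) {
    List T = forest[b];
    IntegerVector feat = T["feat"], left = T["left"], right = T["right"],
                  pred = T["pred"];
    NumericVector thr = T["thr"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      votes(i, pred[node]) += 1.0;
    }
  }
  votes = votes / (double)B;
  return votes;
}

// ---- misc raster helpers -------------------------------------------------

// mean box filter with window w (odd not required); edges renormalised.
// [[Rcpp::export]]
NumericMatrix box_mean_cpp(NumericMatrix x, int w) {
  int H = x.nrow(), W = x.ncol();
  // integral image
  std::vector<double> S((size_t)(H + 1) * (W + 1), 0.0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      S[(size_t)(i + 1) + (size_t)(j + 1) * (H + 1)] =
        x(i, j) + S[(size_t)i + (size_t)(j + 1) * (H + 1)] +
        S[(size_t)(i + 1) + (size_t)j * (H + 1)] -
        S[(size_t)i + (size_t)j * (H + 1)];
  NumericMatrix out(H, W);
  int h0 = w / 2, h1 = w - 1 - w / 2;
  for (int j = 0; j < W; ++j) {
    int j0 = std::max(0, j - h0), j1 = std::min(W - 1, j + h1);
    for (int i = 0; i < H; ++i) {
      int i0 = std::max(0, i - h0), i1 = std::min(H - 1, i + h1);
      double s = S[(size_t)(i1 + 1) + (size_t)(j1 + 1) * (H + 1)] -
                 S[(size_t)i0 + (size_t)(j1 + 1) * (H + 1)] -
                 S[(size_t)(i1 + 1) + (size_t)j0 * (H + 1)] +
                 S[(size_t)i0 + (size_t)j0 * (H + 1)];
      out(i, j) = s / ((double)(i1 - i0 + 1) * (j1 - j0 + 1));
    }
  }
  return out;
}

// geodesic BFS over a skeleton: returns distances from (si, sj) (0-based),
// -1 for unreachable/non-skeleton. 8-connected unit steps are weighted 1
// for axial and sqrt(2) for diagonal moves (Dijkstra on the pixel graph).
// [[Rcpp::export]]
List skel_geodesic_cpp(IntegerMatrix skel, int si, int sj) {
  int H = skel.nrow(), W = skel.ncol();
  NumericMatrix dist(H, W);
  IntegerMatrix prev(H, W);
  std::fill(dist.begin(), dist.end(), -1.0);
  std::fill(prev.begin(), prev.end(), -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist(si, sj) = 0.0;
  pq.push(std::make_pair(0.0, si + sj * H));
  int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int idx = top.second, i = idx % H, j = idx / H;
    if (top.first > dist(i, j) + 1e-9) continue;
    for (int t = 0; t < 8; ++t) {
      int ii = i + di[t], jj = j + dj[t];
      if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
      if (!skel(ii, jj)) continue;
      double w = (di[t] && dj[t]) ? 1.4142135623730951 : 1.0;
      double nd = top.first + w;
      if (dist(ii, jj) < 0 || nd < dist(ii, jj) - 1e-9) {
        dist(ii, jj) = nd;
        prev(ii, jj) = idx;
        pq.push(std::make_pair(nd, ii + jj * H));
      }
    }
  }
  return List::create(_["dist"] = dist, _["prev"] = prev);
}
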