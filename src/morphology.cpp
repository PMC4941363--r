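// Pixel-level operators for the segmentation chain.
//
// Conventions shared with the R layer and documented in the package:
//  - images are base R numeric matrices, (row, col), column-major;
//  - grayscale erosion/dilation use a flat disc {(dr,dc): dr^2+dc^2 <= r^2},
//    pixels outside the image act as +Inf (erosion) / -Inf (dilation);
//  - the local mean uses symmetric (mirror) border reflection;
//  - connectivity is 8 throughout;
//  - distance transforms are exact Euclidean (Felzenszwalb lower envelope),
//    returned squared so integer comparisons stay exact.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1-D min/max filter of half-width k along every column (contiguous in R's
// column-major storage), van Herk/Gil-Werman: O(1) per pixel. Out-of-image
// pixels act as +Inf (min) / -Inf (max).
static void lineFilterDown(const double* in, double* out, int nr, int nc,
                           int k, bool takeMax) {
  const int w = 2 * k + 1;
  const double pad = takeMax ? -INF : INF;
  const int np = nr + 2 * k;
  std::vector<double> buf(np), pre(np), suf(np);
  for (int j = 0; j < nc; ++j) {
    const double* col = in + (size_t)j * nr;
    for (int p = 0; p < np; ++p) {
      int src = p - k;
      buf[p] = (src >= 0 && src < nr) ? col[src] : pad;
    }
    for (int b0 = 0; b0 < np; b0 += w) {
      int b1 = std::min(b0 + w, np);
      pre[b0] = buf[b0];
      for (int p = b0 + 1; p < b1; ++p)
        pre[p] = takeMax ? std::max(pre[p - 1], buf[p])
                         : std::min(pre[p - 1], buf[p]);
      suf[b1 - 1] = buf[b1 - 1];
      for (int p = b1 - 2; p >= b0; --p)
        suf[p] = takeMax ? std::max(suf[p + 1], buf[p])
                         : std::min(suf[p + 1], buf[p]);
    }
    double* ocol = out + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      // window covers padded [i, i + w)
      int e = i + w - 1;
      double v = (e < np) ? std::min(suf[i], pre[e]) : suf[i];
      if (takeMax) v = (e < np) ? std::max(suf[i], pre[e]) : suf[i];
      ocol[i] = v;
    }
  }
}

// Flat-disc erosion (takeMax = false) or dilation (takeMax = true),
// decomposed into vertical line filters, one per disc column offset.
static NumericMatrix discMorph(const NumericMatrix& img, int radius,
                               bool takeMax) {
  const int nr = img.nrow(), nc = img.ncol();
  const double pad = takeMax ? -INF : INF;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), pad);
  std::vector<double> line((size_t)nr * nc);
  for (int dc = -radius; dc <= radius; ++dc) {
    int hh = (int)std::floor(std::sqrt((double)radius * radius -
                                       (double)dc * dc));
    lineFilterDown(&img[0], line.data(), nr, nc, hh, takeMax);
    for (int j = 0; j < nc; ++j) {
      int js = j + dc;
      if (js < 0 || js >= nc) continue;
      const double* src = line.data() + (size_t)js * nr;
      double* o = &out[0] + (size_t)j * nr;
      if (takeMax) {
        for (int i = 0; i < nr; ++i) o[i] = std::max(o[i], src[i]);
      } else {
        for (int i = 0; i < nr; ++i) o[i] = std::min(o[i], src[i]);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_disc_opening(NumericMatrix img, int radius) {
  NumericMatrix er = discMorph(img, radius, false);
  return discMorph(er, radius, true);
}

// ---------------------------------------------------------------------------
// Local mean over a (window x window) square, symmetric mirror reflection at
// borders: index -1 maps to 0, index n maps to n-1 (numpy 'symmetric').
static inline int reflectIdx(int i, int n) {
  // fold until inside; windows are never wider than a few image widths
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_local_mean(NumericMatrix img, int window) {
  if (window < 3 || window % 2 == 0)
    stop("window must be odd and >= 3");
  const int nr = img.nrow(), nc = img.ncol();
  const int k = (window - 1) / 2;
  // separable sum with per-axis symmetric padding
  NumericMatrix colsum(nr, nc);   // sum along rows (vertical) first
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int d = -k; d <= k; ++d) s += img(reflectIdx(i + d, nr), j);
      colsum(i, j) = s;
    }
  }
  NumericMatrix out(nr, nc);
  const double denom = (double)window * window;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (int d = -k; d <= k; ++d) s += colsum(i, reflectIdx(j + d, nc));
      out(i, j) = s / denom;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 8-connected component labeling, labels 1..N assigned in raster scan order
// of the first pixel encountered in each component.

// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(i + j * nr);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              q.push(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform: distance from every pixel to
// the nearest 'site' (true) pixel. Felzenszwalb & Huttenlocher 1-D lower
// envelope applied along rows then columns. No sites -> all Inf.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                  std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) { // no sites in this scanline
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix sites) {
  const int nr = sites.nrow(), nc = sites.ncol();
  NumericMatrix g(nr, nc);
  // pass 1: along columns (vertical)
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  std::vector<int> v(std::max(nr, nc));
  std::vector<double> z(std::max(nr, nc) + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = sites(i, j) ? 0.0 : INF;
    edt1d(f, d, nr, v, z);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    edt1d(f, d, nc, v, z);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale reconstruction by dilation (8-connected): raise 'marker' under
// 'maskImg' until stable. Iterated forward/backward raster sweeps.

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker,
                                       NumericMatrix maskImg) {
  const int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix r = clone(marker);
  bool changed = true;
  int pass = 0;
  while (changed && pass < 2000) {
    changed = false;
    ++pass;
    // forward sweep
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double m = r(i, j);
        if (i > 0)            m = std::max(m, r(i - 1, j));
        if (j > 0)            m = std::max(m, r(i, j - 1));
        if (i > 0 && j > 0)   m = std::max(m, r(i - 1, j - 1));
        if (i < nr - 1 && j > 0) m = std::max(m, r(i + 1, j - 1));
        m = std::min(m, maskImg(i, j));
        if (m > r(i, j)) { r(i, j) = m; changed = true; }
      }
    }
    // backward sweep
    for (int j = nc - 1; j >= 0; --j) {
      for (int i = nr - 1; i >= 0; --i) {
        double m = r(i, j);
        if (i < nr - 1)              m = std::max(m, r(i + 1, j));
        if (j < nc - 1)              m = std::max(m, r(i, j + 1));
        if (i < nr - 1 && j < nc - 1) m = std::max(m, r(i + 1, j + 1));
        if (i > 0 && j < nc - 1)     m = std::max(m, r(i - 1, j + 1));
        m = std::min(m, maskImg(i, j));
        if (m > r(i, j)) { r(i, j) = m; changed = true; }
      }
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// Regional maxima of 'img' restricted to 'mask', returned as a label matrix
// (plateaus labeled 1..N in raster order). A plateau (8-connected component
// of equal value) is a regional maximum iff none of its pixels has a
// strictly greater 8-neighbor inside the mask; neighbors outside the mask
// are ignored.

// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(NumericMatrix img, LogicalMatrix mask) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix plat(nr, nc);
  std::vector<bool> bad;
  bad.push_back(false); // index 0 unused
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || plat(i, j) != 0) continue;
      ++next;
      bad.push_back(false);
      const double val = img(i, j);
      plat(i, j) = next;
      q.push(i + j * nr);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (!mask(qi, qj)) continue;
            double nv = img(qi, qj);
            if (nv > val) { bad[next] = true; }
            else if (nv == val && plat(qi, qj) == 0) {
              plat(qi, qj) = next;
              q.push(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  // renumber surviving plateaus 1..K in raster order of first pixel
  std::vector<int> remap(next + 1, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int L = plat(i, j);
      if (L > 0 && !bad[L] && remap[L] == 0) remap[L] = ++k;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int L = plat(i, j);
      plat(i, j) = (L > 0 && !bad[L]) ? remap[L] : 0;
    }
  return plat;
}

// ---------------------------------------------------------------------------
// Seeded watershed by Meyer flooding on -priority (flood from high priority
// downward), restricted to 'mask'. Ties broken by insertion order (FIFO), so
// the result is deterministic given the raster-ordered seed labels.
struct WsEntry {
  double prio;
  long order;
  int pix;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on priority
    return a.order > b.order;                     // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, LogicalMatrix mask,
                            IntegerMatrix seeds) {
  const int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix lab = clone(seeds);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long counter = 0;
  auto pushNbrs = [&](int pi, int pj, int label) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int qi = pi + di, qj = pj + dj;
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (!mask(qi, qj) || lab(qi, qj) != 0) continue;
        pq.push(WsEntry{priority(qi, qj), counter++, qi + qj * nr, label});
      }
    }
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) pushNbrs(i, j, lab(i, j));
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int pi = e.pix % nr, pj = e.pix / nr;
    if (lab(pi, pj) != 0) continue;
    lab(pi, pj) = e.label;
    pushNbrs(pi, pj, e.label);
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Contested dilation: grow every labeled nucleus by a disc of 'radius'
// pixels; a pixel reachable from several nuclei goes to the nucleus whose
// nearest pixel is closest (exact squared Euclidean), ties to the lower
// label ID. Returns the cell label matrix.

// [[Rcpp::export]]
IntegerMatrix cpp_nearest_label_dilate(IntegerMatrix labels, double radius) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int maxLab = 0;
  for (int p = 0; p < nr * nc; ++p) maxLab = std::max(maxLab, labels[p]);
  IntegerMatrix out(nr, nc);
  if (maxLab == 0) return out;
  NumericMatrix best(nr, nc);
  std::fill(best.begin(), best.end(), INF);
  const double r2 = radius * radius;
  const int pad = (int)std::ceil(radius) + 1;
  // label bounding boxes
  std::vector<int> r0(maxLab + 1, nr), r1(maxLab + 1, -1),
                   c0(maxLab + 1, nc), c1(maxLab + 1, -1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int L = labels(i, j);
      if (L <= 0) continue;
      r0[L] = std::min(r0[L], i); r1[L] = std::max(r1[L], i);
      c0[L] = std::min(c0[L], j); c1[L] = std::max(c1[L], j);
    }
  for (int L = 1; L <= maxLab; ++L) {
    if (r1[L] < 0) continue;
    int br0 = std::max(0, r0[L] - pad), br1 = std::min(nr - 1, r1[L] + pad);
    int bc0 = std::max(0, c0[L] - pad), bc1 = std::min(nc - 1, c1[L] + pad);
    int bnr = br1 - br0 + 1, bnc = bc1 - bc0 + 1;
    LogicalMatrix sites(bnr, bnc);
    for (int j = 0; j < bnc; ++j)
      for (int i = 0; i < bnr; ++i)
        sites(i, j) = (labels(br0 + i, bc0 + j) == L);
    NumericMatrix d = cpp_edt_sq(sites);
    for (int j = 0; j < bnc; ++j)
      for (int i = 0; i < bnr; ++i) {
        double dv = d(i, j);
        // strict <: ties keep the lower (earlier) label
        if (dv <= r2 && dv < best(br0 + i, bc0 + j)) {
          best(br0 + i, bc0 + j) = dv;
          out(br0 + i, bc0 + j) = L;
        }
      }
  }
  return out;
}
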