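// Raster utilities for vessel morphometry and synthetic image generation:
// connected-component filtering, Zhang-Suen thinning, exact Euclidean
// distance transform (Felzenszwalb-Huttenlocher), capsule rasterization
// and separable Gaussian blur.  Masks come in as 0/1 integer matrices in
// R's column-major layout.

#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// 8-connected component labelling; returns labels (1-based, 0 = background).
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(c * H + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nc * H + nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen thinning to a 1 px wide, 8-connected skeleton.
// [[Rcpp::export]]
IntegerMatrix thin_zs_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<int> kill;
  bool changed = true;
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c) != 0 ? 1 : 0;
  };
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (img(r, c) == 0) continue;
          // neighbours p2..p9 clockwise from north
          const int p2 = P(r - 1, c), p3 = P(r - 1, c + 1), p4 = P(r, c + 1),
                    p5 = P(r + 1, c + 1), p6 = P(r + 1, c), p7 = P(r + 1, c - 1),
                    p8 = P(r, c - 1), p9 = P(r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int i = 0; i < 8; ++i)
            if (seq[i] == 0 && seq[i + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(c * H + r);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i] % H, kill[i] / H) = 0;
    }
  }
  return img;
}

// Exact squared Euclidean distance to the nearest zero pixel
// (Felzenszwalb & Huttenlocher lower-envelope transform, two 1D passes).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
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
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(H, W);
  const double INF = 1e20;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // column pass
  NumericMatrix tmp(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = mask(r, c) != 0 ? INF : 0.0;
    dt1d(f, d, H);
    for (int r = 0; r < H; ++r) tmp(r, c) = d[r];
  }
  // row pass
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = tmp(r, c);
    dt1d(f, d, W);
    for (int c = 0; c < W; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// Rasterize thick line segments (capsules).  segs has one row per piece:
// x0, y0, x1, y1, r0, r1 in 1-based pixel coordinates (x = column,
// y = row); radius varies linearly along the piece.  A pixel is set when
// its centre lies within the local radius of the centreline.
// [[Rcpp::export]]
IntegerMatrix raster_capsules_cpp(NumericMatrix segs, int H, int W) {
  IntegerMatrix mask(H, W);
  for (int i = 0; i < segs.nrow(); ++i) {
    const double x0 = segs(i, 0) - 1.0, y0 = segs(i, 1) - 1.0;
    const double x1 = segs(i, 2) - 1.0, y1 = segs(i, 3) - 1.0;
    const double r0 = segs(i, 4), r1 = segs(i, 5);
    const double rmax = std::max(r0, r1);
    const double dx = x1 - x0, dy = y1 - y0;
    const double len2 = dx * dx + dy * dy;
    const int clo = std::max(0, (int)std::floor(std::min(x0, x1) - rmax - 1));
    const int chi = std::min(W - 1, (int)std::ceil(std::max(x0, x1) + rmax + 1));
    const int rlo = std::max(0, (int)std::floor(std::min(y0, y1) - rmax - 1));
    const int rhi = std::min(H - 1, (int)std::ceil(std::max(y0, y1) + rmax + 1));
    for (int c = clo; c <= chi; ++c) {
      for (int r = rlo; r <= rhi; ++r) {
        double t = 0.0;
        if (len2 > 0.0)
          t = std::min(1.0, std::max(0.0, ((c - x0) * dx + (r - y0) * dy) / len2));
        const double px = x0 + t * dx, py = y0 + t * dy;
        const double dd = (c - px) * (c - px) + (r - py) * (r - py);
        const double rad = r0 + t * (r1 - r0);
        if (dd <= rad * rad) mask(r, c) = 1;
      }
    }
  }
  return mask;
}

// Separable Gaussian blur with reflected borders; sigma in pixels.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= ksum;
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int i = -rad; i <= rad; ++i) s += k[i + rad] * img(refl(r + i, H), c);
      tmp(r, c) = s;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int i = -rad; i <= rad; ++i) s += k[i + rad] * tmp(r, refl(c + i, W));
      out(r, c) = s;
    }
  return out;
}

// Post-thinning cleanup by sequential simple-point erosion: a non-endpoint
// pixel whose ON neighbours form a single 8-connected component within the
// 3x3 ring is redundant -- removing it keeps the skeleton connected and
// shortens no branch tip.  Removes the staircase doublings and corner
// pixels that parallel thinning leaves behind, yielding a genuinely
// 1 px wide skeleton.
// [[Rcpp::export]]
IntegerMatrix skel_cleanup_cpp(IntegerMatrix skel) {
  const int H = skel.nrow(), W = skel.ncol();
  IntegerMatrix img(clone(skel));
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c) != 0 ? 1 : 0;
  };
  // ring offsets clockwise from north
  const int RDR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int RDC[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (img(r, c) == 0) continue;
        int on[8], deg = 0;
        for (int i = 0; i < 8; ++i) {
          on[i] = P(r + RDR[i], c + RDC[i]);
          deg += on[i];
        }
        if (deg < 2) continue;  // endpoint or isolated pixel
        // count 8-connected components of ON ring cells (cells are
        // adjacent when their offsets differ by <= 1 in each direction)
        int comp[8];
        for (int i = 0; i < 8; ++i) comp[i] = on[i] ? i : -1;
        bool merged = true;
        while (merged) {
          merged = false;
          for (int i = 0; i < 8; ++i) {
            if (!on[i]) continue;
            for (int j = i + 1; j < 8; ++j) {
              if (!on[j]) continue;
              if (std::abs(RDR[i] - RDR[j]) <= 1 &&
                  std::abs(RDC[i] - RDC[j]) <= 1 && comp[i] != comp[j]) {
                const int a = std::min(comp[i], comp[j]);
                const int b = std::max(comp[i], comp[j]);
                for (int k = 0; k < 8; ++k)
                  if (comp[k] == b) comp[k] = a;
                merged = true;
              }
            }
          }
        }
        int ncomp = 0;
        for (int i = 0; i < 8; ++i)
          if (on[i] && comp[i] == i) ++ncomp;
        if (ncomp == 1) {
          img(r, c) = 0;
          changed = true;
        }
      }
    }
  }
  return img;
}

// Crossing number: number of 0->1 transitions in the circular sequence of
// the 8 neighbours.  Skeleton pixels with crossing number >= 3 are
// junction candidates; staircase pixels (3 clustered neighbours) are not.
// [[Rcpp::export]]
IntegerMatrix crossing_count_cpp(IntegerMatrix skel) {
  const int H = skel.nrow(), W = skel.ncol();
  IntegerMatrix out(H, W);
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return skel(r, c) != 0 ? 1 : 0;
  };
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (skel(r, c) == 0) continue;
      const int seq[9] = {P(r - 1, c),     P(r - 1, c + 1), P(r, c + 1),
                          P(r + 1, c + 1), P(r + 1, c),     P(r + 1, c - 1),
                          P(r, c - 1),     P(r - 1, c - 1), P(r - 1, c)};
      int t = 0;
      for (int i = 0; i < 8; ++i)
        if (seq[i] == 0 && seq[i + 1] == 1) ++t;
      out(r, c) = t;
    }
  return out;
}

// Number of 8-connected skeleton neighbours for every skeleton pixel.
// [[Rcpp::export]]
IntegerMatrix neighbor_count_cpp(IntegerMatrix skel) {
  const int H = skel.nrow(), W = skel.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (skel(r, c) == 0) continue;
      int n = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          const int nr = r + dr, nc = c + dc;
          if (nr >= 0 && nr < H && nc >= 0 && nc < W && skel(nr, nc) != 0) ++n;
        }
      out(r, c) = n;
    }
  return out;
}

// Geodesic skeleton length: orthogonal neighbour steps count 1, diagonal
// steps sqrt(2); a diagonal step is skipped when either of its two
// orthogonal mediators is itself a skeleton pixel (the path already runs
// through the mediator).  Each unordered pixel pair is counted once.
// [[Rcpp::export]]
double skeleton_length_cpp(IntegerMatrix skel) {
  const int H = skel.nrow(), W = skel.ncol();
  double len = 0.0;
  const double SQ2 = std::sqrt(2.0);
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return skel(r, c) != 0 ? 1 : 0;
  };
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (skel(r, c) == 0) continue;
      // count each edge once: only look at (dr,dc) in {(1,0),(0,1),(1,1),(-1,1)}
      if (at(r + 1, c)) len += 1.0;
      if (at(r, c + 1)) len += 1.0;
      if (at(r + 1, c + 1) && !(at(r + 1, c) || at(r, c + 1))) len += SQ2;
      if (at(r - 1, c + 1) && !(at(r - 1, c) || at(r, c + 1))) len += SQ2;
    }
  return len;
}
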