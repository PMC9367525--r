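// Compact U-net style encoder-decoder for vessel segmentation.
//
// Feature maps are stored as arma::fmat with one column per channel and one
// row per pixel, pixel index p = col*H + row (R column-major layout).
// Convolutions are 3x3 (zero padded) via im2col + sgemm; downsampling is
// 2x2 max pooling, upsampling nearest-neighbour, skip connections by
// channel concatenation.  A single forward/backward entry point keeps all
// intermediate buffers local to the call so the R side owns the weights.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 kernel with zero padding 1.
// col columns are ordered k*C + ci with k = (dc+1)*3 + (dr+1).
static void im2col3(const fmat& X, const int H, const int W, fmat& col) {
  const int C = X.n_cols;
  col.zeros((size_t)H * W, 9 * C);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      const int len = r1 - r0 + 1;
      if (len <= 0 || c1 < c0) continue;
      for (int ci = 0; ci < C; ++ci) {
        float* dst = col.colptr(k * C + ci);
        const float* src = X.colptr(ci);
        for (int c = c0; c <= c1; ++c) {
          std::memcpy(dst + (size_t)c * H + r0,
                      src + (size_t)(c + dc) * H + (r0 + dr),
                      (size_t)len * sizeof(float));
        }
      }
    }
  }
}

// Adjoint of im2col3: scatter-add dcol back onto an H*W x C gradient map.
static void col2im3(const fmat& dcol, const int H, const int W, const int C,
                    fmat& dX) {
  dX.zeros((size_t)H * W, C);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      const int len = r1 - r0 + 1;
      if (len <= 0 || c1 < c0) continue;
      for (int ci = 0; ci < C; ++ci) {
        const float* src = dcol.colptr(k * C + ci);
        float* dst = dX.colptr(ci);
        for (int c = c0; c <= c1; ++c) {
          const float* s = src + (size_t)c * H + r0;
          float* d = dst + (size_t)(c + dc) * H + (r0 + dr);
          for (int i = 0; i < len; ++i) d[i] += s[i];
        }
      }
    }
  }
}

static void maxpool2(const fmat& X, const int H, const int W, fmat& Y,
                     Mat<uword>& idx) {
  const int C = X.n_cols, Ho = H / 2, Wo = W / 2;
  Y.set_size((size_t)Ho * Wo, C);
  idx.set_size((size_t)Ho * Wo, C);
  for (int ci = 0; ci < C; ++ci) {
    const float* src = X.colptr(ci);
    float* dst = Y.colptr(ci);
    uword* ix = idx.colptr(ci);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const size_t p00 = (size_t)(2 * co) * H + 2 * ro;
        const size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        size_t best = cand[0];
        float bv = src[cand[0]];
        for (int j = 1; j < 4; ++j)
          if (src[cand[j]] > bv) { bv = src[cand[j]]; best = cand[j]; }
        dst[(size_t)co * Ho + ro] = bv;
        ix[(size_t)co * Ho + ro] = best;
      }
    }
  }
}

static void unpool2(const fmat& dY, const Mat<uword>& idx, const int H,
                    const int W, fmat& dX) {
  const int C = dY.n_cols;
  dX.zeros((size_t)H * W, C);
  for (int ci = 0; ci < C; ++ci) {
    const float* src = dY.colptr(ci);
    const uword* ix = idx.colptr(ci);
    float* dst = dX.colptr(ci);
    const size_t n = dY.n_rows;
    for (size_t i = 0; i < n; ++i) dst[ix[i]] += src[i];
  }
}

// Nearest-neighbour 2x upsample: X lives on (H x W), Y on (2H x 2W).
static void upsample2(const fmat& X, const int H, const int W, fmat& Y) {
  const int C = X.n_cols, Ho = 2 * H, Wo = 2 * W;
  Y.set_size((size_t)Ho * Wo, C);
  for (int ci = 0; ci < C; ++ci) {
    const float* src = X.colptr(ci);
    float* dst = Y.colptr(ci);
    for (int c = 0; c < Wo; ++c) {
      const float* s = src + (size_t)(c / 2) * H;
      float* d = dst + (size_t)c * Ho;
      for (int r = 0; r < Ho; ++r) d[r] = s[r / 2];
    }
  }
}

static void downsample_sum2(const fmat& dY, const int Ho, const int Wo,
                            fmat& dX) {
  // adjoint of upsample2; dY on (Ho x Wo), dX on (Ho/2 x Wo/2)
  const int C = dY.n_cols, H = Ho / 2, W = Wo / 2;
  dX.zeros((size_t)H * W, C);
  for (int ci = 0; ci < C; ++ci) {
    const float* src = dY.colptr(ci);
    float* dst = dX.colptr(ci);
    for (int c = 0; c < Wo; ++c) {
      const float* s = src + (size_t)c * Ho;
      float* d = dst + (size_t)(c / 2) * H;
      for (int r = 0; r < Ho; ++r) d[r / 2] += s[r];
    }
  }
}

static fmat get_w(const Rcpp::List& params, const std::string& nm) {
  Rcpp::NumericMatrix m = params[nm];
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static frowvec get_b(const Rcpp::List& params, const std::string& nm) {
  Rcpp::NumericVector v = params[nm];
  frowvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}

static Rcpp::NumericMatrix put_m(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

static Rcpp::NumericVector put_v(const frowvec& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

static fmat relu_mask(const fmat& a) {
  fmat m(a.n_rows, a.n_cols);
  const float* s = a.memptr();
  float* d = m.memptr();
  const size_t n = a.n_elem;
  for (size_t i = 0; i < n; ++i) d[i] = s[i] > 0.0f ? 1.0f : 0.0f;
  return m;
}

// Forward pass (and optionally backward) through the network.
// image: (H*W) x Cin matrix of centred intensities; target: H*W vector of
// 0/1 labels (ignored unless want_grad).  H and W must be divisible by
// 2^(depth-1).  Returns per-pixel sigmoid scores, plus loss and gradients
// for every parameter when want_grad is TRUE.
// [[Rcpp::export]]
Rcpp::List nn_run_cpp(Rcpp::List params, Rcpp::NumericMatrix image,
                      int H, int W, Rcpp::NumericVector target,
                      bool want_grad, int depth, int base) {
  const int D = depth;
  const int div = 1 << (D - 1);
  if (H % div != 0 || W % div != 0)
    Rcpp::stop("image dims must be divisible by 2^(depth-1)");

  fmat cur(image.nrow(), image.ncol());
  for (int j = 0; j < image.ncol(); ++j)
    for (int i = 0; i < image.nrow(); ++i) cur(i, j) = (float)image(i, j);

  std::vector<int> Hs(D), Ws(D);
  std::vector<fmat> enc_in(D), enc_act(D);
  std::vector<Mat<uword>> pidx(D - 1);

  // encoder
  int h = H, w = W;
  fmat col;
  for (int l = 0; l < D; ++l) {
    Hs[l] = h; Ws[l] = w;
    enc_in[l] = cur;
    im2col3(cur, h, w, col);
    fmat W_ = get_w(params, "eW" + std::to_string(l + 1));
    frowvec b_ = get_b(params, "eb" + std::to_string(l + 1));
    fmat act = col * W_;
    act.each_row() += b_;
    act.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    enc_act[l] = act;
    if (l < D - 1) {
      fmat pooled;
      maxpool2(act, h, w, pooled, pidx[l]);
      cur = pooled;
      h /= 2; w /= 2;
    } else {
      cur = act;
    }
  }

  // decoder
  std::vector<fmat> cat(D - 1), dec_act(D - 1);
  for (int l = D - 2; l >= 0; --l) {
    fmat up;
    upsample2(cur, (l == D - 2) ? Hs[D - 1] : Hs[l + 1], (l == D - 2) ? Ws[D - 1] : Ws[l + 1], up);
    cat[l] = join_rows(up, enc_act[l]);
    im2col3(cat[l], Hs[l], Ws[l], col);
    fmat W_ = get_w(params, "dW" + std::to_string(l + 1));
    frowvec b_ = get_b(params, "db" + std::to_string(l + 1));
    fmat act = col * W_;
    act.each_row() += b_;
    act.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    dec_act[l] = act;
    cur = act;
  }

  // 1x1 output head + sigmoid
  fmat oW = get_w(params, "oW");
  frowvec ob = get_b(params, "ob");
  fvec pre = cur * oW + ob(0);
  fvec scores = 1.0f / (1.0f + exp(-pre));

  Rcpp::NumericVector sc(scores.n_elem);
  for (uword i = 0; i < scores.n_elem; ++i) sc[i] = scores(i);

  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("scores") = sc);

  const size_t N = scores.n_elem;
  fvec tgt(N);
  for (size_t i = 0; i < N; ++i) tgt(i) = (float)target[i];

  // binary cross-entropy, mean over pixels
  double loss = 0.0;
  const double eps = 1e-7;
  for (size_t i = 0; i < N; ++i) {
    const double s = scores(i), t = tgt(i);
    loss -= t * std::log(s + eps) + (1.0 - t) * std::log(1.0 - s + eps);
  }
  loss /= (double)N;

  Rcpp::List grads;
  fvec dpre = (scores - tgt) / (float)N;       // d loss / d pre-sigmoid
  grads["oW"] = put_m(cur.t() * dpre);
  grads["ob"] = Rcpp::NumericVector::create(accu(dpre));
  fmat dcur = dpre * oW.t();                   // grad wrt dec_act[0]

  // decoder backward (levels 1 .. D-1, finest first)
  std::vector<fmat> dskip(D);                  // grads flowing into enc_act
  for (int l = 0; l <= D - 2; ++l) {
    fmat dact = dcur % relu_mask(dec_act[l]);
    im2col3(cat[l], Hs[l], Ws[l], col);
    fmat W_ = get_w(params, "dW" + std::to_string(l + 1));
    grads["dW" + std::to_string(l + 1)] = put_m(col.t() * dact);
    grads["db" + std::to_string(l + 1)] = put_v(frowvec(sum(dact, 0)));
    fmat dcol = dact * W_.t();
    fmat dcat;
    col2im3(dcol, Hs[l], Ws[l], cat[l].n_cols, dcat);
    const int cup = cat[l].n_cols - enc_act[l].n_cols;
    dskip[l] = dcat.cols(cup, dcat.n_cols - 1);
    fmat dup = dcat.cols(0, cup - 1);
    fmat ddown;
    downsample_sum2(dup, Hs[l], Ws[l], ddown);
    dcur = ddown;                              // grad wrt next coarser stage
  }
  dskip[D - 1] = dcur;                         // grad wrt bottleneck act

  // encoder backward (coarsest first)
  fmat g = dskip[D - 1];
  for (int l = D - 1; l >= 0; --l) {
    fmat dact = g % relu_mask(enc_act[l]);
    im2col3(enc_in[l], Hs[l], Ws[l], col);
    fmat W_ = get_w(params, "eW" + std::to_string(l + 1));
    grads["eW" + std::to_string(l + 1)] = put_m(col.t() * dact);
    grads["eb" + std::to_string(l + 1)] = put_v(frowvec(sum(dact, 0)));
    if (l > 0) {
      fmat dcol = dact * W_.t();
      fmat dpooled;
      col2im3(dcol, Hs[l], Ws[l], enc_in[l].n_cols, dpooled);
      fmat dun;
      unpool2(dpooled, pidx[l - 1], Hs[l - 1], Ws[l - 1], dun);
      g = dskip[l - 1] + dun;
    }
  }

  return Rcpp::List::create(Rcpp::Named("scores") = sc,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}
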