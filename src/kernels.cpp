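// Native single-precision compute kernels for the CNN layers and image
// resampling.  Layout convention: activations are R arrays dim (H, W, C, N),
// column-major, so x[h, w, c, n] sits at h + H*(w + W*(c + C*n)).
// Convolution weights are dim (3, 3, Cin, F); flattened column-major this is
// exactly the (9*Cin x F) matrix used by the im2col GEMM.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline std::vector<float> to_float(const NumericVector& x) {
  std::vector<float> out(x.size());
  const double* p = x.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = static_cast<float>(p[i]);
  return out;
}

static inline NumericVector to_numeric(const std::vector<float>& x,
                                       const IntegerVector& dim) {
  NumericVector out(static_cast<R_xlen_t>(x.size()));
  for (size_t i = 0; i < x.size(); ++i) out[i] = x[i];
  out.attr("dim") = dim;
  return out;
}

static void get_dim4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) { H = d[0]; W = d[1]; C = d[2]; N = 1; }
  else if (d.size() == 4) { H = d[0]; W = d[1]; C = d[2]; N = d[3]; }
  else stop("expected a 3-d or 4-d array");
}

// Fill the im2col buffer K ((H*wc) x 9C) for image columns [w0, w1).
static void im2col_chunk(const float* x, int H, int W, int C,
                         int w0, int w1, arma::fmat& K) {
  const int wc = w1 - w0;
  K.zeros(static_cast<arma::uword>(H) * wc, static_cast<arma::uword>(9) * C);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < 3; ++kx) {
      const int dx = kx - 1;
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1;
        const int q = ky + 3 * kx + 9 * c;
        float* dst0 = K.colptr(q);
        for (int w = w0; w < w1; ++w) {
          const int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          const int h_lo = std::max(0, -dy);
          const int h_hi = std::min(H, H - dy);
          const float* src = x + (h_lo + dy) + static_cast<size_t>(H) * (ws + static_cast<size_t>(W) * c);
          float* dst = dst0 + h_lo + static_cast<size_t>(H) * (w - w0);
          std::copy(src, src + (h_hi - h_lo), dst);
        }
      }
    }
  }
}

static int chunk_width(int H, int W) {
  const int target = 1 << 16;  // ~64k output pixels per GEMM tile
  int wc = std::max(1, target / H);
  return std::min(wc, W);
}

// [[Rcpp::export]]
NumericVector fs_conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 3 || wd[1] != 3 || wd[2] != C)
    stop("weight array must have dim (3, 3, Cin, F) matching the input");
  const int F = wd[3];
  std::vector<float> xf = to_float(x), wf = to_float(w), bf = to_float(b);
  arma::fmat Wm(wf.data(), static_cast<arma::uword>(9) * C, F, false, true);
  std::vector<float> yf(static_cast<size_t>(H) * W * F * N);
  const int wc_max = chunk_width(H, W);
  arma::fmat K, Y;
  for (int n = 0; n < N; ++n) {
    const float* xn = xf.data() + static_cast<size_t>(H) * W * C * n;
    float* yn = yf.data() + static_cast<size_t>(H) * W * F * n;
    for (int w0 = 0; w0 < W; w0 += wc_max) {
      const int w1 = std::min(W, w0 + wc_max);
      im2col_chunk(xn, H, W, C, w0, w1, K);
      Y = K * Wm;  // (H*wc) x F
      const size_t npix = static_cast<size_t>(H) * (w1 - w0);
      for (int f = 0; f < F; ++f) {
        const float* src = Y.colptr(f);
        float* dst = yn + static_cast<size_t>(H) * w0 + static_cast<size_t>(H) * W * f;
        const float bias = bf[f];
        for (size_t i = 0; i < npix; ++i) dst[i] = src[i] + bias;
      }
    }
  }
  return to_numeric(yf, IntegerVector::create(H, W, F, N));
}

// [[Rcpp::export]]
List fs_conv3_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int F = wd[3];
  std::vector<float> xf = to_float(x), wf = to_float(w), dyf = to_float(dy);
  arma::fmat Wm(wf.data(), static_cast<arma::uword>(9) * C, F, false, true);
  std::vector<float> dxf(xf.size(), 0.0f);
  arma::fmat dWm(static_cast<arma::uword>(9) * C, F, arma::fill::zeros);
  std::vector<double> db(F, 0.0);
  const int wc_max = chunk_width(H, W);
  arma::fmat K, dY, dK;
  for (int n = 0; n < N; ++n) {
    const float* xn = xf.data() + static_cast<size_t>(H) * W * C * n;
    const float* dyn = dyf.data() + static_cast<size_t>(H) * W * F * n;
    float* dxn = dxf.data() + static_cast<size_t>(H) * W * C * n;
    for (int w0 = 0; w0 < W; w0 += wc_max) {
      const int w1 = std::min(W, w0 + wc_max);
      const size_t npix = static_cast<size_t>(H) * (w1 - w0);
      im2col_chunk(xn, H, W, C, w0, w1, K);
      dY.set_size(npix, F);
      for (int f = 0; f < F; ++f) {
        const float* src = dyn + static_cast<size_t>(H) * w0 + static_cast<size_t>(H) * W * f;
        std::copy(src, src + npix, dY.colptr(f));
      }
      dWm += K.t() * dY;
      dK = dY * Wm.t();  // npix x 9C
      for (int c = 0; c < C; ++c) {
        for (int kx = 0; kx < 3; ++kx) {
          const int dx_off = kx - 1;
          for (int ky = 0; ky < 3; ++ky) {
            const int dy_off = ky - 1;
            const int q = ky + 3 * kx + 9 * c;
            const float* col = dK.colptr(q);
            for (int ww = w0; ww < w1; ++ww) {
              const int ws = ww + dx_off;
              if (ws < 0 || ws >= W) continue;
              const int h_lo = std::max(0, -dy_off);
              const int h_hi = std::min(H, H - dy_off);
              const float* src = col + h_lo + static_cast<size_t>(H) * (ww - w0);
              float* dst = dxn + (h_lo + dy_off) + static_cast<size_t>(H) * (ws + static_cast<size_t>(W) * c);
              for (int h = 0; h < h_hi - h_lo; ++h) dst[h] += src[h];
            }
          }
        }
      }
    }
    for (int f = 0; f < F; ++f) {
      const float* src = dyn + static_cast<size_t>(H) * W * f;
      double s = 0.0;
      for (size_t i = 0; i < static_cast<size_t>(H) * W; ++i) s += src[i];
      db[f] += s;
    }
  }
  std::vector<float> dwf(dWm.begin(), dWm.end());
  NumericVector dbv(F);
  for (int f = 0; f < F; ++f) dbv[f] = db[f];
  return List::create(
    _["dx"] = to_numeric(dxf, IntegerVector::create(H, W, C, N)),
    _["dw"] = to_numeric(dwf, IntegerVector::create(3, 3, C, F)),
    _["db"] = dbv);
}

// [[Rcpp::export]]
List fs_maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  const double* xf = x.begin();
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t i00 = base + 2 * ho + static_cast<size_t>(H) * (2 * wo);
          size_t best = i00; double bv = xf[i00];
          const size_t cand[3] = { i00 + 1, i00 + H, i00 + H + 1 };
          for (int k = 0; k < 3; ++k)
            if (xf[cand[k]] > bv) { bv = xf[cand[k]]; best = cand[k]; }
          // column-major output order is (ho, wo, c, n) but we iterate wo outer;
          // compute the destination index explicitly
          R_xlen_t oi = ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * (c + static_cast<R_xlen_t>(C) * n));
          y[oi] = bv;
          idx[oi] = static_cast<int>(best);
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector fs_maxpool2_bwd(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int C = d[2], N = d.size() == 4 ? d[3] : 1;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export]]
List fs_bn_stats(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  const size_t plane = static_cast<size_t>(H) * W;
  NumericVector mean(C), var(C);
  const double* xf = x.begin();
  const double M = static_cast<double>(plane) * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = xf + plane * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    mean[c] = s / M;
    var[c] = s2 / M - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector fs_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                        NumericVector mean, NumericVector var, double eps) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  const size_t plane = static_cast<size_t>(H) * W;
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c] * inv, bshift = beta[c] - gamma[c] * inv * mean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + static_cast<size_t>(C) * n);
      double* q = y.begin() + plane * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < plane; ++i) q[i] = g * p[i] + bshift;
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
List fs_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
               NumericVector var, NumericVector dy, double eps) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  const size_t plane = static_cast<size_t>(H) * W;
  const double M = static_cast<double>(plane) * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double s_dy = 0.0, s_dyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + static_cast<size_t>(C) * n);
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        s_dy += pd[i];
        s_dyx += pd[i] * (px[i] - mean[c]) * inv;
      }
    }
    dgamma[c] = s_dyx;
    dbeta[c] = s_dy;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + static_cast<size_t>(C) * n);
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      double* pq = dx.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        const double xhat = (px[i] - mean[c]) * inv;
        pq[i] = g * inv * (pd[i] - s_dy / M - xhat * s_dyx / M);
      }
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Pixel-centre bilinear sampling with edge clamping.
// [[Rcpp::export]]
NumericVector fs_resize_bilinear(NumericVector img, int oh, int ow) {
  int H, W, C, N; get_dim4(img, H, W, C, N);
  if (N != 1) stop("resize expects a single image (3-d array)");
  NumericVector out(static_cast<R_xlen_t>(oh) * ow * C);
  const double sy = static_cast<double>(H) / oh, sx = static_cast<double>(W) / ow;
  for (int c = 0; c < C; ++c) {
    const double* p = img.begin() + static_cast<size_t>(H) * W * c;
    double* q = out.begin() + static_cast<size_t>(oh) * ow * c;
    for (int x = 0; x < ow; ++x) {
      double src_x = (x + 0.5) * sx - 0.5;
      src_x = std::min(std::max(src_x, 0.0), W - 1.0);
      const int x0 = static_cast<int>(std::floor(src_x));
      const int x1 = std::min(x0 + 1, W - 1);
      const double fx = src_x - x0;
      for (int y = 0; y < oh; ++y) {
        double src_y = (y + 0.5) * sy - 0.5;
        src_y = std::min(std::max(src_y, 0.0), H - 1.0);
        const int y0 = static_cast<int>(std::floor(src_y));
        const int y1 = std::min(y0 + 1, H - 1);
        const double fy = src_y - y0;
        const double v =
          (1 - fy) * ((1 - fx) * p[y0 + static_cast<size_t>(H) * x0] + fx * p[y0 + static_cast<size_t>(H) * x1]) +
          fy       * ((1 - fx) * p[y1 + static_cast<size_t>(H) * x0] + fx * p[y1 + static_cast<size_t>(H) * x1]);
        q[y + static_cast<size_t>(oh) * x] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  return out;
}

static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  int j = i % period; if (j < 0) j += period;
  return j < n ? j : period - 1 - j;
}

// Affine warp: for each output pixel (r, c) the source location is
// (M[0,0]*r + M[0,1]*c + M[0,2], M[1,0]*r + M[1,1]*c + M[1,2]) in input
// coordinates (0-based rows/cols).  Bilinear sampling, symmetric
// (mirror) padding outside the frame.
// [[Rcpp::export]]
NumericVector fs_affine_warp(NumericVector img, NumericMatrix M) {
  int H, W, C, N; get_dim4(img, H, W, C, N);
  if (N != 1) stop("warp expects a single image (3-d array)");
  NumericVector out(img.size());
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double sr = M(0, 0) * r + M(0, 1) * c + M(0, 2);
      const double sc = M(1, 0) * r + M(1, 1) * c + M(1, 2);
      const int r0 = static_cast<int>(std::floor(sr));
      const int c0 = static_cast<int>(std::floor(sc));
      const double fr = sr - r0, fc = sc - c0;
      const int rr0 = reflect_index(r0, H), rr1 = reflect_index(r0 + 1, H);
      const int cc0 = reflect_index(c0, W), cc1 = reflect_index(c0 + 1, W);
      for (int ch = 0; ch < C; ++ch) {
        const double* p = img.begin() + static_cast<size_t>(H) * W * ch;
        const double v =
          (1 - fr) * ((1 - fc) * p[rr0 + static_cast<size_t>(H) * cc0] + fc * p[rr0 + static_cast<size_t>(H) * cc1]) +
          fr       * ((1 - fc) * p[rr1 + static_cast<size_t>(H) * cc0] + fc * p[rr1 + static_cast<size_t>(H) * cc1]);
        out[r + static_cast<size_t>(H) * (c + static_cast<size_t>(W) * ch)] = v;
      }
    }
  }
  out.attr("dim") = img.attr("dim");
  return out;
}

// 8-connected components of a binary mask, two-pass union-find.
// [[Rcpp::export]]
IntegerMatrix fs_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      const int dr[4] = { -1, -1, -1, 0 };
      const int dc[4] = { -1, 0, 1, -1 };
      std::vector<int> nb;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (lab(rr, cc)) nb.push_back(lab(rr, cc));
      }
      if (nb.empty()) {
        parent.push_back(static_cast<int>(parent.size()));
        best = static_cast<int>(parent.size()) - 1;
      } else {
        best = *std::min_element(nb.begin(), nb.end());
        for (int l : nb) unite(best, l);
      }
      lab(r, c) = best;
    }
  // relabel compactly
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!lab(r, c)) continue;
      const int root = find(lab(r, c));
      if (!remap[root]) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  return lab;
}
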