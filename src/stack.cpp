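// Whole-conv-stack forward/backward in single precision with persistent
// buffers, avoiding per-layer R round trips.  The dense head stays in R.
// Layout matches kernels.cpp: activations (H, W, C, N) column-major;
// weights (3, 3, Cin, F).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct StackLayer {
  int H = 0, W = 0, Cin = 0, Cout = 0;  // H, W of this layer's input
  bool bn = false, pool = false;
  std::vector<float> z;         // pre-BN conv output (+bias), (H,W,Cout,N)
  std::vector<float> relu;      // post-ReLU activation
  std::vector<float> pooled;    // after pool (if any)
  std::vector<int> pool_idx;    // argmax into relu
  std::vector<double> mean, var;  // BN stats used in this pass
};

struct StackCache {
  int N = 0;
  bool training = false;  // batch statistics (true) vs fixed running moments
  std::vector<float> x0;            // network input as float
  std::vector<StackLayer> layers;
};

// im2col for images [n0, n1): K rows ordered h + H*w + H*W*(n - n0).
static void im2col_batch(const float* x, int H, int W, int C, int n0, int n1,
                         arma::fmat& K) {
  const size_t plane = static_cast<size_t>(H) * W;
  const size_t imsz = plane * C;
  K.zeros(plane * (n1 - n0), static_cast<arma::uword>(9) * C);
  for (int c = 0; c < C; ++c)
    for (int kx = 0; kx < 3; ++kx) {
      const int dx = kx - 1;
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1;
        const int q = ky + 3 * kx + 9 * c;
        float* dst0 = K.colptr(q);
        for (int n = n0; n < n1; ++n) {
          const float* xn = x + imsz * n + plane * c;
          float* dstn = dst0 + plane * (n - n0);
          for (int w = 0; w < W; ++w) {
            const int ws = w + dx;
            if (ws < 0 || ws >= W) continue;
            const int h_lo = std::max(0, -dy);
            const int h_hi = std::min(H, H - dy);
            const float* src = xn + (h_lo + dy) + static_cast<size_t>(H) * ws;
            std::copy(src, src + (h_hi - h_lo),
                      dstn + h_lo + static_cast<size_t>(H) * w);
          }
        }
      }
    }
}

static int subbatch_size(int H, int W, int C, int N) {
  const double cap = 150e6;  // bytes for the im2col buffer
  int nb = static_cast<int>(cap / (4.0 * H * W * 9.0 * C));
  return std::max(1, std::min(nb, N));
}

// [[Rcpp::export]]
List fs_stack_fwd(NumericVector x, List layers, bool training, double eps,
                  double momentum, List running) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("input must be a 4-d array");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  XPtr<StackCache> cache(new StackCache, true);
  cache->N = N;
  cache->training = training;
  cache->x0.resize(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) cache->x0[i] = x[i];
  const int L = layers.size();
  cache->layers.resize(L);
  List new_running = clone(running);
  List stats(L);
  const float* a = cache->x0.data();
  int aH = H, aW = W, aC = C;
  arma::fmat K, Y;
  for (int li = 0; li < L; ++li) {
    List ly = layers[li];
    StackLayer& S = cache->layers[li];
    S.H = aH; S.W = aW; S.Cin = aC;
    NumericVector wv = ly["w"], bv = ly["b"];
    IntegerVector wd = wv.attr("dim");
    if (wd[2] != aC) stop("layer ", li + 1, ": channel mismatch");
    const int F = wd[3];
    S.Cout = F;
    S.bn = as<bool>(ly["bn"]);
    S.pool = as<bool>(ly["pool"]);
    std::vector<float> wf(wv.size());
    for (R_xlen_t i = 0; i < wv.size(); ++i) wf[i] = wv[i];
    arma::fmat Wm(wf.data(), static_cast<arma::uword>(9) * aC, F, false, true);
    const size_t plane = static_cast<size_t>(aH) * aW;
    S.z.resize(plane * F * N);
    const int nb = subbatch_size(aH, aW, aC, N);
    for (int n0 = 0; n0 < N; n0 += nb) {
      const int n1 = std::min(N, n0 + nb);
      im2col_batch(a, aH, aW, aC, n0, n1, K);
      Y = K * Wm;
      for (int f = 0; f < F; ++f) {
        const float* src = Y.colptr(f);
        const float bias = static_cast<float>(bv[f]);
        for (int n = n0; n < n1; ++n) {
          float* dst = S.z.data() + plane * (f + static_cast<size_t>(F) * n);
          const float* s2 = src + plane * (n - n0);
          for (size_t i = 0; i < plane; ++i) dst[i] = s2[i] + bias;
        }
      }
    }
    // batch norm (optional) + ReLU, fused
    S.relu.resize(S.z.size());
    S.mean.assign(F, 0.0); S.var.assign(F, 0.0);
    if (S.bn) {
      NumericVector gv = ly["gamma"], bev = ly["beta"];
      const double M = static_cast<double>(plane) * N;
      std::string mkey = "bn" + std::to_string(li + 1) + "_mean";
      std::string vkey = "bn" + std::to_string(li + 1) + "_var";
      for (int f = 0; f < F; ++f) {
        double mu, v2;
        if (training) {
          double s = 0, s2 = 0;
          for (int n = 0; n < N; ++n) {
            const float* p = S.z.data() + plane * (f + static_cast<size_t>(F) * n);
            for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
          }
          mu = s / M;
          v2 = std::max(0.0, s2 / M - mu * mu);
        } else {
          mu = as<NumericVector>(running[mkey])[f];
          v2 = as<NumericVector>(running[vkey])[f];
        }
        S.mean[f] = mu; S.var[f] = v2;
        const float g = static_cast<float>(gv[f] / std::sqrt(v2 + eps));
        const float sh = static_cast<float>(bev[f]) - g * static_cast<float>(mu);
        for (int n = 0; n < N; ++n) {
          const size_t off = plane * (f + static_cast<size_t>(F) * n);
          const float* p = S.z.data() + off;
          float* q = S.relu.data() + off;
          for (size_t i = 0; i < plane; ++i) {
            const float y = g * p[i] + sh;
            q[i] = y > 0 ? y : 0.0f;
          }
        }
      }
      if (training) {
        NumericVector rm = clone(as<NumericVector>(new_running[mkey]));
        NumericVector rv = clone(as<NumericVector>(new_running[vkey]));
        for (int f = 0; f < F; ++f) {
          rm[f] = momentum * rm[f] + (1 - momentum) * S.mean[f];
          rv[f] = momentum * rv[f] + (1 - momentum) * S.var[f];
        }
        new_running[mkey] = rm;
        new_running[vkey] = rv;
      }
    } else {
      for (size_t i = 0; i < S.z.size(); ++i)
        S.relu[i] = S.z[i] > 0 ? S.z[i] : 0.0f;
    }
    // max pool 2x2 stride 2 (optional)
    if (S.pool) {
      const int Ho = aH / 2, Wo = aW / 2;
      const size_t oplane = static_cast<size_t>(Ho) * Wo;
      S.pooled.resize(oplane * F * N);
      S.pool_idx.resize(S.pooled.size());
      for (int n = 0; n < N; ++n)
        for (int f = 0; f < F; ++f) {
          const size_t ibase = plane * (f + static_cast<size_t>(F) * n);
          const size_t obase = oplane * (f + static_cast<size_t>(F) * n);
          for (int wo = 0; wo < Wo; ++wo)
            for (int ho = 0; ho < Ho; ++ho) {
              const size_t i00 = ibase + 2 * ho + static_cast<size_t>(aH) * (2 * wo);
              size_t best = i00; float bvl = S.relu[i00];
              const size_t cand[3] = { i00 + 1, i00 + aH, i00 + aH + 1 };
              for (int kk = 0; kk < 3; ++kk)
                if (S.relu[cand[kk]] > bvl) { bvl = S.relu[cand[kk]]; best = cand[kk]; }
              const size_t oi = obase + ho + static_cast<size_t>(Ho) * wo;
              S.pooled[oi] = bvl;
              S.pool_idx[oi] = static_cast<int>(best);
            }
        }
      a = S.pooled.data(); aH = Ho; aW = Wo; aC = F;
    } else {
      a = S.relu.data(); aC = F;
    }
    stats[li] = List::create(_["mean"] = NumericVector(S.mean.begin(), S.mean.end()),
                             _["var"] = NumericVector(S.var.begin(), S.var.end()));
  }
  // top activation out
  const size_t top = static_cast<size_t>(aH) * aW * aC * N;
  NumericVector out(top);
  for (size_t i = 0; i < top; ++i) out[i] = a[i];
  out.attr("dim") = IntegerVector::create(aH, aW, aC, N);
  return List::create(_["out"] = out, _["cache"] = cache,
                      _["stats"] = stats, _["running"] = new_running);
}

// Retrieve a layer's post-ReLU activation (1-based layer index).
// [[Rcpp::export]]
NumericVector fs_stack_relu(SEXP cache_ptr, int layer) {
  XPtr<StackCache> cache(cache_ptr);
  if (layer < 1 || layer > static_cast<int>(cache->layers.size()))
    stop("invalid layer index");
  const StackLayer& S = cache->layers[layer - 1];
  NumericVector out(S.relu.size());
  for (size_t i = 0; i < S.relu.size(); ++i) out[i] = S.relu[i];
  out.attr("dim") = IntegerVector::create(S.H, S.W, S.Cout, cache->N);
  return out;
}

// [[Rcpp::export]]
List fs_stack_bwd(SEXP cache_ptr, List layers, NumericVector dtop,
                  double eps, int capture_relu) {
  XPtr<StackCache> cache(cache_ptr);
  const int L = layers.size();
  const int N = cache->N;
  List grads(L);
  NumericVector captured;
  std::vector<float> da(dtop.size());
  for (R_xlen_t i = 0; i < dtop.size(); ++i) da[i] = dtop[i];
  arma::fmat K, dY, dK;
  for (int li = L - 1; li >= 0; --li) {
    List ly = layers[li];
    StackLayer& S = cache->layers[li];
    const int aH = S.H, aW = S.W, F = S.Cout, C = S.Cin;
    const size_t plane = static_cast<size_t>(aH) * aW;
    // unpool
    if (S.pool) {
      std::vector<float> du(plane * F * N, 0.0f);
      for (size_t i = 0; i < S.pool_idx.size(); ++i)
        du[S.pool_idx[i]] += da[i];
      da.swap(du);
    }
    if (capture_relu == li + 1) {
      captured = NumericVector(da.size());
      for (size_t i = 0; i < da.size(); ++i) captured[i] = da[i];
      captured.attr("dim") = IntegerVector::create(aH, aW, F, N);
    }
    // ReLU mask
    for (size_t i = 0; i < da.size(); ++i)
      if (S.relu[i] <= 0) da[i] = 0.0f;
    // batch norm backward
    NumericVector dgamma(F), dbeta(F);
    if (S.bn) {
      NumericVector gv = ly["gamma"];
      const double M = static_cast<double>(plane) * N;
      for (int f = 0; f < F; ++f) {
        const double inv = 1.0 / std::sqrt(S.var[f] + eps);
        double s_dy = 0, s_dyx = 0;
        for (int n = 0; n < N; ++n) {
          const size_t off = plane * (f + static_cast<size_t>(F) * n);
          const float* pz = S.z.data() + off;
          const float* pd = da.data() + off;
          for (size_t i = 0; i < plane; ++i) {
            s_dy += pd[i];
            s_dyx += pd[i] * (pz[i] - S.mean[f]) * inv;
          }
        }
        dgamma[f] = s_dyx; dbeta[f] = s_dy;
        const float g = static_cast<float>(gv[f] * inv);
        if (cache->training) {
          // batch statistics depend on x: full coupled backward
          const float c1 = static_cast<float>(s_dy / M);
          const float c2 = static_cast<float>(s_dyx / M);
          const float mu = static_cast<float>(S.mean[f]);
          const float invf = static_cast<float>(inv);
          for (int n = 0; n < N; ++n) {
            const size_t off = plane * (f + static_cast<size_t>(F) * n);
            const float* pz = S.z.data() + off;
            float* pd = da.data() + off;
            for (size_t i = 0; i < plane; ++i)
              pd[i] = g * (pd[i] - c1 - (pz[i] - mu) * invf * c2);
          }
        } else {
          // running moments are constants: plain affine backward
          for (int n = 0; n < N; ++n) {
            const size_t off = plane * (f + static_cast<size_t>(F) * n);
            float* pd = da.data() + off;
            for (size_t i = 0; i < plane; ++i) pd[i] *= g;
          }
        }
      }
    }
    // conv backward
    NumericVector wv = ly["w"];
    std::vector<float> wf(wv.size());
    for (R_xlen_t i = 0; i < wv.size(); ++i) wf[i] = wv[i];
    arma::fmat Wm(wf.data(), static_cast<arma::uword>(9) * C, F, false, true);
    const float* ain = (li == 0) ? cache->x0.data()
                       : (cache->layers[li - 1].pool
                            ? cache->layers[li - 1].pooled.data()
                            : cache->layers[li - 1].relu.data());
    arma::fmat dWm(static_cast<arma::uword>(9) * C, F, arma::fill::zeros);
    NumericVector db(F);
    std::vector<float> dx(plane * C * N, 0.0f);
    const int nb = subbatch_size(aH, aW, C, N);
    for (int n0 = 0; n0 < N; n0 += nb) {
      const int n1 = std::min(N, n0 + nb);
      const size_t rows = plane * (n1 - n0);
      im2col_batch(ain, aH, aW, C, n0, n1, K);
      dY.set_size(rows, F);
      for (int f = 0; f < F; ++f)
        for (int n = n0; n < n1; ++n)
          std::copy(da.data() + plane * (f + static_cast<size_t>(F) * n),
                    da.data() + plane * (f + static_cast<size_t>(F) * n) + plane,
                    dY.colptr(f) + plane * (n - n0));
      dWm += K.t() * dY;
      if (li == 0) continue;  // input gradient of the first layer is unused
      dK = dY * Wm.t();
      // col2im scatter into dx
      for (int c = 0; c < C; ++c)
        for (int kx = 0; kx < 3; ++kx) {
          const int dxo = kx - 1;
          for (int ky = 0; ky < 3; ++ky) {
            const int dyo = ky - 1;
            const float* col = dK.colptr(ky + 3 * kx + 9 * c);
            for (int n = n0; n < n1; ++n) {
              float* dxn = dx.data() + plane * (c + static_cast<size_t>(C) * n);
              const float* coln = col + plane * (n - n0);
              for (int w = 0; w < aW; ++w) {
                const int ws = w + dxo;
                if (ws < 0 || ws >= aW) continue;
                const int h_lo = std::max(0, -dyo);
                const int h_hi = std::min(aH, aH - dyo);
                const float* src = coln + h_lo + static_cast<size_t>(aH) * w;
                float* dst = dxn + (h_lo + dyo) + static_cast<size_t>(aH) * ws;
                for (int h = 0; h < h_hi - h_lo; ++h) dst[h] += src[h];
              }
            }
          }
        }
    }
    for (int f = 0; f < F; ++f) {
      double s = 0;
      for (int n = 0; n < N; ++n) {
        const float* pd = da.data() + plane * (f + static_cast<size_t>(F) * n);
        for (size_t i = 0; i < plane; ++i) s += pd[i];
      }
      db[f] = s;
    }
    NumericVector dw(dWm.n_elem);
    std::copy(dWm.begin(), dWm.end(), dw.begin());
    dw.attr("dim") = IntegerVector::create(3, 3, C, F);
    grads[li] = List::create(_["dw"] = dw, _["db"] = db,
                             _["dgamma"] = dgamma, _["dbeta"] = dbeta);
    da.swap(dx);
  }
  return List::create(_["grads"] = grads, _["captured"] = captured);
}
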