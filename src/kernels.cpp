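#include <Rcpp.h>
using namespace Rcpp;

// Column-major feature maps throughout: x[i, j, c] at i + j*H + c*H*W (0-based).
// All convolutions are stride-1 "same" with zero padding pad = (K-1)/2.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, int H, int W, int C,
                         int K, int pad) {
  NumericMatrix cols(H * W, K * K * C);
  for (int m = 0; m < C; ++m) {
    for (int v = 0; v < K; ++v) {
      for (int u = 0; u < K; ++u) {
        int col = u + v * K + m * K * K;
        for (int j = 0; j < W; ++j) {
          int sj = j + v - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + u - pad;
            if (si < 0 || si >= H) continue;
            cols(i + j * H, col) = x[si + sj * H + m * H * W];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& gcols, int H, int W, int C,
                         int K, int pad) {
  NumericVector gx(H * W * C);
  for (int m = 0; m < C; ++m) {
    for (int v = 0; v < K; ++v) {
      for (int u = 0; u < K; ++u) {
        int col = u + v * K + m * K * K;
        for (int j = 0; j < W; ++j) {
          int sj = j + v - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + u - pad;
            if (si < 0 || si >= H) continue;
            gx[si + sj * H + m * H * W] += gcols(i + j * H, col);
          }
        }
      }
    }
  }
  return gx;
}

// Depthwise convolution: one K x K filter per channel.
// [[Rcpp::export]]
NumericVector cpp_dw_fwd(const NumericVector& x, int H, int W, int C,
                         const NumericVector& w, int K, int pad) {
  NumericVector y(H * W * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[c * H * W];
    const double* wc = &w[c * K * K];
    double* yc = &y[c * H * W];
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double acc = 0.0;
        for (int v = 0; v < K; ++v) {
          int sj = j + v - pad;
          if (sj < 0 || sj >= W) continue;
          for (int u = 0; u < K; ++u) {
            int si = i + u - pad;
            if (si < 0 || si >= H) continue;
            acc += wc[u + v * K] * xc[si + sj * H];
          }
        }
        yc[i + j * H] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dw_bwd(const NumericVector& x, const NumericVector& gy,
                int H, int W, int C, const NumericVector& w, int K, int pad) {
  NumericVector gx(H * W * C), gw(K * K * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[c * H * W];
    const double* wc = &w[c * K * K];
    const double* gyc = &gy[c * H * W];
    double* gxc = &gx[c * H * W];
    double* gwc = &gw[c * K * K];
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double g = gyc[i + j * H];
        if (g == 0.0) continue;
        for (int v = 0; v < K; ++v) {
          int sj = j + v - pad;
          if (sj < 0 || sj >= W) continue;
          for (int u = 0; u < K; ++u) {
            int si = i + u - pad;
            if (si < 0 || si >= H) continue;
            gxc[si + sj * H] += g * wc[u + v * K];
            gwc[u + v * K] += g * xc[si + sj * H];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// 2x2 max pooling with stride 2 (H, W even); idx records the 1-based
// linear argmax into the input so the backward pass can scatter.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = R_NegInf;
        int bi = 0;
        for (int dv = 0; dv < 2; ++dv) {
          for (int du = 0; du < 2; ++du) {
            int p = (2 * i + du) + (2 * j + dv) * H + c * H * W;
            if (x[p] > best) { best = x[p]; bi = p; }
          }
        }
        int q = i + j * Ho + c * Ho * Wo;
        y[q] = best;
        idx[q] = bi + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const IntegerVector& idx, const NumericVector& gy,
                              int H, int W, int C) {
  NumericVector gx(H * W * C);
  for (int q = 0; q < gy.size(); ++q) gx[idx[q] - 1] += gy[q];
  return gx;
}

// Bilinear sampling at continuous (row, col) 0-based coordinates; points
// falling outside the image read the background value 0.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear(const NumericVector& img, int H, int W, int C,
                           const NumericVector& rows, const NumericVector& cols) {
  int P = rows.size();
  NumericMatrix out(P, C);
  for (int p = 0; p < P; ++p) {
    double r = rows[p], cc = cols[p];
    int r0 = (int)std::floor(r), c0 = (int)std::floor(cc);
    double fr = r - r0, fc = cc - c0;
    for (int ch = 0; ch < C; ++ch) {
      double acc = 0.0;
      for (int dr = 0; dr <= 1; ++dr) {
        int ri = r0 + dr;
        if (ri < 0 || ri >= H) continue;
        double wr = dr ? fr : 1.0 - fr;
        for (int dc = 0; dc <= 1; ++dc) {
          int ci = c0 + dc;
          if (ci < 0 || ci >= W) continue;
          double wc = dc ? fc : 1.0 - fc;
          acc += wr * wc * img[ri + ci * H + ch * H * W];
        }
      }
      out(p, ch) = acc;
    }
  }
  return out;
}

// Bresenham rasterization of pen-down segments onto an H x W canvas with a
// square stamp of width `width` (offsets -(width-1)/2 .. width/2).
// Endpoints are 1-based integer (row, col); out-of-canvas ink is clipped.
// [[Rcpp::export]]
NumericMatrix cpp_draw_segments(const IntegerVector& r0, const IntegerVector& c0,
                                const IntegerVector& r1, const IntegerVector& c1,
                                int H, int W, int width) {
  NumericMatrix canvas(H, W);
  int lo = -(width - 1) / 2, hi = width / 2;
  for (int s = 0; s < r0.size(); ++s) {
    int x0 = c0[s] - 1, y0 = r0[s] - 1, x1 = c1[s] - 1, y1 = r1[s] - 1;
    int dx = std::abs(x1 - x0), dy = -std::abs(y1 - y0);
    int sx = x0 < x1 ? 1 : -1, sy = y0 < y1 ? 1 : -1;
    int err = dx + dy;
    while (true) {
      for (int du = lo; du <= hi; ++du) {
        int yy = y0 + du;
        if (yy < 0 || yy >= H) continue;
        for (int dv = lo; dv <= hi; ++dv) {
          int xx = x0 + dv;
          if (xx < 0 || xx >= W) continue;
          canvas(yy, xx) = 1.0;
        }
      }
      if (x0 == x1 && y0 == y1) break;
      int e2 = 2 * err;
      if (e2 >= dy) { err += dy; x0 += sx; }
      if (e2 <= dx) { err += dx; y0 += sy; }
    }
  }
  return canvas;
}
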