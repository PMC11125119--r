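// Dense tensor primitives for the segmentation model.
//
// Feature maps are arma::cube with dims (H, W, C); channel = slice.
// Convolution weights are matrices of shape C_out x (C_in*kh*kw); the
// column layout matches im2col below: col = c*kh*kw + dj*kh + di, i.e.
// channel-major, then kernel column, then kernel row (column-major within
// the window). R-side helpers build these matrices from (kh,kw,cin,cout)
// arrays so callers never handle the flat layout directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int& H2, int& W2) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  H2 = (H + 2 * pad - kh) / stride + 1;
  W2 = (W + 2 * pad - kw) / stride + 1;
  arma::mat cols(C * kh * kw, (size_t)H2 * W2, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = c * kh * kw + dj * kh + di;
        for (int w2 = 0; w2 < W2; ++w2) {
          const int win = w2 * stride - pad + dj;
          if (win < 0 || win >= W) continue;
          for (int h2 = 0; h2 < H2; ++h2) {
            const int hin = h2 * stride - pad + di;
            if (hin < 0 || hin >= H) continue;
            cols(r, (size_t)w2 * H2 + h2) = xc(hin, win);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad, arma::cube& out) {
  const int H2 = (H + 2 * pad - kh) / stride + 1;
  const int W2 = (W + 2 * pad - kw) / stride + 1;
  out.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    arma::mat& oc = out.slice(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = c * kh * kw + dj * kh + di;
        for (int w2 = 0; w2 < W2; ++w2) {
          const int win = w2 * stride - pad + dj;
          if (win < 0 || win >= W) continue;
          for (int h2 = 0; h2 < H2; ++h2) {
            const int hin = h2 * stride - pad + di;
            if (hin < 0 || hin >= H) continue;
            oc(hin, win) += cols(r, (size_t)w2 * H2 + h2);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw,
                      int stride, int pad) {
  int H2, W2;
  arma::mat cols = im2col(x, kh, kw, stride, pad, H2, W2);
  arma::mat y = w * cols;                 // C_out x (H2*W2)
  y.each_col() += b;
  arma::cube out(H2, W2, w.n_rows);
  for (arma::uword c = 0; c < w.n_rows; ++c) {
    out.slice(c) = arma::reshape(y.row(c), H2, W2);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& gout, const arma::cube& x,
                    const arma::mat& w, int kh, int kw,
                    int stride, int pad, bool need_gx) {
  int H2, W2;
  arma::mat cols = im2col(x, kh, kw, stride, pad, H2, W2);
  const int Cout = gout.n_slices;
  arma::mat gmat(Cout, (size_t)H2 * W2);
  for (int c = 0; c < Cout; ++c) {
    gmat.row(c) = arma::vectorise(gout.slice(c)).t();
  }
  arma::mat gW = gmat * cols.t();
  arma::vec gb = arma::sum(gmat, 1);
  arma::cube gx;
  if (need_gx) {
    arma::mat gcols = w.t() * gmat;
    col2im(gcols, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride, pad, gx);
  }
  return List::create(_["gx"] = gx, _["gw"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2d(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = (H + 2 * pad - k) / stride + 1;
  const int W2 = (W + 2 * pad - k) / stride + 1;
  arma::cube out(H2, W2, C);
  for (int c = 0; c < C; ++c) {
    for (int w2 = 0; w2 < W2; ++w2) {
      for (int h2 = 0; h2 < H2; ++h2) {
        double m = -arma::datum::inf;
        for (int dj = 0; dj < k; ++dj) {
          const int win = w2 * stride - pad + dj;
          if (win < 0 || win >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int hin = h2 * stride - pad + di;
            if (hin < 0 || hin >= H) continue;
            m = std::max(m, x(hin, win, c));
          }
        }
        out(h2, w2, c) = m;
      }
    }
  }
  return out;
}

// Nearest-neighbour x2 upsampling and its adjoint (2x2 sum pooling).
// [[Rcpp::export]]
arma::cube cpp_upsample2x(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double v = x(h, w, c);
        out(2 * h, 2 * w, c) = v;
        out(2 * h + 1, 2 * w, c) = v;
        out(2 * h, 2 * w + 1, c) = v;
        out(2 * h + 1, 2 * w + 1, c) = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_downsum2x(const arma::cube& g) {
  const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
  arma::cube out(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        out(h, w, c) = g(2 * h, 2 * w, c) + g(2 * h + 1, 2 * w, c) +
                       g(2 * h, 2 * w + 1, c) + g(2 * h + 1, 2 * w + 1, c);
      }
    }
  }
  return out;
}

static double bilinear_at(const arma::mat& m, double y, double x) {
  const int H = m.n_rows, W = m.n_cols;
  if (y < -1.0 || y > H || x < -1.0 || x > W) return 0.0;
  if (y < 0) y = 0;
  if (x < 0) x = 0;
  int y0 = (int)y, x0 = (int)x;
  int y1 = y0 + 1, x1 = x0 + 1;
  if (y0 >= H - 1) { y0 = y1 = H - 1; y = y0; }
  if (x0 >= W - 1) { x0 = x1 = W - 1; x = x0; }
  const double ly = y - y0, lx = x - x0;
  return m(y0, x0) * (1 - ly) * (1 - lx) + m(y1, x0) * ly * (1 - lx) +
         m(y0, x1) * (1 - ly) * lx + m(y1, x1) * ly * lx;
}

// RoIAlign: boxes are (x1,y1,x2,y2) in image coordinates, half-open;
// spatial_scale maps image to feature coordinates. Two sampling points
// per bin axis, averaged (the standard setting).
// [[Rcpp::export]]
List cpp_roi_align(const arma::cube& x, const arma::mat& boxes,
                   int out_h, int out_w, double spatial_scale) {
  const int C = x.n_slices;
  List out(boxes.n_rows);
  for (arma::uword r = 0; r < boxes.n_rows; ++r) {
    const double x1 = boxes(r, 0) * spatial_scale;
    const double y1 = boxes(r, 1) * spatial_scale;
    const double x2 = boxes(r, 2) * spatial_scale;
    const double y2 = boxes(r, 3) * spatial_scale;
    const double rw = std::max(x2 - x1, 1e-3);
    const double rh = std::max(y2 - y1, 1e-3);
    const double bw = rw / out_w, bh = rh / out_h;
    arma::cube roi(out_h, out_w, C);
    for (int c = 0; c < C; ++c) {
      const arma::mat& xc = x.slice(c);
      for (int j = 0; j < out_w; ++j) {
        for (int i = 0; i < out_h; ++i) {
          double acc = 0.0;
          for (int sy = 0; sy < 2; ++sy) {
            const double yy = y1 + bh * (i + (sy + 0.5) / 2.0) - 0.5;
            for (int sx = 0; sx < 2; ++sx) {
              const double xx = x1 + bw * (j + (sx + 0.5) / 2.0) - 0.5;
              acc += bilinear_at(xc, yy, xx);
            }
          }
          roi(i, j, c) = acc / 4.0;
        }
      }
    }
    out[r] = roi;
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear_resize(const arma::cube& x, int out_h, int out_w) {
  const int C = x.n_slices;
  const double sy = (double)x.n_rows / out_h, sx = (double)x.n_cols / out_w;
  arma::cube out(out_h, out_w, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int j = 0; j < out_w; ++j) {
      const double xx = (j + 0.5) * sx - 0.5;
      for (int i = 0; i < out_h; ++i) {
        const double yy = (i + 0.5) * sy - 0.5;
        out(i, j, c) = bilinear_at(xc, yy, xx);
      }
    }
  }
  return out;
}
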