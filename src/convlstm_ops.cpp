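// Hot kernels for the ConvLSTM: 2D convolution (stride 1, 'same' zero
// padding) and max pooling, forward and backward, over batched R arrays.
// Layouts follow R's column-major convention:
//   activations x : [H, W, C, B]
//   conv weights w: [kh, kw, Cin, F]  (flattened rows match im2col rows)
// Padding before = floor((k-1)/2), after = rest (TensorFlow 'SAME').

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void check_dims(const IntegerVector& d, int n, const char* what) {
  if (d.size() != n) stop("%s must be a %d-d array", what, n);
}

// Fill the im2col matrix (kh*kw*C x H*W) for one batch item.
static void im2col(const double* xb, int H, int W, int C,
                   int kh, int kw, int pt, int pl, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kj * kh + c * kh * kw;
        for (int j = 0; j < W; ++j) {
          int j2 = j + kj - pl;
          double* dst = col.colptr(0) + r; // element (r, p) with p = i + j*H
          if (j2 < 0 || j2 >= W) {
            for (int i = 0; i < H; ++i) col(r, i + j * H) = 0.0;
          } else {
            const double* xcol = xb + ((size_t)c * W + j2) * H;
            for (int i = 0; i < H; ++i) {
              int i2 = i + ki - pt;
              col(r, i + j * H) = (i2 >= 0 && i2 < H) ? xcol[i2] : 0.0;
            }
          }
          (void)dst;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  check_dims(xd, 4, "x"); check_dims(wd, 4, "w");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cw = wd[2], F = wd[3];
  if (Cw != C) stop("weight input channels (%d) != activation channels (%d)", Cw, C);
  if (b.size() != F) stop("bias length != filter count");
  int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  int K = kh * kw * C, HW = H * W;

  NumericVector y((R_xlen_t)H * W * F * B);
  y.attr("dim") = IntegerVector::create(H, W, F, B);
  arma::mat Wm(w.begin(), K, F, false);
  arma::rowvec bv(b.begin(), F, false);
  arma::mat col(K, HW);
  for (int bi = 0; bi < B; ++bi) {
    im2col(x.begin() + (size_t)bi * HW * C, H, W, C, kh, kw, pt, pl, col);
    arma::mat yb(y.begin() + (size_t)bi * HW * F, HW, F, false, true);
    yb = col.t() * Wm;
    yb.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  check_dims(xd, 4, "x"); check_dims(wd, 4, "w");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  int K = kh * kw * C, HW = H * W;

  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)kh * kw * C * F);
  dw.attr("dim") = wd;
  NumericVector db(F);

  arma::mat Wm(w.begin(), K, F, false);
  arma::mat dWm(dw.begin(), K, F, false, true);
  arma::rowvec dbv(db.begin(), F, false, true);
  arma::mat col(K, HW);
  for (int bi = 0; bi < B; ++bi) {
    im2col(x.begin() + (size_t)bi * HW * C, H, W, C, kh, kw, pt, pl, col);
    arma::mat dyb(dy.begin() + (size_t)bi * HW * F, HW, F, false);
    dWm += col * dyb;
    dbv += arma::sum(dyb, 0);
    arma::mat dcol = Wm * dyb.t();   // K x HW
    double* dxb = dx.begin() + (size_t)bi * HW * C;
    for (int c = 0; c < C; ++c) {
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          int r = ki + kj * kh + c * kh * kw;
          for (int j = 0; j < W; ++j) {
            int j2 = j + kj - pl;
            if (j2 < 0 || j2 >= W) continue;
            double* xcol = dxb + ((size_t)c * W + j2) * H;
            for (int i = 0; i < H; ++i) {
              int i2 = i + ki - pt;
              if (i2 >= 0 && i2 < H) xcol[i2] += dcol(r, i + j * H);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward(NumericVector x, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  check_dims(xd, 4, "x");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (ph < 1 || pw < 1) stop("pool kernel must be >= 1");
  int Ho = H / ph, Wo = W / pw;
  if (Ho < 1 || Wo < 1)
    stop("pooling reduces a %dx%d map below 1x1 (kernel %dx%d)", H, W, ph, pw);

  R_xlen_t n = (R_xlen_t)Ho * Wo * C * B;
  NumericVector y(n);
  IntegerVector idx(n);   // 0-based linear index into x of each max
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  R_xlen_t q = 0;
  for (int bi = 0; bi < B; ++bi) {
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)bi * C + c) * H * W;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io, ++q) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dj = 0; dj < pw; ++dj) {
            for (int di = 0; di < ph; ++di) {
              size_t lin = base + (size_t)(jo * pw + dj) * H + (io * ph + di);
              if (xp[lin] > best) { best = xp[lin]; besti = lin; }
            }
          }
          y[q] = best;
          idx[q] = (int)besti;
        }
      }
    }
  }
  // note: q runs in [io, jo, c, bi] order == column-major of [Ho,Wo,C,B]
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int k = 0; k < xdim.size(); ++k) n *= xdim[k];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t q = 0; q < dy.size(); ++q) dx[idx[q]] += dy[q];
  return dx;
}
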