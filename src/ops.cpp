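// Low-level tensor ops for the network graphs.
// Array layout follows R: column-major, dims (H, W, C, N).
// Weights for k x k convs have dims (k, k, Cin, Cout); biases length Cout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Batched im2col, transposed layout: Kt is (H*W*N) x (k*k*Cin) with row
// index n*H*W + i + j*H and column index r = ki + kj*k + c*k*k, so the
// inner copy loop is contiguous in both source and destination.
static void im2col_batch(const double *x, int H, int W, int C, int k, int N,
                         mat &Kt) {
  const int pad = (k - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  Kt.zeros();
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (std::size_t)n * HW * C;
    for (int c = 0; c < C; ++c) {
      const double *xc = xn + (std::size_t)c * HW;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int r = ki + kj * k + c * k * k;
          double *Kcol = Kt.colptr(r) + (std::size_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            const double *src = xc + (std::size_t)sj * H;
            double *dst = Kcol + (std::size_t)j * H;
            const int i0 = std::max(0, -(0 + ki - pad));
            const int i1 = std::min(H, H - (ki - pad));
            for (int i = i0; i < i1; ++i) dst[i] = src[i + ki - pad];
          }
        }
      }
    }
  }
}

static void col2im_batch(const mat &GKt, int H, int W, int C, int k, int N,
                         double *gx) {
  const int pad = (k - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double *xn = gx + (std::size_t)n * HW * C;
    for (int c = 0; c < C; ++c) {
      double *xc = xn + (std::size_t)c * HW;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int r = ki + kj * k + c * k * k;
          const double *Kcol = GKt.colptr(r) + (std::size_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            double *dst = xc + (std::size_t)sj * H;
            const double *src = Kcol + (std::size_t)j * H;
            const int i0 = std::max(0, -(0 + ki - pad));
            const int i1 = std::min(H, H - (ki - pad));
            for (int i = i0; i < i1; ++i) dst[i + ki - pad] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                   Rcpp::NumericVector b, int H, int W,
                                   int Cin, int Cout, int k, int N) {
  const std::size_t HW = (std::size_t)H * W;
  Rcpp::NumericVector out(HW * Cout * N);
  const mat Wmat(const_cast<double *>(w.begin()), k * k * Cin, Cout, false);
  const vec bv(const_cast<double *>(b.begin()), Cout, false);
  mat Kt(HW * N, k * k * Cin);
  im2col_batch(x.begin(), H, W, Cin, k, N, Kt);
  mat O = Kt * Wmat; // (H*W*N) x Cout, rows grouped by sample
  O.each_row() += bv.t();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      std::copy(O.colptr(co) + (std::size_t)n * HW,
                O.colptr(co) + (std::size_t)(n + 1) * HW,
                out.begin() + ((std::size_t)n * Cout + co) * HW);
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                          Rcpp::NumericVector gy, int H, int W, int Cin,
                          int Cout, int k, int N) {
  const std::size_t HW = (std::size_t)H * W;
  Rcpp::NumericVector gx(HW * Cin * N);
  Rcpp::NumericVector gw((std::size_t)k * k * Cin * Cout);
  Rcpp::NumericVector gb(Cout);
  const mat Wmat(const_cast<double *>(w.begin()), k * k * Cin, Cout, false);
  mat Kt(HW * N, k * k * Cin);
  im2col_batch(x.begin(), H, W, Cin, k, N, Kt);
  // restack gy from (H,W,Cout,N) into (H*W*N) x Cout
  mat Gy(HW * N, Cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *src = gy.begin() + ((std::size_t)n * Cout + co) * HW;
      std::copy(src, src + HW, Gy.colptr(co) + (std::size_t)n * HW);
    }
  }
  mat Gw(gw.begin(), k * k * Cin, Cout, false);
  Gw = Kt.t() * Gy;
  vec Gb(gb.begin(), Cout, false);
  Gb = sum(Gy, 0).t();
  mat GKt = Gy * Wmat.t(); // (H*W*N) x (k*k*Cin)
  col2im_batch(GKt, H, W, Cin, k, N, gx.begin());
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Transposed convolution, kernel 2x2, stride 2: (H,W,Cin) -> (2H,2W,Cout).
// Non-overlapping: output pixel (2i+a, 2j+b) gets W[a,b,:,co] . x[i,j,:] + b.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_convT2_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                   Rcpp::NumericVector b, int H, int W, int Cin,
                                   int Cout, int N) {
  const int H2 = 2 * H, W2 = 2 * W;
  Rcpp::NumericVector out((std::size_t)H2 * W2 * Cout * N);
  const vec bv(const_cast<double *>(b.begin()), Cout, false);
  for (int n = 0; n < N; ++n) {
    // X as (H*W) x Cin
    const mat X(const_cast<double *>(x.begin()) + (std::size_t)n * H * W * Cin,
                H * W, Cin, false);
    double *o = out.begin() + (std::size_t)n * H2 * W2 * Cout;
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        mat Wab(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wab(ci, co) = w[a + 2 * bb + 4 * (ci + (std::size_t)Cin * co)];
        mat O = X * Wab; // (H*W) x Cout
        O.each_row() += bv.t();
        for (int co = 0; co < Cout; ++co)
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              o[(std::size_t)(2 * i + a) + (std::size_t)H2 * (2 * j + bb) +
                (std::size_t)H2 * W2 * co] = O(i + (std::size_t)H * j, co);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_convT2_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                          Rcpp::NumericVector gy, int H, int W, int Cin,
                          int Cout, int N) {
  const int H2 = 2 * H, W2 = 2 * W;
  Rcpp::NumericVector gx((std::size_t)H * W * Cin * N);
  Rcpp::NumericVector gw((std::size_t)4 * Cin * Cout);
  Rcpp::NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    const mat X(const_cast<double *>(x.begin()) + (std::size_t)n * H * W * Cin,
                H * W, Cin, false);
    mat GX(gx.begin() + (std::size_t)n * H * W * Cin, H * W, Cin, false);
    const double *g = gy.begin() + (std::size_t)n * H2 * W2 * Cout;
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        mat Gab(H * W, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              Gab(i + (std::size_t)H * j, co) =
                  g[(std::size_t)(2 * i + a) + (std::size_t)H2 * (2 * j + bb) +
                    (std::size_t)H2 * W2 * co];
        mat GWab = X.t() * Gab; // Cin x Cout
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            gw[a + 2 * bb + 4 * (ci + (std::size_t)Cin * co)] += GWab(ci, co);
        for (int co = 0; co < Cout; ++co) gb[co] += accu(Gab.col(co));
        mat Wab(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wab(ci, co) = w[a + 2 * bb + 4 * (ci + (std::size_t)Cin * co)];
        GX += Gab * Wab.t();
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Max pooling 2x2 stride 2 with argmax bookkeeping (0-based linear index
// into the input array) for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(Rcpp::NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector out((std::size_t)Ho * Wo * C * N);
  Rcpp::IntegerVector idx((std::size_t)Ho * Wo * C * N);
  std::size_t q = 0;
  for (int n = 0; n < N; ++n) {
    const std::size_t off = (std::size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bi = 0;
          for (int bb = 0; bb < 2; ++bb) {
            for (int a = 0; a < 2; ++a) {
              const std::size_t p = off + (std::size_t)(2 * i + a) +
                                    (std::size_t)H * (2 * j + bb) +
                                    (std::size_t)H * W * c;
              if (x[p] > best) { best = x[p]; bi = p; }
            }
          }
          out[q] = best;
          idx[q] = (int)bi;
          ++q;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_maxpool2_bwd(Rcpp::IntegerVector idx,
                                     Rcpp::NumericVector gy, int H, int W,
                                     int C, int N) {
  Rcpp::NumericVector gx((std::size_t)H * W * C * N);
  for (R_xlen_t q = 0; q < gy.size(); ++q) gx[idx[q]] += gy[q];
  return gx;
}

// Nearest-neighbour x2 upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2_fwd(Rcpp::NumericVector x, int H, int W,
                                      int C, int N) {
  const int H2 = 2 * H, W2 = 2 * W;
  Rcpp::NumericVector out((std::size_t)H2 * W2 * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xi =
          x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      double *o = out.begin() + (std::size_t)H2 * W2 * (c + (std::size_t)C * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = xi[i + (std::size_t)H * j];
          o[2 * i + (std::size_t)H2 * (2 * j)] = v;
          o[2 * i + 1 + (std::size_t)H2 * (2 * j)] = v;
          o[2 * i + (std::size_t)H2 * (2 * j + 1)] = v;
          o[2 * i + 1 + (std::size_t)H2 * (2 * j + 1)] = v;
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_upsample2_bwd(Rcpp::NumericVector gy, int H, int W,
                                      int C, int N) {
  const int H2 = 2 * H, W2 = 2 * W;
  Rcpp::NumericVector gx((std::size_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *g =
          gy.begin() + (std::size_t)H2 * W2 * (c + (std::size_t)C * n);
      double *o = gx.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          o[i + (std::size_t)H * j] =
              g[2 * i + (std::size_t)H2 * (2 * j)] +
              g[2 * i + 1 + (std::size_t)H2 * (2 * j)] +
              g[2 * i + (std::size_t)H2 * (2 * j + 1)] +
              g[2 * i + 1 + (std::size_t)H2 * (2 * j + 1)];
    }
  }
  return gx;
}
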