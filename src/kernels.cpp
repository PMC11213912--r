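// Low-level numerical kernels for the two-branch segmentation network and
// image plumbing. Feature maps are H x W x C cubes (R column-major arrays);
// convolution weights are (kh*kw*Cin) x Cout matrices so forward/backward
// reduce to one im2col plus BLAS matrix products.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// column order inside an im2col row: (di, dj, c) with di fastest; must match
// the weight layout produced by conv_weight_init() on the R side
static arma::mat im2col_same(const arma::cube &x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat col(H * (size_t)W, (size_t)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const size_t q = (size_t)c * kh * kw + (size_t)dj * kh + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - ph;
            if (si < 0 || si >= H) continue;
            col((size_t)j * H + i, q) = x(si, sj, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube &x, const arma::mat &w,
                     const arma::vec &b, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat col = im2col_same(x, kh, kw);
  arma::mat y = col * w;            // (H*W) x Cout
  y.each_row() += b.t();
  return arma::cube(y.memptr(), H, W, w.n_cols);
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const arma::cube &x, const arma::mat &w,
               const arma::cube &dy, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int Cout = w.n_cols;
  arma::mat col = im2col_same(x, kh, kw);
  arma::mat D(const_cast<double *>(dy.memptr()), (size_t)H * W, Cout, false);
  arma::mat dw = col.t() * D;
  arma::vec db = arma::sum(D, 0).t();
  arma::mat dcol = D * w.t();       // (H*W) x (kh*kw*C)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const size_t q = (size_t)c * kh * kw + (size_t)dj * kh + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - ph;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dcol((size_t)j * H + i, q);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; idx stores the flat index into x per output cell
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf; size_t bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = (size_t)c * H * W + (size_t)sj * H + si; }
          }
        y(i, j, c) = best; idx(i, j, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::cube maxpool2_bw(const arma::ucube &idx, const arma::cube &dy,
                       int H, int W) {
  arma::cube dx(H, W, dy.n_slices, arma::fill::zeros);
  const size_t n = idx.n_elem;
  for (size_t k = 0; k < n; ++k) dx(idx(k)) += dy(k);
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fw")]]
arma::cube upsample2_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::cube upsample2_bw(const arma::cube &dy) {
  const int Ho = dy.n_rows / 2, Wo = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * Wo; ++j)
      for (int i = 0; i < 2 * Ho; ++i)
        dx(i / 2, j / 2, c) += dy(i, j, c);
  return dx;
}

// mean over f x f blocks (box filter downsample; exact for f | dim)
// [[Rcpp::export(name = ".box_downsample")]]
arma::cube box_downsample(const arma::cube &x, int f) {
  const int Ho = x.n_rows / f, Wo = x.n_cols / f, C = x.n_slices;
  arma::cube y(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo * f; ++j)
      for (int i = 0; i < Ho * f; ++i)
        y(i / f, j / f, c) += x(i, j, c);
  y /= (double)(f * f);
  return y;
}

// 4-connected labeling of a binary matrix, labels in raster-scan order
// [[Rcpp::export(name = ".label4")]]
IntegerMatrix label4(const LogicalMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(j * H + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        const int ni[4] = {pi - 1, pi + 1, pi, pi};
        const int nj[4] = {pj, pj, pj - 1, pj + 1};
        for (int k = 0; k < 4; ++k) {
          if (ni[k] < 0 || ni[k] >= H || nj[k] < 0 || nj[k] >= W) continue;
          if (mask(ni[k], nj[k]) && lab(ni[k], nj[k]) == 0) {
            lab(ni[k], nj[k]) = next;
            stack.push_back(nj[k] * H + ni[k]);
          }
        }
      }
    }
  return lab;
}
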