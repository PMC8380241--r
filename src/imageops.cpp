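// Low-level image kernels shared by the synthetic renderer, the gating
// feature extractor and the training-time augmentation. All images are
// column-major arma::mat in [0,1] or raw 16-bit scale; callers own scaling.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Separable Gaussian blur, replicate-edge padding. sigma <= 0 is identity.
// [[Rcpp::export]]
arma::mat cpp_gaussian_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; i++)
    k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= accu(k);
  const int nr = img.n_rows, nc = img.n_cols;
  mat tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; j++) {       // vertical pass
    for (int i = 0; i < nr; i++) {
      double s = 0;
      for (int d = -r; d <= r; d++) {
        int ii = std::min(std::max(i + d, 0), nr - 1);
        s += k(d + r) * img(ii, j);
      }
      tmp(i, j) = s;
    }
  }
  for (int j = 0; j < nc; j++) {       // horizontal pass
    for (int i = 0; i < nr; i++) {
      double s = 0;
      for (int d = -r; d <= r; d++) {
        int jj = std::min(std::max(j + d, 0), nc - 1);
        s += k(d + r) * tmp(i, jj);
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Sobel gradient magnitude, replicate-edge padding.
// [[Rcpp::export]]
arma::mat cpp_sobel_mag(const arma::mat& img) {
  const int nr = img.n_rows, nc = img.n_cols;
  mat out(nr, nc);
  auto at = [&](int i, int j) {
    return img(std::min(std::max(i, 0), nr - 1),
               std::min(std::max(j, 0), nc - 1));
  };
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      double gx = at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)
                - at(i - 1, j - 1) - 2 * at(i, j - 1) - at(i + 1, j - 1);
      double gy = at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1)
                - at(i - 1, j - 1) - 2 * at(i - 1, j) - at(i - 1, j + 1);
      out(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// Inverse-mapped affine resample about the image centre with bilinear
// interpolation and zero padding outside the source. Applied as:
// optional x/y reflection, then rotation by angle_deg, then scaling,
// then translation by (tx, ty) pixels (output = transformed input).
// [[Rcpp::export]]
arma::mat cpp_affine_warp(const arma::mat& img, bool flip_x, bool flip_y,
                          double angle_deg, double tx, double ty,
                          double scale) {
  const int nr = img.n_rows, nc = img.n_cols;
  const double cy = (nr - 1) / 2.0, cx = (nc - 1) / 2.0;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  mat out(nr, nc, fill::zeros);
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      // inverse map: undo translation, scale, rotation, reflection
      double y = (i - cy - ty) / scale, x = (j - cx - tx) / scale;
      double xs =  ct * x + st * y;        // rotate by -angle
      double ys = -st * x + ct * y;
      if (flip_x) xs = -xs;
      if (flip_y) ys = -ys;
      double si = ys + cy, sj = xs + cx;
      int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      double fi = si - i0, fj = sj - j0;
      double v = 0;
      for (int di = 0; di <= 1; di++) {
        for (int dj = 0; dj <= 1; dj++) {
          int ii = i0 + di, jj = j0 + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          double w = (di ? fi : 1 - fi) * (dj ? fj : 1 - fj);
          v += w * img(ii, jj);
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}
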