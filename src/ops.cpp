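#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// symmetric reflection of an out-of-range index into [0, n-1]
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  int h = img.nrow(), w = img.ncol(), r = k / 2;
  NumericMatrix out(h, w);
  std::vector<double> buf(k * k);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = reflect_idx(j + dj, w);
        for (int di = -r; di <= r; ++di) {
          buf[m++] = img(reflect_idx(i + di, h), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(i, j) = buf[m / 2];
    }
  }
  return out;
}

// Sample `img` on an `oh` x `ow` output grid through the pull map
//   src_x = a11*x + a12*y + t1,  src_y = a21*x + a22*y + t2
// where (x, y) = (column, row) in 1-based pixel-centre coordinates.
// method 0 = bilinear (background outside), 1 = nearest (background outside),
// method 2 = bilinear with clamp-to-edge (used for resizing).
// [[Rcpp::export]]
NumericMatrix affine_sample_cpp(NumericMatrix img, NumericVector A,
                                NumericVector t, int oh, int ow,
                                int method, double background) {
  int h = img.nrow(), w = img.ncol();
  double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3]; // column-major 2x2
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j) {
    double x = j + 1.0;
    for (int i = 0; i < oh; ++i) {
      double y = i + 1.0;
      double sx = a11 * x + a12 * y + t[0];
      double sy = a21 * x + a22 * y + t[1];
      if (method == 1) {
        int ci = (int)std::lround(sy) - 1, cj = (int)std::lround(sx) - 1;
        out(i, j) = (ci < 0 || ci >= h || cj < 0 || cj >= w)
                        ? background : img(ci, cj);
        continue;
      }
      if (method == 2) { // clamp coordinates into the grid
        sx = std::min(std::max(sx, 1.0), (double)w);
        sy = std::min(std::max(sy, 1.0), (double)h);
      }
      double fx = std::floor(sx), fy = std::floor(sy);
      int j0 = (int)fx - 1, i0 = (int)fy - 1;
      double wx = sx - fx, wy = sy - fy;
      double acc = 0.0;
      for (int dj = 0; dj <= 1; ++dj) {
        for (int di = 0; di <= 1; ++di) {
          double wgt = (dj ? wx : 1.0 - wx) * (di ? wy : 1.0 - wy);
          if (wgt == 0.0) continue;
          int ii = i0 + di, jj = j0 + dj;
          double v;
          if (ii < 0 || ii >= h || jj < 0 || jj >= w) {
            if (method == 2) { // clamped: replicate edge pixel
              v = img(std::min(std::max(ii, 0), h - 1),
                      std::min(std::max(jj, 0), w - 1));
            } else {
              v = background;
            }
          } else {
            v = img(ii, jj);
          }
          acc += wgt * v;
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// map output pixel centre to input coordinates for a resize ih,iw -> oh,ow
static inline double resize_src(double x, int nin, int nout) {
  return (x - 0.5) * ((double)nin / nout) + 0.5;
}

// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int oh, int ow) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j) {
    double sx = resize_src(j + 1.0, w, ow);
    sx = std::min(std::max(sx, 1.0), (double)w);
    double fx = std::floor(sx);
    int j0 = (int)fx - 1;
    double wx = sx - fx;
    int j1 = std::min(j0 + 1, w - 1);
    for (int i = 0; i < oh; ++i) {
      double sy = resize_src(i + 1.0, h, oh);
      sy = std::min(std::max(sy, 1.0), (double)h);
      double fy = std::floor(sy);
      int i0 = (int)fy - 1;
      double wy = sy - fy;
      int i1 = std::min(i0 + 1, h - 1);
      out(i, j) = (1 - wy) * ((1 - wx) * img(i0, j0) + wx * img(i0, j1)) +
                  wy * ((1 - wx) * img(i1, j0) + wx * img(i1, j1));
    }
  }
  return out;
}

// adjoint of resize_bilinear_cpp: scatter output-grid gradients back to the
// ih x iw input grid with the same interpolation weights
// [[Rcpp::export]]
NumericMatrix resize_bilinear_bwd_cpp(NumericMatrix gout, int ih, int iw) {
  int oh = gout.nrow(), ow = gout.ncol();
  NumericMatrix gin(ih, iw);
  for (int j = 0; j < ow; ++j) {
    double sx = resize_src(j + 1.0, iw, ow);
    sx = std::min(std::max(sx, 1.0), (double)iw);
    double fx = std::floor(sx);
    int j0 = (int)fx - 1;
    double wx = sx - fx;
    int j1 = std::min(j0 + 1, iw - 1);
    for (int i = 0; i < oh; ++i) {
      double sy = resize_src(i + 1.0, ih, oh);
      sy = std::min(std::max(sy, 1.0), (double)ih);
      double fy = std::floor(sy);
      int i0 = (int)fy - 1;
      double wy = sy - fy;
      int i1 = std::min(i0 + 1, ih - 1);
      double g = gout(i, j);
      gin(i0, j0) += (1 - wy) * (1 - wx) * g;
      gin(i0, j1) += (1 - wy) * wx * g;
      gin(i1, j0) += wy * (1 - wx) * g;
      gin(i1, j1) += wy * wx * g;
    }
  }
  return gin;
}

// Unfold an [h, w, c] array into a [k*k*c, oh*ow] matrix (zero padding).
// Row index runs (dr, dc, channel) fastest-first; column index runs over
// output pixels in column-major (row fastest) order, matching R arrays.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector input, int h, int w, int c,
                         int k, int stride, int pad) {
  int oh = (h + 2 * pad - k) / stride + 1;
  int ow = (w + 2 * pad - k) / stride + 1;
  NumericMatrix cols(k * k * c, oh * ow);
  const double *in = input.begin();
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      int col = orow + oc * oh;
      for (int ch = 0; ch < c; ++ch) {
        const double *plane = in + (size_t)ch * h * w;
        for (int dc = 0; dc < k; ++dc) {
          int jj = oc * stride - pad + dc;
          bool jok = (jj >= 0 && jj < w);
          for (int dr = 0; dr < k; ++dr) {
            int ii = orow * stride - pad + dr;
            double v = 0.0;
            if (jok && ii >= 0 && ii < h) v = plane[ii + (size_t)jj * h];
            cols(dr + dc * k + ch * k * k, col) = v;
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col_cpp: fold column gradients back onto the input grid
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int h, int w, int c,
                         int k, int stride, int pad) {
  int oh = (h + 2 * pad - k) / stride + 1;
  int ow = (w + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)h * w * c);
  double *o = out.begin();
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      int col = orow + oc * oh;
      for (int ch = 0; ch < c; ++ch) {
        double *plane = o + (size_t)ch * h * w;
        for (int dc = 0; dc < k; ++dc) {
          int jj = oc * stride - pad + dc;
          if (jj < 0 || jj >= w) continue;
          for (int dr = 0; dr < k; ++dr) {
            int ii = orow * stride - pad + dr;
            if (ii < 0 || ii >= h) continue;
            plane[ii + (size_t)jj * h] += cols(dr + dc * k + ch * k * k, col);
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, c);
  return out;
}
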