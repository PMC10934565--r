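// Low-level image operations shared by the segmentation, registration and
// comparison stages. All images are numeric matrices (rows x cols); masks are
// integer matrices with values {0,1}.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample with replicate-edge (clamp) border handling.
static inline double sample_bilinear(const NumericMatrix& img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  r = clampd(r, 0.0, nr - 1.0);
  c = clampd(c, 0.0, nc - 1.0);
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * (1 - fc) * img(r0, c0) + (1 - fr) * fc * img(r0, c1) +
         fr * (1 - fc) * img(r1, c0) + fr * fc * img(r1, c1);
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int out_r, int out_c) {
  NumericMatrix out(out_r, out_c);
  const double sr = (double)img.nrow() / out_r, sc = (double)img.ncol() / out_c;
  for (int i = 0; i < out_r; ++i) {
    double r = (i + 0.5) * sr - 0.5;
    for (int j = 0; j < out_c; ++j) {
      double c = (j + 0.5) * sc - 0.5;
      out(i, j) = sample_bilinear(img, r, c);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_resize_nearest(const IntegerMatrix& img, int out_r, int out_c) {
  IntegerMatrix out(out_r, out_c);
  const double sr = (double)img.nrow() / out_r, sc = (double)img.ncol() / out_c;
  for (int i = 0; i < out_r; ++i) {
    int r = clampi((int)std::floor((i + 0.5) * sr), 0, img.nrow() - 1);
    for (int j = 0; j < out_c; ++j) {
      int c = clampi((int)std::floor((j + 0.5) * sc), 0, img.ncol() - 1);
      out(i, j) = img(r, c);
    }
  }
  return out;
}

// Pull-back warp: out(p) = img(p + field(p)), bilinear, replicate border.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(const NumericMatrix& img,
                                const NumericMatrix& drow,
                                const NumericMatrix& dcol) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = sample_bilinear(img, i + drow(i, j), j + dcol(i, j));
  return out;
}

// Warp plus the derivative of each output pixel with respect to its two
// displacement components (the image gradient sampled at the pull-back
// location, central-difference flavour of the bilinear surface).
// [[Rcpp::export]]
List cpp_warp_with_grad(const NumericMatrix& img,
                        const NumericMatrix& drow,
                        const NumericMatrix& dcol) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc), gr(nr, nc), gc(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double r = clampd(i + drow(i, j), 0.0, nr - 1.0);
      double c = clampd(j + dcol(i, j), 0.0, nc - 1.0);
      int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
      double fr = r - r0, fc = c - c0;
      double v00 = img(r0, c0), v01 = img(r0, c1), v10 = img(r1, c0), v11 = img(r1, c1);
      out(i, j) = (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
                  fr * (1 - fc) * v10 + fr * fc * v11;
      gr(i, j) = (1 - fc) * (v10 - v00) + fc * (v11 - v01);
      gc(i, j) = (1 - fr) * (v01 - v00) + fr * (v11 - v10);
    }
  }
  return List::create(_["warped"] = out, _["grad_row"] = gr, _["grad_col"] = gc);
}

// Windowed sums over (2*radius+1)^2 boxes, truncated at borders, via an
// integral image. Returns the per-pixel window sum.
static NumericMatrix box_sum(const NumericMatrix& x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  // integral image with a zero row/col in front
  std::vector<double> ii((nr + 1) * (nc + 1), 0.0);
  for (int i = 0; i < nr; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < nc; ++j) {
      rowsum += x(i, j);
      ii[(i + 1) * (nc + 1) + (j + 1)] = ii[i * (nc + 1) + (j + 1)] + rowsum;
    }
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    int r0 = std::max(0, i - radius), r1 = std::min(nr - 1, i + radius);
    for (int j = 0; j < nc; ++j) {
      int c0 = std::max(0, j - radius), c1 = std::min(nc - 1, j + radius);
      out(i, j) = ii[(r1 + 1) * (nc + 1) + (c1 + 1)] - ii[r0 * (nc + 1) + (c1 + 1)] -
                  ii[(r1 + 1) * (nc + 1) + c0] + ii[r0 * (nc + 1) + c0];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_box_sum(const NumericMatrix& x, int radius) {
  return box_sum(x, radius);
}

// Mean local (windowed) normalized cross-correlation squared-free variant:
// mean over pixels of cov^2/(var_a var_b), signed by the covariance. Windows
// with (near) zero variance in either image are skipped. Optionally returns
// the analytic gradient with respect to image `a`.
// [[Rcpp::export]]
List cpp_local_ncc(const NumericMatrix& a, const NumericMatrix& b, int radius,
                   bool want_grad) {
  const int nr = a.nrow(), nc = a.ncol();
  const double var_tol = 1e-12, eps = 1e-12;
  NumericMatrix ones(nr, nc);
  std::fill(ones.begin(), ones.end(), 1.0);
  NumericMatrix n = box_sum(ones, radius);
  NumericMatrix sa = box_sum(a, radius), sb = box_sum(b, radius);
  NumericMatrix ab(nr, nc), aa(nr, nc), bb(nr, nc);
  for (int k = 0; k < nr * nc; ++k) {
    ab[k] = a[k] * b[k];
    aa[k] = a[k] * a[k];
    bb[k] = b[k] * b[k];
  }
  NumericMatrix sab = box_sum(ab, radius), saa = box_sum(aa, radius),
                sbb = box_sum(bb, radius);
  // per-window stats
  NumericMatrix A(nr, nc), Ab(nr, nc), B(nr, nc), Ba(nr, nc);
  double acc = 0.0;
  long nvalid = 0;
  for (int k = 0; k < nr * nc; ++k) {
    double nn = n[k];
    double am = sa[k] / nn, bm = sb[k] / nn;
    double cross = sab[k] - nn * am * bm;
    double va = saa[k] - nn * am * am;
    double vb = sbb[k] - nn * bm * bm;
    if (va < var_tol || vb < var_tol) continue;
    double denom = va * vb + eps;
    double cc = cross * std::fabs(cross) / denom;  // signed
    acc += cc;
    ++nvalid;
    if (want_grad) {
      // cc = sign(cross) * cross^2 / denom;
      // dcc/da_q = A*(b_q - b_mean) - B*(a_q - a_mean) with
      A[k] = 2.0 * std::fabs(cross) / denom;
      B[k] = 2.0 * cross * std::fabs(cross) * vb / (denom * denom);
      Ab[k] = A[k] * bm;
      Ba[k] = B[k] * am;
    }
  }
  double value = nvalid > 0 ? acc / nvalid : 0.0;
  if (!want_grad)
    return List::create(_["value"] = value, _["n_valid"] = (double)nvalid);
  NumericMatrix SA = box_sum(A, radius), SAb = box_sum(Ab, radius),
                SB = box_sum(B, radius), SBa = box_sum(Ba, radius);
  NumericMatrix grad(nr, nc);
  double scale = nvalid > 0 ? 1.0 / nvalid : 0.0;
  for (int k = 0; k < nr * nc; ++k)
    grad[k] = scale * (b[k] * SA[k] - SAb[k] - a[k] * SB[k] + SBa[k]);
  return List::create(_["value"] = value, _["n_valid"] = (double)nvalid,
                      _["grad_a"] = grad);
}

// Joint-histogram mutual information in bits, with an optional gradient with
// respect to `a` from linear (partial-volume) binning along the a-axis.
// [[Rcpp::export]]
List cpp_mutual_information(const NumericMatrix& a, const NumericMatrix& b,
                            int bins, bool want_grad) {
  const int npix = a.nrow() * a.ncol();
  std::vector<double> joint(bins * bins, 0.0);
  std::vector<int> ia_of(npix), jb_of(npix);
  for (int k = 0; k < npix; ++k) {
    int ia = clampi((int)std::floor(a[k] * bins), 0, bins - 1);
    int jb = clampi((int)std::floor(b[k] * bins), 0, bins - 1);
    joint[ia * bins + jb] += 1.0;
    ia_of[k] = ia; jb_of[k] = jb;
  }
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      double p = joint[i * bins + j] / npix;
      pa[i] += p; pb[j] += p;
    }
  const double log2e = 1.0 / std::log(2.0);
  double mi = 0.0;
  std::vector<double> W(bins * bins, 0.0);  // log2(p_ab/(p_a p_b))
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      double p = joint[i * bins + j] / npix;
      if (p > 0.0 && pa[i] > 0.0 && pb[j] > 0.0) {
        double w = std::log(p / (pa[i] * pb[j])) * log2e;
        W[i * bins + j] = w;
        mi += p * w;
      }
    }
  if (!want_grad) return List::create(_["mi"] = mi);
  // approximate dMI/da via the change of the log-ratio table between
  // adjacent a-bins (partial-volume reasoning)
  NumericMatrix grad(a.nrow(), a.ncol());
  for (int k = 0; k < npix; ++k) {
    int i = ia_of[k], j = jb_of[k];
    double lo = (i > 0) ? W[(i - 1) * bins + j] : W[i * bins + j];
    double hi = (i < bins - 1) ? W[(i + 1) * bins + j] : W[i * bins + j];
    double span = (i > 0 && i < bins - 1) ? 2.0 : 1.0;
    grad[k] = ((double)bins / npix) * (hi - lo) / span;
  }
  return List::create(_["mi"] = mi, _["grad_a"] = grad);
}

// Separable Gaussian blur with reflect padding; kernel radius = ceil(3 sigma).
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& x, double sigma) {
  if (sigma <= 0) return clone(x);
  const int nr = x.nrow(), nc = x.ncol();
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& v : k) v /= s;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d) acc += k[d + rad] * x(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d) acc += k[d + rad] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

// Separable correlation with an arbitrary symmetric 1-D kernel, valid region
// only (used by SSIM). Returns an (nr-2*rad) x (nc-2*rad) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_valid(const NumericMatrix& x, const NumericVector& kernel) {
  const int nr = x.nrow(), nc = x.ncol(), kl = kernel.size(), rad = (kl - 1) / 2;
  const int or_ = nr - 2 * rad, oc = nc - 2 * rad;
  NumericMatrix tmp(or_, nc), out(or_, oc);
  for (int i = 0; i < or_; ++i)
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int d = 0; d < kl; ++d) acc += kernel[d] * x(i + d, j);
      tmp(i, j) = acc;
    }
  for (int i = 0; i < or_; ++i)
    for (int j = 0; j < oc; ++j) {
      double acc = 0.0;
      for (int d = 0; d < kl; ++d) acc += kernel[d] * tmp(i, j + d);
      out(i, j) = acc;
    }
  return out;
}

// Contrast-limited adaptive histogram equalization on an 8-bit image.
// clip_limit is the multiple of the mean histogram bin height at which tile
// histograms are clipped (excess redistributed uniformly); tile mappings are
// blended bilinearly across the image.
// [[Rcpp::export]]
IntegerMatrix cpp_clahe(const IntegerMatrix& img, int tiles_r, int tiles_c,
                        double clip_limit) {
  const int nr = img.nrow(), nc = img.ncol();
  if (tiles_r > nr || tiles_c > nc)
    stop("CLAHE tile grid larger than image");
  const int th = (nr + tiles_r - 1) / tiles_r, tw = (nc + tiles_c - 1) / tiles_c;
  // per-tile LUTs
  std::vector<double> lut(tiles_r * tiles_c * 256);
  for (int ti = 0; ti < tiles_r; ++ti) {
    for (int tj = 0; tj < tiles_c; ++tj) {
      int r0 = ti * th, r1 = std::min(nr, r0 + th);
      int c0 = tj * tw, c1 = std::min(nc, c0 + tw);
      double hist[256] = {0};
      int area = (r1 - r0) * (c1 - c0);
      for (int i = r0; i < r1; ++i)
        for (int j = c0; j < c1; ++j) hist[clampi(img(i, j), 0, 255)] += 1.0;
      double limit = std::max(1.0, clip_limit * area / 256.0);
      double excess = 0.0;
      for (int v = 0; v < 256; ++v)
        if (hist[v] > limit) { excess += hist[v] - limit; hist[v] = limit; }
      double add = excess / 256.0;
      double cum = 0.0;
      double* L = &lut[(ti * tiles_c + tj) * 256];
      for (int v = 0; v < 256; ++v) {
        cum += hist[v] + add;
        L[v] = 255.0 * cum / area;
      }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    double tr = ((double)i - th / 2.0 + 0.5) / th;  // tile-space row coord
    int ti0 = (int)std::floor(tr);
    double fr = tr - ti0;
    int ti1 = clampi(ti0 + 1, 0, tiles_r - 1);
    ti0 = clampi(ti0, 0, tiles_r - 1);
    for (int j = 0; j < nc; ++j) {
      double tc = ((double)j - tw / 2.0 + 0.5) / tw;
      int tj0 = (int)std::floor(tc);
      double fc = tc - tj0;
      int tj1 = clampi(tj0 + 1, 0, tiles_c - 1);
      int tj0c = clampi(tj0, 0, tiles_c - 1);
      int v = clampi(img(i, j), 0, 255);
      double m00 = lut[(ti0 * tiles_c + tj0c) * 256 + v];
      double m01 = lut[(ti0 * tiles_c + tj1) * 256 + v];
      double m10 = lut[(ti1 * tiles_c + tj0c) * 256 + v];
      double m11 = lut[(ti1 * tiles_c + tj1) * 256 + v];
      double val = (1 - fr) * ((1 - fc) * m00 + fc * m01) +
                   fr * ((1 - fc) * m10 + fc * m11);
      out(i, j) = clampi((int)std::lround(val), 0, 255);
    }
  }
  return out;
}

static IntegerMatrix morph_disk(const IntegerMatrix& mask, int radius, bool dilate) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // rounded discrete disk: radius 1 is the full 3x3 square, larger radii
  // drop far corners ((r + 0.5)^2 threshold), so opening keeps rectangles
  std::vector<std::pair<int, int>> off;
  const double r2 = (radius + 0.5) * (radius + 0.5);
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= r2) off.push_back({dr, dc});
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int hit = dilate ? 0 : 1;
      for (auto& o : off) {
        int r = i + o.first, c = j + o.second;
        // out-of-image counts as background for dilation but as foreground
        // for erosion, so shapes are not eaten at the image border
        int v = (r < 0 || r >= nr || c < 0 || c >= nc) ? (dilate ? 0 : 1)
                                                       : mask(r, c);
        if (dilate) { if (v) { hit = 1; break; } }
        else { if (!v) { hit = 0; break; } }
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_dilate_disk(const IntegerMatrix& mask, int radius) {
  return morph_disk(mask, radius, true);
}

// [[Rcpp::export]]
IntegerMatrix cpp_erode_disk(const IntegerMatrix& mask, int radius) {
  return morph_disk(mask, radius, false);
}

// Connected components by BFS; labels assigned in raster order of each
// component's first pixel, so labeling is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;
  std::queue<std::pair<int, int>> q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push({i, j});
      while (!q.empty()) {
        auto p = q.front();
        q.pop();
        for (int t = 0; t < nn; ++t) {
          int r = p.first + dr[t], c = p.second + dc[t];
          if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
          if (mask(r, c) && !lab(r, c)) {
            lab(r, c) = next;
            q.push({r, c});
          }
        }
      }
    }
  }
  return lab;
}
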