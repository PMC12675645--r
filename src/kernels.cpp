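#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3D trilinear resampling about the grid centre.
// Output voxel at centred mm coords c takes the input value at R %*% c
// (V_rot(r) = V(R r)); voxels sampled outside the field are air (0).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".rotate_volume_cpp")]]
NumericVector rotate_volume_cpp(NumericVector vol, IntegerVector dims,
                                NumericMatrix R, NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const double c1 = (n1 - 1) / 2.0, c2 = (n2 - 1) / 2.0, c3 = (n3 - 1) / 2.0;
  NumericVector out(vol.size());
  const double *v = vol.begin();
  double *o = out.begin();
  const double r11 = R(0,0), r12 = R(0,1), r13 = R(0,2);
  const double r21 = R(1,0), r22 = R(1,1), r23 = R(1,2);
  const double r31 = R(2,0), r32 = R(2,1), r33 = R(2,2);

  for (int k = 0; k < n3; ++k) {
    const double z = (k - c3) * s3;
    for (int j = 0; j < n2; ++j) {
      const double y = (j - c2) * s2;
      for (int i = 0; i < n1; ++i) {
        const double x = (i - c1) * s1;
        const double px = r11 * x + r12 * y + r13 * z;
        const double py = r21 * x + r22 * y + r23 * z;
        const double pz = r31 * x + r32 * y + r33 * z;
        const double q1 = px / s1 + c1;
        const double q2 = py / s2 + c2;
        const double q3 = pz / s3 + c3;
        const int i0 = (int)std::floor(q1), j0 = (int)std::floor(q2),
                  k0 = (int)std::floor(q3);
        double acc = 0.0;
        if (i0 >= -1 && i0 < n1 && j0 >= -1 && j0 < n2 && k0 >= -1 && k0 < n3) {
          const double fx = q1 - i0, fy = q2 - j0, fz = q3 - k0;
          for (int dk = 0; dk <= 1; ++dk) {
            const int kk = k0 + dk;
            if (kk < 0 || kk >= n3) continue;
            const double wz = dk ? fz : 1.0 - fz;
            for (int dj = 0; dj <= 1; ++dj) {
              const int jj = j0 + dj;
              if (jj < 0 || jj >= n2) continue;
              const double wy = dj ? fy : 1.0 - fy;
              for (int di = 0; di <= 1; ++di) {
                const int ii = i0 + di;
                if (ii < 0 || ii >= n1) continue;
                const double wx = di ? fx : 1.0 - fx;
                acc += wx * wy * wz * v[ii + (size_t)n1 * (jj + (size_t)n2 * kk)];
              }
            }
          }
        }
        o[i + (size_t)n1 * (j + (size_t)n2 * k)] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// 2D affine warp (bilinear). The transform maps output (reference) pixel
// coordinates to input coordinates: p_in = s * Rot(theta) * (p_out - centre)
// + centre + t, with p = (col, row) and theta in degrees (CCW). Samples
// outside the input are 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".warp_affine2d_cpp")]]
NumericMatrix warp_affine2d_cpp(NumericMatrix img, double tx, double ty,
                                double rot_deg, double scale) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double th = rot_deg * M_PI / 180.0;
  const double a = scale * std::cos(th), b = scale * std::sin(th);
  for (int r = 0; r < H; ++r) {
    const double yo = r - cy;
    for (int c = 0; c < W; ++c) {
      const double xo = c - cx;
      const double xi = a * xo - b * yo + cx + tx;
      const double yi = b * xo + a * yo + cy + ty;
      const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
      double acc = 0.0;
      if (x0 >= -1 && x0 < W && y0 >= -1 && y0 < H) {
        const double fx = xi - x0, fy = yi - y0;
        for (int dy = 0; dy <= 1; ++dy) {
          const int yy = y0 + dy;
          if (yy < 0 || yy >= H) continue;
          const double wy = dy ? fy : 1.0 - fy;
          for (int dx = 0; dx <= 1; ++dx) {
            const int xx = x0 + dx;
            if (xx < 0 || xx >= W) continue;
            const double wx = dx ? fx : 1.0 - fx;
            acc += wx * wy * img(yy, xx);
          }
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int H2, int W2) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H2, W2);
  const double ry = (double)H / H2, rx = (double)W / W2;
  for (int r = 0; r < H2; ++r) {
    double yi = (r + 0.5) * ry - 0.5;
    yi = std::min(std::max(yi, 0.0), (double)(H - 1));
    const int y0 = (int)std::floor(yi);
    const int y1 = std::min(y0 + 1, H - 1);
    const double fy = yi - y0;
    for (int c = 0; c < W2; ++c) {
      double xi = (c + 0.5) * rx - 0.5;
      xi = std::min(std::max(xi, 0.0), (double)(W - 1));
      const int x0 = (int)std::floor(xi);
      const int x1 = std::min(x0 + 1, W - 1);
      const double fx = xi - x0;
      out(r, c) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Convolution primitives for the residual U-Net. Feature maps are arrays of
// dim (H, W, C); 3x3 kernels use same-padding (zero). Weights for a 3x3 conv
// with C_in inputs and K outputs are a (9*C_in) x K matrix whose rows are
// ordered channel-major, then kernel column (dj), then kernel row (di) --
// matching the im2col layout below.
// ---------------------------------------------------------------------------

static arma::mat im2col3(const arma::cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::mat M(H * (size_t)W, 9 * (size_t)C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat &S = X.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        // output pixel (i,j) reads input (i+di, j+dj)
        const int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
        const int j_lo = std::max(0, -dj), j_hi = std::min(W, W - dj);
        for (int j = j_lo; j < j_hi; ++j) {
          double *dst = M.colptr(col) + (size_t)j * H;
          const double *src = S.colptr(j + dj);
          for (int i = i_lo; i < i_hi; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
  return M;
}

static void col2im3_add(const arma::mat &Mc, int H, int W, int C,
                        arma::cube &dX) {
  for (int c = 0; c < C; ++c) {
    arma::mat &S = dX.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        const int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
        const int j_lo = std::max(0, -dj), j_hi = std::min(W, W - dj);
        for (int j = j_lo; j < j_hi; ++j) {
          const double *src = Mc.colptr(col) + (size_t)j * H;
          double *dst = S.colptr(j + dj);
          for (int i = i_lo; i < i_hi; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
arma::cube conv3_fwd_cpp(const arma::cube &X, const arma::mat &Wm,
                         const arma::vec &b) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int K = Wm.n_cols;
  arma::mat Y = im2col3(X) * Wm;
  Y.each_row() += b.t();
  arma::cube out(H, Wd, K);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
List conv3_bwd_cpp(const arma::cube &X, const arma::mat &Wm,
                   const arma::cube &dY) {
  const int H = X.n_rows, Wd = X.n_cols, C = X.n_slices;
  const int K = dY.n_slices;
  arma::mat dYm(const_cast<double *>(dY.memptr()), H * (size_t)Wd, K, false);
  arma::mat M = im2col3(X);
  arma::mat dW = M.t() * dYm;
  arma::vec db = arma::sum(dYm, 0).t();
  arma::mat dM = dYm * Wm.t();
  arma::cube dX(H, Wd, C, arma::fill::zeros);
  col2im3_add(dM, H, Wd, C, dX);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd_cpp(const arma::cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  arma::cube Y(H2, W2, C);
  IntegerVector idx(H2 * (size_t)W2 * C); // 1-based linear index into X
  size_t q = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bidx = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double val = X(ii, jj, c);
            if (val > best) {
              best = val;
              bidx = ii + (size_t)H * (jj + (size_t)W * c);
            }
          }
        }
        Y(i, j, c) = best;
        idx[q++] = (int)(bidx + 1);
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
arma::cube maxpool2_bwd_cpp(const arma::cube &dY, const IntegerVector &idx,
                            int H, int W) {
  const int C = dY.n_slices;
  arma::cube dX(H, W, C, arma::fill::zeros);
  const double *g = dY.memptr();
  double *o = dX.memptr();
  for (size_t q = 0; q < (size_t)idx.size(); ++q) o[idx[q] - 1] += g[q];
  return dX;
}

// [[Rcpp::export(name = ".upsample2_fwd_cpp")]]
arma::cube upsample2_fwd_cpp(const arma::cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::cube Y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = X(i, j, c);
        Y(2 * i, 2 * j, c) = v;
        Y(2 * i + 1, 2 * j, c) = v;
        Y(2 * i, 2 * j + 1, c) = v;
        Y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return Y;
}

// [[Rcpp::export(name = ".upsample2_bwd_cpp")]]
arma::cube upsample2_bwd_cpp(const arma::cube &dY) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  arma::cube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dX(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
                      dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
  return dX;
}

// ---------------------------------------------------------------------------
// 5x5 median filter with reflected borders.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".median5_cpp")]]
NumericMatrix median5_cpp(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double buf[25];
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int q = 0;
      for (int dr = -2; dr <= 2; ++dr) {
        int rr = r + dr;
        if (rr < 0) rr = -rr - 1;            // reflect
        if (rr >= H) rr = 2 * H - rr - 1;
        for (int dc = -2; dc <= 2; ++dc) {
          int cc = c + dc;
          if (cc < 0) cc = -cc - 1;
          if (cc >= W) cc = 2 * W - cc - 1;
          buf[q++] = img(rr, cc);
        }
      }
      std::nth_element(buf, buf + 12, buf + 25);
      out(r, c) = buf[12];
    }
  }
  return out;
}

// Separable 2D convolution, 'valid' output, symmetric 1D kernel g.
// [[Rcpp::export(name = ".sepconv2_valid_cpp")]]
NumericMatrix sepconv2_valid_cpp(NumericMatrix img, NumericVector g) {
  const int H = img.nrow(), W = img.ncol(), L = g.size();
  const int H2 = H - L + 1, W2 = W - L + 1;
  NumericMatrix tmp(H2, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H2; ++r) {
      double s = 0;
      for (int q = 0; q < L; ++q) s += g[q] * img(r + q, c);
      tmp(r, c) = s;
    }
  NumericMatrix out(H2, W2);
  for (int c = 0; c < W2; ++c)
    for (int r = 0; r < H2; ++r) {
      double s = 0;
      for (int q = 0; q < L; ++q) s += g[q] * tmp(r, c + q);
      out(r, c) = s;
    }
  return out;
}

// ---------------------------------------------------------------------------
// NCC search. The similarity is the printed template-matching form: cross
// correlation normalised by the product of root energies, with no mean
// subtraction; a zero-mean variant is available behind a flag. Positions are
// 0-based top-left (row, col) offsets here; the R wrapper converts. Ties are
// broken by the first maximum in row-major scan order (smallest row, then
// smallest column).
// ---------------------------------------------------------------------------

static double ncc_at(const arma::mat &frame, const arma::mat &T,
                     double te, double tn, int r, int c, bool zero_mean) {
  const int th = T.n_rows, tw = T.n_cols;
  double num = 0, en = 0, wsum = 0;
  for (int j = 0; j < tw; ++j) {
    const double *fp = frame.colptr(c + j) + r;
    const double *tp = T.colptr(j);
    for (int i = 0; i < th; ++i) {
      const double f = fp[i];
      num += f * tp[i];
      en += f * f;
      wsum += f;
    }
  }
  if (zero_mean) en -= wsum * wsum / tn; // T is already zero-mean
  if (en <= 0 || te <= 0) return 0.0;
  return num / (std::sqrt(en) * te);
}

// [[Rcpp::export(name = ".ncc_search_cpp")]]
List ncc_search_cpp(const arma::mat &frame, const arma::mat &tmpl,
                    int r_lo, int r_hi, int c_lo, int c_hi,
                    int r_init, int c_init, bool zero_mean) {
  const int th = tmpl.n_rows, tw = tmpl.n_cols;
  const double tn = (double)(th * tw);
  double tsum = arma::accu(tmpl);
  arma::mat T = tmpl;
  if (zero_mean) T -= tsum / tn;
  const double te = std::sqrt(arma::accu(T % T));
  // the previous position wins exact ties (so featureless frames keep it);
  // strictly better candidates are taken in row-major scan order
  double best = ncc_at(frame, T, te, tn, r_init, c_init, zero_mean);
  int br = r_init, bc = c_init;
  for (int r = r_lo; r <= r_hi; ++r) {
    for (int c = c_lo; c <= c_hi; ++c) {
      const double score = ncc_at(frame, T, te, tn, r, c, zero_mean);
      if (score > best) {
        best = score;
        br = r;
        bc = c;
      }
    }
  }
  return List::create(_["row"] = br, _["col"] = bc, _["score"] = best);
}
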