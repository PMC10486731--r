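// Dense 3D convolution / pooling kernels backing the autodiff ops.
// Tensors are R arrays with dim (x, y, z, channel), column-major, doubles.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Gather the im2col matrix: rows = output positions (x fastest),
// cols = (kx, ky, kz, cin) with kx fastest, matching the column-major
// reshape of a (k,k,k,cin,cout) weight array into (k^3*cin, cout).
static arma::mat im2col3d(const double* xp, int nx, int ny, int nz, int ci,
                          int k, int stride, int pad,
                          int ox, int oy, int oz) {
  const int npos = ox * oy * oz;
  arma::mat col(npos, (arma::uword)k * k * k * ci, arma::fill::zeros);
  for (int c = 0; c < ci; ++c)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int cj = kx + k * (ky + k * (kz + k * c));
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride - pad + kz;
            if (iz < 0 || iz >= nz) continue;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride - pad + ky;
              if (iy < 0 || iy >= ny) continue;
              const double* xb = xp + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * c));
              double* cb = col.colptr(cj) + (size_t)ox * (y + (size_t)oy * z);
              for (int xo = 0; xo < ox; ++xo) {
                const int ix = xo * stride - pad + kx;
                if (ix < 0 || ix >= nx) continue;
                cb[xo] = xb[ix];
              }
            }
          }
        }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector b, int stride, int pad) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int k = wd[0], co = wd[4];
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const int oz = out_dim(nz, k, stride, pad);
  if (ox < 1 || oy < 1 || oz < 1)
    stop("conv3d: output would be empty (input %dx%dx%d, kernel %d)", nx, ny, nz, k);
  arma::mat W(w.begin(), (arma::uword)k * k * k * ci, co, false, true);
  arma::mat Y;
  if (k == 1 && stride == 1 && pad == 0) {
    // pointwise convolution: plain GEMM on the (voxels x channels) view
    arma::mat X(x.begin(), (arma::uword)nx * ny * nz, ci, false, true);
    Y = X * W;
  } else {
    arma::mat col = im2col3d(x.begin(), nx, ny, nz, ci, k, stride, pad, ox, oy, oz);
    Y = col * W;
  }
  if (b.size() == (R_xlen_t)co) {
    arma::rowvec bv(b.begin(), co, false, true);
    Y.each_row() += bv;
  }
  NumericVector out(Y.n_elem);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector dy, int stride, int pad,
                   bool need_dx, bool has_bias) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int k = wd[0], co = wd[4];
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const int oz = out_dim(nz, k, stride, pad);
  const int npos = ox * oy * oz;
  arma::mat dY(dy.begin(), npos, co, false, true);
  const bool pointwise = (k == 1 && stride == 1 && pad == 0);

  NumericVector dwv((R_xlen_t)k * k * k * ci * co);
  {
    arma::mat dW(dwv.begin(), (arma::uword)k * k * k * ci, co, false, true);
    if (pointwise) {
      arma::mat X(x.begin(), (arma::uword)npos, ci, false, true);
      dW = X.t() * dY;
    } else {
      arma::mat col = im2col3d(x.begin(), nx, ny, nz, ci, k, stride, pad, ox, oy, oz);
      dW = col.t() * dY;
    }
  }
  dwv.attr("dim") = wd;

  NumericVector dbv;
  if (has_bias) {
    arma::rowvec db = arma::sum(dY, 0);
    dbv = NumericVector(db.begin(), db.end());
  }

  NumericVector dxv;
  if (need_dx && pointwise) {
    arma::mat W(w.begin(), (arma::uword)ci, co, false, true);
    dxv = NumericVector((R_xlen_t)npos * ci);
    arma::mat dX(dxv.begin(), (arma::uword)npos, ci, false, true);
    dX = dY * W.t();
    dxv.attr("dim") = xd;
  } else if (need_dx) {
    arma::mat W(w.begin(), (arma::uword)k * k * k * ci, co, false, true);
    arma::mat dcol = dY * W.t();  // npos x k^3*ci
    dxv = NumericVector((R_xlen_t)nx * ny * nz * ci);
    double* dxp = dxv.begin();
    for (int c = 0; c < ci; ++c)
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const int cj = kx + k * (ky + k * (kz + k * c));
            for (int z = 0; z < oz; ++z) {
              const int iz = z * stride - pad + kz;
              if (iz < 0 || iz >= nz) continue;
              for (int y = 0; y < oy; ++y) {
                const int iy = y * stride - pad + ky;
                if (iy < 0 || iy >= ny) continue;
                double* db2 = dxp + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * c));
                const double* sb = dcol.colptr(cj) + (size_t)ox * (y + (size_t)oy * z);
                for (int xo = 0; xo < ox; ++xo) {
                  const int ix = xo * stride - pad + kx;
                  if (ix < 0 || ix >= nx) continue;
                  db2[ix] += sb[xo];
                }
              }
            }
          }
    dxv.attr("dim") = xd;
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Depthwise 3D convolution: one k^3 filter per channel, w dim (k,k,k,C).
// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fw(NumericVector x, IntegerVector xd,
                              NumericVector w, int k,
                              NumericVector b, int stride, int pad) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const int oz = out_dim(nz, k, stride, pad);
  NumericVector out((R_xlen_t)ox * oy * oz * nc);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  const bool hb = b.size() == (R_xlen_t)nc;
  for (int c = 0; c < nc; ++c) {
    const double* wc = wp + (size_t)k * k * k * c;
    const double* xc = xp + (size_t)nx * ny * nz * c;
    double* oc = op + (size_t)ox * oy * oz * c;
    const double bc = hb ? b[c] : 0.0;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          double acc = bc;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = z * stride - pad + kz;
            if (iz < 0 || iz >= nz) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = y * stride - pad + ky;
              if (iy < 0 || iy >= ny) continue;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = xo * stride - pad + kx;
                if (ix < 0 || ix >= nx) continue;
                acc += wc[kx + k * (ky + k * kz)] *
                       xc[ix + (size_t)nx * (iy + (size_t)ny * iz)];
              }
            }
          }
          oc[xo + (size_t)ox * (y + (size_t)oy * z)] = acc;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv3d_bw(NumericVector x, IntegerVector xd,
                     NumericVector w, int k,
                     NumericVector dy, int stride, int pad, bool has_bias,
                     bool need_dx) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const int oz = out_dim(nz, k, stride, pad);
  NumericVector dx((R_xlen_t)nx * ny * nz * nc);
  NumericVector dw((R_xlen_t)k * k * k * nc);
  NumericVector db(has_bias ? nc : 0);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  for (int c = 0; c < nc; ++c) {
    const double* wc = wp + (size_t)k * k * k * c;
    const double* xc = xp + (size_t)nx * ny * nz * c;
    const double* gc = dyp + (size_t)ox * oy * oz * c;
    double* dxc = dx.begin() + (size_t)nx * ny * nz * c;
    double* dwc = dw.begin() + (size_t)k * k * k * c;
    double accb = 0.0;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          const double g = gc[xo + (size_t)ox * (y + (size_t)oy * z)];
          if (g == 0.0) continue;
          accb += g;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = z * stride - pad + kz;
            if (iz < 0 || iz >= nz) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = y * stride - pad + ky;
              if (iy < 0 || iy >= ny) continue;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = xo * stride - pad + kx;
                if (ix < 0 || ix >= nx) continue;
                const size_t xi = ix + (size_t)nx * (iy + (size_t)ny * iz);
                if (need_dx) dxc[xi] += g * wc[kx + k * (ky + k * kz)];
                dwc[kx + k * (ky + k * kz)] += g * xc[xi];
              }
            }
          }
        }
    if (has_bias) db[c] = accb;
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = IntegerVector::create(k, k, k, nc);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x, IntegerVector xd,
                      int k, int stride, int pad) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const int oz = out_dim(nz, k, stride, pad);
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  IntegerVector am(y.size());
  const double* xp = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xo = 0; xo < ox; ++xo) {
          double best = R_NegInf;
          int bi = -1;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = z * stride - pad + kz;
            if (iz < 0 || iz >= nz) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = yy * stride - pad + ky;
              if (iy < 0 || iy >= ny) continue;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = xo * stride - pad + kx;
                if (ix < 0 || ix >= nx) continue;
                const size_t xi = ix + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * c));
                // !(x <= best) instead of (x > best) so NaNs propagate
                if (bi < 0 || !(xp[xi] <= best)) { best = xp[xi]; bi = (int)xi; }
              }
            }
          }
          const size_t oi = xo + (size_t)ox * (yy + (size_t)oy * (z + (size_t)oz * c));
          y[oi] = bi < 0 ? 0.0 : best;
          am[oi] = bi;
        }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bw(IntegerVector argmax, NumericVector dy,
                               IntegerVector xd) {
  NumericVector dx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (argmax[i] >= 0) dx[argmax[i]] += dy[i];
  dx.attr("dim") = xd;
  return dx;
}

// Adaptive average pooling to an (ox, oy, oz) grid, region boundaries
// floor(i*n/o) .. floor((i+1)*n/o).
// [[Rcpp::export]]
NumericVector cpp_adapool3d_fw(NumericVector x, IntegerVector xd,
                               IntegerVector od) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int ox = od[0], oy = od[1], oz = od[2];
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  const double* xp = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z) {
      const int z0 = (int)((size_t)z * nz / oz), z1 = (int)((size_t)(z + 1) * nz / oz);
      for (int yy = 0; yy < oy; ++yy) {
        const int y0 = (int)((size_t)yy * ny / oy), y1 = (int)((size_t)(yy + 1) * ny / oy);
        for (int xo = 0; xo < ox; ++xo) {
          const int x0 = (int)((size_t)xo * nx / ox), x1 = (int)((size_t)(xo + 1) * nx / ox);
          double acc = 0.0;
          for (int iz = z0; iz < z1; ++iz)
            for (int iy = y0; iy < y1; ++iy)
              for (int ix = x0; ix < x1; ++ix)
                acc += xp[ix + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * c))];
          y[xo + (size_t)ox * (yy + (size_t)oy * (z + (size_t)oz * c))] =
            acc / ((double)(x1 - x0) * (y1 - y0) * (z1 - z0));
        }
      }
    }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_adapool3d_bw(NumericVector dy, IntegerVector xd,
                               IntegerVector od) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int ox = od[0], oy = od[1], oz = od[2];
  NumericVector dx((R_xlen_t)nx * ny * nz * nc);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z) {
      const int z0 = (int)((size_t)z * nz / oz), z1 = (int)((size_t)(z + 1) * nz / oz);
      for (int yy = 0; yy < oy; ++yy) {
        const int y0 = (int)((size_t)yy * ny / oy), y1 = (int)((size_t)(yy + 1) * ny / oy);
        for (int xo = 0; xo < ox; ++xo) {
          const int x0 = (int)((size_t)xo * nx / ox), x1 = (int)((size_t)(xo + 1) * nx / ox);
          const double g = dy[xo + (size_t)ox * (yy + (size_t)oy * (z + (size_t)oz * c))] /
            ((double)(x1 - x0) * (y1 - y0) * (z1 - z0));
          for (int iz = z0; iz < z1; ++iz)
            for (int iy = y0; iy < y1; ++iy)
              for (int ix = x0; ix < x1; ++ix)
                dx[ix + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * c))] += g;
        }
      }
    }
  dx.attr("dim") = xd;
  return dx;
}
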