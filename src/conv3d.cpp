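// 3D convolution ("same" padding, stride 1) via im2col + GEMM.
// Layout: volumes are R arrays dim = (nx, ny, nz, c), column-major, x fastest.
// Weight matrix: (k^3 * cin) x cout, row index = ((ci*k + kz)*k + ky)*k + kx.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col3(const double* x, int nx, int ny, int nz, int cin, int k,
                    arma::mat& col) {
  const int pad = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  col.zeros(nvox, (R_xlen_t)k * k * k * cin);
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (R_xlen_t)ci * nvox;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t ccol = (((R_xlen_t)ci * k + kz) * k + ky) * k + kx;
          double* dst = col.colptr(ccol);
          const int dz = kz - pad, dy = ky - pad, dx = kx - pad;
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const int x0 = std::max(0, -dx);
              const int x1 = std::min(nx, nx - dx);
              if (x1 <= x0) continue;
              const double* src = xc + ((R_xlen_t)sz * ny + sy) * nx + (x0 + dx);
              double* out = dst + ((R_xlen_t)z * ny + y) * nx + x0;
              std::copy(src, src + (x1 - x0), out);
            }
          }
        }
      }
    }
  }
}

static void col2im3(const arma::mat& col, int nx, int ny, int nz, int cin, int k,
                    double* dx_out) {
  const int pad = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::fill(dx_out, dx_out + nvox * cin, 0.0);
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = dx_out + (R_xlen_t)ci * nvox;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t ccol = (((R_xlen_t)ci * k + kz) * k + ky) * k + kx;
          const double* src0 = col.colptr(ccol);
          const int dz = kz - pad, dy = ky - pad, dxo = kx - pad;
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const int x0 = std::max(0, -dxo);
              const int x1 = std::min(nx, nx - dxo);
              if (x1 <= x0) continue;
              const double* src = src0 + ((R_xlen_t)z * ny + y) * nx + x0;
              double* dst = xc + ((R_xlen_t)sz * ny + sy) * nx + (x0 + dxo);
              for (int i = 0; i < x1 - x0; ++i) dst[i] += src[i];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3dForward")]]
NumericVector conv3d_forward(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector bias, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int cout = w.ncol();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if ((R_xlen_t)w.nrow() != (R_xlen_t)k * k * k * cin)
    stop("weight rows do not match kernel/channel geometry");
  arma::mat col;
  im2col3(x.begin(), nx, ny, nz, cin, k, col);
  const arma::mat W(const_cast<double*>(w.begin()), w.nrow(), cout, false, true);
  arma::mat out = col * W;
  out.each_row() += arma::rowvec(const_cast<double*>(bias.begin()), cout, false, true);
  NumericVector res(nvox * cout);
  std::copy(out.memptr(), out.memptr() + nvox * cout, res.begin());
  res.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return res;
}

// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3d_backward(NumericVector x, IntegerVector dims, NumericMatrix w,
                     int k, NumericVector gout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int cout = w.ncol();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  arma::mat col;
  im2col3(x.begin(), nx, ny, nz, cin, k, col);
  const arma::mat W(const_cast<double*>(w.begin()), w.nrow(), cout, false, true);
  const arma::mat G(const_cast<double*>(gout.begin()), nvox, cout, false, true);
  arma::mat dW = col.t() * G;
  arma::rowvec db = arma::sum(G, 0);
  arma::mat dcol = G * W.t();
  NumericVector dx(nvox * cin);
  col2im3(dcol, nx, ny, nz, cin, k, dx.begin());
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  NumericMatrix dWr(w.nrow(), cout);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWr.begin());
  NumericVector dbr(cout);
  std::copy(db.memptr(), db.memptr() + cout, dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}
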