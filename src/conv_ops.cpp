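#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major arrays with dim (C, X, Y, Z): channel fastest.
// im2col unrolls 3D patches so a convolution becomes W[Cout, C*KX*KY*KZ] %*% cols.

// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericVector x, IntegerVector kdim,
                           IntegerVector stride, IntegerVector pad) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  const int KX = kdim[0], KY = kdim[1], KZ = kdim[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int PX = pad[0], PY = pad[1], PZ = pad[2];
  const int OX = (X + 2 * PX - KX) / SX + 1;
  const int OY = (Y + 2 * PY - KY) / SY + 1;
  const int OZ = (Z + 2 * PZ - KZ) / SZ + 1;
  const int nrow = C * KX * KY * KZ;
  NumericMatrix out = no_init(nrow, OX * OY * OZ);
  const double *px = x.begin();
  double *po = out.begin();
  const size_t cb = (size_t)C * sizeof(double);
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int col = ox + OX * (oy + OY * oz);
        double *dst = po + (size_t)col * nrow;
        for (int kz = 0; kz < KZ; ++kz) {
          const int iz = oz * SZ - PZ + kz;
          const bool zok = iz >= 0 && iz < Z;
          for (int ky = 0; ky < KY; ++ky) {
            const int iy = oy * SY - PY + ky;
            const bool yok = zok && iy >= 0 && iy < Y;
            double *d0 = dst + C * (KX * (ky + KY * kz));
            const int ix0 = ox * SX - PX;
            if (yok && ix0 >= 0 && ix0 + KX <= X && SX == 1) {
              // common interior case: KX contiguous channel blocks
              const double *s0 = px + (size_t)C * (ix0 + X * (iy + (size_t)Y * iz));
              memcpy(d0, s0, cb * KX);
            } else {
              for (int kx = 0; kx < KX; ++kx) {
                const int ix = ox * SX - PX + kx;
                if (!yok || ix < 0 || ix >= X) {
                  memset(d0 + C * kx, 0, cb);
                } else {
                  const double *s0 = px + (size_t)C * (ix + X * (iy + (size_t)Y * iz));
                  memcpy(d0 + C * kx, s0, cb);
                }
              }
            }
          }
        }
      }
    }
  }
  out.attr("outdim") = IntegerVector::create(OX, OY, OZ);
  return out;
}

// Adjoint of im2col: scatter-add columns back onto the (C, X, Y, Z) grid.
// [[Rcpp::export]]
NumericVector cpp_col2im3d(NumericMatrix cols, IntegerVector xdim,
                           IntegerVector kdim, IntegerVector stride,
                           IntegerVector pad) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int KX = kdim[0], KY = kdim[1], KZ = kdim[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int PX = pad[0], PY = pad[1], PZ = pad[2];
  const int OX = (X + 2 * PX - KX) / SX + 1;
  const int OY = (Y + 2 * PY - KY) / SY + 1;
  const int OZ = (Z + 2 * PZ - KZ) / SZ + 1;
  const int nrow = C * KX * KY * KZ;
  NumericVector x((size_t)C * X * Y * Z);
  double *px = x.begin();
  const double *po = cols.begin();
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int col = ox + OX * (oy + OY * oz);
        const double *src = po + (size_t)col * nrow;
        for (int kz = 0; kz < KZ; ++kz) {
          const int iz = oz * SZ - PZ + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < KY; ++ky) {
            const int iy = oy * SY - PY + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < KX; ++kx) {
              const int ix = ox * SX - PX + kx;
              if (ix < 0 || ix >= X) continue;
              const double *s0 = src + C * (kx + KX * (ky + KY * kz));
              double *d0 = px + (size_t)C * (ix + X * (iy + (size_t)Y * iz));
              for (int c = 0; c < C; ++c) d0[c] += s0[c];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return x;
}

// Max pooling with argmax bookkeeping (1-based flat indices into x) so the
// backward pass is an exact scatter.
// [[Rcpp::export]]
List cpp_maxpool3d(NumericVector x, IntegerVector pool) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  const int PX = pool[0], PY = pool[1], PZ = pool[2];
  const int OX = X / PX, OY = Y / PY, OZ = Z / PZ;
  NumericVector out((size_t)C * OX * OY * OZ);
  IntegerVector arg((size_t)C * OX * OY * OZ);
  const double *px = x.begin();
  for (int oz = 0; oz < OZ; ++oz)
    for (int oy = 0; oy < OY; ++oy)
      for (int ox = 0; ox < OX; ++ox)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; size_t bi = 0;
          for (int kz = 0; kz < PZ; ++kz)
            for (int ky = 0; ky < PY; ++ky)
              for (int kx = 0; kx < PX; ++kx) {
                const size_t i = c + (size_t)C * ((ox * PX + kx) +
                    (size_t)X * ((oy * PY + ky) + (size_t)Y * (oz * PZ + kz)));
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          const size_t o = c + (size_t)C * (ox + (size_t)OX * (oy + (size_t)OY * oz));
          out[o] = best; arg[o] = (int)(bi + 1);
        }
  out.attr("dim") = IntegerVector::create(C, OX, OY, OZ);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_grad(NumericVector dout, IntegerVector argmax,
                                 IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += dout[i];
  dx.attr("dim") = xdim;
  return dx;
}
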