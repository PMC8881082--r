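#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-summation structure factors on an arbitrary list of Fourier terms.
//
// F(h) = sum_atoms occ * f_elem(s) * exp(-B s^2 / 4) * exp(2 pi i h . x_frac)
//
// Atom phases are built from per-axis tables exp(2 pi i h x) via complex
// recursion (h is integer), so the inner loop is multiplications plus one
// exp() for the B damping.
//
// hkl:   n x 3 integer Miller indices
// s2:    n, squared reciprocal-vector magnitudes (A^-2)
// frac:  m x 3 fractional coordinates
// occ,b: m, occupancy and isotropic B (A^2)
// elem:  m, 0-based row index into coefs
// coefs: nelem x 9 Gaussian form-factor coefficients (a1..a4, b1..b4, c)
// [[Rcpp::export]]
ComplexVector sf_direct_cpp(const IntegerMatrix& hkl, const NumericVector& s2,
                            const NumericMatrix& frac, const NumericVector& occ,
                            const NumericVector& b, const IntegerVector& elem,
                            const NumericMatrix& coefs) {
  const int n = hkl.nrow(), m = frac.nrow(), nelem = coefs.nrow();
  // per-element scattering factor at every term
  std::vector<double> fel((size_t)nelem * n);
  for (int e = 0; e < nelem; ++e) {
    for (int i = 0; i < n; ++i) {
      double q = s2[i] / 4.0, f = coefs(e, 8);
      for (int g = 0; g < 4; ++g) f += coefs(e, g) * std::exp(-coefs(e, g + 4) * q);
      fel[(size_t)e * n + i] = f;
    }
  }
  int hmin[3], hmax[3];
  for (int ax = 0; ax < 3; ++ax) {
    hmin[ax] = hkl(0, ax); hmax[ax] = hkl(0, ax);
    for (int i = 1; i < n; ++i) {
      if (hkl(i, ax) < hmin[ax]) hmin[ax] = hkl(i, ax);
      if (hkl(i, ax) > hmax[ax]) hmax[ax] = hkl(i, ax);
    }
  }
  std::vector<double> Fr(n, 0.0), Fi(n, 0.0);
  std::vector<double> tr[3], ti[3];
  for (int ax = 0; ax < 3; ++ax) {
    tr[ax].resize(hmax[ax] - hmin[ax] + 1);
    ti[ax].resize(hmax[ax] - hmin[ax] + 1);
  }
  const double twopi = 2.0 * M_PI;
  for (int j = 0; j < m; ++j) {
    if (occ[j] == 0.0) continue;
    for (int ax = 0; ax < 3; ++ax) {
      const double ang = twopi * frac(j, ax);
      const double sr = std::cos(ang), si = std::sin(ang);
      // start at hmin
      double cr = std::cos(ang * hmin[ax]), ci = std::sin(ang * hmin[ax]);
      for (int h = hmin[ax]; h <= hmax[ax]; ++h) {
        tr[ax][h - hmin[ax]] = cr; ti[ax][h - hmin[ax]] = ci;
        const double nr = cr * sr - ci * si, ni = cr * si + ci * sr;
        cr = nr; ci = ni;
      }
    }
    const double b4 = b[j] / 4.0, oj = occ[j];
    const double* fe = &fel[(size_t)elem[j] * n];
    for (int i = 0; i < n; ++i) {
      const double w = oj * fe[i] * std::exp(-b4 * s2[i]);
      const int h = hkl(i, 0) - hmin[0], k = hkl(i, 1) - hmin[1], l = hkl(i, 2) - hmin[2];
      double pr = tr[0][h] * tr[1][k] - ti[0][h] * ti[1][k];
      double pi = tr[0][h] * ti[1][k] + ti[0][h] * tr[1][k];
      const double qr = pr * tr[2][l] - pi * ti[2][l];
      const double qi = pr * ti[2][l] + pi * tr[2][l];
      Fr[i] += w * qr; Fi[i] += w * qi;
    }
  }
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) { out[i].r = Fr[i]; out[i].i = Fi[i]; }
  return out;
}

// Sample smeared atomic density on an orthogonal periodic grid.
//
// Each atom contributes sum_g a_g (4pi/(b_g+B))^{3/2} exp(-4pi^2 r^2/(b_g+B)),
// the real-space counterpart of a_g exp(-(b_g+B) s^2/4); the constant
// form-factor term c rides on a narrow Gaussian of width bc. Gaussians are
// separable, so each (atom, Gaussian) costs three 1-D exp tables plus a
// multiply-accumulate triple loop.
//
// xyz:  m x 3 Cartesian coordinates inside [0,cell) (A)
// cell: a, b, c box lengths (A); ng: grid points per axis
// bc:   width given to the constant term (A^2); cutoff in sigmas of support
// [[Rcpp::export]]
NumericVector density_grid_cpp(const NumericMatrix& xyz, const NumericVector& occ,
                               const NumericVector& b, const IntegerVector& elem,
                               const NumericMatrix& coefs, const NumericVector& cell,
                               const IntegerVector& ng, double bc, double logtol) {
  const int m = xyz.nrow();
  const int nx = ng[0], ny = ng[1], nz = ng[2];
  NumericVector rho((R_xlen_t)nx * ny * nz);
  const double dx = cell[0] / nx, dy = cell[1] / ny, dz = cell[2] / nz;
  const double fourpi2 = 4.0 * M_PI * M_PI;
  std::vector<double> ex, ey, ez;
  for (int j = 0; j < m; ++j) {
    if (occ[j] == 0.0) continue;
    const int e = elem[j];
    for (int g = 0; g < 5; ++g) {
      double a = (g < 4) ? coefs(e, g) : coefs(e, 8);
      if (a == 0.0) continue;
      const double bg = ((g < 4) ? coefs(e, g + 4) : bc) + b[j];
      const double alpha = fourpi2 / bg;                  // exp(-alpha r^2)
      const double amp = occ[j] * a * std::pow(fourpi2 / (M_PI * bg), 1.5);
      const double rcut = std::sqrt(logtol / alpha);
      const int wx = (int)std::ceil(rcut / dx), wy = (int)std::ceil(rcut / dy),
                wz = (int)std::ceil(rcut / dz);
      const int ix0 = (int)std::floor(xyz(j, 0) / dx), iy0 = (int)std::floor(xyz(j, 1) / dy),
                iz0 = (int)std::floor(xyz(j, 2) / dz);
      ex.assign(2 * wx + 1, 0.0); ey.assign(2 * wy + 1, 0.0); ez.assign(2 * wz + 1, 0.0);
      for (int i = -wx; i <= wx; ++i) {
        const double d = (ix0 + i) * dx - xyz(j, 0); ex[i + wx] = std::exp(-alpha * d * d);
      }
      for (int i = -wy; i <= wy; ++i) {
        const double d = (iy0 + i) * dy - xyz(j, 1); ey[i + wy] = std::exp(-alpha * d * d);
      }
      for (int i = -wz; i <= wz; ++i) {
        const double d = (iz0 + i) * dz - xyz(j, 2); ez[i + wz] = std::exp(-alpha * d * d);
      }
      for (int kz = -wz; kz <= wz; ++kz) {
        int iz = ((iz0 + kz) % nz + nz) % nz;
        const double az = amp * ez[kz + wz];
        for (int ky = -wy; ky <= wy; ++ky) {
          int iy = ((iy0 + ky) % ny + ny) % ny;
          const double ayz = az * ey[ky + wy];
          double* row = &rho[((R_xlen_t)iz * ny + iy) * nx];
          for (int kx = -wx; kx <= wx; ++kx) {
            int ix = ((ix0 + kx) % nx + nx) % nx;
            row[ix] += ayz * ex[kx + wx];
          }
        }
      }
    }
  }
  rho.attr("dim") = IntegerVector::create(nx, ny, nz);
  return rho;
}
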