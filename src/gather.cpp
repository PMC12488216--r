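// Hot kernels for the dual-sphere gather reconstruction and the
// curved-sphere forward projector.  All Fourier grids are centred
// (DC at 0-based index box/2) and column-major, matching the R side.
//
// Conventions shared with the R code (see R/optics.R, R/geometry.R):
//   * pose matrix R maps particle-frame vectors into the reconstruction
//     frame; the particle-frame coordinates of a reconstruction-grid
//     frequency q are u = R^T q.
//   * Ewald sphere surface sits at zeta = +z0(k) in the particle frame,
//     its Friedel mate at zeta = -z0(k), z0 = lambda*k^2/2 (paraboloid)
//     or the exact spherical form behind `exact_sphere`.
//   * wavefront phase phi(k) = -pi * defocus * lambda * k^2 (radians),
//     positive defocus = underfocus.
//   * interference amplitudes: cos^2(phi) for the Hermite (real)
//     component, sin^2(phi) for the anti-Hermite (imaginary) component;
//     kernel terms add for the real component and subtract for the
//     imaginary one.

#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;

typedef std::complex<double> cplx;

static inline double ewald_z0(double k2, double lambda, bool exact) {
  if (lambda == 0.0) return 0.0;
  if (!exact) return 0.5 * lambda * k2;
  double t = 1.0 - lambda * lambda * k2;
  if (t <= 0.0) return 1.0 / lambda;  // caller keeps |k| < 1/lambda
  return (1.0 - std::sqrt(t)) / lambda;
}

// bilinear interpolation on an n x n column-major complex grid;
// caller guarantees 0 <= x,y <= n-2 (+1 neighbour in bounds)
static inline cplx bilin2(const cplx* img, int n, double x, double y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double tx = x - x0, ty = y - y0;
  const cplx* c0 = img + (size_t)n * y0;
  const cplx* c1 = img + (size_t)n * (y0 + 1);
  return c0[x0] * ((1.0 - tx) * (1.0 - ty)) + c0[x0 + 1] * (tx * (1.0 - ty)) +
         c1[x0] * ((1.0 - tx) * ty) + c1[x0 + 1] * (tx * ty);
}

// trilinear interpolation on an n^3 column-major complex grid;
// returns 0 outside the symmetric valid range
static inline cplx trilin3(const cplx* vol, int n, double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x >= n - 1.000000001 || y >= n - 1.000000001 || z >= n - 1.000000001)
    return cplx(0.0, 0.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double tx = x - x0, ty = y - y0, tz = z - z0;
  cplx out(0.0, 0.0);
  for (int dz = 0; dz < 2; ++dz) {
    double wz = dz ? tz : 1.0 - tz;
    if (wz == 0.0) continue;
    const cplx* plane = vol + (size_t)n * n * (z0 + dz);
    double w00 = (1.0 - tx) * (1.0 - ty) * wz, w10 = tx * (1.0 - ty) * wz;
    double w01 = (1.0 - tx) * ty * wz, w11 = tx * ty * wz;
    const cplx* c0 = plane + (size_t)n * y0;
    const cplx* c1 = plane + (size_t)n * (y0 + 1);
    out += c0[x0] * w00 + c0[x0 + 1] * w10 + c1[x0] * w01 + c1[x0 + 1] * w11;
  }
  return out;
}

// Accumulate a stack of factorized particles into the four running sums.
// hstack/astack: (box*os, box*os, P) centred complex grids (Hermite /
// anti-Hermite, Fourier-oversampled by integer factor `oversample` to tame
// interpolation error).  rot: P x 9 pose matrices, row-major per row
// (r11, r12, ..., r33).  Returns signal and weight-squared sums for both
// components on the box^3 reconstruction grid.
// [[Rcpp::export]]
List cpp_accumulate(ComplexVector hstack, ComplexVector astack,
                    NumericMatrix rot, NumericVector defocus,
                    int box, double pixel_size, double wavelength,
                    double sigma_vox, double support_vox, double kmax_vox,
                    bool exact_sphere, int oversample) {
  const int n = box, c = box / 2, np = rot.nrow();
  const int os = oversample, nimg = box * oversample, cimg = nimg / 2;
  const size_t n2 = (size_t)nimg * nimg, n3 = (size_t)n * n * n;
  if (os < 1) stop("oversample must be >= 1");
  if ((size_t)hstack.size() != n2 * np || (size_t)astack.size() != n2 * np)
    stop("component stack size does not match box, oversample and particle count");
  const double dk = 1.0 / (n * pixel_size);
  const double kmax2 = kmax_vox * kmax_vox;
  const double inv2s2 = 1.0 / (2.0 * sigma_vox * sigma_vox);

  ComplexVector sigR(n3), sigI(n3);
  NumericVector wsqR(n3), wsqI(n3);
  cplx* pSR = reinterpret_cast<cplx*>(COMPLEX(sigR));
  cplx* pSI = reinterpret_cast<cplx*>(COMPLEX(sigI));
  double* pWR = REAL(wsqR);
  double* pWI = REAL(wsqI);
  const cplx* hbase = reinterpret_cast<const cplx*>(COMPLEX(hstack));
  const cplx* abase = reinterpret_cast<const cplx*>(COMPLEX(astack));

  for (int p = 0; p < np; ++p) {
    const cplx* H = hbase + n2 * (size_t)p;
    const cplx* A = abase + n2 * (size_t)p;
    const double z = defocus[p];
    double r[9];
    for (int j = 0; j < 9; ++j) r[j] = rot(p, j);
    for (int iz = 0; iz < n; ++iz) {
      const double vz = iz - c;
      for (int iy = 0; iy < n; ++iy) {
        const double vy = iy - c;
        const double rzy2 = vz * vz + vy * vy;
        if (rzy2 > kmax2) continue;
        size_t idx0 = (size_t)n * (iy + (size_t)n * iz);
        for (int ix = 0; ix < n; ++ix) {
          const double vx = ix - c;
          if (vx * vx + rzy2 > kmax2) continue;
          // particle-frame coordinates (voxel units): u = R^T v
          const double ux = r[0] * vx + r[3] * vy + r[6] * vz;
          const double uy = r[1] * vx + r[4] * vy + r[7] * vz;
          const double uz = r[2] * vx + r[5] * vy + r[8] * vz;
          const double k2 = (ux * ux + uy * uy) * dk * dk;  // in-plane, A^-2
          const double z0v = ewald_z0(k2, wavelength, exact_sphere) / dk;
          const double dE = uz - z0v, dM = uz + z0v;
          const double kE = std::fabs(dE) <= support_vox ? std::exp(-dE * dE * inv2s2) : 0.0;
          const double kM = std::fabs(dM) <= support_vox ? std::exp(-dM * dM * inv2s2) : 0.0;
          if (kE == 0.0 && kM == 0.0) continue;
          const double phi = -M_PI * z * wavelength * k2;
          const double cph = std::cos(phi), sph = std::sin(phi);
          const double wR = (kE + kM) * cph * cph;
          const double wI = (kE - kM) * sph * sph;
          const double x = cimg + os * ux, y = cimg + os * uy;
          const size_t idx = idx0 + ix;
          if (wR != 0.0) {
            pSR[idx] += wR * bilin2(H, nimg, x, y);
            pWR[idx] += wR * wR;
          }
          if (wI != 0.0) {
            pSI[idx] += wI * bilin2(A, nimg, x, y);
            pWI[idx] += wI * wI;
          }
        }
      }
    }
  }
  sigR.attr("dim") = IntegerVector::create(n, n, n);
  sigI.attr("dim") = IntegerVector::create(n, n, n);
  wsqR.attr("dim") = IntegerVector::create(n, n, n);
  wsqI.attr("dim") = IntegerVector::create(n, n, n);
  return List::create(_["signal_real"] = sigR, _["wsq_real"] = wsqR,
                      _["signal_imag"] = sigI, _["wsq_imag"] = wsqI);
}

// Curved-sphere forward projector (weak-contrast linear model).
// f3d: centred 3D FT of the ground-truth density, Fourier-oversampled by
// `oversample` (FT of the zero-padded truth).  For each particle and
// in-plane frequency k the image FT is
//   M(k) = 1/2 [ exp(-i phi) F3D(R (k, +z0)) + exp(+i phi) F3D(R (k, -z0)) ]
// which is Hermitian (real image) because F3D is.
// Returns a (box, box, P) centred complex stack of image FTs.
// [[Rcpp::export]]
ComplexVector cpp_forward_project(ComplexVector f3d, NumericMatrix rot,
                                  NumericVector defocus, int box,
                                  double pixel_size, double wavelength,
                                  double kmax_vox, bool exact_sphere,
                                  int oversample) {
  const int n = box, c = box / 2, np = rot.nrow();
  const int os = oversample, nvol = box * oversample, cvol = nvol / 2;
  const size_t n2 = (size_t)n * n;
  if (os < 1) stop("oversample must be >= 1");
  if ((size_t)f3d.size() != (size_t)nvol * nvol * nvol)
    stop("volume FT size does not match box and oversample");
  const double dk = 1.0 / (n * pixel_size);
  const double kmax2 = kmax_vox * kmax_vox;

  ComplexVector out(n2 * np);
  cplx* pout = reinterpret_cast<cplx*>(COMPLEX(out));
  const cplx* F = reinterpret_cast<const cplx*>(COMPLEX(f3d));

  for (int p = 0; p < np; ++p) {
    cplx* M = pout + n2 * (size_t)p;
    const double z = defocus[p];
    double r[9];
    for (int j = 0; j < 9; ++j) r[j] = rot(p, j);
    for (int iy = 0; iy < n; ++iy) {
      const double vy = iy - c;
      for (int ix = 0; ix < n; ++ix) {
        const double vx = ix - c;
        const double rv2 = vx * vx + vy * vy;
        if (rv2 > kmax2) continue;
        const double k2 = rv2 * dk * dk;
        const double z0v = ewald_z0(k2, wavelength, exact_sphere) / dk;
        // recon-frame coordinates of the two sphere points: q = R u
        const double qpx = r[0] * vx + r[1] * vy + r[2] * z0v;
        const double qpy = r[3] * vx + r[4] * vy + r[5] * z0v;
        const double qpz = r[6] * vx + r[7] * vy + r[8] * z0v;
        const double qmx = r[0] * vx + r[1] * vy - r[2] * z0v;
        const double qmy = r[3] * vx + r[4] * vy - r[5] * z0v;
        const double qmz = r[6] * vx + r[7] * vy - r[8] * z0v;
        const cplx Fp = trilin3(F, nvol, cvol + os * qpx, cvol + os * qpy,
                                cvol + os * qpz);
        const cplx Fm = trilin3(F, nvol, cvol + os * qmx, cvol + os * qmy,
                                cvol + os * qmz);
        const double phi = -M_PI * z * wavelength * k2;
        const cplx eneg(std::cos(phi), -std::sin(phi));  // exp(-i phi)
        M[(size_t)n * iy + ix] = 0.5 * (eneg * Fp + std::conj(eneg) * Fm);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, np);
  return out;
}
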