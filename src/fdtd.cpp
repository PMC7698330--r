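// 3-D FDTD solver on a uniform cubic Yee lattice with CPML absorbing
// boundaries, a thin-wire PEC dipole and a resistive edge-port source.
//
// Field placement relative to cell centers (cell (i,j,k) centered at
// (i,j,k)*dx): Ex at +x/2, Ey at +y/2, Ez at +z/2, Hx at +(y+z)/2,
// Hy at +(x+z)/2, Hz at +(x+y)/2.  Materials are cell-centered; E-edge
// coefficients average the two straddling cells along the edge direction.

#include <Rcpp.h>
#include <vector>
#include <cmath>

#if defined(__SSE2__)
#include <xmmintrin.h>
#endif
#if defined(__SSE3__)
#include <pmmintrin.h>
#endif

using namespace Rcpp;

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

namespace {

// Denormal field values in freshly excited / PML-damped regions cripple the
// stepper (each op costs ~100 cycles); flush them to zero.
inline void set_flush_to_zero() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
#endif
#if defined(__SSE3__)
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

const double EPS0 = 8.8541878128e-12;
const double MU0  = 1.25663706212e-6;

struct Pml1d {
  // CPML recursive-convolution coefficients along one axis, kappa = 1,
  // sampled at integer (E) and half-integer (H) positions
  std::vector<double> be, ce, bh, ch;
};

Pml1d make_pml(int n, int npml, double m, double sig_max, double alpha_max,
               double dt) {
  Pml1d p;
  p.be.assign(n, 0.0); p.ce.assign(n, 0.0);
  p.bh.assign(n, 0.0); p.ch.assign(n, 0.0);
  auto coef = [&](double depth, double* b, double* c) {
    // depth in [0,1] measured from the PML interface toward the wall
    if (depth <= 0) return;
    double sg = sig_max * std::pow(depth, m);
    double al = alpha_max * (1.0 - depth);
    double bb = std::exp(-(sg + al) * dt / EPS0);
    double cc = (sg + al > 0) ? sg / (sg + al) * (bb - 1.0) : 0.0;
    *b = bb; *c = cc;
  };
  for (int i = 0; i < n; ++i) {
    // integer positions
    double dlo = (npml - 0.5 - i) / npml;
    double dhi = (i - (n - 1 - npml) - 0.5) / npml;
    coef(std::max(dlo, dhi), &p.be[i], &p.ce[i]);
    // half positions (i + 1/2)
    double dlo_h = (npml - 1.0 - i) / npml;
    double dhi_h = (i + 0.5 - (n - 1 - npml) - 0.5) / npml;
    coef(std::max(dlo_h, dhi_h), &p.bh[i], &p.ch[i]);
  }
  return p;
}

struct Fdtd {
  int nx, ny, nz;
  long nn;
  double dx, dt;
  std::vector<double> Ex, Ey, Ez, Hx, Hy, Hz;
  std::vector<double> CaX, CbX, CaY, CbY, CaZ, CbZ;
  // CPML auxiliary fields: psi[component][derivative-axis]
  std::vector<double> pExy, pExz, pEyx, pEyz, pEzx, pEzy;
  std::vector<double> pHxy, pHxz, pHyx, pHyz, pHzx, pHzy;
  Pml1d px, py, pz;
  std::vector<int> pec;     // PEC Ex edge indices
  long feed;                // feed Ex edge index
  double CaF, CbF, src_scale;
  double inv_dx, dtmu;
  int npml_;

  long at(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * k);
  }

  void init(IntegerVector dims, double dx_, double dt_,
            const NumericVector& eps_r, const NumericVector& sigma,
            IntegerVector pec_idx, long feed_idx, double Rs,
            int npml, double pml_m, double pml_sig_factor, double pml_alpha,
            double eps_bg) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    npml_ = npml;
    nn = (long)nx * ny * nz;
    dx = dx_; dt = dt_;
    inv_dx = 1.0 / dx;
    dtmu = dt / (MU0 * dx);
    Ex.assign(nn, 0); Ey.assign(nn, 0); Ez.assign(nn, 0);
    Hx.assign(nn, 0); Hy.assign(nn, 0); Hz.assign(nn, 0);
    pExy.assign(nn, 0); pExz.assign(nn, 0); pEyx.assign(nn, 0);
    pEyz.assign(nn, 0); pEzx.assign(nn, 0); pEzy.assign(nn, 0);
    pHxy.assign(nn, 0); pHxz.assign(nn, 0); pHyx.assign(nn, 0);
    pHyz.assign(nn, 0); pHzx.assign(nn, 0); pHzy.assign(nn, 0);

    double eta = 376.730313668 / std::sqrt(eps_bg);
    double sig_max = pml_sig_factor * (pml_m + 1.0) / (eta * dx);
    px = make_pml(nx, npml, pml_m, sig_max, pml_alpha, dt);
    py = make_pml(ny, npml, pml_m, sig_max, pml_alpha, dt);
    pz = make_pml(nz, npml, pml_m, sig_max, pml_alpha, dt);

    CaX.assign(nn, 0); CbX.assign(nn, 0);
    CaY.assign(nn, 0); CbY.assign(nn, 0);
    CaZ.assign(nn, 0); CbZ.assign(nn, 0);
    auto set_coef = [&](std::vector<double>& Ca, std::vector<double>& Cb,
                        int si, int sj, int sk) {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            long id = at(i, j, k);
            int i2 = std::min(i + si, nx - 1);
            int j2 = std::min(j + sj, ny - 1);
            int k2 = std::min(k + sk, nz - 1);
            long id2 = at(i2, j2, k2);
            double ep = 0.5 * (eps_r[id] + eps_r[id2]) * EPS0;
            double sg = 0.5 * (sigma[id] + sigma[id2]);
            double q = sg * dt / (2.0 * ep);
            Ca[id] = (1.0 - q) / (1.0 + q);
            Cb[id] = (dt / ep) / (1.0 + q) * inv_dx;
          }
    };
    set_coef(CaX, CbX, 1, 0, 0);
    set_coef(CaY, CbY, 0, 1, 0);
    set_coef(CaZ, CbZ, 0, 0, 1);

    pec.assign(pec_idx.begin(), pec_idx.end());
    feed = feed_idx;
    if (feed >= 0) {
      int fi = feed % nx;
      long rem = feed / nx;
      int fj = rem % ny, fk = rem / ny;
      long id2 = at(std::min(fi + 1, nx - 1), fj, fk);
      double ep = 0.5 * (eps_r[feed] + eps_r[id2]) * EPS0;
      double sg = 0.5 * (sigma[feed] + sigma[id2]) + 1.0 / (Rs * dx);
      double q = sg * dt / (2.0 * ep);
      CaF = (1.0 - q) / (1.0 + q);
      CbF = (dt / ep) / (1.0 + q);           // note: not pre-divided by dx
      src_scale = 1.0 / (Rs * dx * dx);
    }
  }

  // pass 1: plain Yee curl updates over the whole domain; pass 2 adds the
  // CPML recursive-convolution corrections inside the absorbing slabs only
  // (identical arithmetic to a fused update, but the psi arrays are touched
  // only where their coefficients are nonzero).

  bool in_pml_h(const Pml1d& p, int i) const { return p.ch[i] != 0.0; }
  bool in_pml_e(const Pml1d& p, int i) const { return p.ce[i] != 0.0; }

  void step_h() {
    const long sy = nx, sz = (long)nx * ny;
    const double* RESTRICT ex = Ex.data();
    const double* RESTRICT ey = Ey.data();
    const double* RESTRICT ez = Ez.data();
    double* RESTRICT hx = Hx.data();
    double* RESTRICT hy = Hy.data();
    double* RESTRICT hz = Hz.data();
    const double f = dt / MU0 * inv_dx;
    for (int k = 0; k < nz - 1; ++k) {
      for (int j = 0; j < ny - 1; ++j) {
        long base = sy * j + sz * k;
        for (long id = base; id < base + nx - 1; ++id) {
          hx[id] -= f * (ez[id + sy] - ez[id] - ey[id + sz] + ey[id]);
          hy[id] -= f * (ex[id + sz] - ex[id] - ez[id + 1] + ez[id]);
          hz[id] -= f * (ey[id + 1] - ey[id] - ex[id + sy] + ex[id]);
        }
        // i = nx-1 column: only Hx has a valid stencil
        long id = base + nx - 1;
        hx[id] -= f * (ez[id + sy] - ez[id] - ey[id + sz] + ey[id]);
      }
      // j = ny-1 row: only Hy valid
      long base = sy * (ny - 1) + sz * k;
      for (long id = base; id < base + nx - 1; ++id)
        hy[id] -= f * (ex[id + sz] - ex[id] - ez[id + 1] + ez[id]);
    }
    // k = nz-1 plane: only Hz valid
    for (int j = 0; j < ny - 1; ++j) {
      long base = sy * j + sz * (nz - 1);
      for (long id = base; id < base + nx - 1; ++id)
        hz[id] -= f * (ey[id + 1] - ey[id] - ex[id + sy] + ex[id]);
    }

    const double fd = dt / MU0;
    // x-PML: psi for dE?/dx terms (Hy, Hz)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long base = sy * j + sz * k;
        for (int i = 0; i < nx - 1; ++i) {
          if (!in_pml_h(px, i)) { if (i < npml_) i = nx - npml_ - 2; continue; }
          long id = base + i;
          double dzx = (Ez[id + 1] - Ez[id]) * inv_dx;
          double dyx = (Ey[id + 1] - Ey[id]) * inv_dx;
          double p1 = pHyx[id] = px.bh[i] * pHyx[id] + px.ch[i] * dzx;
          double p2 = pHzx[id] = px.bh[i] * pHzx[id] + px.ch[i] * dyx;
          if (k < nz - 1) Hy[id] += fd * p1;
          if (j < ny - 1) Hz[id] -= fd * p2;
        }
      }
    // y-PML: psi for dE?/dy terms (Hx, Hz)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny - 1; ++j) {
        if (!in_pml_h(py, j)) { if (j < npml_) j = ny - npml_ - 2; continue; }
        long base = sy * j + sz * k;
        for (int i = 0; i < nx; ++i) {
          long id = base + i;
          double dzy = (Ez[id + sy] - Ez[id]) * inv_dx;
          double dxy = (Ex[id + sy] - Ex[id]) * inv_dx;
          double p1 = pHxy[id] = py.bh[j] * pHxy[id] + py.ch[j] * dzy;
          double p2 = pHzy[id] = py.bh[j] * pHzy[id] + py.ch[j] * dxy;
          if (k < nz - 1) Hx[id] -= fd * p1;
          if (i < nx - 1) Hz[id] += fd * p2;
        }
      }
    // z-PML: psi for dE?/dz terms (Hx, Hy)
    for (int k = 0; k < nz - 1; ++k) {
      if (!in_pml_h(pz, k)) { if (k < npml_) k = nz - npml_ - 2; continue; }
      for (int j = 0; j < ny; ++j) {
        long base = sy * j + sz * k;
        for (int i = 0; i < nx; ++i) {
          long id = base + i;
          double dyz = (Ey[id + sz] - Ey[id]) * inv_dx;
          double dxz = (Ex[id + sz] - Ex[id]) * inv_dx;
          double p1 = pHxz[id] = pz.bh[k] * pHxz[id] + pz.ch[k] * dyz;
          double p2 = pHyz[id] = pz.bh[k] * pHyz[id] + pz.ch[k] * dxz;
          if (j < ny - 1) Hx[id] += fd * p1;
          if (i < nx - 1) Hy[id] -= fd * p2;
        }
      }
    }
  }

  // vs: source EMF at the E-update time
  void step_e(double vs) {
    const long sy = nx, sz = (long)nx * ny;
    double ex_feed_old = (feed >= 0) ? Ex[feed] : 0.0;
    double feed_curl = 0.0;
    {
      const double* RESTRICT hx = Hx.data();
      const double* RESTRICT hy = Hy.data();
      const double* RESTRICT hz = Hz.data();
      double* RESTRICT ex = Ex.data();
      double* RESTRICT ey = Ey.data();
      double* RESTRICT ez = Ez.data();
      const double* RESTRICT cax = CaX.data();
      const double* RESTRICT cbx = CbX.data();
      const double* RESTRICT cay = CaY.data();
      const double* RESTRICT cby = CbY.data();
      const double* RESTRICT caz = CaZ.data();
      const double* RESTRICT cbz = CbZ.data();
      for (int k = 1; k < nz; ++k) {
        for (int j = 1; j < ny; ++j) {
          long base = sy * j + sz * k;
          for (long id = base + 1; id < base + nx; ++id) {
            ex[id] = cax[id] * ex[id] +
              cbx[id] * (hz[id] - hz[id - sy] - hy[id] + hy[id - sz]);
            ey[id] = cay[id] * ey[id] +
              cby[id] * (hx[id] - hx[id - sz] - hz[id] + hz[id - 1]);
            ez[id] = caz[id] * ez[id] +
              cbz[id] * (hy[id] - hy[id - 1] - hx[id] + hx[id - sy]);
          }
        }
      }
    }
    // x-PML corrections (dH?/dx terms: Ey, Ez)
    for (int k = 1; k < nz; ++k)
      for (int j = 1; j < ny; ++j) {
        long base = sy * j + sz * k;
        for (int i = 1; i < nx; ++i) {
          if (!in_pml_e(px, i)) { if (i < npml_) i = nx - npml_ - 1; continue; }
          long id = base + i;
          double dzx = (Hz[id] - Hz[id - 1]) * inv_dx;
          double dyx = (Hy[id] - Hy[id - 1]) * inv_dx;
          double p1 = pEyx[id] = px.be[i] * pEyx[id] + px.ce[i] * dzx;
          double p2 = pEzx[id] = px.be[i] * pEzx[id] + px.ce[i] * dyx;
          Ey[id] -= CbY[id] * dx * p1;
          Ez[id] += CbZ[id] * dx * p2;
        }
      }
    // y-PML corrections (dH?/dy terms: Ex, Ez)
    for (int k = 1; k < nz; ++k)
      for (int j = 1; j < ny; ++j) {
        if (!in_pml_e(py, j)) { if (j < npml_) j = ny - npml_ - 1; continue; }
        long base = sy * j + sz * k;
        for (int i = 1; i < nx; ++i) {
          long id = base + i;
          double dzy = (Hz[id] - Hz[id - sy]) * inv_dx;
          double dxy = (Hx[id] - Hx[id - sy]) * inv_dx;
          double p1 = pExy[id] = py.be[j] * pExy[id] + py.ce[j] * dzy;
          double p2 = pEzy[id] = py.be[j] * pEzy[id] + py.ce[j] * dxy;
          Ex[id] += CbX[id] * dx * p1;
          Ez[id] -= CbZ[id] * dx * p2;
        }
      }
    // z-PML corrections (dH?/dz terms: Ex, Ey)
    for (int k = 1; k < nz; ++k) {
      if (!in_pml_e(pz, k)) { if (k < npml_) k = nz - npml_ - 1; continue; }
      for (int j = 1; j < ny; ++j) {
        long base = sy * j + sz * k;
        for (int i = 1; i < nx; ++i) {
          long id = base + i;
          double dyz = (Hy[id] - Hy[id - sz]) * inv_dx;
          double dxz = (Hx[id] - Hx[id - sz]) * inv_dx;
          double p1 = pExz[id] = pz.be[k] * pExz[id] + pz.ce[k] * dyz;
          double p2 = pEyz[id] = pz.be[k] * pEyz[id] + pz.ce[k] * dxz;
          Ex[id] -= CbX[id] * dx * p1;
          Ey[id] += CbY[id] * dx * p2;
        }
      }
    }

    if (feed >= 0) {
      long id = feed;
      double dhzy = (Hz[id] - Hz[id - sy]) * inv_dx;
      double dhyz = (Hy[id] - Hy[id - sz]) * inv_dx;
      feed_curl = dhzy + pExy[id] - dhyz - pExz[id];
      Ex[id] = CaF * ex_feed_old + CbF * (feed_curl - vs * src_scale);
    }
    for (size_t q = 0; q < pec.size(); ++q) Ex[pec[q]] = 0.0;
  }
};

} // namespace

// Time-harmonic solve: drive the port at frequency f, demodulate the field
// to phasors window by window until the port phasors settle.
// [[Rcpp::export]]
List fdtd_harmonic_cpp(IntegerVector dims, double dx, double courant,
                       NumericVector eps_r, NumericVector sigma,
                       IntegerVector pec_idx, int feed_idx,
                       double Rs, double f, double amplitude,
                       double phase_deg,
                       int npml, double pml_m, double pml_sig_factor,
                       double pml_alpha, double eps_bg,
                       int ramp_periods, int window_periods, double tol,
                       int max_windows, IntegerVector probe_idx) {
  set_flush_to_zero();
  const double c0 = 299792458.0;
  double dt_cfl = courant * dx / (c0 * std::sqrt(3.0));
  double T = 1.0 / f;
  int spp = (int)std::ceil(T / dt_cfl);      // integer steps per period
  double dt = T / spp;
  // field demodulation decimation: sampling every `stride` steps keeps the
  // quadrature sums exact as long as stride divides the steps per period
  int stride = 1;
  for (int d = 6; d >= 2; --d) if (spp % d == 0) { stride = d; break; }

  Fdtd g;
  g.init(dims, dx, dt, eps_r, sigma, pec_idx, feed_idx, Rs,
         npml, pml_m, pml_sig_factor, pml_alpha, eps_bg);

  double w = 2.0 * M_PI * f;
  double phase = phase_deg * M_PI / 180.0;
  double t_ramp = ramp_periods * T;
  int wsteps = window_periods * spp;

  long nn = g.nn;
  std::vector<double> accEc(3 * nn), accEs(3 * nn);
  int np = probe_idx.size();
  std::vector<std::complex<double>> prevP(np + 2), curP(np + 2);
  std::complex<double> Vph(0, 0), Iph(0, 0);
  double drift = NA_REAL;
  int nsamp_last = 1;
  bool converged = false;
  int windows = 0;
  long stepno = 0;

  for (windows = 1; windows <= max_windows; ++windows) {
    std::fill(accEc.begin(), accEc.end(), 0.0);
    std::fill(accEs.begin(), accEs.end(), 0.0);
    std::vector<double> accVc(1, 0), accVs(1, 0), accIc(1, 0), accIs(1, 0);
    std::vector<double> accPc(np, 0), accPs(np, 0);
    int nsamp = 0;
    for (int s = 0; s < wsteps; ++s) {
      g.step_h();
      double t = (stepno + 0.5) * dt;
      double ramp = (t < t_ramp) ? 0.5 * (1 - std::cos(M_PI * t / t_ramp)) : 1.0;
      double vs = ramp * amplitude * std::cos(w * t + phase);
      g.step_e(vs);
      ++stepno;
      double te = stepno * dt;
      double cw = std::cos(w * te), sw = std::sin(w * te);
      if (s % stride == 0) {
        ++nsamp;
        auto axpy2 = [nn](double a, double b, const double* RESTRICT x,
                          double* RESTRICT yc, double* RESTRICT ys) {
          for (long id = 0; id < nn; ++id) {
            yc[id] += a * x[id];
            ys[id] += b * x[id];
          }
        };
        axpy2(cw, sw, g.Ex.data(), accEc.data(), accEs.data());
        axpy2(cw, sw, g.Ey.data(), accEc.data() + nn, accEs.data() + nn);
        axpy2(cw, sw, g.Ez.data(), accEc.data() + 2 * nn, accEs.data() + 2 * nn);
      }
      if (feed_idx >= 0) {
        double rampe = (te < t_ramp) ? 0.5 * (1 - std::cos(M_PI * te / t_ramp)) : 1.0;
        double vse = rampe * amplitude * std::cos(w * te + phase);
        double vport = -g.Ex[feed_idx] * dx;
        double iport = (vse - vport) / Rs;
        accVc[0] += vport * cw; accVs[0] += vport * sw;
        accIc[0] += iport * cw; accIs[0] += iport * sw;
      }
      for (int p = 0; p < np; ++p) {
        accPc[p] += g.Ex[probe_idx[p]] * cw;
        accPs[p] += g.Ex[probe_idx[p]] * sw;
      }
    }
    nsamp_last = nsamp;
    double sc = 2.0 / wsteps;
    Vph = std::complex<double>(sc * accVc[0], -sc * accVs[0]);
    Iph = std::complex<double>(sc * accIc[0], -sc * accIs[0]);
    curP[0] = Vph; curP[1] = Iph;
    for (int p = 0; p < np; ++p)
      curP[2 + p] = std::complex<double>(sc * accPc[p], -sc * accPs[p]);
    if (windows > 1) {
      double ref = 0;
      for (size_t q = 0; q < curP.size(); ++q)
        ref = std::max(ref, std::abs(curP[q]));
      drift = 0;
      for (size_t q = 0; q < curP.size(); ++q)
        drift = std::max(drift, std::abs(curP[q] - prevP[q]) / (ref + 1e-300));
      if (drift < tol) { converged = true; }
    }
    prevP = curP;
    if (converged) break;
    Rcpp::checkUserInterrupt();
  }
  if (windows > max_windows) windows = max_windows;

  double sc = 2.0 / nsamp_last;
  ComplexVector Exp(nn), Eyp(nn), Ezp(nn);
  for (long id = 0; id < nn; ++id) {
    Exp[id].r = sc * accEc[id];          Exp[id].i = -sc * accEs[id];
    Eyp[id].r = sc * accEc[nn + id];     Eyp[id].i = -sc * accEs[nn + id];
    Ezp[id].r = sc * accEc[2 * nn + id]; Ezp[id].i = -sc * accEs[2 * nn + id];
  }
  return List::create(
    _["Ex"] = Exp, _["Ey"] = Eyp, _["Ez"] = Ezp,
    _["V"] = Rcomplex{Vph.real(), Vph.imag()},
    _["I"] = Rcomplex{Iph.real(), Iph.imag()},
    _["windows"] = windows, _["drift"] = drift,
    _["converged"] = converged, _["dt"] = dt,
    _["steps_per_period"] = spp);
}

// Broadband port run: Gaussian-modulated sinusoid drive, records the port
// voltage and current time series for impedance / reflection sweeps.
// [[Rcpp::export]]
List fdtd_port_cpp(IntegerVector dims, double dx, double courant,
                   NumericVector eps_r, NumericVector sigma,
                   IntegerVector pec_idx, int feed_idx,
                   double Rs, double f0, double bw, double amplitude,
                   int npml, double pml_m, double pml_sig_factor,
                   double pml_alpha, double eps_bg, int nsteps) {
  set_flush_to_zero();
  const double c0 = 299792458.0;
  double dt = courant * dx / (c0 * std::sqrt(3.0));

  Fdtd g;
  g.init(dims, dx, dt, eps_r, sigma, pec_idx, feed_idx, Rs,
         npml, pml_m, pml_sig_factor, pml_alpha, eps_bg);

  double tau = 0.5 / bw;            // Gaussian envelope width from bandwidth
  double t0 = 4.0 * tau;
  double w0 = 2.0 * M_PI * f0;
  NumericVector Vt(nsteps), It(nsteps), St(nsteps);
  for (int s = 0; s < nsteps; ++s) {
    g.step_h();
    double t = (s + 0.5) * dt;
    double vs = amplitude * std::sin(w0 * (t - t0)) *
      std::exp(-std::pow((t - t0) / tau, 2));
    g.step_e(vs);
    double te = (s + 1) * dt;
    double vse = amplitude * std::sin(w0 * (te - t0)) *
      std::exp(-std::pow((te - t0) / tau, 2));
    double vport = -g.Ex[feed_idx] * dx;
    Vt[s] = vport;
    It[s] = (vse - vport) / Rs;
    St[s] = vse;
    if (s % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["V"] = Vt, _["I"] = It, _["Vs"] = St, _["dt"] = dt);
}
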