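// Explicit finite-difference stepper for the Pennes bioheat equation on a
// labeled voxel grid: harmonic-mean face conductivities, blood-perfusion
// sink, metabolic + external volumetric sources, Robin (convective) faces
// where skin meets air, insulated elsewhere, and the nonlinear
// temperature-dependent perfusion model inside the tumor.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List bioheat_run_cpp(IntegerVector dims, double dx,
                     IntegerVector labels,      // 0 = air
                     NumericVector rhoC,        // rho * C, J/m^3/K
                     NumericVector kcond,       // W/m/K
                     NumericVector perf,        // W/m^3/K (0 in tumor)
                     NumericVector src,         // rho*HGR + Q, W/m^3
                     NumericVector T0,
                     double Tb, double dt, int nsteps,
                     double h, double Text, int skin_label,
                     LogicalVector tumor_mask,
                     double Cb, double om_base, double om_amp,
                     double om_denom,
                     LogicalVector fixed_mask,
                     int record_idx, int record_every) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long nn = (long)nx * ny * nz;
  std::vector<double> T(T0.begin(), T0.end()), Tn(T.begin(), T.end());
  long sy = nx, sz = (long)nx * ny;
  double inv_dx2 = 1.0 / (dx * dx);
  bool has_fixed = fixed_mask.size() == nn;

  int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec), rec_T(nrec), rec_tumor_max(nrec);
  int ir = 0;
  auto record = [&](int step) {
    rec_t[ir] = step * dt;
    rec_T[ir] = (record_idx >= 0) ? T[record_idx] : NA_REAL;
    double tm = R_NegInf;
    for (long id = 0; id < nn; ++id)
      if (tumor_mask[id] && T[id] > tm) tm = T[id];
    rec_tumor_max[ir] = (tm == R_NegInf) ? NA_REAL : tm;
    ++ir;
  };
  record(0);

  for (int s = 1; s <= nsteps; ++s) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long id = i + sy * j + sz * k;
          int lab = labels[id];
          if (lab == 0) { Tn[id] = T[id]; continue; }
          if (has_fixed && fixed_mask[id]) { Tn[id] = T[id]; continue; }
          double kc = kcond[id], Tc = T[id];
          double flux = 0.0;   // sum of face fluxes * dx^2 terms
          int n_robin = 0;
          auto face = [&](long nb_id, bool in_bounds) {
            if (in_bounds && labels[nb_id] != 0) {
              double kn = kcond[nb_id];
              double kf = 2.0 * kc * kn / (kc + kn);
              flux += kf * (T[nb_id] - Tc);
            } else if (in_bounds && lab == skin_label) {
              // air-facing skin face: Robin convective exchange
              ++n_robin;
            }
            // out-of-domain or air next to non-skin tissue: insulated
          };
          face(id - 1, i > 0);       face(id + 1, i < nx - 1);
          face(id - sy, j > 0);      face(id + sy, j < ny - 1);
          face(id - sz, k > 0);      face(id + sz, k < nz - 1);
          double perf_term;
          if (tumor_mask[id]) {
            double d = Tc - 37.0;
            double om = om_base + om_amp * std::exp(-(d * d * d * d) / om_denom);
            perf_term = Cb * om * (Tb - Tc);
          } else {
            perf_term = perf[id] * (Tb - Tc);
          }
          double rhs = flux * inv_dx2 - n_robin * h * (Tc - Text) / dx +
            perf_term + src[id];
          Tn[id] = Tc + dt / rhoC[id] * rhs;
        }
    std::swap(T, Tn);
    if (s % record_every == 0 && ir < nrec) record(s);
    if (s % 50 == 0) {
      for (long id = 0; id < nn; id += 97)
        if (!std::isfinite(T[id]))
          stop("bioheat instability: non-finite temperature at step %d", s);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericVector Tout(nn);
  std::copy(T.begin(), T.end(), Tout.begin());
  return List::create(_["T"] = Tout,
                      _["time"] = rec_t[Range(0, ir - 1)],
                      _["T_center"] = rec_T[Range(0, ir - 1)],
                      _["T_tumor_max"] = rec_tumor_max[Range(0, ir - 1)]);
}
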