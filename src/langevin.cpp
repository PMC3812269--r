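#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (position) Langevin integrator for point particles under a
// tabulated radial pair potential and an optional implicit membrane slab
// along z. Units: nm, ps, kJ/mol, amu. Uses R's RNG (seed from R side).
//
// The pair force comes from a dense pre-tabulated dV/dr grid (linear
// interpolation); |dV/dr| is clamped at force_cap and pairs that end a step
// below the table floor r_lo are reflected back to r_lo (hard-core
// reflection). max_drift reports the largest deterministic displacement
// component seen in any step, for the timestep diagnostic on the R side.
// [[Rcpp::export(name = ".langevin_run")]]
List langevin_run(NumericMatrix X0, NumericVector L, LogicalVector periodic,
                  NumericVector rgrid, NumericVector dVgrid, double force_cap,
                  bool has_well, double well_cz, double well_h,
                  double well_off, double well_depth, double well_w,
                  double barrier,
                  double mob, double kT, double dt, int nsteps, int stride) {
  int n = X0.nrow();
  NumericMatrix X = clone(X0);
  double noise_sd = std::sqrt(2.0 * kT * mob * dt);
  int nout = nsteps / stride;
  NumericVector times(nout);
  NumericVector frames((R_xlen_t)nout * n * 3);
  double dr = rgrid[1] - rgrid[0];
  int ng = rgrid.size();
  double r_lo = rgrid[0], r_hi = rgrid[ng - 1];
  double max_drift = 0.0;
  RNGScope scope;
  int fi = 0;
  for (int s = 1; s <= nsteps; s++) {
    NumericMatrix F(n, 3);
    for (int i = 0; i < n - 1; i++) for (int j = i + 1; j < n; j++) {
      double dv[3]; double r2 = 0;
      for (int k = 0; k < 3; k++) {
        double d = X(i, k) - X(j, k);
        if (periodic[k]) d -= L[k] * std::round(d / L[k]);
        dv[k] = d; r2 += d * d;
      }
      double r = std::sqrt(r2);
      if (r > r_hi || r < 1e-12) continue;
      double dV;
      if (r < r_lo) dV = -force_cap;
      else {
        double u = (r - r_lo) / dr;
        int k0 = (int)u; if (k0 > ng - 2) k0 = ng - 2;
        double f = u - k0;
        dV = dVgrid[k0] * (1 - f) + dVgrid[k0 + 1] * f;
        if (dV < -force_cap) dV = -force_cap;
        if (dV > force_cap) dV = force_cap;
      }
      double fmag = -dV / r;
      for (int k = 0; k < 3; k++) { F(i, k) += fmag * dv[k]; F(j, k) -= fmag * dv[k]; }
    }
    if (has_well) {
      for (int i = 0; i < n; i++) {
        double dz = X(i, 2) - well_cz;
        double adz = std::fabs(dz), sg = (dz >= 0 ? 1.0 : -1.0);
        if (adz < well_h + 2.0 * well_w) {
          double arg = adz - well_off;
          F(i, 2) += -well_depth * std::exp(-arg * arg / (2 * well_w * well_w)) *
                     arg / (well_w * well_w) * sg;
          if (barrier > 0) {
            double argb = adz - well_h;
            F(i, 2) += barrier * std::exp(-argb * argb / (2 * well_w * well_w)) *
                       argb / (well_w * well_w) * sg;
          }
        }
      }
    }
    for (int i = 0; i < n; i++) for (int k = 0; k < 3; k++) {
      double drift = F(i, k) * mob * dt;
      if (std::fabs(drift) > max_drift) max_drift = std::fabs(drift);
      double x = X(i, k) + drift + norm_rand() * noise_sd;
      if (periodic[k]) x -= L[k] * std::floor(x / L[k]);
      X(i, k) = x;
    }
    // hard-core reflection below the table floor
    for (int i = 0; i < n - 1; i++) for (int j = i + 1; j < n; j++) {
      double dv[3]; double r2 = 0;
      for (int k = 0; k < 3; k++) {
        double d = X(i, k) - X(j, k);
        if (periodic[k]) d -= L[k] * std::round(d / L[k]);
        dv[k] = d; r2 += d * d;
      }
      double r = std::sqrt(r2);
      if (r < r_lo && r > 1e-12) {
        double push = (r_lo - r) / 2.0;
        for (int k = 0; k < 3; k++) {
          X(i, k) += push * dv[k] / r;
          X(j, k) -= push * dv[k] / r;
          if (periodic[k]) {
            X(i, k) -= L[k] * std::floor(X(i, k) / L[k]);
            X(j, k) -= L[k] * std::floor(X(j, k) / L[k]);
          }
        }
      }
    }
    if (stride > 0 && s % stride == 0 && fi < nout) {
      times[fi] = s * dt;
      for (int i = 0; i < n; i++) for (int k = 0; k < 3; k++)
        frames[(R_xlen_t)fi * n * 3 + i * 3 + k] = X(i, k);
      fi++;
    }
  }
  return List::create(_["times"] = times, _["frames"] = frames,
                      _["max_drift"] = max_drift);
}
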