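#include <Rcpp.h>
using namespace Rcpp;

// Fused reaction-diffusion inner loop.
//
// U: ncell x nspecies concentrations, cells in R's column-major field order
//    (cell = row + col * ny). D: same shape, per-cell per-species diffusion
//    coefficients (static in time). siteIdx: one row per (circuit, site) unit
//    with 0-based column indices [T, iT, R, Sf, Sb, Sd]; siteRate: per-unit
//    [kOn, kDisp].
//
// Each substep applies a Heun (RK2) local reaction update followed by an
// explicit conservative diffusion update with harmonic-mean interface
// coefficients and no-flux boundaries; negative excursions are clamped at
// zero and counted. Mirrors the R reference stepper stepRD(). The face
// coefficients are precomputed once per call since D does not change.

static void reactionRates(const double* U, double* dU, int ncell, int nsp,
                          const int* sidx, int nunit, const double* srate,
                          double kCat, double Km, double kHyb, double enzyme,
                          bool shared, bool twoStep, double* sumIT) {
  std::fill(dU, dU + (size_t) ncell * nsp, 0.0);
  if (shared) {
    std::fill(sumIT, sumIT + ncell, 0.0);
    for (int j = 0; j < nunit; ++j) {
      const double* uIT = U + (size_t) sidx[j + nunit] * ncell;
      for (int c = 0; c < ncell; ++c) sumIT[c] += uIT[c];
    }
  }
  for (int j = 0; j < nunit; ++j) {
    const double* uT = U + (size_t) sidx[j] * ncell;
    const double* uIT = U + (size_t) sidx[j + nunit] * ncell;
    const double* uR = U + (size_t) sidx[j + 2 * nunit] * ncell;
    const double* uSf = U + (size_t) sidx[j + 3 * nunit] * ncell;
    const double* uSb = U + (size_t) sidx[j + 4 * nunit] * ncell;
    double* dT = dU + (size_t) sidx[j] * ncell;
    double* dIT = dU + (size_t) sidx[j + nunit] * ncell;
    double* dR = dU + (size_t) sidx[j + 2 * nunit] * ncell;
    double* dSf = dU + (size_t) sidx[j + 3 * nunit] * ncell;
    double* dSb = dU + (size_t) sidx[j + 4 * nunit] * ncell;
    double* dSd = dU + (size_t) sidx[j + 5 * nunit] * ncell;
    const double kOn = srate[j], kDisp = srate[j + nunit];
    const double vmax = kCat * enzyme;
    for (int c = 0; c < ncell; ++c) {
      const double denom = Km + (shared ? sumIT[c] : uIT[c]);
      const double rel = vmax * uIT[c] / denom;
      const double inh = kHyb * uT[c] * uR[c];
      dIT[c] += inh - rel;
      dR[c] -= inh;
      if (twoStep) {
        const double bind = kOn * uT[c] * uSf[c];
        const double disp = kDisp * uSb[c];
        dT[c] += rel - inh - bind;
        dSf[c] -= bind;
        dSb[c] += bind - disp;
        dSd[c] += disp;
      } else {
        const double clv = kOn * uT[c] * uSf[c];
        dT[c] += rel - inh - clv;
        dSf[c] -= clv;
        dSd[c] += clv;
      }
    }
  }
}

static inline double harm(double a, double b) {
  return (a + b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
}

// [[Rcpp::export(name = ".rdStepCpp")]]
List rdStepCpp(NumericMatrix U, NumericMatrix D, int ny, int nx,
               double spacing, double dt, int nSteps,
               IntegerMatrix siteIdx, NumericMatrix siteRate,
               double kCat, double Km, double kHyb, double enzyme,
               bool shared, bool twoStep, LogicalVector mobile) {
  const int ncell = ny * nx;
  const int nsp = U.ncol();
  const int nunit = siteIdx.nrow();
  if (U.nrow() != ncell || D.nrow() != ncell || D.ncol() != nsp)
    stop("field dimensions do not match the grid");

  NumericMatrix Uout = clone(U);
  double* u = REAL(Uout);
  const double* d = REAL(D);
  std::vector<double> k1((size_t) ncell * nsp), k2((size_t) ncell * nsp),
      mid((size_t) ncell * nsp), sumIT(ncell), lap(ncell);
  std::vector<int> mob;
  for (int p = 0; p < nsp; ++p) if (mobile[p]) mob.push_back(p);

  // precomputed harmonic-mean face coefficients, scaled by dt / h^2
  const double fac = dt / (spacing * spacing);
  const size_t nvf = (size_t) (ny - 1) * nx;   // vertical faces (row, row+1)
  const size_t nhf = (size_t) ny * (nx - 1);   // horizontal faces (col, col+1)
  std::vector<double> cv(mob.size() * nvf), ch(mob.size() * nhf);
  for (size_t m = 0; m < mob.size(); ++m) {
    const double* dp = d + (size_t) mob[m] * ncell;
    double* cvp = cv.data() + m * nvf;
    double* chp = ch.data() + m * nhf;
    for (int col = 0; col < nx; ++col)
      for (int row = 0; row + 1 < ny; ++row)
        cvp[row + (size_t) col * (ny - 1)] =
          fac * harm(dp[row + col * ny], dp[row + 1 + col * ny]);
    for (int col = 0; col + 1 < nx; ++col)
      for (int row = 0; row < ny; ++row)
        chp[row + (size_t) col * ny] =
          fac * harm(dp[row + col * ny], dp[row + (col + 1) * ny]);
  }

  const int* sidx = INTEGER(siteIdx);
  const double* srate = REAL(siteRate);
  long clamped = 0;

  for (int s = 0; s < nSteps; ++s) {
    // reaction: Heun
    reactionRates(u, k1.data(), ncell, nsp, sidx, nunit, srate,
                  kCat, Km, kHyb, enzyme, shared, twoStep, sumIT.data());
    for (size_t i = 0; i < (size_t) ncell * nsp; ++i) {
      double v = u[i] + dt * k1[i];
      mid[i] = v > 0.0 ? v : 0.0;
    }
    reactionRates(mid.data(), k2.data(), ncell, nsp, sidx, nunit, srate,
                  kCat, Km, kHyb, enzyme, shared, twoStep, sumIT.data());
    for (size_t i = 0; i < (size_t) ncell * nsp; ++i)
      u[i] += 0.5 * dt * (k1[i] + k2[i]);

    // diffusion: conservative explicit update, no-flux boundaries
    for (size_t m = 0; m < mob.size(); ++m) {
      double* up = u + (size_t) mob[m] * ncell;
      const double* cvp = cv.data() + m * nvf;
      const double* chp = ch.data() + m * nhf;
      std::fill(lap.begin(), lap.end(), 0.0);
      for (int col = 0; col < nx; ++col) {
        const int base = col * ny;
        for (int row = 0; row + 1 < ny; ++row) {
          const double f = cvp[row + (size_t) col * (ny - 1)] *
            (up[base + row + 1] - up[base + row]);
          lap[base + row] += f;
          lap[base + row + 1] -= f;
        }
      }
      for (int col = 0; col + 1 < nx; ++col) {
        const int base = col * ny;
        for (int row = 0; row < ny; ++row) {
          const double f = chp[row + (size_t) col * ny] *
            (up[base + ny + row] - up[base + row]);
          lap[base + row] += f;
          lap[base + ny + row] -= f;
        }
      }
      for (int c = 0; c < ncell; ++c) up[c] += lap[c];
    }

    // non-negativity clamp
    for (size_t i = 0; i < (size_t) ncell * nsp; ++i)
      if (u[i] < 0.0) { u[i] = 0.0; ++clamped; }
  }
  return List::create(Named("U") = Uout, Named("clamped") = (double) clamped);
}
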