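// Time steppers for the reaction-(advection-)diffusion models on periodic
// grids.  Reactions are advanced explicitly; the slowly diffusing fields
// (biomass, soil water; e <= O(0.1) m^2/d) use an explicit 5-point Laplacian,
// which is stable for dt <= dx^2/(4 e); the stiff surface-water field is
// advanced exactly in Fourier space (diffusion decay + advection phase
// shift), removing its stability constraint.  Inner loops are written out by
// hand: the step cost is dominated by the h-field FFT pair.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double lap5(const mat& x, int i, int j, int nx, int ny,
                          double inv_dx2, bool oned) {
  const int im = (i == 0) ? nx - 1 : i - 1, ip = (i == nx - 1) ? 0 : i + 1;
  double l = x(im, j) + x(ip, j) - 2.0 * x(i, j);
  if (!oned) {
    const int jm = (j == 0) ? ny - 1 : j - 1, jp = (j == ny - 1) ? 0 : j + 1;
    l += x(i, jm) + x(i, jp) - 2.0 * x(i, j);
  }
  return l * inv_dx2;
}

// [[Rcpp::export]]
Rcpp::List cpp_grazing_run(arma::mat b, const arma::mat& K,
                           double a, double c, double bn, double e,
                           double dx, double dt, int nsteps) {
  const int nx = b.n_rows, ny = b.n_cols;
  const bool oned = (ny == 1);
  const double inv_dx2 = 1.0 / (dx * dx), bn2 = bn * bn;
  double clipped = 0.0;
  mat bn_(nx, ny);
  for (int s = 0; s < nsteps; s++) {
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const double bi = b(i, j);
        double r = a * bi * (1.0 - bi / K(i, j)) - c * bi * bi / (bn2 + bi * bi)
                 + e * lap5(b, i, j, nx, ny, inv_dx2, oned);
        double v = bi + dt * r;
        if (v < 0) { clipped -= v; v = 0.0; }
        bn_(i, j) = v;
      }
    b = bn_;
    if (s % 200 == 199 && !b.is_finite())
      Rcpp::stop("grazing integration diverged at step %d", s + 1);
  }
  if (!b.is_finite()) Rcpp::stop("grazing integration diverged");
  return Rcpp::List::create(Rcpp::Named("b") = b,
                            Rcpp::Named("clipped") = clipped * dx * dx);
}

// [[Rcpp::export]]
Rcpp::List cpp_rietkerk_run(arma::mat b, arma::mat w, arma::mat h,
                            const arma::mat& a,
                            double cb, double db, double gb, double eb,
                            double kI, double rw, double ew,
                            double vh, double ehx, double ehy, double Rh,
                            double w0, double kU,
                            double dx, double dt, int nsteps) {
  const int nx = b.n_rows, ny = b.n_cols;
  const bool oned = (ny == 1);
  const bool spectral_h = (ehx > 0.0) || (ehy > 0.0);
  const double inv_dx2 = 1.0 / (dx * dx), kIw0 = kI * w0;
  double clipped = 0.0;
  // advection: exact circular shift when v dt/dx is an integer Courant
  // number (no numerical diffusion), first-order upwind otherwise
  const double courant = vh * dt / dx;
  const int mshift = (int) std::lround(courant);
  const bool exact_adv = (vh != 0.0) && std::abs(courant - mshift) < 1e-9;
  if (vh != 0.0 && !exact_adv && std::abs(courant) > 1.0)
    Rcpp::stop("advection violates the CFL bound |v_h| dt/dx <= 1");

  // exact one-step diffusion multiplier exp(-(ehx kx^2 + ehy ky^2) dt);
  // advection is first-order upwind (monotone: spectral phase shifts ring at
  // the sharp infiltration fronts and generate negative water depths)
  cx_mat M;
  if (spectral_h) {
    M.set_size(nx, ny);
    for (int j = 0; j < ny; j++) {
      const double ky = 2.0 * datum::pi * ((j < (ny + 1) / 2) ? j : j - ny) / (ny * dx);
      for (int i = 0; i < nx; i++) {
        const double kx = 2.0 * datum::pi * ((i < (nx + 1) / 2) ? i : i - nx) / (nx * dx);
        M(i, j) = std::exp(cx_double(-(ehx * kx * kx + ehy * ky * ky) * dt, 0.0));
      }
    }
  }

  // Patankar-type update: production terms explicit in the numerator, sink
  // terms (all proportional to the field itself) as implicit denominator
  // coefficients, x' = (x + dt P)/(1 + dt D).  Unconditionally positive, so
  // the nonlinear sinks (uptake, infiltration, upwind outflow) cannot drive
  // a field negative and no mass is created by clipping.
  const int nbr = oned ? 2 : 4;
  mat bnew(nx, ny), wnew(nx, ny);
  cx_mat H(nx, ny);
  for (int s = 0; s < nsteps; s++) {
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const double bi = b(i, j), wi = w(i, j), hi = h(i, j);
        const double U = gb * wi / (wi + kU) * bi;
        const double ie = (bi + kIw0) / (bi + kI);
        const double I = a(i, j) * hi * ie;
        // neighbor sums (diffusion inflow); self-outflow goes to the sink
        const double nb_b = lap5(b, i, j, nx, ny, inv_dx2, oned) + nbr * inv_dx2 * bi;
        const double nb_w = lap5(w, i, j, nx, ny, inv_dx2, oned) + nbr * inv_dx2 * wi;
        const double bv = (bi + dt * (cb * U + eb * nb_b)) /
                          (1.0 + dt * (db + eb * nbr * inv_dx2));
        const double wv = (wi + dt * (I + ew * nb_w)) /
                          (1.0 + dt * (gb * bi / (wi + kU) + rw + ew * nbr * inv_dx2));
        double Ph = Rh, Dh = a(i, j) * ie;
        if (vh > 0.0 && !exact_adv) {
          const int ip = (i == nx - 1) ? 0 : i + 1;
          Ph += vh * h(ip, j) / dx; Dh += vh / dx;
        } else if (vh < 0.0 && !exact_adv) {
          const int im = (i == 0) ? nx - 1 : i - 1;
          Ph += -vh * h(im, j) / dx; Dh += -vh / dx;
        }
        const double hv = (hi + dt * Ph) / (1.0 + dt * Dh);
        bnew(i, j) = bv; wnew(i, j) = wv;
        H(i, j) = cx_double(hv, 0.0);
      }
    b = bnew; w = wnew;
    if (exact_adv) {
      // h(x, t+dt) = h(x + v dt, t): circular shift by -mshift rows
      cx_mat Hs = shift(H, -mshift, 0);
      H = Hs;
    }
    if (spectral_h) {
      H = fft2(H);
      H %= M;
      h = real(ifft2(H));
    } else {
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) h(i, j) = H(i, j).real();
    }
    double hc = 0.0;
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        if (h(i, j) < 0) { hc -= h(i, j); h(i, j) = 0.0; }
    clipped += hc;
    if (s % 200 == 199 && (!b.is_finite() || !w.is_finite() || !h.is_finite()))
      Rcpp::stop("Rietkerk integration diverged at step %d", s + 1);
  }
  if (!b.is_finite() || !w.is_finite() || !h.is_finite())
    Rcpp::stop("Rietkerk integration diverged");
  return Rcpp::List::create(Rcpp::Named("b") = b, Rcpp::Named("w") = w,
                            Rcpp::Named("h") = h,
                            Rcpp::Named("clipped") = clipped * dx * dx);
}
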