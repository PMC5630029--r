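#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrators for the two linear compartment systems used
// throughout the package. Time-varying coefficients are supplied sampled on
// the half-step grid: column 2*j   -> value at node t_j,
//                     column 2*j+1 -> value at t_j + dt_j/2,
//                     column 2*j+2 -> value at t_{j+1}.
// All genes (rows) are advanced simultaneously.

// Two-compartment RNA model: dP/dt = k1(t) - k2(t) P ; dM/dt = k2(t) P - k3(t) M
// [[Rcpp::export]]
List rna_rk4(NumericMatrix k1, NumericMatrix k2, NumericMatrix k3,
             NumericVector P0, NumericVector M0, NumericVector dts) {
  const int n = k1.nrow();
  const int N = dts.size();
  NumericMatrix P(n, N + 1), M(n, N + 1);
  for (int g = 0; g < n; ++g) { P(g, 0) = P0[g]; M(g, 0) = M0[g]; }
  for (int j = 0; j < N; ++j) {
    const double dt = dts[j];
    const int c0 = 2 * j, ch = 2 * j + 1, c1 = 2 * j + 2;
    for (int g = 0; g < n; ++g) {
      const double a0 = k1(g, c0), ah = k1(g, ch), a1 = k1(g, c1);
      const double b0 = k2(g, c0), bh = k2(g, ch), b1 = k2(g, c1);
      const double d0 = k3(g, c0), dh = k3(g, ch), d1 = k3(g, c1);
      const double p = P(g, j), m = M(g, j);
      double kP1 = a0 - b0 * p;
      double kM1 = b0 * p - d0 * m;
      double p2 = p + 0.5 * dt * kP1, m2 = m + 0.5 * dt * kM1;
      double kP2 = ah - bh * p2;
      double kM2 = bh * p2 - dh * m2;
      double p3 = p + 0.5 * dt * kP2, m3 = m + 0.5 * dt * kM2;
      double kP3 = ah - bh * p3;
      double kM3 = bh * p3 - dh * m3;
      double p4 = p + dt * kP3, m4 = m + dt * kM3;
      double kP4 = a1 - b1 * p4;
      double kM4 = b1 * p4 - d1 * m4;
      double pn = p + dt / 6.0 * (kP1 + 2 * kP2 + 2 * kP3 + kP4);
      double mn = m + dt / 6.0 * (kM1 + 2 * kM2 + 2 * kM3 + kM4);
      P(g, j + 1) = pn < 0 ? 0.0 : pn;
      M(g, j + 1) = mn < 0 ? 0.0 : mn;
    }
  }
  return List::create(_["P"] = P, _["M"] = M);
}

// Three-compartment RNAPII model:
//   dPr/dt = p1(t) - p2(t) Pr
//   dGb/dt = p2(t) Pr - p3(t) Gb
//   dTe/dt = p3(t) Gb - p4(t) Te
// p1 may be negative; densities are clamped at zero (count of clamps returned).
// [[Rcpp::export]]
List polii_rk4(NumericMatrix p1, NumericMatrix p2, NumericMatrix p3,
               NumericMatrix p4, NumericVector Pr0, NumericVector Gb0,
               NumericVector Te0, NumericVector dts) {
  const int n = p1.nrow();
  const int N = dts.size();
  NumericMatrix Pr(n, N + 1), Gb(n, N + 1), Te(n, N + 1);
  int clamped = 0;
  for (int g = 0; g < n; ++g) {
    Pr(g, 0) = Pr0[g]; Gb(g, 0) = Gb0[g]; Te(g, 0) = Te0[g];
  }
  for (int j = 0; j < N; ++j) {
    const double dt = dts[j];
    const int c0 = 2 * j, ch = 2 * j + 1, c1 = 2 * j + 2;
    for (int g = 0; g < n; ++g) {
      const double a0 = p1(g, c0), ah = p1(g, ch), a1 = p1(g, c1);
      const double b0 = p2(g, c0), bh = p2(g, ch), b1 = p2(g, c1);
      const double e0 = p3(g, c0), eh = p3(g, ch), e1 = p3(g, c1);
      const double f0 = p4(g, c0), fh = p4(g, ch), f1 = p4(g, c1);
      const double x = Pr(g, j), y = Gb(g, j), z = Te(g, j);
      double kx1 = a0 - b0 * x;
      double ky1 = b0 * x - e0 * y;
      double kz1 = e0 * y - f0 * z;
      double x2 = x + 0.5 * dt * kx1, y2 = y + 0.5 * dt * ky1, z2 = z + 0.5 * dt * kz1;
      double kx2 = ah - bh * x2;
      double ky2 = bh * x2 - eh * y2;
      double kz2 = eh * y2 - fh * z2;
      double x3 = x + 0.5 * dt * kx2, y3 = y + 0.5 * dt * ky2, z3 = z + 0.5 * dt * kz2;
      double kx3 = ah - bh * x3;
      double ky3 = bh * x3 - eh * y3;
      double kz3 = eh * y3 - fh * z3;
      double x4 = x + dt * kx3, y4 = y + dt * ky3, z4 = z + dt * kz3;
      double kx4 = a1 - b1 * x4;
      double ky4 = b1 * x4 - e1 * y4;
      double kz4 = e1 * y4 - f1 * z4;
      double xn = x + dt / 6.0 * (kx1 + 2 * kx2 + 2 * kx3 + kx4);
      double yn = y + dt / 6.0 * (ky1 + 2 * ky2 + 2 * ky3 + ky4);
      double zn = z + dt / 6.0 * (kz1 + 2 * kz2 + 2 * kz3 + kz4);
      if (xn < 0) { xn = 0.0; ++clamped; }
      if (yn < 0) { yn = 0.0; ++clamped; }
      if (zn < 0) { zn = 0.0; ++clamped; }
      Pr(g, j + 1) = xn; Gb(g, j + 1) = yn; Te(g, j + 1) = zn;
    }
  }
  return List::create(_["Pr"] = Pr, _["Gb"] = Gb, _["Te"] = Te,
                      _["clamped"] = clamped);
}
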