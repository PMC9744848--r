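#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Twisted-torus metric: the neural sheet tiles the plane by the triangular
// lattice generated by e1 = (1, 0) and e2 = (0.5, Py), Py = sqrt(3)/2 for a
// square sheet.  For displacements arising between neurons in the fundamental
// domain (plus a small velocity offset) the minimum over m, n in {-2 ... 2}
// of || d + m e1 + n e2 || attains the global lattice minimum (the 5x5
// neighbourhood covers the corner cases a 3x3 one misses).
static inline double min_torus_norm2(double dx, double dy, double Py) {
  double best = R_PosInf;
  for (int m = -2; m <= 2; ++m) {
    for (int n = -2; n <= 2; ++n) {
      double ax = dx + m + 0.5 * n;
      double ay = dy + n * Py;
      double d2 = ax * ax + ay * ay;
      if (d2 < best) best = d2;
    }
  }
  return best;
}

// One full CAN run over a sequence of (already gain- and rotation-modulated)
// velocities.  Weights depend on neuron index differences only, so each step
// computes ncls = Nx*Ny distinct weights instead of N^2.
//
// A0      initial activity (length N)
// cls     N x N integer matrix, 0-based displacement class of (i, j)
// repx/y  representative raw displacement per class
// vrx/y   modulated velocity sequence (torus units per step)
// record  if true, return the full activity trace (nsteps x N)
// [[Rcpp::export]]
List can_run_cpp(NumericVector A0, IntegerMatrix cls,
                 NumericVector repx, NumericVector repy,
                 NumericVector vrx, NumericVector vry,
                 double Ia, double sigma_w, double Tshift, double tau,
                 double Py, NumericVector cx, NumericVector cy,
                 bool record) {
  const int N = A0.size();
  const int nsteps = vrx.size();
  const int ncls = repx.size();
  const double s2 = sigma_w * sigma_w;
  const double TWOPI = 2.0 * M_PI;

  std::vector<double> A(A0.begin(), A0.end());
  std::vector<double> B(N), w(ncls);
  // precomputed phase factors for the circular (resultant-vector) bump center
  std::vector<double> cxs(N), cxc(N), cys(N), cyc(N);
  for (int i = 0; i < N; ++i) {
    cxc[i] = std::cos(TWOPI * cx[i]);
    cxs[i] = std::sin(TWOPI * cx[i]);
    cyc[i] = std::cos(TWOPI * cy[i] / Py);
    cys[i] = std::sin(TWOPI * cy[i] / Py);
  }

  NumericMatrix centers(nsteps, 2);
  NumericVector maxA(nsteps);
  NumericMatrix act(record ? nsteps : 1, record ? N : 1);
  const int* clsp = cls.begin();

  for (int t = 0; t < nsteps; ++t) {
    const double vx = vrx[t], vy = vry[t];
    for (int k = 0; k < ncls; ++k) {
      double d2 = min_torus_norm2(repx[k] + vx, repy[k] + vy, Py);
      w[k] = Ia * std::exp(-d2 / s2) - Tshift;
    }
    double sumB = 0.0;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      const int* cj = clsp + (size_t)N * j;
      for (int i = 0; i < N; ++i) s += A[i] * w[cj[i]];
      B[j] = s;
      sumB += s;
    }
    double meanB = sumB / N;
    if (!std::isfinite(meanB) || meanB <= 0.0)
      stop("grid dynamics collapsed at step %d (mean input %g)", t + 1, meanB);
    double mx = 0.0;
    double rxc = 0.0, rxs = 0.0, ryc = 0.0, rys = 0.0;
    for (int i = 0; i < N; ++i) {
      double x = B[i] + tau * (B[i] / meanB - B[i]);
      double a = x > 0.0 ? x : 0.0;
      A[i] = a;
      if (a > mx) mx = a;
      rxc += a * cxc[i]; rxs += a * cxs[i];
      ryc += a * cyc[i]; rys += a * cys[i];
    }
    if (mx <= 0.0)
      stop("grid dynamics collapsed at step %d (all activity rectified to 0)", t + 1);
    double angx = std::atan2(rxs, rxc) / TWOPI;
    if (angx < 0) angx += 1.0;
    double angy = std::atan2(rys, ryc) / TWOPI;
    if (angy < 0) angy += 1.0;
    centers(t, 0) = angx;
    centers(t, 1) = angy * Py;
    maxA[t] = mx;
    if (record) for (int i = 0; i < N; ++i) act(t, i) = A[i];
  }

  NumericVector Afin(A.begin(), A.end());
  return List::create(_["activity"] = record ? act : NumericMatrix(0, 0),
                      _["centers"] = centers,
                      _["max_activity"] = maxA,
                      _["A"] = Afin);
}
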