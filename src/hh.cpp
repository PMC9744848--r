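#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classic squid-axon Hodgkin-Huxley rate functions, written for the
// depolarisation v = Vm - Vr (mV).  Removable singularities at v = 10 and
// v = 25 are patched with their limits.
// Three shared exponentials cover all six rates:
// exp((25-v)/10) = e1 * e^1.5, exp((30-v)/10) = e1 * e^2, exp(-v/20) = e2^4
// (same composition as the R reference implementation, so the two match
// bit for bit).
static const double E15 = std::exp(1.5);
static const double E20 = std::exp(2.0);
static inline void hh_rates(double v, double* r) {
  double e1 = std::exp((10.0 - v) / 10.0);
  double e2 = std::exp(-v / 80.0);
  double e3 = std::exp(-v / 18.0);
  double x1 = 10.0 - v, x2 = 25.0 - v;
  r[0] = std::fabs(x1) < 1e-6 ? 0.1 : 0.01 * x1 / (e1 - 1.0);        // a_n
  r[1] = 0.125 * e2;                                                  // b_n
  r[2] = std::fabs(x2) < 1e-6 ? 1.0 : 0.1 * x2 / (e1 * E15 - 1.0);   // a_m
  r[3] = 4.0 * e3;                                                    // b_m
  r[4] = 0.07 * e2 * e2 * e2 * e2;                                    // a_h
  r[5] = 1.0 / (e1 * E20 + 1.0);                                      // b_h
}

// Forward-Euler integration of a population of independent H-H units for
// nsub sub-steps of size dt.  Gating variables are clamped to [0, 1] after
// every step.  A spike is an upward crossing of 0 mV (absolute).
// [[Rcpp::export]]
List hh_integrate_cpp(NumericVector V, NumericVector m, NumericVector h,
                      NumericVector n, NumericVector I, int nsub, double dt,
                      double Vr, double gna, double gk, double gl,
                      double ena, double ek, double el, double Cm) {
  const int nc = V.size();
  NumericVector Vo = clone(V), mo = clone(m), ho = clone(h), no = clone(n);
  IntegerVector spikes(nc);

  for (int c = 0; c < nc; ++c) {
    double v = Vo[c] - Vr, mm = mo[c], hh = ho[c], nn = no[c];
    const double Ic = I[c];
    int sp = 0;
    bool above = (Vo[c] >= 0.0);
    for (int s = 0; s < nsub; ++s) {
      double dv = (gna * mm * mm * mm * hh * (ena - v) +
                   gk * nn * nn * nn * nn * (ek - v) +
                   gl * (el - v) + Ic) / Cm;
      double r[6];
      hh_rates(v, r);
      double vm = v + dt * dv;
      double m2 = mm + dt * (r[2] * (1.0 - mm) - r[3] * mm);
      double h2 = hh + dt * (r[4] * (1.0 - hh) - r[5] * hh);
      double n2 = nn + dt * (r[0] * (1.0 - nn) - r[1] * nn);
      if (!std::isfinite(vm))
        stop("H-H integration overflow in unit %d: V=%g m=%g h=%g n=%g I=%g",
             c + 1, v + Vr, mm, hh, nn, Ic);
      if (m2 < 0) m2 = 0; else if (m2 > 1) m2 = 1;
      if (h2 < 0) h2 = 0; else if (h2 > 1) h2 = 1;
      if (n2 < 0) n2 = 0; else if (n2 > 1) n2 = 1;
      v = vm; mm = m2; hh = h2; nn = n2;
      bool now = (v + Vr >= 0.0);
      if (now && !above) ++sp;
      above = now;
    }
    Vo[c] = v + Vr; mo[c] = mm; ho[c] = hh; no[c] = nn;
    spikes[c] = sp;
  }
  return List::create(_["V"] = Vo, _["m"] = mo, _["h"] = ho, _["n"] = no,
                      _["spikes"] = spikes);
}
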