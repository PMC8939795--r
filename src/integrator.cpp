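#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled second-order neural mass
// equations with discrete synaptic delays.
//
// State per population i: voltage v_i and rate vd_i, advanced as
//   vd <- vd + dt * ((H/tau) * p - (2/tau) * vd - v / tau^2)
//            + (H/tau) * C * sigma * sqrt(dt) * xi
//   v  <- v + dt * vd_old
// with p the delayed sigmoid-coupled afferent drive plus any injected
// stimulation. Delays are expressed in integration steps (>= 1 wherever
// the weight is nonzero), so the drive only ever reads strictly past rows
// of the voltage buffer; the buffer is written in place, which lets the
// closed-loop driver integrate in chunks between controller updates while
// remaining bit-identical to a single uninterrupted call.
//
// vbuf rows store v at t = (row index + 1) * dt; history before t = 0 is
// zero. `v`/`vd` hold the state at t = from * dt and are updated in place.
//
// Returns 0 on success; on a guard violation returns 1 and fills
// `diag` = (population index (1-based), global step index (1-based)).
// [[Rcpp::export(name = ".integrate_chunk")]]
int integrate_chunk(NumericMatrix vbuf, NumericVector v, NumericVector vd,
                    int from, int nsteps,
                    const NumericMatrix& noise,
                    const NumericVector& stim, int stim_pop,
                    const IntegerMatrix& dsteps, const NumericMatrix& W,
                    const NumericVector& tau, const NumericVector& H,
                    const NumericVector& slope, const NumericVector& csd,
                    double dt, double guard, IntegerVector diag) {
  const int np = W.nrow();
  const double sqdt = std::sqrt(dt);

  // sparse connection list
  std::vector<int> ci, cj, cd;
  std::vector<double> cw;
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < np; ++j)
      if (W(i, j) != 0.0) {
        ci.push_back(i); cj.push_back(j); cd.push_back(dsteps(i, j));
        cw.push_back(W(i, j));
      }
  const int ncon = (int)ci.size();

  std::vector<double> a(np), b(np), c(np), ncoef(np), p(np);
  for (int i = 0; i < np; ++i) {
    a[i] = H[i] / tau[i];
    b[i] = 2.0 / tau[i];
    c[i] = 1.0 / (tau[i] * tau[i]);
    ncoef[i] = a[i] * csd[i] * sqdt;
  }

  for (int s = from; s < from + nsteps; ++s) {
    std::fill(p.begin(), p.end(), 0.0);
    for (int k = 0; k < ncon; ++k) {
      const int lag = s - cd[k];
      // row (lag - 1) holds v at t = lag * dt; zero history before t = 0
      const double vdel = (lag >= 1) ? vbuf(lag - 1, cj[k]) : 0.0;
      p[ci[k]] += cw[k] / (1.0 + std::exp(-slope[cj[k]] * vdel));
    }
    if (stim_pop >= 0) p[stim_pop] += stim[s];
    for (int i = 0; i < np; ++i) {
      const double vold = v[i];
      v[i] += dt * vd[i];
      vd[i] += dt * (a[i] * p[i] - b[i] * vd[i] - c[i] * vold)
             + ncoef[i] * noise(s, i);
      if (!(std::fabs(v[i]) <= guard)) {
        diag[0] = i + 1; diag[1] = s + 1;
        return 1;
      }
      vbuf(s, i) = v[i];
    }
  }
  return 0;
}
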