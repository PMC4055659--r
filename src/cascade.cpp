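// Fast simulation of the crosstalk-cascade ODE family.
//
// Two four-species transcription-factor cascades (state vector of length
// 2 * n_per_pathway, pathway 1 first) with Hill-activated production,
// linear degradation, optional crosstalk links (extra Hill inputs that
// combine multiplicatively), and rectangular stimulus pulses added to the
// production of the top species of each pathway.
//
// Integration is an adaptive Dormand-Prince 5(4) scheme; the time axis is
// split at stimulus switch points so that the discontinuous right-hand
// side never straddles a step.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct CascadeSys {
  arma::vec v, lambda, k;
  double nH;
  // links: each row (src_state, tgt_state), 0-based global indices
  arma::imat links;
  int n_per;          // species per pathway
  double s1, s2, delay, dur;

  inline double hill(double u, double kk) const {
    if (u <= 0.0) return 0.0;
    double un = std::pow(u / kk, nH);
    return un / (1.0 + un);
  }

  void rhs(double t, const arma::vec& y, arma::vec& dy) const {
    const int n = y.n_elem;
    for (int i = 0; i < n; ++i) {
      int pos = i % n_per;
      // production: constitutive for pathway tops, Hill-activated otherwise;
      // each crosstalk link adds a further Hill production term with the
      // target's kinetics
      double prod = (pos > 0) ? hill(y[i - 1], k[i]) : 1.0;
      for (unsigned int l = 0; l < links.n_rows; ++l) {
        if (links(l, 1) == i) prod += hill(y[links(l, 0)], k[i]);
      }
      double stim = 0.0;
      if (i == 0 && t >= 0.0 && t < dur) stim = s1;
      if (i == n_per && t >= delay && t < delay + dur) stim = s2;
      dy[i] = v[i] * prod - lambda[i] * y[i] + stim;
    }
  }
};

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// integrate sys from t0 to t1 in place; throws on failure
void dp45_span(const CascadeSys& sys, arma::vec& y, double t0, double t1,
               double rtol, double atol) {
  if (t1 <= t0) return;
  const int n = y.n_elem;
  arma::vec k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), ytmp(n), ynew(n),
      yerr(n);
  double t = t0;
  double h = (t1 - t0) / 10.0;
  sys.rhs(t, y, k1);
  int nsteps = 0;
  while (t < t1) {
    if (++nsteps > 1000000)
      stop("cascade integrator: step limit exceeded at t=%f", t);
    if (t + h > t1) h = t1 - t;
    ytmp = y + h * a21 * k1;
    sys.rhs(t + c2 * h, ytmp, k2);
    ytmp = y + h * (a31 * k1 + a32 * k2);
    sys.rhs(t + c3 * h, ytmp, k3);
    ytmp = y + h * (a41 * k1 + a42 * k2 + a43 * k3);
    sys.rhs(t + c4 * h, ytmp, k4);
    ytmp = y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
    sys.rhs(t + c5 * h, ytmp, k5);
    ytmp = y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
    sys.rhs(t + h, ytmp, k6);
    ynew = y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    sys.rhs(t + h, ynew, k7);
    yerr = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
      double e = yerr[i] / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm))
      stop("cascade integrator: non-finite state at t=%f", t);
    if (errnorm <= 1.0) {
      t += h;
      y = ynew;
      k1 = k7;  // FSAL
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12 * std::max(1.0, std::abs(t)))
      stop("cascade integrator: step size underflow at t=%f", t);
  }
}

}  // namespace

// [[Rcpp::export(name = ".cascade_integrate_cpp")]]
arma::mat cascade_integrate_cpp(const arma::vec& y0, const arma::vec& v,
                                const arma::vec& lambda, const arma::vec& k,
                                double nH, const arma::imat& links, double s1,
                                double s2, double delay, double dur,
                                double t_start, const arma::vec& times,
                                double rtol, double atol) {
  CascadeSys sys;
  sys.v = v;
  sys.lambda = lambda;
  sys.k = k;
  sys.nH = nH;
  sys.links = links;
  sys.n_per = y0.n_elem / 2;
  sys.s1 = s1;
  sys.s2 = s2;
  sys.delay = delay;
  sys.dur = dur;

  // breakpoints where the rhs is discontinuous in t
  std::vector<double> brk = {0.0, dur, delay, delay + dur};

  arma::mat out(times.n_elem, y0.n_elem);
  arma::vec y = y0;
  double t = t_start;
  for (unsigned int j = 0; j < times.n_elem; ++j) {
    double tj = times[j];
    if (tj < t) stop("cascade integrator: times must be nondecreasing");
    // split [t, tj] at interior breakpoints
    std::vector<double> cuts;
    for (double b : brk)
      if (b > t + 1e-12 && b < tj - 1e-12) cuts.push_back(b);
    std::sort(cuts.begin(), cuts.end());
    cuts.push_back(tj);
    for (double tc : cuts) {
      dp45_span(sys, y, t, tc, rtol, atol);
      t = tc;
    }
    out.row(j) = y.t();
  }
  return out;
}
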