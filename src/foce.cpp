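// Fast kernels for the FOCE-I engine: closed-form one-compartment
// infusion predictions and the per-subject conditional-mode objective.
// Only CL carries a random effect, so the inner problem is a 1-D
// minimization solved with Brent's method on a bracketed interval.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Subj {
  const double *dstart, *ddur, *drate;
  int nd;
  const double *t, *y, *tvcl, *tvv;
  int no;
  double om2, s2p, s2a;
};

// superposition of constant-rate infusion solutions over the dose history
inline double conc_at(double CL, double V, double tt, const Subj &S) {
  double ke = CL / V;
  double c = 0.0;
  double last_dur = -1.0, edur = 0.0; // infusion durations rarely vary
  for (int d = 0; d < S.nd; ++d) {
    double t0 = S.dstart[d];
    if (tt <= t0) continue;
    double dur = S.ddur[d];
    double te = t0 + dur;
    double a = S.drate[d] / CL;
    if (tt <= te) {
      c += a * (1.0 - std::exp(-ke * (tt - t0)));
    } else {
      if (dur != last_dur) {
        edur = std::exp(-ke * dur);
        last_dur = dur;
      }
      c += a * (1.0 - edur) * std::exp(-ke * (tt - te));
    }
  }
  return c;
}

inline void preds_at(double eta, const Subj &S, double *f) {
  double e = std::exp(eta);
  for (int j = 0; j < S.no; ++j)
    f[j] = conc_at(S.tvcl[j] * e, S.tvv[j], S.t[j], S);
}

// penalized conditional objective: extended least squares + prior on eta,
// with the residual variance evaluated at the conditional prediction
double inner_obj(double eta, void *info) {
  const Subj *S = static_cast<const Subj *>(info);
  double g = S->om2 > 0 ? eta * eta / S->om2 : 0.0;
  double e = std::exp(eta);
  for (int j = 0; j < S->no; ++j) {
    double f = conc_at(S->tvcl[j] * e, S->tvv[j], S->t[j], *S);
    double v = S->s2p * f * f + S->s2a;
    if (v < 1e-12) v = 1e-12;
    double r = S->y[j] - f;
    g += r * r / v + std::log(v);
  }
  return g;
}

// Brent's derivative-free minimizer on [ax, bx] (golden-section with
// parabolic interpolation), the classical localmin algorithm
double brent_fmin(double ax, double bx, double (*f)(double, void *),
                  void *info, double tol) {
  const double c = (3.0 - std::sqrt(5.0)) * 0.5;
  const double eps = std::sqrt(2.220446049250313e-16);
  double a = ax, b = bx;
  double v = a + c * (b - a), w = v, x = v;
  double d = 0.0, e = 0.0;
  double fx = f(x, info), fv = fx, fw = fx;
  for (int iter = 0; iter < 200; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        use_golden = false;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm > x) ? tol1 : -tol1;
      }
    }
    if (use_golden) {
      e = (x < xm) ? b - x : a - x;
      d = c * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d
                                      : x + ((d > 0.0) ? tol1 : -tol1);
    double fu = f(u, info);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw;
      w = x; fw = fx;
      x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw;
        w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

} // namespace

// [[Rcpp::export]]
List foce_engine_cpp(IntegerVector obs_off, NumericVector obs_time,
                     NumericVector dv, NumericVector tvcl, NumericVector tvv,
                     IntegerVector dose_off, NumericVector dose_start,
                     NumericVector dose_dur, NumericVector dose_rate,
                     double omega2, double s2prop, double s2add,
                     bool diagnostics = false,
                     Rcpp::Nullable<NumericVector> eta_init = R_NilValue) {
  const int nsub = obs_off.size() - 1;
  const int nobs = obs_time.size();
  const double *p_t = REAL(obs_time), *p_y = REAL(dv);
  const double *p_cl = REAL(tvcl), *p_v = REAL(tvv);
  const double *p_ds = REAL(dose_start), *p_dd = REAL(dose_dur),
               *p_dr = REAL(dose_rate);

  NumericVector contrib(nsub), eta(nsub);
  LogicalVector at_bound(nsub);
  NumericVector ipred, pred, gvec, vvec, rvec;
  if (diagnostics) {
    ipred = NumericVector(nobs);
    pred = NumericVector(nobs);
    gvec = NumericVector(nobs);
    vvec = NumericVector(nobs);
    rvec = NumericVector(nobs);
  }

  double ofv = 0.0;
  std::vector<double> f0, fp, fm;
  for (int i = 0; i < nsub; ++i) {
    Subj S;
    const int o0 = obs_off[i], o1 = obs_off[i + 1];
    const int d0 = dose_off[i], d1 = dose_off[i + 1];
    S.t = p_t + o0;
    S.y = p_y + o0;
    S.tvcl = p_cl + o0;
    S.tvv = p_v + o0;
    S.no = o1 - o0;
    S.dstart = p_ds + d0;
    S.ddur = p_dd + d0;
    S.drate = p_dr + d0;
    S.nd = d1 - d0;
    S.om2 = omega2;
    S.s2p = s2prop;
    S.s2a = s2add;

    double ehat = 0.0;
    if (omega2 > 0) {
      double w = std::sqrt(omega2);
      double lo = -6.0 * w, hi = 6.0 * w;
      bool solved = false;
      if (eta_init.isNotNull()) {
        NumericVector e0v(eta_init);
        if (e0v.size() == nsub) {
          // warm start: the conditional mode moves little between outer
          // optimizer steps, so search a narrow window first and fall
          // back to the full bracket when the solution hugs its edge
          double e0 = e0v[i];
          double lo2 = std::max(lo, e0 - 0.4), hi2 = std::min(hi, e0 + 0.4);
          if (hi2 > lo2) {
            ehat = brent_fmin(lo2, hi2, inner_obj, &S, 1e-6);
            solved = (ehat > lo2 + 1e-4 && ehat < hi2 - 1e-4);
          }
        }
      }
      if (!solved) ehat = brent_fmin(lo, hi, inner_obj, &S, 1e-6);
      if (ehat < lo + 1e-3 * w || ehat > hi - 1e-3 * w) at_bound[i] = true;
    }

    const int n = S.no;
    f0.assign(n, 0.0);
    fp.assign(n, 0.0);
    fm.assign(n, 0.0);
    preds_at(ehat, S, f0.data());
    const double h = 1e-4;
    preds_at(ehat + h, S, fp.data());
    preds_at(ehat - h, S, fm.data());

    // FOCE-I Laplace-type contribution via the rank-one Woodbury identity:
    // C = diag(v) + omega2 * G G', r = y - f(ehat) + G * ehat
    double A = 0.0, B = 0.0, logdet = 0.0, quad0 = 0.0;
    for (int j = 0; j < n; ++j) {
      double G = (fp[j] - fm[j]) / (2.0 * h);
      double v = s2prop * f0[j] * f0[j] + s2add;
      if (v < 1e-12) v = 1e-12;
      double r = p_y[o0 + j] - f0[j] + G * ehat;
      A += G * G / v;
      B += G * r / v;
      logdet += std::log(v);
      quad0 += r * r / v;
      if (diagnostics) {
        ipred[o0 + j] = f0[j];
        gvec[o0 + j] = G;
        vvec[o0 + j] = v;
        rvec[o0 + j] = r;
      }
    }
    double ci;
    if (omega2 > 0) {
      double denom = 1.0 + omega2 * A;
      ci = logdet + std::log(denom) + quad0 - omega2 * B * B / denom;
    } else {
      ci = logdet + quad0;
    }
    contrib[i] = ci;
    eta[i] = ehat;
    ofv += ci;
    if (diagnostics) {
      preds_at(0.0, S, f0.data());
      for (int j = 0; j < n; ++j) pred[o0 + j] = f0[j];
    }
  }

  if (diagnostics)
    return List::create(_["ofv"] = ofv, _["contrib"] = contrib, _["eta"] = eta,
                        _["at_bound"] = at_bound, _["ipred"] = ipred,
                        _["pred"] = pred, _["G"] = gvec, _["v"] = vvec,
                        _["r"] = rvec);
  return List::create(_["ofv"] = ofv, _["contrib"] = contrib, _["eta"] = eta,
                      _["at_bound"] = at_bound);
}

// concentration profiles for a grid of (CL, V) pairs sharing one dose
// history; used by the Monte Carlo simulation layers
// [[Rcpp::export]]
NumericMatrix conc_profile_cpp(NumericVector CL, NumericVector V,
                               NumericVector times, NumericVector dose_start,
                               NumericVector dose_dur,
                               NumericVector dose_rate) {
  const int np = CL.size(), nt = times.size();
  Subj S;
  S.dstart = REAL(dose_start);
  S.ddur = REAL(dose_dur);
  S.drate = REAL(dose_rate);
  S.nd = dose_start.size();
  NumericMatrix out(nt, np);
  for (int k = 0; k < np; ++k)
    for (int j = 0; j < nt; ++j)
      out(j, k) = conc_at(CL[k], V[k], times[j], S);
  return out;
}
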