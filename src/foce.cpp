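// FOCE-with-interaction marginal -2 log-likelihood for the pediatric
// prucalopride model: log-normal observation model (additive error on log
// concentrations), exponential inter-individual variability on CL, V2, V3.
//
// Per subject the conditional mode eta-hat is found by Levenberg-damped
// Gauss-Newton on the penalised least-squares problem, then the marginal
// likelihood is approximated by linearising the log-prediction around
// eta-hat:  y ~ N(f(eta^) - G eta^, G Omega G' + sigma^2 I).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Disp {
  double k10, k12, k21, l1, l2;
};

Disp make_disp(double cl, double v2, double q, double v3) {
  Disp d;
  d.k10 = cl / v2;
  d.k12 = q / v2;
  d.k21 = q / v3;
  double s = d.k10 + d.k12 + d.k21;
  double disc = s * s - 4.0 * d.k10 * d.k21;
  if (disc < 1e-14 * s * s) disc = 1e-14 * s * s;
  double r = std::sqrt(disc);
  d.l1 = 0.5 * (s + r);
  d.l2 = 0.5 * (s - r);
  return d;
}

double guard_ka(double ka, const Disp& d) {
  double eps = 1e-8;
  if (std::fabs(ka - d.l1) < eps * d.l1) ka = d.l1 * (1.0 + 1e-7);
  if (std::fabs(ka - d.l2) < eps * d.l2) ka = d.l2 * (1.0 + 1e-7);
  return ka;
}

struct State { double ad, a2, a3; };

State propagate(const State& s0, double tau, double ka_in, const Disp& d) {
  double ka = guard_ka(ka_in, d);
  double l1 = d.l1, l2 = d.l2, k21 = d.k21;
  double e1 = std::exp(-l1 * tau), e2 = std::exp(-l2 * tau),
         ek = std::exp(-ka * tau);
  double B1 = ((k21 - l1) * s0.a2 + k21 * s0.a3) / (l2 - l1);
  double B2 = ((k21 - l2) * s0.a2 + k21 * s0.a3) / (l1 - l2);
  double kad = ka * s0.ad;
  double Dk = kad * (k21 - ka) / ((l1 - ka) * (l2 - ka));
  double D1 = kad * (k21 - l1) / ((ka - l1) * (l2 - l1));
  double D2 = kad * (k21 - l2) / ((ka - l2) * (l1 - l2));
  double ksum = d.k10 + d.k12;
  double C1 = ((ksum - l1) * s0.a3 + d.k12 * s0.a2) / (l2 - l1);
  double C2 = ((ksum - l2) * s0.a3 + d.k12 * s0.a2) / (l1 - l2);
  double kk = d.k12 * kad;
  double Ek = kk / ((l1 - ka) * (l2 - ka));
  double E1 = kk / ((ka - l1) * (l2 - l1));
  double E2 = kk / ((ka - l2) * (l1 - l2));
  State s;
  s.ad = s0.ad * ek;
  s.a2 = (B1 + D1) * e1 + (B2 + D2) * e2 + Dk * ek;
  s.a3 = (C1 + E1) * e1 + (C2 + E2) * e2 + Ek * ek;
  return s;
}

double dose_central(double famt, double tau, double ka1, double ka2,
                    double mtime, const Disp& d) {
  if (tau <= 0.0) return 0.0;
  State s0{famt, 0.0, 0.0};
  if (mtime <= 0.0) return propagate(s0, tau, ka2, d).a2;
  if (tau <= mtime) return propagate(s0, tau, ka1, d).a2;
  State sm = propagate(s0, mtime, ka1, d);
  return propagate(sm, tau - mtime, ka2, d).a2;
}

struct Subj {
  arma::vec y;          // log observed concentrations
  arma::vec obs_t;
  arma::vec dose_t;
  arma::vec dose_a;
  double wt_cl, wt_q, wt_v; // covariate multipliers
  int study;                // 0-based study index
};

struct Theta {
  arma::vec cl_tv;   // per study
  double v2_tv, q_tv, v3_tv, ka1, ka2, mtime, f1;
  arma::vec om_cl;   // per study
  double om_v2, om_v3;
  arma::vec sig;     // per study
};

// log-predicted concentrations for one subject at eta = (eta_cl, eta_v2, eta_v3)
arma::vec log_pred(const Subj& s, const Theta& th, const arma::vec& eta) {
  double cl = th.cl_tv[s.study] * s.wt_cl * std::exp(eta[0]);
  double v2 = th.v2_tv * s.wt_v * std::exp(eta[1]);
  double v3 = th.v3_tv * s.wt_v * std::exp(eta[2]);
  double q = th.q_tv * s.wt_q;
  Disp d = make_disp(cl, v2, q, v3);
  int n = s.obs_t.n_elem, nd = s.dose_t.n_elem;
  arma::vec out(n);
  for (int i = 0; i < n; ++i) {
    double a2 = 0.0;
    for (int j = 0; j < nd; ++j) {
      double tau = s.obs_t[i] - s.dose_t[j];
      if (tau <= 0.0 || s.dose_a[j] <= 0.0) continue;
      a2 += dose_central(th.f1 * s.dose_a[j], tau, th.ka1, th.ka2, th.mtime, d);
    }
    out[i] = std::log(std::max(a2 / v2, 1e-300));
  }
  return out;
}

// penalised objective (no constants): sum((y-f)^2)/sig^2 + sum(eta^2/om^2)
double inner_obj(const Subj& s, const Theta& th, const arma::vec& eta,
                 const arma::vec& om2, const arma::uvec& act, double sig2) {
  arma::vec f = log_pred(s, th, eta);
  double v = arma::accu(arma::square(s.y - f)) / sig2;
  for (arma::uword k = 0; k < act.n_elem; ++k)
    v += eta[act[k]] * eta[act[k]] / om2[act[k]];
  return v;
}

// central-difference Jacobian of log_pred wrt active etas
arma::mat jac(const Subj& s, const Theta& th, const arma::vec& eta,
              const arma::uvec& act) {
  double h = 1e-4;
  arma::mat J(s.y.n_elem, act.n_elem);
  for (arma::uword k = 0; k < act.n_elem; ++k) {
    arma::vec ep = eta, em = eta;
    ep[act[k]] += h; em[act[k]] -= h;
    J.col(k) = (log_pred(s, th, ep) - log_pred(s, th, em)) / (2.0 * h);
  }
  return J;
}

// conditional mode by Levenberg-damped Gauss-Newton; eta starts at 0
arma::vec map_eta(const Subj& s, const Theta& th, const arma::vec& om2,
                  const arma::uvec& act, double sig2) {
  arma::vec eta(3, arma::fill::zeros);
  if (act.n_elem == 0 || s.y.n_elem == 0) return eta;
  double mu = 1e-4;
  double g0 = inner_obj(s, th, eta, om2, act, sig2);
  for (int it = 0; it < 50; ++it) {
    arma::vec f = log_pred(s, th, eta);
    arma::mat J = jac(s, th, eta, act);
    arma::vec r = s.y - f;
    arma::vec grad(act.n_elem);
    arma::mat H(act.n_elem, act.n_elem);
    for (arma::uword k = 0; k < act.n_elem; ++k) {
      grad[k] = -2.0 * arma::dot(J.col(k), r) / sig2 +
                2.0 * eta[act[k]] / om2[act[k]];
    }
    H = 2.0 * (J.t() * J) / sig2;
    for (arma::uword k = 0; k < act.n_elem; ++k)
      H(k, k) += 2.0 / om2[act[k]];
    if (arma::norm(grad, "inf") < 1e-6) break;
    bool stepped = false;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Hd = H;
      Hd.diag() += mu;
      arma::vec delta;
      bool ok = arma::solve(delta, Hd, -grad, arma::solve_opts::no_approx);
      if (ok) {
        arma::vec etn = eta;
        for (arma::uword k = 0; k < act.n_elem; ++k) etn[act[k]] += delta[k];
        double g1 = inner_obj(s, th, etn, om2, act, sig2);
        if (std::isfinite(g1) && g1 <= g0 + 1e-12) {
          eta = etn; g0 = g1; mu = std::max(mu / 3.0, 1e-10);
          stepped = true;
          break;
        }
      }
      mu *= 10.0;
    }
    if (!stepped) break;
  }
  return eta;
}

Theta unpack_theta(const List& th) {
  Theta t;
  t.cl_tv = as<arma::vec>(th["cl_tv"]);
  t.v2_tv = th["v2_tv"]; t.q_tv = th["q_tv"]; t.v3_tv = th["v3_tv"];
  t.ka1 = th["ka1"]; t.ka2 = th["ka2"];
  t.mtime = th["mtime"]; t.f1 = th["f1"];
  t.om_cl = as<arma::vec>(th["om_cl"]);
  t.om_v2 = th["om_v2"]; t.om_v3 = th["om_v3"];
  t.sig = as<arma::vec>(th["sig"]);
  return t;
}

Subj unpack_subj(const List& sl) {
  Subj s;
  s.y = as<arma::vec>(sl["y"]);
  s.obs_t = as<arma::vec>(sl["obs_times"]);
  s.dose_t = as<arma::vec>(sl["dose_times"]);
  s.dose_a = as<arma::vec>(sl["dose_amts"]);
  s.wt_cl = sl["wt_cl"]; s.wt_q = sl["wt_q"]; s.wt_v = sl["wt_v"];
  s.study = sl["study"];
  return s;
}

} // namespace

// [[Rcpp::export(name = ".foce_eval_cpp")]]
List foce_eval_cpp(List subjects, List theta, bool details = false) {
  Theta th = unpack_theta(theta);
  int ns = subjects.size();
  double ofv = 0.0;
  bool valid = true;
  List det(details ? ns : 0);
  const double log2pi = std::log(2.0 * M_PI);

  for (int i = 0; i < ns; ++i) {
    Subj s = unpack_subj(subjects[i]);
    double om_cl = th.om_cl[s.study];
    double sig = th.sig[s.study];
    double sig2 = sig * sig;
    arma::vec om(3);
    om[0] = om_cl; om[1] = th.om_v2; om[2] = th.om_v3;
    arma::vec om2 = arma::square(om);
    arma::uvec act = arma::find(om > 1e-8);
    int n = s.y.n_elem;

    if (n == 0) {
      if (details) {
        det[i] = List::create(_["eta"] = NumericVector(3),
                              _["ipred_log"] = NumericVector(0),
                              _["pred_log"] = NumericVector(0),
                              _["G"] = NumericMatrix(0, 3),
                              _["ofv_i"] = 0.0);
      }
      continue;
    }

    arma::vec eta = map_eta(s, th, om2, act, sig2);
    arma::vec f = log_pred(s, th, eta);
    arma::mat Ga(n, act.n_elem);
    if (act.n_elem > 0) Ga = jac(s, th, eta, act);

    // C = G Omega G' + sig^2 I ; res = y - f(eta^) + G eta^
    arma::mat C(n, n, arma::fill::zeros);
    arma::vec res = s.y - f;
    if (act.n_elem > 0) {
      arma::vec eta_act(act.n_elem);
      for (arma::uword k = 0; k < act.n_elem; ++k) eta_act[k] = eta[act[k]];
      arma::mat Om = arma::diagmat(om2.elem(act));
      C = Ga * Om * Ga.t();
      res += Ga * eta_act;
    }
    C.diag() += sig2;

    double ofv_i;
    arma::mat L;
    if (arma::chol(L, C, "lower")) {
      arma::vec z = arma::solve(arma::trimatl(L), res);
      double logdet = 2.0 * arma::accu(arma::log(L.diag()));
      ofv_i = logdet + arma::dot(z, z) + n * log2pi;
    } else {
      ofv_i = 1e10;
      valid = false;
    }
    ofv += ofv_i;

    if (details) {
      arma::vec f0 = log_pred(s, th, arma::vec(3, arma::fill::zeros));
      arma::mat Gfull(n, 3, arma::fill::zeros);
      for (arma::uword k = 0; k < act.n_elem; ++k)
        Gfull.col(act[k]) = Ga.col(k);
      det[i] = List::create(_["eta"] = NumericVector(eta.begin(), eta.end()),
                            _["ipred_log"] = NumericVector(f.begin(), f.end()),
                            _["pred_log"] = NumericVector(f0.begin(), f0.end()),
                            _["G"] = wrap(Gfull),
                            _["ofv_i"] = ofv_i);
    }
  }

  if (details)
    return List::create(_["ofv"] = ofv, _["valid"] = valid,
                        _["subjects"] = det);
  return List::create(_["ofv"] = ofv, _["valid"] = valid);
}
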