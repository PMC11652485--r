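// Closed-form kinetics of the 5-state linear system (two absorption depots,
// central + two peripheral compartments) and a Laplace marginal -2LL for the
// population model. The disposition matrix of a mamillary system is similar
// to a symmetric matrix under the diag(1/sqrt(V)) transform, so its
// eigenvalues are real and the bolus response from/into the central
// compartment is sum_j c_j exp(lambda_j t) with c_j = Q(0,j)^2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659;

struct Pars {
  // volumes L/kg, clearances L/kg/h, rate constants 1/h, lag h,
  // bioavailabilities as fractions
  double V1, V2, V3, Cl, Cld2, Cld3, Ka1, Ka2, Tlag, Ftot, Frapid;
};

struct Disp {
  arma::vec3 lam;
  arma::vec3 c; // central->central bolus weights, sum to 1
  bool ok;
};

static bool pars_ok(const Pars &p) {
  double v[] = {p.V1, p.V2, p.V3, p.Cl, p.Cld2, p.Cld3, p.Ka1, p.Ka2};
  for (double x : v)
    if (!std::isfinite(x) || x <= 0.0 || x > 1e12) return false;
  return std::isfinite(p.Tlag) && p.Tlag >= 0.0 && p.Tlag < 1e6 &&
         std::isfinite(p.Ftot) && std::isfinite(p.Frapid);
}

static Disp disposition(const Pars &p) {
  Disp d;
  d.ok = pars_ok(p);
  if (!d.ok) return d;
  double k10 = p.Cl / p.V1, k21 = p.Cld2 / p.V2, k31 = p.Cld3 / p.V3;
  double k12 = p.Cld2 / p.V1, k13 = p.Cld3 / p.V1;
  arma::mat33 B;
  B.zeros();
  B(0, 0) = -(k10 + k12 + k13);
  B(1, 1) = -k21;
  B(2, 2) = -k31;
  double b12 = p.Cld2 / std::sqrt(p.V1 * p.V2);
  double b13 = p.Cld3 / std::sqrt(p.V1 * p.V3);
  B(0, 1) = B(1, 0) = b12;
  B(0, 2) = B(2, 0) = b13;
  // closed-form symmetric 3x3 eigendecomposition (Smith's trigonometric
  // method); falls back to LAPACK near-degenerate
  double p1 = b12 * b12 + b13 * b13; // B(1,2) is 0 by construction
  double q = arma::trace(B) / 3.0;
  double a11 = B(0, 0) - q, a22 = B(1, 1) - q, a33 = B(2, 2) - q;
  double p2 = a11 * a11 + a22 * a22 + a33 * a33 + 2.0 * p1;
  double pp = std::sqrt(p2 / 6.0);
  bool done = false;
  if (pp > 1e-14) {
    arma::mat33 Bq = B;
    Bq(0, 0) = a11; Bq(1, 1) = a22; Bq(2, 2) = a33;
    double detv = arma::det(Bq) / (pp * pp * pp) / 2.0;
    if (detv > 1.0) detv = 1.0;
    if (detv < -1.0) detv = -1.0;
    double phi = std::acos(detv) / 3.0;
    double l1 = q + 2.0 * pp * std::cos(phi);
    double l3 = q + 2.0 * pp * std::cos(phi + 2.0 * M_PI / 3.0);
    double l2 = 3.0 * q - l1 - l3;
    d.lam[0] = l3; d.lam[1] = l2; d.lam[2] = l1;
    // separated eigenvalues: weights from the characteristic projectors,
    // c_j = prod_{k!=j} (B - lam_k I)(0,0) / prod_{k!=j} (lam_j - lam_k)
    double sep = std::min(std::fabs(l1 - l2), std::fabs(l2 - l3));
    if (sep > 1e-9 * std::fabs(l3)) {
      double m00 = B(0, 0), m01 = B(0, 1), m02 = B(0, 2);
      for (int j = 0; j < 3; ++j) {
        double lj = d.lam[j];
        double la = d.lam[(j + 1) % 3], lb = d.lam[(j + 2) % 3];
        // ((B - la I)(B - lb I))(0,0)
        double num = (m00 - la) * (m00 - lb) + m01 * m01 + m02 * m02;
        d.c[j] = num / ((lj - la) * (lj - lb));
      }
      done = true;
    }
  }
  if (!done) {
    arma::vec lam;
    arma::mat Q;
    if (!arma::eig_sym(lam, Q, arma::mat(B))) {
      d.ok = false;
      return d;
    }
    for (int j = 0; j < 3; ++j) {
      d.lam[j] = lam[j];
      d.c[j] = Q(0, j) * Q(0, j);
    }
  }
  return d;
}

// central amount at time-since-event tau for a unit bolus into central
static inline double resp_bolus(const Disp &d, double tau) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j) s += d.c[j] * std::exp(d.lam[j] * tau);
  return s;
}

// central amount from depot amount X0 draining at first-order rate ka,
// input started tau hours ago
static inline double resp_depot(const Disp &d, double ka, double tau) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j) {
    double den = d.lam[j] + ka;
    if (std::fabs(den) < 1e-10) {
      s += d.c[j] * tau * std::exp(d.lam[j] * tau);
    } else {
      s += d.c[j] * (std::exp(d.lam[j] * tau) - std::exp(-ka * tau)) / den;
    }
  }
  return ka * s;
}

// central amount from a constant-rate (unit rate) input switched on tau ago
static inline double resp_ramp(const Disp &d, double tau) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j)
    s += d.c[j] * (1.0 - std::exp(d.lam[j] * tau)) / (-d.lam[j]);
  return s;
}

// doses: columns time, amount (mg/kg), route (1 iv bolus, 2 iv infusion,
// 3 im dual-absorption), duration (h, infusions)
static bool conc_at(const Pars &p, const Disp &d, const arma::mat &doses,
                    const arma::vec &times, arma::vec &out) {
  int n = times.n_elem, nd = doses.n_rows;
  // Frapid is the fraction of the total bioavailability absorbed through
  // the rapid route; the remainder enters the slow depot after the lag
  double f_fast = p.Ftot * p.Frapid;
  double f_slow = p.Ftot * (1.0 - p.Frapid);
  for (int i = 0; i < n; ++i) {
    double t = times[i], amt = 0.0;
    for (int k = 0; k < nd; ++k) {
      double t0 = doses(k, 0), a = doses(k, 1);
      int route = (int)doses(k, 2);
      if (route == 1) {
        if (t >= t0) amt += a * resp_bolus(d, t - t0);
      } else if (route == 2) {
        double dur = doses(k, 3), r = a / dur;
        if (t >= t0) amt += r * resp_ramp(d, t - t0);
        if (t >= t0 + dur) amt -= r * resp_ramp(d, t - t0 - dur);
      } else { // im: rapid depot at t0, slow depot at t0 + Tlag
        if (t >= t0) amt += f_fast * a * resp_depot(d, p.Ka1, t - t0);
        double ts = t0 + p.Tlag;
        if (t >= ts) amt += f_slow * a * resp_depot(d, p.Ka2, t - ts);
      }
    }
    double c = amt / p.V1;
    if (!std::isfinite(c)) return false;
    out[i] = c;
  }
  return true;
}

static Pars pars_from_vec(const arma::vec &v) {
  Pars p;
  p.V1 = v[0]; p.V2 = v[1]; p.V3 = v[2];
  p.Cl = v[3]; p.Cld2 = v[4]; p.Cld3 = v[5];
  p.Ka1 = v[6]; p.Ka2 = v[7]; p.Tlag = v[8];
  p.Ftot = v[9]; p.Frapid = v[10];
  return p;
}

//' @title Closed-form concentration profile (internal)
//' @description Central-compartment concentration (mg/L) of the dual
//'   absorption three-compartment system for one individual, by
//'   superposition of analytic dose responses.
//' @param pars numeric(11): V1,V2,V3 (L/kg), Cl,Cld2,Cld3 (L/kg/h),
//'   Ka1,Ka2 (1/h), Tlag (h), F_total, F_rapid (fractions)
//' @param doses matrix with columns time, amount, route, duration
//' @param times observation times (h)
//' @keywords internal
// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector pars, NumericMatrix doses,
                       NumericVector times) {
  Pars p = pars_from_vec(as<arma::vec>(pars));
  Disp d = disposition(p);
  if (!d.ok) stop("disposition eigendecomposition failed");
  arma::vec t = as<arma::vec>(times), out(t.n_elem);
  if (!conc_at(p, d, as<arma::mat>(doses), t, out))
    stop("non-finite concentration");
  return NumericVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// Laplace marginal likelihood
//
// theta order: tvV1,tvV2,tvV3 (mL/kg), tvCl,tvCld2,tvCld3 (mL/kg/h),
//              tvKa1,tvKa2 (1/h), tvTlag (h), tvF1, tvFrapid (logit)
// dvec order:  d_V1,d_V2,d_V3,d_Cl,d_Cld2,d_Cld3 (calf exponents)
// eta order (full, 11): nKa1,nKa2,nF1,nTlag,nFrapid,nV1,nV2,nV3,nCl,nCl2,nCl3
// ---------------------------------------------------------------------------

static inline double ilogit_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static Pars individual_pars(const arma::vec &theta, const arma::vec &dvec,
                            int age, const arma::vec &eta11) {
  Pars p;
  double a = (age == 1) ? 1.0 : 0.0;
  p.V1 = theta[0] / 1000.0 * std::exp(a * dvec[0] + eta11[5]);
  p.V2 = theta[1] / 1000.0 * std::exp(a * dvec[1] + eta11[6]);
  p.V3 = theta[2] / 1000.0 * std::exp(a * dvec[2] + eta11[7]);
  p.Cl = theta[3] / 1000.0 * std::exp(a * dvec[3] + eta11[8]);
  p.Cld2 = theta[4] / 1000.0 * std::exp(a * dvec[4] + eta11[9]);
  p.Cld3 = theta[5] / 1000.0 * std::exp(a * dvec[5] + eta11[10]);
  p.Ka1 = theta[6] * std::exp(eta11[0]);
  p.Ka2 = theta[7] * std::exp(eta11[1]);
  p.Tlag = theta[8] * std::exp(eta11[3]);
  p.Ftot = ilogit_(theta[9] + eta11[2]);
  p.Frapid = ilogit_(theta[10] + eta11[4]);
  return p;
}

struct Subject {
  arma::vec times, dv;
  arma::mat doses;
  int age;
};

// negative log joint density (eta prior + residual likelihood), the
// quantity whose Laplace approximation integrates out the etas
static double g_joint(const arma::vec &etaA, const Subject &s,
                      const arma::vec &theta, const arma::vec &dvec,
                      const arma::ivec &active, const arma::mat &Oinv,
                      double ldetO, double cv, double addsd) {
  int m = etaA.n_elem;
  arma::vec eta11(11, arma::fill::zeros);
  for (int j = 0; j < m; ++j) eta11[active[j]] = etaA[j];
  Pars p = individual_pars(theta, dvec, s.age, eta11);
  Disp d = disposition(p);
  if (!d.ok) return 1e10;
  arma::vec f(s.times.n_elem);
  if (!conc_at(p, d, s.doses, s.times, f)) return 1e10;
  double ll = 0.0;
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    double fj = f[j] > 0.0 ? f[j] : 0.0;
    double v = addsd * addsd + cv * cv * fj * fj;
    if (v < 1e-12) v = 1e-12;
    double r = s.dv[j] - f[j];
    ll += 0.5 * (LOG2PI + std::log(v) + r * r / v);
  }
  double prior = 0.5 * arma::as_scalar(etaA.t() * Oinv * etaA) +
                 0.5 * (m * LOG2PI + ldetO);
  double g = ll + prior;
  return std::isfinite(g) ? g : 1e10;
}

// Laplace -2 log marginal likelihood for one subject; eta is warm start on
// entry and the empirical Bayes mode on exit. The inner optimization is
// Gauss-Newton with the Fisher (expected) information of the combined
// error model, which is also the curvature used in the Laplace/FOCE-class
// correction; it is positive definite by construction.
static double laplace_subject(const Subject &s, const arma::vec &theta,
                              const arma::vec &dvec, const arma::ivec &active,
                              const arma::mat &Oinv, double ldetO, double cv,
                              double addsd, arma::vec &eta, bool &flagged) {
  int m = eta.n_elem;
  int nobs = s.times.n_elem;
  const double h = 1e-4;
  flagged = false;
  double c2 = cv * cv, a2 = addsd * addsd;
  auto predict = [&](const arma::vec &e, arma::vec &f) -> bool {
    arma::vec eta11(11, arma::fill::zeros);
    for (int j = 0; j < m; ++j) eta11[active[j]] = e[j];
    Pars p = individual_pars(theta, dvec, s.age, eta11);
    Disp d = disposition(p);
    if (!d.ok) return false;
    return conc_at(p, d, s.doses, s.times, f);
  };
  auto gval = [&](const arma::vec &e) -> double {
    arma::vec f(nobs);
    if (!predict(e, f)) return 1e10;
    double ll = 0.0;
    for (int j = 0; j < nobs; ++j) {
      double fj = f[j] > 0.0 ? f[j] : 0.0;
      double v = a2 + c2 * fj * fj;
      if (v < 1e-12) v = 1e-12;
      double r = s.dv[j] - f[j];
      ll += 0.5 * (LOG2PI + std::log(v) + r * r / v);
    }
    double g = ll + 0.5 * arma::as_scalar(e.t() * Oinv * e) +
               0.5 * (m * LOG2PI + ldetO);
    return std::isfinite(g) ? g : 1e10;
  };

  arma::vec f(nobs), fp(nobs), fm(nobs);
  arma::mat H(m, m);
  // one Levenberg-Marquardt descent from a given start; returns g at the
  // mode and leaves H at the Fisher Hessian of the final iterate
  auto descend = [&](arma::vec &e) -> double {
    double g0 = gval(e);
    if (g0 >= 1e10) { e.zeros(); g0 = gval(e); }
    for (int iter = 0; iter < 60; ++iter) {
      if (!predict(e, f)) { flagged = true; break; }
      arma::mat J(nobs, m);
      bool ok = true;
      for (int j = 0; j < m && ok; ++j) {
        arma::vec ep = e;
        ep[j] += h;
        ok = predict(ep, fp);
        if (ok) J.col(j) = (fp - f) / h;
      }
      if (!ok) { flagged = true; break; }
      arma::vec grad = Oinv * e;
      H = Oinv;
      for (int j = 0; j < nobs; ++j) {
        double fj = f[j] > 0.0 ? f[j] : 0.0;
        double v = a2 + c2 * fj * fj;
        if (v < 1e-12) v = 1e-12;
        double r = s.dv[j] - f[j];
        // d/df of 0.5*log v + r^2/(2v): variance and residual terms
        double coeff = c2 * fj / v - r / v - r * r * c2 * fj / (v * v);
        double q = 1.0 / v + 2.0 * c2 * c2 * fj * fj / (v * v);
        grad += coeff * J.row(j).t();
        H += q * (J.row(j).t() * J.row(j));
      }
      // ridge the Fisher Hessian until the step decreases g; the
      // predicted decrease of the quadratic model is the scale-invariant
      // convergence measure
      bool improved = false, converged = false;
      double lam = 0.0;
      for (int tries = 0; tries < 25 && !improved; ++tries) {
        arma::vec step;
        arma::mat Hl = H + lam * arma::eye(m, m);
        if (!arma::solve(step, Hl, -grad, arma::solve_opts::likely_sympd)) {
          lam = (lam == 0.0) ? 1e-6 : lam * 10.0;
          continue;
        }
        double pred_dec = -0.5 * arma::dot(grad, step);
        if (pred_dec < 1e-10) { converged = true; break; }
        double gnew = gval(e + step);
        if (gnew < g0 - 1e-13) {
          e += step;
          g0 = gnew;
          improved = true;
        } else {
          lam = (lam == 0.0) ? std::max(1e-3 * arma::trace(H) / m, 1e-8)
                             : lam * 10.0;
        }
      }
      if (converged || !improved) break;
    }
    return g0;
  };
  // With an eta on either bioavailability the conditional density can be
  // bimodal (the slow-absorption fraction clips at zero), so descend from
  // the warm start and from zero and keep the better mode; otherwise a
  // single descent suffices.
  bool f_eta = false;
  for (int j = 0; j < m; ++j)
    if (active[j] == 2 || active[j] == 4) f_eta = true;
  arma::vec e1 = eta;
  double g1 = descend(e1);
  double g0;
  if (f_eta && arma::norm(eta, "inf") > 1e-12) {
    arma::vec e2(m, arma::fill::zeros);
    arma::mat H1 = H;
    double g2 = descend(e2);
    if (g1 <= g2) { eta = e1; g0 = g1; H = H1; }
    else { eta = e2; g0 = g2; }
  } else {
    eta = e1;
    g0 = g1;
  }
  // curvature term at the mode
  arma::mat L;
  double ridge = 0.0;
  while (!arma::chol(L, H + ridge * arma::eye(m, m), "lower")) {
    ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
    if (ridge > 1e4) { flagged = true; return 2.0 * g0 + 50.0; }
  }
  if (ridge > 0) flagged = true;
  double ldetH = 2.0 * arma::accu(arma::log(L.diag()));
  return 2.0 * g0 - m * LOG2PI + ldetH;
}

//' @title Laplace -2 log-likelihood (internal)
//' @description Marginal -2LL of the population model over a list of
//'   subjects, integrating the active etas out by Laplace approximation
//'   around per-subject posterior modes (empirical Bayes estimates).
//' @keywords internal
// [[Rcpp::export]]
List cpp_neg2ll(NumericVector theta, NumericVector dvec, List subjects,
                NumericMatrix omega, IntegerVector active,
                NumericVector resid, NumericMatrix eta_init) {
  arma::vec th = as<arma::vec>(theta), dv = as<arma::vec>(dvec);
  arma::mat Om = as<arma::mat>(omega);
  arma::ivec act = as<arma::ivec>(active); // 0-based indices into eta11
  int m = act.n_elem, n = subjects.size();
  double cv = resid[0], addsd = resid[1];
  arma::mat Oinv;
  double ldetO;
  {
    arma::mat L;
    if (!arma::chol(L, Om, "lower")) stop("omega not positive definite");
    Oinv = arma::inv_sympd(Om);
    ldetO = 2.0 * arma::accu(arma::log(L.diag()));
  }
  arma::mat ebes = as<arma::mat>(eta_init); // m x n
  arma::vec ill(n);
  LogicalVector flags(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    List si = subjects[i];
    Subject s;
    s.times = as<arma::vec>(si["times"]);
    s.dv = as<arma::vec>(si["dv"]);
    s.doses = as<arma::mat>(si["doses"]);
    s.age = as<int>(si["age"]);
    arma::vec eta = ebes.col(i);
    bool fl;
    double li = laplace_subject(s, th, dv, act, Oinv, ldetO, cv, addsd, eta,
                                fl);
    ebes.col(i) = eta;
    ill[i] = li;
    flags[i] = fl;
    tot += li;
  }
  return List::create(_["m2ll"] = tot, _["ebes"] = wrap(ebes),
                      _["subject_m2ll"] = wrap(ill), _["flagged"] = flags);
}
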