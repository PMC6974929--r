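// Structural solver and subject-level marginal-likelihood machinery for the
// artesunate -> dihydroartemisinin transit-absorption population PK model.
//
// State vector (nn transit compartments): depot, T1..Tnn, ARS central,
// DHA central, eliminated-mass sink. All flows first order; the sink row
// makes mass balance checkable directly from the solved amounts.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat rate_matrix(double ktr, double k23, double k30, int nn) {
  int ns = nn + 4;                 // depot + nn transits + ARS + DHA + sink
  mat K(ns, ns, fill::zeros);
  // depot -> T1 -> ... -> Tnn -> ARS, all at ktr
  for (int i = 0; i <= nn; ++i) {
    K(i, i) = -ktr;
    K(i + 1, i) = ktr;
  }
  int iars = nn + 1, idha = nn + 2, isink = nn + 3;
  K(iars, iars) = -k23;
  K(idha, iars) = k23;             // complete conversion ARS -> DHA
  K(idha, idha) = -k30;
  K(isink, idha) = k30;
  return K;
}

// Propagate the linear system through sorted dose/observation events.
// times must be non-decreasing; a dose at time t is applied before any
// propagation past t, after recording observations at exactly t.
static mat solve_amounts(double ktr, double k23, double k30, int nn,
                         const vec& dose_time, const vec& dose_amt,
                         const vec& times) {
  int ns = nn + 4, nt = times.n_elem;
  mat K = rate_matrix(ktr, k23, k30, nn);
  mat out(ns, nt, fill::zeros);
  vec a(ns, fill::zeros);
  // Propagators per interval length. Intervals equal to within rounding
  // share an entry (regular grids produce lengths differing in the last
  // bit), and a length that is a small integer multiple of the smallest
  // one is composed from it by binary powering instead of a fresh matrix
  // exponential -- the common fixed sampling grids then need one expm.
  struct ApproxLess {
    bool operator()(double a, double b) const { return a < b - 1e-12 * (1 + b); }
  };
  std::map<double, mat, ApproxLess> cache;
  double dt_min = datum::inf;
  {
    double prev = 0.0;
    std::vector<double> ev;
    for (unsigned int i = 0; i < dose_time.n_elem; ++i) ev.push_back(dose_time(i));
    for (int i = 0; i < nt; ++i) ev.push_back(times(i));
    std::sort(ev.begin(), ev.end());
    for (double t : ev) {
      double dt = t - prev;
      if (dt > 1e-12 && dt < dt_min) dt_min = dt;
      prev = t;
    }
  }
  mat base;
  bool have_base = false;
  auto propagator = [&](double dt) -> const mat& {
    auto it = cache.find(dt);
    if (it != cache.end()) return it->second;
    double ratio = dt / dt_min;
    long k = std::lround(ratio);
    if (k >= 1 && k <= 4096 && std::fabs(ratio - k) < 1e-9) {
      if (!have_base) { base = expmat(K * dt_min); have_base = true; }
      mat P = eye(size(K)), sq = base;
      long m = k;
      while (m) {
        if (m & 1) P = sq * P;
        m >>= 1;
        if (m) sq = sq * sq;
      }
      return cache.emplace(dt, std::move(P)).first->second;
    }
    return cache.emplace(dt, expmat(K * dt)).first->second;
  };
  double tcur = 0.0;
  unsigned int idose = 0;
  auto step_to = [&](double t) {
    double dt = t - tcur;
    if (dt > 0) {
      a = propagator(dt) * a;
      tcur = t;
    }
  };
  for (int j = 0; j < nt; ++j) {
    // apply doses strictly before the current observation time
    while (idose < dose_time.n_elem && dose_time(idose) < times(j)) {
      step_to(dose_time(idose));
      a(0) += dose_amt(idose);
      ++idose;
    }
    step_to(times(j));
    out.col(j) = a;
    // a dose exactly at an observation time lands after that observation
    while (idose < dose_time.n_elem && dose_time(idose) == times(j)) {
      a(0) += dose_amt(idose);
      ++idose;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat solve_amounts_cpp(double ktr, double k23, double k30, int nn,
                            arma::vec dose_time, arma::vec dose_amt,
                            arma::vec times) {
  if (!times.is_sorted()) Rcpp::stop("times must be non-decreasing");
  if (times.n_elem && times.min() < 0) Rcpp::stop("negative times");
  return solve_amounts(ktr, k23, k30, nn, dose_time, dose_amt, times);
}

// ---------------------------------------------------------------------------
// Subject data, parsed once per objective evaluation.

struct Subj {
  double tvclp, v2, tvclm, v3, tvmt, tvf1;
  int nn;
  vec dose_time, dose_amt;
  vec utime;                        // unique sorted observation times
  uvec obs_ut;                      // index into utime per observation row
  ivec obs_cmt;                     // 2 = ARS, 3 = DHA
  vec obs_dv;                       // natural-log concentration (ng/mL)
  ivec obs_bql;
  vec sigma2;                       // (ARS, DHA) log-scale residual variances
  vec loglloq;                      // (ARS, DHA) log LLOQ
  double blq_floor;                 // additive floor on censored probability
};

static Subj parse_subj(const Rcpp::List& s, const rowvec& tv,
                       const vec& sigma2, const vec& loglloq,
                       double blq_floor) {
  Subj out;
  out.tvclp = tv(0); out.v2 = tv(1); out.tvclm = tv(2);
  out.v3 = tv(3); out.tvmt = tv(4); out.tvf1 = tv(5);
  out.nn = Rcpp::as<int>(s["nn"]);
  out.dose_time = Rcpp::as<vec>(s["dose_time"]);
  out.dose_amt  = Rcpp::as<vec>(s["dose_amt"]);
  vec ot = Rcpp::as<vec>(s["obs_time"]);
  out.obs_cmt = Rcpp::as<ivec>(s["obs_cmt"]);
  out.obs_dv  = Rcpp::as<vec>(s["obs_dv"]);
  out.obs_bql = Rcpp::as<ivec>(s["obs_bql"]);
  out.utime = unique(ot);           // sorted unique
  out.obs_ut.set_size(ot.n_elem);
  for (unsigned int i = 0; i < ot.n_elem; ++i) {
    uvec w = find(out.utime == ot(i), 1);
    out.obs_ut(i) = w(0);
  }
  out.sigma2 = sigma2;
  out.loglloq = loglloq;
  out.blq_floor = blq_floor;
  return out;
}

static const double LOG2PI = 1.8378770664093454836;

// -log joint density of (observations, eta); eta order: CL_ARS, CL_DHA, MTT, F
static double negjoint(const Subj& S, const vec& eta, const vec& omega2) {
  double clp = S.tvclp * std::exp(eta(0));
  double clm = S.tvclm * std::exp(eta(1));
  double mt  = S.tvmt  * std::exp(eta(2));
  double f1  = S.tvf1  * std::exp(eta(3));
  double ktr = (S.nn + 1.0) / mt;
  double k23 = clp / S.v2, k30 = clm / S.v3;
  // reject unphysical rate regions (sub-microsecond half-lives) that the
  // optimizer may probe transiently and that overflow the matrix exponential
  if (!std::isfinite(ktr) || !std::isfinite(k23) || !std::isfinite(k30) ||
      !std::isfinite(f1) || ktr > 1e7 || k23 > 1e7 || k30 > 1e7)
    return 1e10;
  mat A;
  try {
    A = solve_amounts(ktr, k23, k30, S.nn, S.dose_time, f1 * S.dose_amt,
                      S.utime);
  } catch (const std::exception&) {
    return 1e10;
  }
  if (!A.is_finite()) return 1e10;
  int iars = S.nn + 1, idha = S.nn + 2;
  double ll = 0.0;
  for (unsigned int i = 0; i < S.obs_ut.n_elem; ++i) {
    int ai = (S.obs_cmt(i) == 2) ? 0 : 1;
    double amt = (ai == 0) ? A(iars, S.obs_ut(i)) : A(idha, S.obs_ut(i));
    double vol = (ai == 0) ? S.v2 : S.v3;
    double conc = 1000.0 * amt / vol;                 // mg/L -> ng/mL
    double ipred = std::log(std::max(conc, 1e-300));
    double s2 = S.sigma2(ai), w = std::sqrt(s2);
    if (S.obs_bql(i) == 1) {
      double z = (S.loglloq(ai) - ipred) / w;
      double p = R::pnorm(z, 0.0, 1.0, 1, 0) + S.blq_floor;
      ll += std::log(p);
    } else {
      double r = S.obs_dv(i) - ipred;
      ll += -0.5 * (LOG2PI + std::log(s2) + r * r / s2);
    }
  }
  for (unsigned int k = 0; k < eta.n_elem; ++k)
    ll += -0.5 * (LOG2PI + std::log(omega2(k)) + eta(k) * eta(k) / omega2(k));
  return -ll;
}

static vec fd_grad(const Subj& S, const vec& eta, const vec& omega2) {
  int d = eta.n_elem;
  vec g(d);
  for (int k = 0; k < d; ++k) {
    double h = 1e-5 * (1.0 + std::fabs(eta(k)));
    vec ep = eta, em = eta;
    ep(k) += h; em(k) -= h;
    g(k) = (negjoint(S, ep, omega2) - negjoint(S, em, omega2)) / (2 * h);
  }
  return g;
}

// fd_mode 0: central differences (accurate; used for reported objective
// values and oracle comparisons); 1: forward differences (half the
// evaluations; used inside the outer optimization where only consistency
// across nearby parameter values matters).
static mat fd_hess(const Subj& S, const vec& eta, const vec& omega2,
                   int fd_mode = 0) {
  int d = eta.n_elem;
  mat H(d, d);
  vec h(d);
  for (int k = 0; k < d; ++k) h(k) = 1e-3 * (1.0 + std::fabs(eta(k)));
  if (fd_mode == 1) {
    double f0 = negjoint(S, eta, omega2);
    vec fp(d);
    for (int k = 0; k < d; ++k) {
      vec e1 = eta, e2 = eta;
      e1(k) += h(k); e2(k) += 2 * h(k);
      fp(k) = negjoint(S, e1, omega2);
      H(k, k) = (negjoint(S, e2, omega2) - 2 * fp(k) + f0) / (h(k) * h(k));
    }
    for (int k = 0; k < d; ++k)
      for (int l = k + 1; l < d; ++l) {
        vec e = eta;
        e(k) += h(k); e(l) += h(l);
        H(k, l) = H(l, k) =
          (negjoint(S, e, omega2) - fp(k) - fp(l) + f0) / (h(k) * h(l));
      }
    return H;
  }
  double f0 = negjoint(S, eta, omega2);
  for (int k = 0; k < d; ++k) {
    vec ep = eta, em = eta;
    ep(k) += h(k); em(k) -= h(k);
    H(k, k) = (negjoint(S, ep, omega2) - 2 * f0 + negjoint(S, em, omega2)) /
              (h(k) * h(k));
  }
  for (int k = 0; k < d; ++k)
    for (int l = k + 1; l < d; ++l) {
      vec epp = eta, epm = eta, emp = eta, emm = eta;
      epp(k) += h(k); epp(l) += h(l);
      epm(k) += h(k); epm(l) -= h(l);
      emp(k) -= h(k); emp(l) += h(l);
      emm(k) -= h(k); emm(l) -= h(l);
      H(k, l) = H(l, k) =
        (negjoint(S, epp, omega2) - negjoint(S, epm, omega2) -
         negjoint(S, emp, omega2) + negjoint(S, emm, omega2)) /
        (4 * h(k) * h(l));
    }
  return H;
}

// Gauss-Newton (first-order conditional style) curvature about eta:
// outer products of the per-record score in ipred times d(ipred)/d(eta),
// plus the prior precision.
static mat gn_hess(const Subj& S, const vec& eta, const vec& omega2) {
  int d = eta.n_elem;
  unsigned int nrec = S.obs_ut.n_elem;
  // ipred vector as a function of eta, by central differences
  auto ipreds = [&](const vec& e) {
    double clp = S.tvclp * std::exp(e(0));
    double clm = S.tvclm * std::exp(e(1));
    double mt  = S.tvmt  * std::exp(e(2));
    double f1  = S.tvf1  * std::exp(e(3));
    double ktr = (S.nn + 1.0) / mt;
    mat A = solve_amounts(ktr, clp / S.v2, clm / S.v3, S.nn, S.dose_time,
                          f1 * S.dose_amt, S.utime);
    int iars = S.nn + 1, idha = S.nn + 2;
    vec out(nrec);
    for (unsigned int i = 0; i < nrec; ++i) {
      double amt = (S.obs_cmt(i) == 2) ? A(iars, S.obs_ut(i))
                                       : A(idha, S.obs_ut(i));
      double vol = (S.obs_cmt(i) == 2) ? S.v2 : S.v3;
      out(i) = std::log(std::max(1000.0 * amt / vol, 1e-300));
    }
    return out;
  };
  vec ip0 = ipreds(eta);
  mat J(nrec, d);
  for (int k = 0; k < d; ++k) {
    double h = 1e-5 * (1.0 + std::fabs(eta(k)));
    vec ep = eta, em = eta;
    ep(k) += h; em(k) -= h;
    J.col(k) = (ipreds(ep) - ipreds(em)) / (2 * h);
  }
  mat H(d, d, fill::zeros);
  for (unsigned int i = 0; i < nrec; ++i) {
    int ai = (S.obs_cmt(i) == 2) ? 0 : 1;
    double s2 = S.sigma2(ai), wgt;
    if (S.obs_bql(i) == 1) {
      double w = std::sqrt(s2);
      double z = (S.loglloq(ai) - ip0(i)) / w;
      double p = R::pnorm(z, 0.0, 1.0, 1, 0) + S.blq_floor;
      double score = R::dnorm(z, 0.0, 1.0, 0) / (w * p);
      wgt = score * score;
    } else {
      wgt = 1.0 / s2;
    }
    H += wgt * (J.row(i).t() * J.row(i));
  }
  for (int k = 0; k < d; ++k) H(k, k) += 1.0 / omega2(k);
  return H;
}

struct LaplaceOut {
  vec eta;
  double g;        // negjoint at the mode
  double logdet;   // log|H| of the chosen curvature
  bool ok;
  int nev;
};

static LaplaceOut laplace_subject(const Subj& S, const vec& omega2,
                                  vec eta, int hess_method,
                                  double gtol, int maxit, int fd_mode = 0) {
  int d = eta.n_elem;
  double g = negjoint(S, eta, omega2);
  bool ok = true;
  for (int it = 0; it < maxit; ++it) {
    vec gr = fd_grad(S, eta, omega2);
    if (norm(gr, "inf") < gtol) break;
    mat H = fd_hess(S, eta, omega2, fd_mode);
    double lambda = 0.0;
    bool moved = false;
    for (int tri = 0; tri < 12; ++tri) {
      mat Hl = H + lambda * eye(d, d);
      vec delta;
      bool solved = solve(delta, Hl, -gr, solve_opts::no_approx);
      if (solved && delta.is_finite()) {
        double step = 1.0;
        for (int ls = 0; ls < 8; ++ls) {
          vec cand = eta + step * delta;
          double gc = negjoint(S, cand, omega2);
          if (std::isfinite(gc) && gc <= g + 1e-12) {
            eta = cand; g = gc; moved = true; break;
          }
          step *= 0.5;
        }
      }
      if (moved) break;
      lambda = (lambda == 0.0) ? 1e-4 : lambda * 10.0;
    }
    if (!moved) break;             // stalled; report current point
  }
  vec grf = fd_grad(S, eta, omega2);
  if (norm(grf, "inf") > std::max(1e-3, gtol * 100)) ok = false;
  mat H = (hess_method == 1) ? gn_hess(S, eta, omega2)
                             : fd_hess(S, eta, omega2, fd_mode);
  H = 0.5 * (H + H.t());
  double ridge = 0.0;
  mat L;
  while (!chol(L, H + ridge * eye(d, d), "lower")) {
    ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
    if (ridge > 1e2) { ok = false; break; }
  }
  LaplaceOut out;
  out.eta = eta; out.g = g; out.ok = ok && (ridge <= 1e-4); out.nev = 0;
  out.logdet = 2.0 * sum(log(L.diag()));
  return out;
}

// [[Rcpp::export]]
double subject_negjoint_cpp(Rcpp::List subj, arma::rowvec tv,
                            arma::vec sigma2, arma::vec loglloq,
                            arma::vec omega2, arma::vec eta,
                            double blq_floor = 1e-6) {
  Subj S = parse_subj(subj, tv, sigma2, loglloq, blq_floor);
  return negjoint(S, eta, omega2);
}

static Rcpp::List ofv_loop(std::vector<Subj>& subj, const mat& tv,
                           const vec& sigma2, const vec& omega2,
                           const mat& eta_start, int hess_method,
                           double gtol, int maxit, int fd_mode) {
  int n = subj.size(), d = omega2.n_elem;
  mat eta_modes(n, d);
  vec contrib(n);
  Rcpp::LogicalVector ok(n);
  double ofv = 0.0;
  for (int i = 0; i < n; ++i) {
    Subj& S = subj[i];
    S.tvclp = tv(i, 0); S.v2 = tv(i, 1); S.tvclm = tv(i, 2);
    S.v3 = tv(i, 3); S.tvmt = tv(i, 4); S.tvf1 = tv(i, 5);
    S.sigma2 = sigma2;
    LaplaceOut L = laplace_subject(S, omega2, eta_start.row(i).t(),
                                   hess_method, gtol, maxit, fd_mode);
    contrib(i) = 2.0 * L.g - d * LOG2PI + L.logdet;
    ofv += contrib(i);
    eta_modes.row(i) = L.eta.t();
    ok(i) = L.ok;
  }
  return Rcpp::List::create(
    Rcpp::Named("ofv") = ofv,
    Rcpp::Named("eta") = eta_modes,
    Rcpp::Named("contrib") = contrib,
    Rcpp::Named("ok") = ok);
}

// Total Laplacian objective over subjects.
// OFV = sum_i [ 2 g_i(eta_hat) - d log(2 pi) + log|H_i| ]  (full constants).
// [[Rcpp::export]]
Rcpp::List ofv_cpp(Rcpp::List subjects, arma::mat tv, arma::vec sigma2,
                   arma::vec loglloq, arma::vec omega2, arma::mat eta_start,
                   int hess_method = 0, double blq_floor = 1e-6,
                   double gtol = 1e-7, int maxit = 100) {
  int n = subjects.size();
  std::vector<Subj> subj;
  subj.reserve(n);
  for (int i = 0; i < n; ++i)
    subj.push_back(parse_subj(subjects[i], tv.row(i), sigma2, loglloq,
                              blq_floor));
  return ofv_loop(subj, tv, sigma2, omega2, eta_start, hess_method, gtol,
                  maxit, 0);
}

// Parse subject data once and keep it across outer-optimizer iterations.
// [[Rcpp::export]]
SEXP prepare_subjects_ptr(Rcpp::List subjects, arma::vec sigma2,
                          arma::vec loglloq, double blq_floor = 1e-6) {
  auto* v = new std::vector<Subj>;
  v->reserve(subjects.size());
  rowvec z(6, fill::ones);
  for (int i = 0; i < subjects.size(); ++i)
    v->push_back(parse_subj(subjects[i], z, sigma2, loglloq, blq_floor));
  return Rcpp::XPtr<std::vector<Subj>>(v, true);
}

// [[Rcpp::export]]
Rcpp::List ofv_ptr_cpp(SEXP ptr, arma::mat tv, arma::vec sigma2,
                       arma::vec omega2, arma::mat eta_start,
                       int hess_method = 0, double gtol = 1e-7,
                       int maxit = 100, int fd_mode = 1) {
  Rcpp::XPtr<std::vector<Subj>> xp(ptr);
  return ofv_loop(*xp, tv, sigma2, omega2, eta_start, hess_method, gtol,
                  maxit, fd_mode);
}
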