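// EM core for K-class growth mixture models under the restricted
// multivariate skew-t family.
//
// Model per class g:
//   Y_i = Lambda eta_i + delta_g u_i + eps_i
//   eta_i | w ~ N(alpha_g, Psi_g / w),  eps_i | w ~ N(0, diag(theta_g) / w),
//   u_i = |U0|, U0 | w ~ N(0, 1/w),  w ~ Gamma(nu_g/2, nu_g/2).
// Marginally Y_i ~ rMST(mu_g, Sigma_g, delta_g, nu_g) with mu_g = Lambda
// alpha_g and Sigma_g = Lambda Psi_g Lambda' + diag(theta_g).
//
// Structure flags:
//   skew_factor  - delta_g = Lambda delta_eta_g (skew carried by the
//                  growth factors, 2 free parameters) instead of a free
//                  p-vector.
//   shared_cov   - Psi, theta, delta, nu are class-invariant (only the
//                  factor means and mixing weights vary by class), the
//                  usual mixture-model default; otherwise everything is
//                  class-specific.
//
// E-step: posterior class probabilities plus the conditional moments
//   e1 = E[W | y], e2 = E[W u | y], e3 = E[W u^2 | y]
// in closed form from the Gamma mixture representation (univariate t CDF
// calls only), then linear maps for the latent growth factors. M-step:
// closed-form ECM updates of pi, alpha, delta, Psi, theta; nu by a local
// golden-section ECME step on the observed log-likelihood (kept only if
// it improves), so the log-likelihood trajectory is monotone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

struct ClassPar {
  vec alpha;   // 2
  mat Psi;     // 2x2
  vec theta;   // p
  vec delta;   // p
  double nu;   // Inf for normal / skew-normal members
};

struct ClassCache {
  vec mu;        // p
  mat Sigma;     // p x p
  mat U;         // chol(Omega), upper: U'U = Omega
  double logdet; // log|Omega|
  vec oid;       // Omega^{-1} delta
  double sig2;   // 1 - delta' Omega^{-1} delta
  vec d;         // n, Mahalanobis under Omega
  vec q;         // n, delta' Omega^{-1} (y - mu)
  vec logf;      // n, log component density
  vec logT;      // n, log t-CDF factor of the density (finite nu only)
  bool ok;
};

// per-class E-step/M-step accumulators
struct ClassStats {
  vec e1, e2, e3;       // n
  mat a0;               // 2 x n   E[eta | y, u=0-part]: alpha + A(y - mu)
  vec a1;               // 2       A delta
  mat Cmat;             // 2x2 conditional factor covariance (times 1/w)
  double sw, swe1, sze3;
  vec sum_zEweta;       // 2
  vec sum_zEwueta;      // 2
  vec sze2y;            // p       Y' (z % e2)
  mat See;              // 2x2     sum_i z_i E[w eta eta' | y_i]
  vec th_base;          // p       theta numerator terms not involving delta_new
  vec ze1, ze2;         // n (needed for theta cross term)
};

// log component density given cached d, q for one value of nu
static void logf_from_cache(ClassCache& C, double nu, int p) {
  const uword n = C.d.n_elem;
  C.logf.set_size(n);
  double sig = std::sqrt(C.sig2);
  if (std::isfinite(nu)) {
    C.logT.set_size(n);
    double cst = std::log(2.0) + std::lgamma((nu + p) / 2.0) -
      std::lgamma(nu / 2.0) - 0.5 * p * std::log(nu * M_PI) - 0.5 * C.logdet;
    for (uword i = 0; i < n; ++i) {
      double qs = C.q(i) / sig;
      double arg = qs * std::sqrt((nu + p) / (nu + C.d(i)));
      C.logT(i) = R::pt(arg, nu + p, 1, 1);
      C.logf(i) = cst - 0.5 * (nu + p) * std::log1p(C.d(i) / nu) + C.logT(i);
    }
  } else {
    double cst = std::log(2.0) - 0.5 * p * LOG2PI - 0.5 * C.logdet;
    for (uword i = 0; i < n; ++i) {
      C.logf(i) = cst - 0.5 * C.d(i) + R::pnorm(C.q(i) / sig, 0.0, 1.0, 1, 1);
    }
  }
}

// Rebuild all per-class structure and densities from current parameters.
static bool build_cache(const mat& Y, const mat& Lambda, const ClassPar& P,
                        ClassCache& C) {
  const int p = Y.n_cols;
  C.ok = false;
  C.mu = Lambda * P.alpha;
  C.Sigma = Lambda * P.Psi * Lambda.t() + diagmat(P.theta);
  mat Omega = C.Sigma + P.delta * P.delta.t();
  mat U;
  if (!chol(U, Omega)) return false;
  C.U = U;
  C.logdet = 2.0 * sum(log(U.diag()));
  mat yc = Y.each_row() - C.mu.t();          // n x p
  mat Zt = solve(trimatl(U.t()), yc.t());    // p x n
  C.d = sum(square(Zt), 0).t();
  C.oid = solve(trimatu(U), solve(trimatl(U.t()), P.delta));
  C.sig2 = 1.0 - dot(P.delta, C.oid);
  if (C.sig2 <= 0) return false;
  C.q = yc * C.oid;
  logf_from_cache(C, P.nu, p);
  if (!C.logf.is_finite()) return false;
  C.ok = true;
  return true;
}

// log-sum-exp across classes of log(pi_g) + logf_g, filling posteriors
static double mixture_loglik(const std::vector<ClassCache>& caches,
                             const vec& logpi, mat& Z) {
  const uword n = caches[0].logf.n_elem;
  const uword K = caches.size();
  double ll = 0.0;
  for (uword i = 0; i < n; ++i) {
    double m = -datum::inf;
    for (uword k = 0; k < K; ++k) {
      double v = logpi(k) + caches[k].logf(i);
      Z(i, k) = v;
      if (v > m) m = v;
    }
    double s = 0.0;
    for (uword k = 0; k < K; ++k) s += std::exp(Z(i, k) - m);
    double lse = m + std::log(s);
    ll += lse;
    for (uword k = 0; k < K; ++k) Z(i, k) = std::exp(Z(i, k) - lse);
  }
  return ll;
}

// Conditional moments e1 = E[W|y], e2 = E[Wu|y], e3 = E[Wu^2|y].
static void e_moments(const ClassCache& C, double nu, int p, bool skew,
                      vec& e1, vec& e2, vec& e3) {
  const uword n = C.d.n_elem;
  e1.set_size(n); e2.set_size(n); e3.set_size(n);
  double sig = std::sqrt(C.sig2);
  if (std::isfinite(nu)) {
    double A = (nu + p) / 2.0;
    double lgA = std::lgamma(A), lgA5 = std::lgamma(A + 0.5);
    for (uword i = 0; i < n; ++i) {
      double qs = C.q(i) / sig;
      double B = (nu + C.d(i)) / 2.0;
      double logT = C.logT(i);   // pt at the density argument, cached
      double logT2 = R::pt(qs * std::sqrt((nu + p + 2.0) / (nu + C.d(i))),
                           nu + p + 2.0, 1, 1);
      e1(i) = (nu + p) / (nu + C.d(i)) * std::exp(logT2 - logT);
      if (skew) {
        double logr = -0.5 * LOG2PI + lgA5 - lgA + A * std::log(B) -
          (A + 0.5) * std::log(B + 0.5 * qs * qs) - logT;
        e2(i) = C.q(i) * e1(i) + sig * std::exp(logr);
        e3(i) = C.q(i) * e2(i) + C.sig2;
      }
    }
  } else {
    e1.ones();
    if (skew) {
      for (uword i = 0; i < n; ++i) {
        double qs = C.q(i) / sig;
        double h = std::exp(R::dnorm(qs, 0.0, 1.0, 1) -
                            R::pnorm(qs, 0.0, 1.0, 1, 1));
        e2(i) = C.q(i) + sig * h;
        e3(i) = C.q(i) * e2(i) + C.sig2;
      }
    }
  }
  if (!skew) { e2.zeros(); e3.zeros(); }
}

// Golden-section ECME step for nu on the observed log-likelihood; when
// `shared` all classes move together. Search is local (at most a factor
// of 2 per call) so the df update is a line search, not a basin hop.
static double nu_linesearch(const vec& logpi, std::vector<ClassCache>& caches,
                            const std::vector<int>& ks, int p,
                            double nu_cur, double nu_min, double nu_max) {
  const uword n = caches[0].d.n_elem;
  const uword K = caches.size();
  std::vector<double> vals(K);
  std::vector<vec> logf_save(K);
  auto eval = [&](double nu) {
    for (int k : ks) {
      ClassCache tmp = caches[k];
      logf_from_cache(tmp, nu, p);
      logf_save[k] = tmp.logf;
    }
    double ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      double m = -datum::inf;
      for (uword g = 0; g < K; ++g) {
        bool in = std::find(ks.begin(), ks.end(), (int)g) != ks.end();
        double v = logpi(g) + (in ? logf_save[g](i) : caches[g].logf(i));
        vals[g] = v;
        if (v > m) m = v;
      }
      double s = 0.0;
      for (uword g = 0; g < K; ++g) s += std::exp(vals[g] - m);
      ll += m + std::log(s);
    }
    return ll;
  };
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double lo = std::log(std::max(nu_min, nu_cur / 2.0));
  double hi = std::log(std::min(nu_max, nu_cur * 2.0));
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = eval(std::exp(x1)), f2 = eval(std::exp(x2));
  for (int it = 0; it < 11 && (hi - lo) > 3e-3; ++it) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo); f2 = eval(std::exp(x2));
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo); f1 = eval(std::exp(x1));
    }
  }
  double xb = (f1 > f2) ? x1 : x2;
  double fb = std::max(f1, f2);
  if (fb > eval(nu_cur)) return std::exp(xb);
  return nu_cur;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
Rcpp::List em_fit_cpp(const arma::mat& Y, const arma::mat& Lambda,
                      Rcpp::List init, arma::vec weights,
                      bool skew, bool tdist, bool skew_factor,
                      bool shared_cov,
                      int maxit, double tol, double pi_floor,
                      double nu_min, double nu_max, bool track) {
  const int n = Y.n_rows, p = Y.n_cols;
  const int K = init.size();

  std::vector<ClassPar> par(K);
  for (int k = 0; k < K; ++k) {
    Rcpp::List ik = init[k];
    par[k].alpha = Rcpp::as<vec>(ik["alpha"]);
    par[k].Psi = Rcpp::as<mat>(ik["Psi"]);
    par[k].theta = Rcpp::as<vec>(ik["theta"]);
    par[k].delta = skew ? Rcpp::as<vec>(ik["delta"]) : zeros<vec>(p);
    par[k].nu = tdist ? Rcpp::as<double>(ik["nu"]) : datum::inf;
    if (tdist) par[k].nu = std::min(std::max(par[k].nu, nu_min), nu_max);
  }
  if (shared_cov && K > 1) {
    // enforce class-invariance from the start
    for (int k = 1; k < K; ++k) {
      par[k].Psi = par[0].Psi;
      par[k].theta = par[0].theta;
      par[k].delta = par[0].delta;
      par[k].nu = par[0].nu;
    }
  }

  std::vector<ClassCache> caches(K);
  std::vector<ClassStats> st(K);
  mat Z(n, K);
  vec logpi = log(weights);
  std::vector<double> traj;
  bool degenerate = false;
  double ll = -datum::inf, ll_prev = -datum::inf;
  int iter = 0;
  bool converged = false;
  mat Yt = Y.t();                               // p x n

  for (int k = 0; k < K; ++k) {
    if (!build_cache(Y, Lambda, par[k], caches[k])) degenerate = true;
  }

  if (!degenerate) {
    ll = mixture_loglik(caches, logpi, Z);
    if (track) traj.push_back(ll);

    for (iter = 1; iter <= maxit; ++iter) {
      // ---- E-step accumulators per class (old parameters throughout)
      for (int k = 0; k < K && !degenerate; ++k) {
        ClassPar& P = par[k];
        ClassCache& C = caches[k];
        ClassStats& S = st[k];
        e_moments(C, P.nu, p, skew, S.e1, S.e2, S.e3);
        vec z = Z.col(k);
        S.sw = accu(z);
        if (S.sw < pi_floor * n || !std::isfinite(S.sw)) { degenerate = true; break; }

        mat LP = Lambda * P.Psi;                  // p x 2
        mat Amat = solve(C.Sigma, LP).t();        // 2 x p = Psi L' Sigma^{-1}
        S.Cmat = P.Psi - Amat * LP;               // 2x2 conditional cov
        S.a1 = Amat * P.delta;
        mat yc = Yt.each_col() - C.mu;            // p x n
        S.a0 = Amat * yc;
        S.a0.each_col() += P.alpha;

        S.ze1 = z % S.e1;
        S.ze2 = z % S.e2;
        vec ze3 = z % S.e3;
        S.swe1 = accu(S.ze1);
        S.sze3 = accu(ze3);

        mat Eweta = S.a0.each_row() % S.e1.t();   // 2 x n
        if (skew) Eweta -= S.a1 * S.e2.t();
        S.sum_zEweta = Eweta * z;
        S.sum_zEwueta = skew ? vec(S.a0 * S.ze2 - S.a1 * S.sze3)
                             : vec(zeros<vec>(2));
        S.sze2y = skew ? vec(Y.t() * S.ze2) : vec(zeros<vec>(p));

        S.See = S.sw * S.Cmat + (S.a0.each_row() % S.ze1.t()) * S.a0.t();
        if (skew) {
          mat cr = (S.a0 * S.ze2) * S.a1.t();
          S.See -= cr + cr.t();
          S.See += (S.a1 * S.a1.t()) * S.sze3;
        }
        // theta terms independent of the new delta:
        //   sum z e1 y^2 - 2 sum z y (Lambda Eweta) + diag(Lambda See Lambda')
        mat LEweta = Lambda * Eweta;              // p x n
        S.th_base = square(Yt) * S.ze1
          - 2.0 * sum(Yt % (LEweta.each_row() % z.t()), 1)
          + sum((Lambda * S.See) % Lambda, 1);
      }
      if (degenerate) break;

      // ---- M-step
      // factor means, always class-specific
      for (int k = 0; k < K; ++k) par[k].alpha = st[k].sum_zEweta / st[k].swe1;

      // skew vector
      if (skew) {
        auto solve_delta = [&](const vec& num, double den, const vec& theta) {
          vec out;
          if (den <= 1e-12) return out;  // empty => keep old
          if (skew_factor) {
            mat LtTi = Lambda.t() * diagmat(1.0 / theta);
            vec de = solve(LtTi * Lambda, LtTi * (num / den));
            out = Lambda * de;
          } else {
            out = num / den;
          }
          return out;
        };
        if (shared_cov) {
          vec num(p, fill::zeros);
          double den = 0;
          for (int k = 0; k < K; ++k) {
            num += st[k].sze2y - Lambda * st[k].sum_zEwueta;
            den += st[k].sze3;
          }
          vec d_new = solve_delta(num, den, par[0].theta);
          if (d_new.n_elem)
            for (int k = 0; k < K; ++k) par[k].delta = d_new;
        } else {
          for (int k = 0; k < K; ++k) {
            vec num = st[k].sze2y - Lambda * st[k].sum_zEwueta;
            vec d_new = solve_delta(num, st[k].sze3, par[k].theta);
            if (d_new.n_elem) par[k].delta = d_new;
          }
        }
      }

      // factor covariance
      auto psi_num = [&](int k) {
        const ClassStats& S = st[k];
        const vec& a = par[k].alpha;
        mat M = S.See - S.sum_zEweta * a.t() - a * S.sum_zEweta.t() +
          S.swe1 * (a * a.t());
        return M;
      };
      if (shared_cov) {
        mat M(2, 2, fill::zeros);
        double sw = 0;
        for (int k = 0; k < K; ++k) { M += psi_num(k); sw += st[k].sw; }
        M /= sw;
        M = 0.5 * (M + M.t());
        M.diag() += 1e-9;
        for (int k = 0; k < K; ++k) par[k].Psi = M;
      } else {
        for (int k = 0; k < K; ++k) {
          mat M = psi_num(k) / st[k].sw;
          M = 0.5 * (M + M.t());
          M.diag() += 1e-9;
          par[k].Psi = M;
        }
      }

      // residual variances
      auto theta_num = [&](int k) {
        const ClassStats& S = st[k];
        vec th = S.th_base;
        if (skew) {
          const vec& d = par[k].delta;
          th += -2.0 * (d % S.sze2y) + 2.0 * (d % (Lambda * S.sum_zEwueta)) +
            square(d) * S.sze3;
        }
        return th;
      };
      if (shared_cov) {
        vec th(p, fill::zeros);
        double sw = 0;
        for (int k = 0; k < K; ++k) { th += theta_num(k); sw += st[k].sw; }
        th /= sw;
        for (int j = 0; j < p; ++j) th(j) = std::max(th(j), 1e-8);
        for (int k = 0; k < K; ++k) par[k].theta = th;
      } else {
        for (int k = 0; k < K; ++k) {
          vec th = theta_num(k) / st[k].sw;
          for (int j = 0; j < p; ++j) th(j) = std::max(th(j), 1e-8);
          par[k].theta = th;
        }
      }

      // mixing weights
      for (int k = 0; k < K; ++k) weights(k) = st[k].sw / n;
      if (K > 1) {
        weights /= accu(weights);
        if (weights.min() < std::max(pi_floor, 1.0 / n)) { degenerate = true; break; }
      }
      logpi = log(weights);

      // rebuild caches under new parameters
      for (int k = 0; k < K && !degenerate; ++k) {
        if (!build_cache(Y, Lambda, par[k], caches[k])) degenerate = true;
      }
      if (degenerate) break;

      double ll_new = mixture_loglik(caches, logpi, Z);

      // ECME step for the degrees of freedom (every third iteration: the
      // line search costs several CDF sweeps per evaluation)
      bool nu_updated = false;
      if (tdist && (iter % 3 == 1 || iter == maxit)) {
        nu_updated = true;
        if (shared_cov) {
          std::vector<int> all(K);
          for (int k = 0; k < K; ++k) all[k] = k;
          double nu_new = nu_linesearch(logpi, caches, all, p, par[0].nu,
                                        nu_min, nu_max);
          if (nu_new != par[0].nu) {
            for (int k = 0; k < K; ++k) {
              par[k].nu = nu_new;
              logf_from_cache(caches[k], nu_new, p);
            }
          }
        } else {
          for (int k = 0; k < K; ++k) {
            double nu_new = nu_linesearch(logpi, caches, {k}, p, par[k].nu,
                                          nu_min, nu_max);
            if (nu_new != par[k].nu) {
              par[k].nu = nu_new;
              logf_from_cache(caches[k], nu_new, p);
            }
          }
        }
        ll_new = mixture_loglik(caches, logpi, Z);
      }

      ll_prev = ll;
      ll = ll_new;
      if (track) traj.push_back(ll);
      if (std::abs(ll - ll_prev) < tol * (1.0 + std::abs(ll_prev)) &&
          (!tdist || nu_updated)) {
        converged = true;
        break;
      }
    }
  }

  Rcpp::List classes(K);
  for (int k = 0; k < K; ++k) {
    classes[k] = Rcpp::List::create(
      Rcpp::Named("alpha") = par[k].alpha,
      Rcpp::Named("Psi") = par[k].Psi,
      Rcpp::Named("theta") = par[k].theta,
      Rcpp::Named("delta") = par[k].delta,
      Rcpp::Named("nu") = par[k].nu);
  }
  return Rcpp::List::create(
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("weights") = weights,
    Rcpp::Named("classes") = classes,
    Rcpp::Named("posteriors") = Z,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("degenerate") = degenerate,
    Rcpp::Named("trajectory") = traj);
}

// [[Rcpp::export(name = ".mixture_loglik_cpp")]]
double mixture_loglik_cpp(const arma::mat& Y, const arma::mat& Lambda,
                          Rcpp::List pars, arma::vec weights,
                          bool skew, bool tdist) {
  const int n = Y.n_rows;
  const int K = pars.size();
  std::vector<ClassCache> caches(K);
  for (int k = 0; k < K; ++k) {
    Rcpp::List ik = pars[k];
    ClassPar P;
    P.alpha = Rcpp::as<vec>(ik["alpha"]);
    P.Psi = Rcpp::as<mat>(ik["Psi"]);
    P.theta = Rcpp::as<vec>(ik["theta"]);
    P.delta = skew ? Rcpp::as<vec>(ik["delta"]) : zeros<vec>(Y.n_cols);
    P.nu = tdist ? Rcpp::as<double>(ik["nu"]) : datum::inf;
    if (!build_cache(Y, Lambda, P, caches[k])) return -datum::inf;
  }
  mat Z(n, K);
  return mixture_loglik(caches, log(weights), Z);
}
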