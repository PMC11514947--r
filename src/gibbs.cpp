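// Gibbs sampler for the normal-multinomial mixture with an MRF prior on
// domain labels, plus small exported kernels used by unit tests.
//
// Randomness: three independent mt19937_64 streams (labels, normal
// sub-component parameters, composition parameters) fanned out from one
// seed, so a chain that never touches the image profile consumes exactly
// the same label/parameter streams as a w = 0 chain.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

typedef std::mt19937_64 rng_t;

static rng_t make_stream(int seed, int id) {
  std::seed_seq ss{static_cast<unsigned int>(seed),
                   static_cast<unsigned int>(id),
                   0x9e3779b9u};
  return rng_t(ss);
}

static inline double draw_unif(rng_t &g) {
  std::uniform_real_distribution<double> d(0.0, 1.0);
  return d(g);
}

static inline double draw_norm(rng_t &g) {
  std::normal_distribution<double> d(0.0, 1.0);
  return d(g);
}

// shape/rate parameterization
static inline double draw_gamma(rng_t &g, double shape, double rate) {
  std::gamma_distribution<double> d(shape, 1.0 / rate);
  return d(g);
}

static inline double draw_chisq(rng_t &g, double df) {
  return draw_gamma(g, df / 2.0, 0.5);
}

// categorical draw from normalized probabilities
static inline int draw_cat(rng_t &g, const arma::vec &p) {
  double u = draw_unif(g);
  double acc = 0.0;
  for (arma::uword k = 0; k < p.n_elem; ++k) {
    acc += p(k);
    if (u <= acc) return static_cast<int>(k);
  }
  return static_cast<int>(p.n_elem) - 1;
}

static arma::vec normalize_log(const arma::vec &lp) {
  double m = lp.max();
  if (!std::isfinite(m))
    stop("all component log-probabilities are -Inf; cannot normalize");
  arma::vec p = arma::exp(lp - m);
  return p / arma::accu(p);
}

// Sigma ~ IW(eta, Phi) via Bartlett decomposition of W ~ Wishart(eta, Phi^-1)
static arma::mat draw_invwishart(rng_t &g, double eta, const arma::mat &Phi) {
  const arma::uword P = Phi.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(Phi), "lower");
  arma::mat A(P, P, arma::fill::zeros);
  for (arma::uword i = 0; i < P; ++i) {
    A(i, i) = std::sqrt(draw_chisq(g, eta - static_cast<double>(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = draw_norm(g);
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(W);
}

struct PriorSet {
  arma::vec nu0;    // normal prior mean, length P
  double tau0;      // prior precision scale
  double eta0;      // IW degrees of freedom
  arma::mat Phi0;   // IW scale matrix
  double ig_a;      // IG shape (diagonal variant)
  double ig_b;      // IG rate (diagonal variant)
  arma::vec alpha0; // Dirichlet concentration, length Q
  arma::vec dvec;   // MRF offsets, length K
  double f;         // MRF smoothness
  double w;         // image-profile weight
};

// sufficient statistics of domain k under labels z (0-based)
static void cluster_stats(const arma::mat &Y, const arma::ivec &z, int k,
                          int &nk, arma::vec &ybar, arma::mat &S) {
  const arma::uword P = Y.n_cols;
  nk = 0;
  ybar.zeros(P);
  S.zeros(P, P);
  for (arma::uword i = 0; i < Y.n_rows; ++i)
    if (z(i) == k) { ++nk; ybar += Y.row(i).t(); }
  if (nk > 0) ybar /= nk;
  for (arma::uword i = 0; i < Y.n_rows; ++i)
    if (z(i) == k) {
      arma::vec r = Y.row(i).t() - ybar;
      S += r * r.t();
    }
}

// Normal-inverse-Wishart posterior hyperparameters for domain k
static void niw_post(const arma::mat &Y, const arma::ivec &z, int k,
                     const PriorSet &pr, double &tau_k, double &eta_k,
                     arma::vec &nu_k, arma::mat &Phi_k) {
  int nk;
  arma::vec ybar;
  arma::mat S;
  cluster_stats(Y, z, k, nk, ybar, S);
  tau_k = pr.tau0 + nk;
  eta_k = pr.eta0 + nk;
  if (nk == 0) {
    nu_k = pr.nu0;
    Phi_k = pr.Phi0;
    return;
  }
  nu_k = (pr.tau0 * pr.nu0 + nk * ybar) / (nk + pr.tau0);
  arma::vec dmean = ybar - pr.nu0;
  Phi_k = pr.Phi0 + S + (nk * pr.tau0 / (pr.tau0 + nk)) * (dmean * dmean.t());
}

// diagonal (normal-inverse-gamma) posterior hyperparameters for domain k
static void nig_post(const arma::mat &Y, const arma::ivec &z, int k,
                     const PriorSet &pr, double &tau_k, double &shape_k,
                     arma::vec &nu_k, arma::vec &rate_k) {
  const arma::uword P = Y.n_cols;
  int nk;
  arma::vec ybar;
  arma::mat S;
  cluster_stats(Y, z, k, nk, ybar, S);
  tau_k = pr.tau0 + nk;
  shape_k = pr.ig_a + nk / 2.0;
  nu_k.set_size(P);
  rate_k.set_size(P);
  for (arma::uword p = 0; p < P; ++p) {
    if (nk == 0) {
      nu_k(p) = pr.nu0(p);
      rate_k(p) = pr.ig_b;
    } else {
      nu_k(p) = (pr.tau0 * pr.nu0(p) + nk * ybar(p)) / (nk + pr.tau0);
      double dm = ybar(p) - pr.nu0(p);
      rate_k(p) = pr.ig_b +
        0.5 * (S(p, p) + (nk * pr.tau0 / (pr.tau0 + nk)) * dm * dm);
    }
  }
}

// multivariate normal log-density given the lower-triangular inverse
// Cholesky factor Li = inv(chol(Sigma, "lower")) and logdet(Sigma)
static inline double mvn_logpdf(const arma::vec &y, const arma::vec &mu,
                                const arma::mat &Li, double logdet) {
  arma::vec q = Li * (y - mu);
  return -0.5 * (y.n_elem * LOG2PI + logdet + arma::dot(q, q));
}

static inline double diag_logpdf(const arma::rowvec &y, const arma::rowvec &mu,
                                 const arma::rowvec &sig2) {
  double acc = 0.0;
  for (arma::uword p = 0; p < y.n_elem; ++p) {
    double r = y(p) - mu(p);
    acc += std::log(sig2(p)) + r * r / sig2(p);
  }
  return -0.5 * (y.n_elem * LOG2PI + acc);
}

// [[Rcpp::export]]
List gibbs_fit_cpp(const arma::mat &Y, const arma::imat &V, const List &nbrs,
                   int K, const arma::vec &nu0, double tau0, double eta0,
                   const arma::mat &Phi0, double ig_a, double ig_b,
                   const arma::vec &alpha0, const arma::vec &dvec, double f,
                   double w, int n_iter, int burn_in, int seed, bool diagonal,
                   bool use_image, bool tempered, const arma::ivec &z_init) {
  const int N = Y.n_rows, P = Y.n_cols, Q = V.n_cols;
  if (K < 2) stop("K must be at least 2");
  if (n_iter <= burn_in || burn_in < 0) stop("need n_iter > burn_in >= 0");
  if (static_cast<int>(z_init.n_elem) != N) stop("z_init length mismatch");

  PriorSet pr{nu0, tau0, eta0, Phi0, ig_a, ig_b, alpha0, dvec, f, w};
  rng_t g_z = make_stream(seed, 1);
  rng_t g_th = make_stream(seed, 2);
  rng_t g_om = make_stream(seed, 3);

  // neighbor lists (0-based) into flat storage
  std::vector<std::vector<int>> nb(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v = nbrs[i];
    nb[i].assign(v.begin(), v.end());
  }

  // per-spot multinomial coefficients and totals
  arma::vec logcoef(N, arma::fill::zeros);
  arma::ivec mtot(N, arma::fill::zeros);
  if (use_image) {
    for (int i = 0; i < N; ++i) {
      double m = 0, lc = 0;
      for (int q = 0; q < Q; ++q) {
        m += V(i, q);
        lc -= std::lgamma(V(i, q) + 1.0);
      }
      mtot(i) = static_cast<int>(m);
      logcoef(i) = std::lgamma(m + 1.0) + lc;
    }
  }

  arma::ivec z = z_init;
  arma::mat mu(K, P, arma::fill::zeros);
  arma::mat sig2(K, P, arma::fill::ones);       // diagonal variant
  arma::cube Sig(P, P, K, arma::fill::zeros);   // full variant
  arma::cube Li(P, P, K, arma::fill::zeros);
  arma::vec logdet(K, arma::fill::zeros);
  arma::mat omega(K, Q);
  omega.fill(1.0 / Q);
  arma::mat logom = arma::log(omega);

  const int U = n_iter - burn_in;
  arma::imat zdraws(U, N);
  arma::cube mudraws(K, P, U);
  arma::cube sigdraws(K, P * P, U);
  arma::cube omdraws(K, Q, U);

  auto update_theta = [&]() {
    for (int k = 0; k < K; ++k) {
      if (diagonal) {
        double tau_k, shape_k;
        arma::vec nu_k, rate_k;
        nig_post(Y, z, k, pr, tau_k, shape_k, nu_k, rate_k);
        for (int p = 0; p < P; ++p) {
          double s2 = 1.0 / draw_gamma(g_th, shape_k, rate_k(p));
          sig2(k, p) = s2;
          mu(k, p) = nu_k(p) + std::sqrt(s2 / tau_k) * draw_norm(g_th);
        }
        logdet(k) = arma::accu(arma::log(sig2.row(k)));
      } else {
        double tau_k, eta_k;
        arma::vec nu_k;
        arma::mat Phi_k;
        niw_post(Y, z, k, pr, tau_k, eta_k, nu_k, Phi_k);
        arma::mat S = draw_invwishart(g_th, eta_k, Phi_k);
        if (!S.is_finite()) stop("non-finite covariance draw (upstream NaN?)");
        Sig.slice(k) = S;
        arma::mat L = arma::chol(S, "lower");
        Li.slice(k) = arma::inv(arma::trimatl(L));
        logdet(k) = 2.0 * arma::accu(arma::log(L.diag()));
        arma::vec zz(P);
        for (int p = 0; p < P; ++p) zz(p) = draw_norm(g_th);
        arma::vec m = nu_k + (L * zz) / std::sqrt(tau_k);
        mu.row(k) = m.t();
      }
    }
  };

  auto update_omega = [&]() {
    if (!use_image) return;
    double wl = tempered ? w : 1.0;
    for (int k = 0; k < K; ++k) {
      arma::vec alpha = alpha0;
      for (int i = 0; i < N; ++i)
        if (z(i) == k)
          for (int q = 0; q < Q; ++q) alpha(q) += wl * V(i, q);
      arma::vec gdraw(Q);
      double tot = 0.0;
      for (int q = 0; q < Q; ++q) {
        double x = draw_gamma(g_om, alpha(q), 1.0);
        if (x < 1e-300) x = 1e-300;
        gdraw(q) = x;
        tot += x;
      }
      omega.row(k) = (gdraw / tot).t();
    }
    logom = arma::log(omega);
  };

  auto update_z = [&]() {
    arma::vec lp(K);
    for (int i = 0; i < N; ++i) {
      arma::vec ycol = Y.row(i).t();
      for (int k = 0; k < K; ++k) {
        double l;
        if (diagonal)
          l = diag_logpdf(Y.row(i), mu.row(k), sig2.row(k));
        else
          l = mvn_logpdf(ycol, mu.row(k).t(), Li.slice(k), logdet(k));
        if (use_image && w > 0.0 && mtot(i) > 0) {
          double lm = logcoef(i);
          for (int q = 0; q < Q; ++q) lm += V(i, q) * logom(k, q);
          l += w * lm;
        }
        int nn = 0;
        for (int j : nb[i]) nn += (z(j) == k);
        lp(k) = l + dvec(k) + f * nn;
      }
      z(i) = draw_cat(g_z, normalize_log(lp));
    }
  };

  // parameter draws given the initial labels, then sweep
  update_theta();
  update_omega();
  for (int it = 0; it < n_iter; ++it) {
    update_z();
    update_theta();
    update_omega();
    if (!mu.is_finite()) stop("chain produced NaN at iteration " +
                              std::to_string(it + 1));
    if (it >= burn_in) {
      int u = it - burn_in;
      for (int i = 0; i < N; ++i) zdraws(u, i) = z(i) + 1;
      mudraws.slice(u) = mu;
      if (diagonal) {
        arma::mat flat(K, P * P, arma::fill::zeros);
        for (int k = 0; k < K; ++k)
          for (int p = 0; p < P; ++p) flat(k, p * P + p) = sig2(k, p);
        sigdraws.slice(u) = flat;
      } else {
        arma::mat flat(K, P * P);
        for (int k = 0; k < K; ++k)
          flat.row(k) = arma::vectorise(Sig.slice(k)).t();
        sigdraws.slice(u) = flat;
      }
      omdraws.slice(u) = use_image ? omega : arma::mat(K, Q, arma::fill::zeros);
    }
  }

  return List::create(_["z"] = zdraws, _["mu"] = mudraws,
                      _["sigma"] = sigdraws, _["omega"] = omdraws);
}

// Full-conditional label probabilities for one spot (normalized), matching
// the sweep kernel above; exported for verification and diagnostics.
// [[Rcpp::export]]
arma::vec z_cond_probs_cpp(const arma::vec &y, const arma::ivec &v,
                           const arma::mat &mu, const arma::mat &sigflat,
                           const arma::mat &omega, const arma::ivec &nbr_count,
                           const arma::vec &dvec, double f, double w,
                           bool diagonal, bool use_image) {
  const int K = mu.n_rows, P = mu.n_cols, Q = omega.n_cols;
  int m = arma::accu(v);
  double logcoef = std::lgamma(m + 1.0);
  for (int q = 0; q < Q; ++q) logcoef -= std::lgamma(v(q) + 1.0);
  arma::vec lp(K);
  for (int k = 0; k < K; ++k) {
    arma::mat S = arma::reshape(sigflat.row(k), P, P);
    double l;
    if (diagonal) {
      arma::rowvec s2 = S.diag().t();
      l = diag_logpdf(y.t(), mu.row(k), s2);
    } else {
      arma::mat L = arma::chol(S, "lower");
      l = mvn_logpdf(y, mu.row(k).t(),
                     arma::inv(arma::trimatl(L)),
                     2.0 * arma::accu(arma::log(L.diag())));
    }
    if (use_image && w > 0.0 && m > 0) {
      double lm = logcoef;
      for (int q = 0; q < Q; ++q) lm += v(q) * std::log(omega(k, q));
      l += w * lm;
    }
    lp(k) = l + dvec(k) + f * nbr_count(k);
  }
  return normalize_log(lp);
}

// [[Rcpp::export]]
List niw_posterior_cpp(const arma::mat &Y, const arma::ivec &z, int k,
                       const arma::vec &nu0, double tau0, double eta0,
                       const arma::mat &Phi0) {
  PriorSet pr{nu0, tau0, eta0, Phi0, 0, 0, arma::vec(), arma::vec(), 0, 0};
  double tau_k, eta_k;
  arma::vec nu_k;
  arma::mat Phi_k;
  niw_post(Y, z - 1, k - 1, pr, tau_k, eta_k, nu_k, Phi_k);
  return List::create(_["tau"] = tau_k, _["eta"] = eta_k, _["nu"] = nu_k,
                      _["Phi"] = Phi_k);
}

// [[Rcpp::export]]
List nig_posterior_cpp(const arma::mat &Y, const arma::ivec &z, int k,
                       const arma::vec &nu0, double tau0, double ig_a,
                       double ig_b) {
  PriorSet pr{nu0, tau0, 0, arma::mat(), ig_a, ig_b,
              arma::vec(), arma::vec(), 0, 0};
  double tau_k, shape_k;
  arma::vec nu_k, rate_k;
  nig_post(Y, z - 1, k - 1, pr, tau_k, shape_k, nu_k, rate_k);
  return List::create(_["tau"] = tau_k, _["shape"] = shape_k, _["nu"] = nu_k,
                      _["rate"] = rate_k);
}

// [[Rcpp::export]]
List sample_niw_cpp(int n, const arma::vec &nu, double tau, double eta,
                    const arma::mat &Phi, int seed) {
  const int P = nu.n_elem;
  rng_t g = make_stream(seed, 2);
  arma::mat mus(n, P);
  arma::cube Sigs(P, P, n);
  for (int r = 0; r < n; ++r) {
    arma::mat S = draw_invwishart(g, eta, Phi);
    Sigs.slice(r) = S;
    arma::mat L = arma::chol(S, "lower");
    arma::vec zz(P);
    for (int p = 0; p < P; ++p) zz(p) = draw_norm(g);
    mus.row(r) = (nu + (L * zz) / std::sqrt(tau)).t();
  }
  return List::create(_["mu"] = mus, _["Sigma"] = Sigs);
}

// [[Rcpp::export]]
List sample_nig_cpp(int n, const arma::vec &nu, double tau, double shape,
                    const arma::vec &rate, int seed) {
  const int P = nu.n_elem;
  rng_t g = make_stream(seed, 2);
  arma::mat mus(n, P), s2s(n, P);
  for (int r = 0; r < n; ++r)
    for (int p = 0; p < P; ++p) {
      double s2 = 1.0 / draw_gamma(g, shape, rate(p));
      s2s(r, p) = s2;
      mus(r, p) = nu(p) + std::sqrt(s2 / tau) * draw_norm(g);
    }
  return List::create(_["mu"] = mus, _["sig2"] = s2s);
}

// [[Rcpp::export]]
arma::mat sample_dirichlet_cpp(int n, const arma::vec &alpha, int seed) {
  const int Q = alpha.n_elem;
  rng_t g = make_stream(seed, 3);
  arma::mat out(n, Q);
  for (int r = 0; r < n; ++r) {
    double tot = 0.0;
    for (int q = 0; q < Q; ++q) {
      double x = draw_gamma(g, alpha(q), 1.0);
      if (x < 1e-300) x = 1e-300;
      out(r, q) = x;
      tot += x;
    }
    out.row(r) /= tot;
  }
  return out;
}
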