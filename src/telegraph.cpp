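// Compiled core: truncated CME steady state for generalized telegraph models,
// exact stochastic simulation (SSA), and the adaptive Metropolis-Hastings loop.
// Gene states are 0..S-1; the last state is the sole active (ejecting) state.
// Joint state space is (gene state, mRNA count 0..N); the stationary vector is
// obtained by block-tridiagonal elimination over mRNA levels, leaving an SxS
// null-space problem at the truncation boundary.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG (splitmix64 + Box-Muller), bit-reproducible across runs
// ---------------------------------------------------------------------------
struct SmallRNG {
  uint64_t state;
  bool have_spare;
  double spare;
  explicit SmallRNG(uint64_t seed) : state(seed), have_spare(false), spare(0.0) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0,1)
  double unif() { return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    spare = r * std::sin(2.0 * M_PI * v);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * v);
  }
  double expo() { return -std::log(unif()); }
};

// ---------------------------------------------------------------------------
// tiny dense linear algebra on S x S row-major matrices (S <= 3 in practice)
// ---------------------------------------------------------------------------
static bool solve_small(std::vector<double> A, std::vector<double>& b, int S) {
  for (int c = 0; c < S; ++c) {
    int p = c; double best = std::fabs(A[c * S + c]);
    for (int r = c + 1; r < S; ++r) {
      double v = std::fabs(A[r * S + c]);
      if (v > best) { best = v; p = r; }
    }
    if (best < 1e-300) return false;
    if (p != c) {
      for (int j = 0; j < S; ++j) std::swap(A[c * S + j], A[p * S + j]);
      std::swap(b[c], b[p]);
    }
    double d = A[c * S + c];
    for (int r = c + 1; r < S; ++r) {
      double f = A[r * S + c] / d; if (f == 0.0) continue;
      for (int j = c; j < S; ++j) A[r * S + j] -= f * A[c * S + j];
      b[r] -= f * b[c];
    }
  }
  for (int r = S - 1; r >= 0; --r) {
    double s = b[r];
    for (int j = r + 1; j < S; ++j) s -= A[r * S + j] * b[j];
    b[r] = s / A[r * S + r];
  }
  return true;
}

// X = inv(A); returns false if singular
static bool inv_small(const std::vector<double>& A, std::vector<double>& X, int S) {
  X.assign(S * S, 0.0);
  for (int k = 0; k < S; ++k) {
    std::vector<double> e(S, 0.0); e[k] = 1.0;
    if (!solve_small(A, e, S)) return false;
    for (int i = 0; i < S; ++i) X[i * S + k] = e[i];
  }
  return true;
}

// lower Cholesky factor of a small SPD matrix (row-major); false if not PD
static bool chol_small(const std::vector<double>& A, std::vector<double>& L,
                       int d) {
  L.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

// normalized null vector of a (numerically) rank S-1 matrix F:
// solve (F^T F + 11^T) v = 1, the unique v with F v = 0, sum(v) = 1
static bool null_vec_small(const std::vector<double>& F, std::vector<double>& v, int S) {
  if (S == 1) { v.assign(1, 1.0); return true; }
  std::vector<double> G(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) {
      double s = 1.0; // 11^T border enforcing sum-to-one
      for (int k = 0; k < S; ++k) s += F[k * S + i] * F[k * S + j];
      G[i * S + j] = s;
    }
  v.assign(S, 1.0);
  return solve_small(G, v, S);
}

// transposed generator of the gene-state switching chain from the rate matrix
// sw (row i, col j = rate i -> j, diagonal ignored)
static void switching_mt(const std::vector<double>& sw, int S, std::vector<double>& Mt) {
  Mt.assign(S * S, 0.0);
  for (int i = 0; i < S; ++i) {
    double out = 0.0;
    for (int j = 0; j < S; ++j) {
      if (i == j) continue;
      out += sw[i * S + j];
      Mt[j * S + i] += sw[i * S + j];
    }
    Mt[i * S + i] -= out;
  }
}

// stationary distribution of the switching chain alone
static bool switching_stationary(const std::vector<double>& sw, int S, std::vector<double>& pi) {
  if (S == 1) { pi.assign(1, 1.0); return true; }
  std::vector<double> Mt;
  switching_mt(sw, S, Mt);
  return null_vec_small(Mt, pi, S);
}

// ---------------------------------------------------------------------------
// truncated CME steady state, marginalized over gene states
// ---------------------------------------------------------------------------
// Block-tridiagonal elimination from BOTH boundaries towards the level m*
// nearest the stationary mean, where the S x S null-space problem is solved;
// the stationary vector is then rebuilt by sweeps outward from m*, which are
// contractive in both directions (roundoff decays with the solution), so the
// head and the tail are both computed stably. Because mRNA is created only
// in the active state, each top-side fold has the rank-one form
// p_{m+1} = r_m * p_m[active].
static bool cme_steady_fixed(const std::vector<double>& sw, int S, double nu,
                             double kd, int N, std::vector<double>& marg) {
  marg.assign(N + 1, 0.0);
  if (nu <= 0.0) { marg[0] = 1.0; return true; }
  std::vector<double> Mt;
  switching_mt(sw, S, Mt);
  int act = S - 1;
  // matching level: the stationary mean, clamped to [0, N]
  std::vector<double> pi;
  double p_on = 1.0;
  if (switching_stationary(sw, S, pi)) p_on = pi[S - 1];
  int mstar = (int)std::lround(nu * p_on / kd);
  if (mstar < 0) mstar = 0;
  if (mstar > N) mstar = N;

  std::vector<double> G(S * S), x(S);
  // bottom elimination: p_m = Smat[m] p_{m+1} for m = 0..mstar-1
  std::vector<std::vector<double> > Smat(mstar);
  for (int m = 0; m < mstar; ++m) {
    for (int i = 0; i < S * S; ++i) G[i] = Mt[i];
    G[act * S + act] -= nu;
    for (int i = 0; i < S; ++i) G[i * S + i] -= m * kd;
    if (m > 0)
      for (int j = 0; j < S; ++j)
        G[act * S + j] += nu * Smat[m - 1][act * S + j];
    std::vector<double> X;
    if (!inv_small(G, X, S)) return false;
    Smat[m].resize(S * S);
    double c = -(m + 1) * kd;
    for (int i = 0; i < S * S; ++i) Smat[m][i] = c * X[i];
  }
  // top elimination: p_{m+1} = rvec[m] * p_m[act] for m = N-1..mstar
  std::vector<std::vector<double> > rvec(N);
  if (mstar <= N - 1) {
    for (int i = 0; i < S * S; ++i) G[i] = Mt[i];
    for (int i = 0; i < S; ++i) G[i * S + i] -= N * kd;
    x.assign(S, 0.0); x[act] = 1.0;
    if (!solve_small(G, x, S)) return false;
    rvec[N - 1].resize(S);
    for (int i = 0; i < S; ++i) rvec[N - 1][i] = -nu * x[i];
    for (int m = N - 1; m >= mstar + 1; --m) {
      for (int i = 0; i < S * S; ++i) G[i] = Mt[i];
      G[act * S + act] -= nu;
      for (int i = 0; i < S; ++i) {
        G[i * S + i] -= m * kd;
        G[i * S + act] += (m + 1) * kd * rvec[m][i];
      }
      x.assign(S, 0.0); x[act] = 1.0;
      if (!solve_small(G, x, S)) return false;
      rvec[m - 1].resize(S);
      for (int i = 0; i < S; ++i) rvec[m - 1][i] = -nu * x[i];
    }
  }
  // matching block at mstar
  std::vector<double> F(S * S);
  for (int i = 0; i < S * S; ++i) F[i] = Mt[i];
  for (int i = 0; i < S; ++i) F[i * S + i] -= mstar * kd;
  if (mstar < N) F[act * S + act] -= nu;
  if (mstar >= 1)
    for (int j = 0; j < S; ++j)
      F[act * S + j] += nu * Smat[mstar - 1][act * S + j];
  if (mstar <= N - 1)
    for (int i = 0; i < S; ++i)
      F[i * S + act] += (mstar + 1) * kd * rvec[mstar][i];
  std::vector<double> pstar;
  if (!null_vec_small(F, pstar, S)) return false;
  for (int i = 0; i < S; ++i) if (pstar[i] < 0.0) pstar[i] = 0.0;

  std::vector<std::vector<double> > P(N + 1);
  P[mstar] = pstar;
  // downward sweep (head)
  for (int m = mstar - 1; m >= 0; --m) {
    P[m].assign(S, 0.0);
    for (int i = 0; i < S; ++i) {
      double s = 0.0;
      for (int j = 0; j < S; ++j) s += Smat[m][i * S + j] * P[m + 1][j];
      P[m][i] = s > 0.0 ? s : 0.0;
    }
  }
  // upward sweep (tail)
  for (int m = mstar; m < N; ++m) {
    double pact = P[m][act];
    P[m + 1].assign(S, 0.0);
    for (int i = 0; i < S; ++i) {
      double v = rvec[m][i] * pact;
      P[m + 1][i] = v > 0.0 ? v : 0.0;
    }
  }
  double tot = 0.0;
  for (int m = 0; m <= N; ++m) {
    double s = 0.0;
    for (int i = 0; i < S; ++i) s += P[m][i];
    marg[m] = s; tot += s;
  }
  if (!(tot > 0.0) || !std::isfinite(tot)) return false;
  for (int m = 0; m <= N; ++m) marg[m] /= tot;
  return true;
}

// heuristic starting truncation from moment estimates
static int trunc_start(const std::vector<double>& sw, int S, double nu, double kd,
                       int min_trunc) {
  std::vector<double> pi;
  double p_on = 1.0;
  if (switching_stationary(sw, S, pi)) p_on = pi[S - 1];
  double mean = nu * p_on / kd;
  double off_on = 0.0; // total rate out of the active state
  for (int j = 0; j < S - 1; ++j) off_on += sw[(S - 1) * S + j];
  double burst = (S == 1) ? 0.0 : nu / (off_on + kd);
  double var = mean * (1.0 + burst);
  int N = (int)(4.0 * std::ceil(mean) + 10.0 * std::ceil(std::sqrt(var)));
  if (N < min_trunc) N = min_trunc;
  if (N < 8) N = 8;
  return N;
}

// adaptive truncation: double N until the tail mass beyond N-1 drops below tol
static bool cme_steady_adaptive(const std::vector<double>& sw, int S, double nu,
                                double kd, int min_trunc, double tol, int cap,
                                std::vector<double>& marg, int& N_used) {
  if (nu <= 0.0) {
    int N = std::max(min_trunc, 1);
    marg.assign(N + 1, 0.0); marg[0] = 1.0; N_used = N;
    return true;
  }
  int N = trunc_start(sw, S, nu, kd, min_trunc);
  if (N > cap) N = cap;
  for (;;) {
    if (!cme_steady_fixed(sw, S, nu, kd, N, marg)) return false;
    double tail = marg[N] + (N >= 1 ? marg[N - 1] : 0.0);
    if (tail < tol) { N_used = N; return true; }
    if (N >= cap) return false;
    N = std::min(2 * N, cap);
  }
}

// n-fold self-convolution of p, computed only up to max_m
static void convolve_self(const std::vector<double>& p, int n_alleles, int max_m,
                          std::vector<double>& out) {
  int L = std::min((int)p.size() - 1, max_m);
  out.assign(max_m + 1, 0.0);
  for (int m = 0; m <= L; ++m) out[m] = p[m];
  std::vector<double> tmp(max_m + 1);
  for (int a = 1; a < n_alleles; ++a) {
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int m = 0; m <= max_m; ++m) {
      double acc = 0.0;
      int lo = std::max(0, m - L);
      for (int k = lo; k <= m; ++k) acc += out[k] * (m - k <= L ? p[m - k] : 0.0);
      tmp[m] = acc;
    }
    out.swap(tmp);
  }
}

// ---------------------------------------------------------------------------
// exported: steady state
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cme_steady_state_cpp(NumericMatrix sw, double nu, double kd, int trunc) {
  int S = sw.nrow();
  std::vector<double> swv(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) swv[i * S + j] = sw(i, j);
  std::vector<double> marg;
  if (!cme_steady_fixed(swv, S, nu, kd, trunc, marg))
    stop("degenerate null space: steady state could not be computed");
  return NumericVector(marg.begin(), marg.end());
}

// [[Rcpp::export]]
List cme_steady_adaptive_cpp(NumericMatrix sw, double nu, double kd, int min_trunc,
                             double tol, int cap) {
  int S = sw.nrow();
  std::vector<double> swv(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) swv[i * S + j] = sw(i, j);
  std::vector<double> marg; int N_used = 0;
  if (!cme_steady_adaptive(swv, S, nu, kd, min_trunc, tol, cap, marg, N_used))
    stop("distribution not concentrated below the truncation cap");
  return List::create(_["probs"] = NumericVector(marg.begin(), marg.end()),
                      _["truncation"] = N_used);
}

// [[Rcpp::export]]
NumericVector switching_stationary_cpp(NumericMatrix sw) {
  int S = sw.nrow();
  std::vector<double> swv(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) swv[i * S + j] = sw(i, j);
  std::vector<double> pi;
  if (!switching_stationary(swv, S, pi))
    stop("switching chain has no unique stationary distribution");
  return NumericVector(pi.begin(), pi.end());
}

// ---------------------------------------------------------------------------
// exported: exact stochastic simulation (one count per cell at t = burn_in)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector gillespie_counts_cpp(NumericMatrix sw, double nu, double kd,
                                   int n_cells, double burn_in, int init_m,
                                   NumericVector init_state_probs, double seed) {
  int S = sw.nrow();
  std::vector<double> swv(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) swv[i * S + j] = (i == j) ? 0.0 : sw(i, j);
  SmallRNG rng((uint64_t)seed);
  IntegerVector out(n_cells);
  for (int cell = 0; cell < n_cells; ++cell) {
    // initial gene state from the supplied (stationary) distribution
    double u = rng.unif(); int g = S - 1; double acc = 0.0;
    for (int i = 0; i < S; ++i) { acc += init_state_probs[i]; if (u <= acc) { g = i; break; } }
    long m = init_m;
    double t = 0.0;
    for (;;) {
      double r_sw = 0.0;
      for (int j = 0; j < S; ++j) r_sw += swv[g * S + j];
      double r_ej = (g == S - 1) ? nu : 0.0;
      double r_dec = m * kd;
      double R = r_sw + r_ej + r_dec;
      if (R <= 0.0) break; // absorbing (no events possible)
      t += rng.expo() / R;
      if (t > burn_in) break;
      double x = rng.unif() * R;
      if (x < r_sw) {
        for (int j = 0; j < S; ++j) {
          x -= swv[g * S + j];
          if (x < 0.0) { g = j; break; }
        }
      } else if (x < r_sw + r_ej) {
        ++m;
      } else {
        --m;
      }
    }
    out[cell] = (int)m;
  }
  return out;
}

// ---------------------------------------------------------------------------
// exported: adaptive random-scan Metropolis-Hastings over log rates
// ---------------------------------------------------------------------------

struct PostEval {
  const std::vector<int>& hist; // hist[m] = number of cells with count m
  int max_m, S, n_sw, n_alleles, cap;
  const std::vector<int>& from_i; // free switching-rate positions
  const std::vector<int>& to_j;
  double kd, tol;
  const std::vector<double>& mu; // normal prior on log rates
  const std::vector<double>& sd;
  long n_cells;

  // returns log posterior; -inf if invalid
  double operator()(const std::vector<double>& theta, double* loglik_out) const {
    int n_free = n_sw + 1;
    for (int i = 0; i < n_free; ++i)
      if (theta[i] < -30.0 || theta[i] > 12.0) return R_NegInf;
    std::vector<double> sw(S * S, 0.0);
    for (int k = 0; k < n_sw; ++k) sw[from_i[k] * S + to_j[k]] = std::exp(theta[k]);
    double nu = std::exp(theta[n_sw]);
    std::vector<double> marg; int N_used = 0;
    if (!cme_steady_adaptive(sw, S, nu, kd, max_m + 5, tol, cap, marg, N_used))
      return R_NegInf;
    std::vector<double> pm;
    if (n_alleles > 1) convolve_self(marg, n_alleles, max_m, pm);
    else { pm.assign(marg.begin(), marg.begin() + max_m + 1); }
    double ll = 0.0;
    for (int m = 0; m <= max_m; ++m) {
      if (hist[m] == 0) continue;
      double p = pm[m];
      if (p < 1e-300) p = 1e-300;
      ll += hist[m] * std::log(p);
    }
    if (loglik_out) *loglik_out = ll;
    double lp = ll;
    for (int i = 0; i < n_free; ++i) {
      double z = (theta[i] - mu[i]) / sd[i];
      lp += -0.5 * z * z - std::log(sd[i]);
    }
    return lp;
  }
};

// [[Rcpp::export]]
List mh_chain_cpp(IntegerVector hist, int n_states, int n_alleles,
                  IntegerVector sw_from, IntegerVector sw_to, double kd,
                  NumericVector prior_mu, NumericVector prior_sd,
                  NumericVector theta_init, int n_samples, int n_warmup,
                  double scale_init, double trunc_tol, int trunc_cap,
                  double seed) {
  int max_m = hist.size() - 1;
  int n_sw = sw_from.size();
  int n_free = n_sw + 1;
  std::vector<int> histv(hist.begin(), hist.end());
  std::vector<int> fi(sw_from.begin(), sw_from.end());
  std::vector<int> tj(sw_to.begin(), sw_to.end());
  std::vector<double> mu(prior_mu.begin(), prior_mu.end());
  std::vector<double> sd(prior_sd.begin(), prior_sd.end());
  long n_cells = 0;
  for (int m = 0; m <= max_m; ++m) n_cells += histv[m];
  PostEval post{histv, max_m, n_states, n_sw, n_alleles, trunc_cap,
                fi, tj, kd, trunc_tol, mu, sd, n_cells};

  SmallRNG rng((uint64_t)seed);
  // parallel tempering: three states per chain, the likelihood tempered by
  // betaT (the prior stays cold, so the hottest state is near the prior and
  // crosses between posterior modes; swap moves propagate mixing down)
  const int n_temp = 3;
  const double betaT[n_temp] = {1.0, 0.5, 0.25};
  std::vector<std::vector<double> > th(n_temp,
      std::vector<double>(theta_init.begin(), theta_init.end()));
  std::vector<double> ll_t(n_temp), tgt_t(n_temp), pr_t(n_temp);
  auto log_prior_of = [&](const std::vector<double>& t) {
    double lp = 0.0;
    for (int i = 0; i < n_free; ++i) {
      double zz = (t[i] - mu[i]) / sd[i];
      lp += -0.5 * zz * zz - std::log(sd[i]);
    }
    return lp;
  };
  {
    double ll0 = 0.0;
    double lp0 = post(th[0], &ll0);
    if (!std::isfinite(lp0)) {
      for (int t = 0; t < n_temp; ++t) th[t] = mu;
      lp0 = post(th[0], &ll0);
    }
    if (!std::isfinite(lp0))
      stop("could not find a valid starting point for the chain");
    for (int t = 0; t < n_temp; ++t) {
      ll_t[t] = ll0;
      pr_t[t] = log_prior_of(th[t]);
      tgt_t[t] = betaT[t] * ll0 + pr_t[t];
    }
  }

  std::vector<std::vector<double> > scale(n_temp,
      std::vector<double>(n_free, scale_init));
  std::vector<std::vector<int> > batch_prop(n_temp,
      std::vector<int>(n_free, 0)), batch_acc(n_temp,
      std::vector<int>(n_free, 0));
  int batch_num = 1;
  int n_keep = n_samples - n_warmup;
  NumericMatrix draws(n_keep, n_free);
  NumericVector logliks(n_keep);
  long n_acc = 0, n_moves = 0;

  // running moments of the cold state for the joint-proposal covariance
  int w_collect = n_warmup / 4;
  int w_joint = n_warmup / 2;
  long mom_n = 0;
  std::vector<double> mom_sum(n_free, 0.0), mom_sq(n_free * n_free, 0.0);
  std::vector<double> L;
  bool have_L = false;
  double jscale = 2.38 / std::sqrt((double)n_free);
  int jbatch_prop = 0, jbatch_acc = 0;

  auto refresh_L = [&]() {
    if (mom_n < 10) return;
    std::vector<double> C(n_free * n_free);
    for (int i = 0; i < n_free; ++i)
      for (int j = 0; j < n_free; ++j) {
        double c = (mom_sq[i * n_free + j] -
                    mom_sum[i] * mom_sum[j] / mom_n) / (mom_n - 1);
        C[i * n_free + j] = c;
        if (i == j) C[i * n_free + j] += 1e-6;
      }
    have_L = chol_small(C, L, n_free);
  };

  std::vector<double> prop(n_free), z(n_free);
  for (int it = 0; it < n_samples; ++it) {
    for (int t = 0; t < n_temp; ++t) {
      double u_kind = rng.unif();
      // hot states use prior-independence moves more aggressively
      double p_indep = (t == 0) ? 0.05 : 0.15;
      bool indep = u_kind < p_indep;
      bool joint = !indep && t == 0 && have_L && it >= w_joint &&
        u_kind < 0.55;
      prop = th[t];
      int j = 0;
      if (indep) {
        if (rng.unif() < 0.5) {
          for (int k = 0; k < n_free; ++k)
            prop[k] = mu[k] + sd[k] * rng.normal();
        } else {
          int k = (int)(rng.unif() * n_free);
          if (k >= n_free) k = n_free - 1;
          prop[k] = mu[k] + sd[k] * rng.normal();
        }
      } else if (joint) {
        for (int k = 0; k < n_free; ++k) z[k] = rng.normal();
        for (int i = 0; i < n_free; ++i) {
          double s = 0.0;
          for (int k = 0; k <= i; ++k) s += L[i * n_free + k] * z[k];
          prop[i] += jscale * s;
        }
      } else {
        j = (int)(rng.unif() * n_free);
        if (j >= n_free) j = n_free - 1;
        prop[j] += scale[t][j] * rng.normal();
      }
      double ll_p = 0.0;
      double lp_full = post(prop, &ll_p); // ll + cold prior
      bool ok = std::isfinite(lp_full);
      double pr_p = ok ? (lp_full - ll_p) : R_NegInf;
      double tgt_p = betaT[t] * ll_p + pr_p;
      // prior-independence move: the proposal density cancels the prior
      double log_alpha = indep ? (betaT[t] * (ll_p - ll_t[t]))
                               : (tgt_p - tgt_t[t]);
      bool accepted = ok && std::log(rng.unif()) < log_alpha;
      if (accepted) {
        th[t] = prop; ll_t[t] = ll_p; pr_t[t] = pr_p; tgt_t[t] = tgt_p;
      }
      if (t == 0) {
        ++n_moves;
        if (accepted) ++n_acc;
      }
      if (!indep) {
        if (joint) { ++jbatch_prop; if (accepted) ++jbatch_acc; }
        else { ++batch_prop[t][j]; if (accepted) ++batch_acc[t][j]; }
      }
    }
    // swap move between a random adjacent temperature pair
    {
      int t = (int)(rng.unif() * (n_temp - 1));
      if (t >= n_temp - 1) t = n_temp - 2;
      double log_alpha = (betaT[t] - betaT[t + 1]) * (ll_t[t + 1] - ll_t[t]);
      if (std::log(rng.unif()) < log_alpha) {
        std::swap(th[t], th[t + 1]);
        std::swap(ll_t[t], ll_t[t + 1]);
        std::swap(pr_t[t], pr_t[t + 1]);
        tgt_t[t] = betaT[t] * ll_t[t] + pr_t[t];
        tgt_t[t + 1] = betaT[t + 1] * ll_t[t + 1] + pr_t[t + 1];
      }
    }

    if (it >= w_collect && it < n_warmup) {
      ++mom_n;
      for (int i = 0; i < n_free; ++i) {
        mom_sum[i] += th[0][i];
        for (int k = 0; k <= i; ++k) {
          mom_sq[i * n_free + k] += th[0][i] * th[0][k];
          mom_sq[k * n_free + i] = mom_sq[i * n_free + k];
        }
      }
      if (it == w_joint || (it > w_joint && (it - w_joint) % 1000 == 0))
        refresh_L();
    }
    // warmup adaptation toward 20-40% acceptance per temperature
    if (it < n_warmup) {
      bool batch_done = true;
      for (int k = 0; k < n_free; ++k)
        if (batch_prop[0][k] < 50 / n_free + 1) { batch_done = false; break; }
      if (batch_done) {
        double delta = std::min(0.25, 1.0 / std::sqrt((double)batch_num));
        for (int t = 0; t < n_temp; ++t)
          for (int k = 0; k < n_free; ++k) {
            double ar = batch_prop[t][k] > 0 ?
              (double)batch_acc[t][k] / batch_prop[t][k] : 0.3;
            if (ar > 0.40) scale[t][k] *= std::exp(delta);
            else if (ar < 0.20) scale[t][k] *= std::exp(-delta);
            batch_prop[t][k] = 0; batch_acc[t][k] = 0;
          }
        ++batch_num;
      }
      if (jbatch_prop >= 50) {
        double ar = (double)jbatch_acc / jbatch_prop;
        double delta = std::min(0.25, 1.0 / std::sqrt((double)batch_num));
        if (ar > 0.40) jscale *= std::exp(delta);
        else if (ar < 0.20) jscale *= std::exp(-delta);
        jbatch_prop = 0; jbatch_acc = 0;
      }
    }
    if (it >= n_warmup) {
      int r = it - n_warmup;
      for (int k = 0; k < n_free; ++k) draws(r, k) = th[0][k];
      logliks[r] = ll_t[0];
    }
  }
  return List::create(_["draws"] = draws, _["loglik"] = logliks,
                      _["acceptance"] = (double)n_acc / n_moves,
                      _["scales"] = NumericVector(scale[0].begin(),
                                                  scale[0].end()));
}

// log P(m) for m = 0..max_m at each draw of log rates (rows of `draws`)
// [[Rcpp::export]]
NumericMatrix logprob_matrix_cpp(NumericMatrix draws, int n_states, int n_alleles,
                                 IntegerVector sw_from, IntegerVector sw_to,
                                 double kd, int max_m, double trunc_tol,
                                 int trunc_cap) {
  int n_draws = draws.nrow();
  int n_sw = sw_from.size();
  int S = n_states;
  NumericMatrix out(n_draws, max_m + 1);
  for (int d = 0; d < n_draws; ++d) {
    std::vector<double> sw(S * S, 0.0);
    for (int k = 0; k < n_sw; ++k)
      sw[sw_from[k] * S + sw_to[k]] = std::exp(draws(d, k));
    double nu = std::exp(draws(d, n_sw));
    std::vector<double> marg; int N_used = 0;
    if (!cme_steady_adaptive(sw, S, nu, kd, max_m + 5, trunc_tol, trunc_cap,
                             marg, N_used)) {
      for (int m = 0; m <= max_m; ++m) out(d, m) = std::log(1e-300);
      continue;
    }
    std::vector<double> pm;
    if (n_alleles > 1) convolve_self(marg, n_alleles, max_m, pm);
    else pm.assign(marg.begin(), marg.begin() + max_m + 1);
    for (int m = 0; m <= max_m; ++m) {
      double p = pm[m] < 1e-300 ? 1e-300 : pm[m];
      out(d, m) = std::log(p);
    }
  }
  return out;
}
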