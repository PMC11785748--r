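// Selection-mutation Markov chain over the discrete strategy simplex:
// hypergeometric fitness from a precomputed group-payoff table, pairwise
// comparison (Fermi) transition probabilities, sparse stationary solve,
// and seeded trajectory sampling. Hot paths only; all contracts are
// enforced at the R level.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Pascal table: ch(n, k) for 0 <= n <= nmax, 0 <= k <= kmax.
// Entries are exact in double for the sizes used here (n <= Z + S).
struct ChooseTab {
  int nmax, kmax;
  std::vector<double> v;
  ChooseTab(int nmax_, int kmax_) : nmax(nmax_), kmax(kmax_),
      v((size_t)(nmax_ + 1) * (kmax_ + 1), 0.0) {
    for (int n = 0; n <= nmax; ++n) {
      at(n, 0) = 1.0;
      for (int k = 1; k <= std::min(n, kmax); ++k) {
        at(n, k) = get(n - 1, k - 1) + get(n - 1, k);
      }
    }
  }
  double& at(int n, int k) { return v[(size_t)n * (kmax + 1) + k]; }
  double get(int n, int k) const {
    if (k < 0 || n < 0 || k > n) return 0.0;
    if (k > kmax) Rcpp::stop("choose table overflow");
    return v[(size_t)n * (kmax + 1) + k];
  }
};

// Lexicographic rank (0-based) of active counts c (sum Z) among all
// compositions of Z into S parts, via hockey-stick partial sums.
inline long rank_state(const int* c, int S, int Z, const ChooseTab& ch) {
  long r = 0;
  int rem = Z;
  for (int t = 0; t < S - 1; ++t) {
    int q = S - 1 - t;  // parts after this coordinate
    r += (long)(ch.get(rem + q, q) - ch.get(rem - c[t] + q, q));
    rem -= c[t];
  }
  return r;
}

}  // namespace

// All compositions of n into `parts` non-negative integers, increasing
// lexicographic order (row-major fill of the M x parts matrix).
// [[Rcpp::export]]
IntegerMatrix cpp_compositions(int n, int parts) {
  ChooseTab ch(n + parts, parts);
  const R_xlen_t M = (R_xlen_t)ch.get(n + parts - 1, parts - 1);
  IntegerMatrix out(M, parts);
  std::vector<int> cur(parts, 0);
  cur[parts - 1] = n;
  for (R_xlen_t m = 0;; ++m) {
    for (int t = 0; t < parts; ++t) out(m, t) = cur[t];
    if (m + 1 == M) break;
    // successor: carry one unit from the rightmost nonzero position into
    // the slot to its left, dumping the rest of the suffix into the tail
    int u = parts - 1;
    while (cur[u] == 0) --u;
    int suffix = 0;
    for (int v = u; v < parts; ++v) { suffix += cur[v]; cur[v] = 0; }
    cur[u - 1] += 1;
    cur[parts - 1] = suffix - 1;
  }
  return out;
}

// Build fitness for every state and the off-diagonal transition triplets.
// states: M x S active counts; comps: n_c x S co-player compositions
// (rows sum to N-1); pay: n_c x S payoff of focal strategy s joining
// co-players comps[k, ].
// [[Rcpp::export]]
List cpp_build_chain(IntegerMatrix states, int Z, int N, double mu,
                     double beta, int mut_targets, IntegerMatrix comps,
                     NumericMatrix pay) {
  const int M = states.nrow(), S = states.ncol(), nc = comps.nrow();
  ChooseTab ch(Z + S, std::max(N, S));
  const double denom = ch.get(Z - 1, N - 1);

  NumericMatrix F(M, S);
  NumericVector diag(M);
  std::vector<int> from, to;
  std::vector<double> val;
  from.reserve((size_t)M * S);
  to.reserve((size_t)M * S);
  val.reserve((size_t)M * S);

  std::vector<int> cnt(S), tgt(S);
  for (int m = 0; m < M; ++m) {
    for (int s = 0; s < S; ++s) cnt[s] = states(m, s);

    // hypergeometric fitness: average payoff over co-player draws
    for (int s = 0; s < S; ++s) {
      if (cnt[s] == 0) { F(m, s) = NA_REAL; continue; }
      double acc = 0.0;
      for (int k = 0; k < nc; ++k) {
        double w = ch.get(cnt[s] - 1, comps(k, s));
        for (int l = 0; w != 0.0 && l < S; ++l) {
          if (l != s) w *= ch.get(cnt[l], comps(k, l));
        }
        if (w != 0.0) acc += w * pay(k, s);
      }
      F(m, s) = acc / denom;
    }

    // pairwise comparison + mutation transitions
    double offsum = 0.0;
    for (int l = 0; l < S; ++l) {
      if (cnt[l] == 0) continue;
      for (int k = 0; k < S; ++k) {
        if (k == l) continue;
        double prob = mu * cnt[l] / ((double)mut_targets * Z);
        if (cnt[k] > 0) {
          double x = F(m, k) - F(m, l);
          prob += (1.0 - mu) * ((double)cnt[l] / Z) *
                  ((double)cnt[k] / (Z - 1)) /
                  (1.0 + std::exp(-beta * x));
        }
        if (prob > 0.0) {
          for (int t = 0; t < S; ++t) tgt[t] = cnt[t];
          --tgt[l];
          ++tgt[k];
          from.push_back(m + 1);
          to.push_back((int)rank_state(tgt.data(), S, Z, ch) + 1);
          val.push_back(prob);
          offsum += prob;
        }
      }
    }
    diag[m] = 1.0 - offsum;
  }

  return List::create(_["from"] = wrap(from), _["to"] = wrap(to),
                      _["x"] = wrap(val), _["diag"] = diag,
                      _["fitness"] = F);
}

namespace {

// assemble A = T^T from the off-diagonal moves (1-based from/to) plus the
// stay-put diagonal; temporaries are scoped so they free before the
// caller's workspace is allocated
arma::sp_mat chain_transpose(const IntegerVector& from,
                             const IntegerVector& to,
                             const NumericVector& x,
                             const NumericVector& diag, int M) {
  const R_xlen_t noff = x.size();
  arma::umat locs(2, noff + M);
  arma::vec vals(noff + M);
  for (R_xlen_t t = 0; t < noff; ++t) {
    locs(0, t) = (arma::uword)(to[t] - 1);
    locs(1, t) = (arma::uword)(from[t] - 1);
    vals[t] = x[t];
  }
  for (int k = 0; k < M; ++k) {
    locs(0, noff + k) = (arma::uword)k;
    locs(1, noff + k) = (arma::uword)k;
    vals[noff + k] = diag[k];
  }
  return arma::sp_mat(true, locs, vals, M, M);
}

}  // namespace

// Leading eigenvector (eigenvalue 1) of A = T^T (column-stochastic).
// Sparse Arnoldi; dense fallback for tiny systems.
// [[Rcpp::export]]
List cpp_stationary(IntegerVector from, IntegerVector to, NumericVector x,
                    NumericVector diag, int M, int subdim, int maxiter,
                    double tol) {
  arma::sp_mat A = chain_transpose(from, to, x, diag, M);

  arma::cx_vec eval;
  arma::cx_mat evec;
  bool ok = false;
  if (M >= 10) {
    arma::eigs_opts opts;
    opts.tol = tol;
    opts.maxiter = maxiter;
    opts.subdim = (arma::uword)std::min(subdim, M - 1);
    int k = std::min(3, (int)opts.subdim - 2);
    if (k >= 1) ok = arma::eigs_gen(eval, evec, A, k, "lm", opts);
  }
  if (!ok) {
    if (M > 4000) stop("sparse eigensolver failed to converge");
    arma::cx_vec dv;
    arma::cx_mat dm;
    arma::eig_gen(dv, dm, arma::mat(A));
    eval = dv;
    evec = dm;
  }

  // eigenvalue closest to 1
  arma::uword best = arma::index_min(arma::abs(eval - arma::cx_double(1.0)));
  arma::cx_vec v = evec.col(best);
  // rotate out the arbitrary complex phase, keep the real part
  arma::uword imax = arma::index_max(arma::abs(v));
  v *= std::conj(v(imax)) / std::abs(v(imax));
  arma::vec p = arma::real(v);
  if (arma::accu(p) < 0) p = -p;
  p.clamp(0.0, arma::datum::inf);
  p /= arma::accu(p);

  double residual = arma::norm(A * p - p, 1);
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["eigenvalue"] = std::abs(eval(best)),
                      _["residual"] = residual,
                      _["sparse"] = ok);
}

// Stationary vector via a grounded linear solve: pick a reference state g
// in the dominant basin (argmax of a short power-iteration estimate), fix
// p_g = 1, and solve (I - A) x = A e_g over the remaining states with
// Jacobi-preconditioned BiCGSTAB. Metastability costs a Krylov method only
// a few extra iterations (one outlier eigenvalue), whereas it stalls
// restarted eigensolvers, so this is the fast path for large chains.
// [[Rcpp::export]]
List cpp_stationary_ground(IntegerVector from, IntegerVector to,
                           NumericVector x, NumericVector diag, int M,
                           NumericVector v0, int power_steps, int maxiter,
                           double tol) {
  arma::sp_mat A = chain_transpose(from, to, x, diag, M);

  // rough estimate to locate the dominant basin (or reuse a warm start)
  arma::vec v = (v0.size() == M) ? as<arma::vec>(v0)
                                 : arma::vec(M, arma::fill::value(1.0 / M));
  for (int t = 0; t < power_steps; ++t) {
    v = A * v;
    v /= arma::accu(v);
  }
  arma::uword g = v.index_max();

  // masked operator: y = (I - A) x on the grounded subspace (x_g fixed 0)
  auto op = [&](const arma::vec& in) {
    arma::vec tmp = in;
    tmp(g) = 0.0;
    arma::vec out = tmp - A * tmp;
    out(g) = 0.0;
    return out;
  };
  arma::vec dinv(M);
  for (arma::uword i = 0; i < M; ++i) {
    double d = 1.0 - A(i, i);
    dinv(i) = (d > 1e-300) ? 1.0 / d : 1.0;
  }
  dinv(g) = 1.0;

  // rhs: inflow from the grounded state
  arma::vec eg(M, arma::fill::zeros);
  eg(g) = 1.0;
  arma::vec b = A * eg;
  b(g) = 0.0;

  // BiCGSTAB with Jacobi (right) preconditioning
  arma::vec xs(M, arma::fill::zeros);
  arma::vec r = b - op(xs);
  arma::vec rhat = r;
  double rho = 1.0, alpha = 1.0, omega = 1.0;
  arma::vec p(M, arma::fill::zeros), vv(M, arma::fill::zeros);
  const double bnorm = std::max(arma::norm(b, 2), 1e-300);
  bool converged = false;
  int it = 0;
  for (; it < maxiter; ++it) {
    double rho_new = arma::dot(rhat, r);
    if (std::abs(rho_new) < 1e-300) break;  // breakdown
    if (it == 0) {
      p = r;
    } else {
      double beta = (rho_new / rho) * (alpha / omega);
      p = r + beta * (p - omega * vv);
    }
    rho = rho_new;
    arma::vec phat = dinv % p;
    vv = op(phat);
    double denom = arma::dot(rhat, vv);
    if (std::abs(denom) < 1e-300) break;
    alpha = rho / denom;
    arma::vec s = r - alpha * vv;
    if (arma::norm(s, 2) / bnorm < tol) {
      xs += alpha * phat;
      converged = true;
      break;
    }
    arma::vec shat = dinv % s;
    arma::vec t2 = op(shat);
    double tt = arma::dot(t2, t2);
    if (tt < 1e-300) break;
    omega = arma::dot(t2, s) / tt;
    xs += alpha * phat + omega * shat;
    r = s - omega * t2;
    if (arma::norm(r, 2) / bnorm < tol) { converged = true; break; }
    if (std::abs(omega) < 1e-300) break;
  }

  xs(g) = 1.0;
  xs.clamp(0.0, arma::datum::inf);
  xs /= arma::accu(xs);
  double residual = arma::norm(A * xs - xs, 1);
  return List::create(_["p"] = NumericVector(xs.begin(), xs.end()),
                      _["residual"] = residual,
                      _["iterations"] = it + 1,
                      _["converged"] = converged);
}

// For every state, the hypergeometric group-sampling average of a
// per-composition value: sum_j value[j] * prod_l C(i_l, j_l) / C(Z, N).
// comps rows sum to N.
// [[Rcpp::export]]
NumericVector cpp_state_average(IntegerMatrix states, int Z, int N,
                                IntegerMatrix comps, NumericVector value) {
  const int M = states.nrow(), S = states.ncol(), nc = comps.nrow();
  ChooseTab ch(Z + S, std::max(N, S));
  const double denom = ch.get(Z, N);
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    double acc = 0.0;
    for (int k = 0; k < nc; ++k) {
      if (value[k] == 0.0) continue;
      double w = 1.0;
      for (int l = 0; w != 0.0 && l < S; ++l) {
        w *= ch.get(states(m, l), comps(k, l));
      }
      if (w != 0.0) acc += w * value[k];
    }
    out[m] = acc / denom;
  }
  return out;
}

// Sample a trajectory of the one-step chain. Off-diagonal transition
// probabilities in CSR form over state ranks (0-based); staying put takes
// the complementary probability. Uses R's RNG: seeding via set.seed() in R
// makes runs reproducible. Records the state every `stride` steps.
// [[Rcpp::export]]
IntegerVector cpp_simulate(IntegerVector rowptr, IntegerVector colidx,
                           NumericVector prob, int start, int steps,
                           int stride) {
  const int nrec = steps / stride + 1;
  IntegerVector rec(nrec);
  int cur = start, ri = 0;
  rec[ri++] = cur;
  for (int t = 1; t <= steps; ++t) {
    double u = unif_rand();
    double acc = 0.0;
    for (int e = rowptr[cur]; e < rowptr[cur + 1]; ++e) {
      acc += prob[e];
      if (u < acc) { cur = colidx[e]; break; }
    }
    if (t % stride == 0) rec[ri++] = cur;
  }
  return rec;
}
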