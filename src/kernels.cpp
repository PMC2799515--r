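#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Node layout (heap): internal nodes 1..G-1, leaf u (1..G) is node G-1+u.
// `lca` is the G x G matrix from hier_tree(): lca(u,v) is the node whose
// Bernoulli parameter pairs of vertices in leaves u and v contribute to.

static void compute_stats(const NumericMatrix &A, const NumericMatrix &tau,
                          const IntegerMatrix &lca, int G,
                          std::vector<double> &e, std::vector<double> &n) {
  const int N = A.nrow();
  const int M = 2 * G - 1;
  std::fill(e.begin(), e.end(), 0.0);
  std::fill(n.begin(), n.end(), 0.0);
  // At = A %*% tau ; S = tau' At ; C2 = tau' tau ; cs = colSums(tau)
  std::vector<double> At((size_t)N * G, 0.0), S((size_t)G * G, 0.0),
      C2((size_t)G * G, 0.0), cs(G, 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      double a = A(i, j);
      if (a != 0.0)
        for (int u = 0; u < G; ++u) At[(size_t)i * G + u] += a * tau(j, u);
    }
  for (int i = 0; i < N; ++i)
    for (int u = 0; u < G; ++u) {
      double tiu = tau(i, u);
      cs[u] += tiu;
      for (int v = u; v < G; ++v) {
        S[(size_t)u * G + v] += tiu * At[(size_t)i * G + v];
        C2[(size_t)u * G + v] += tiu * tau(i, v);
      }
    }
  for (int u = 0; u < G; ++u)
    for (int v = 0; v < u; ++v) {
      S[(size_t)u * G + v] = S[(size_t)v * G + u];
      C2[(size_t)u * G + v] = C2[(size_t)v * G + u];
    }
  for (int u = 0; u < G; ++u) {
    int id = G - 1 + u;  // leaf node (0-based index id in arrays of size M)
    double eu = S[(size_t)u * G + u] / 2.0;
    double pu = (cs[u] * cs[u] - C2[(size_t)u * G + u]) / 2.0;
    e[id] += eu;
    n[id] += pu - eu;
    for (int v = u + 1; v < G; ++v) {
      int r = lca(u, v) - 1;
      double euv = S[(size_t)u * G + v];
      double puv = cs[u] * cs[v] - C2[(size_t)u * G + v];
      e[r] += euv;
      n[r] += puv - euv;
    }
  }
  for (int r = 0; r < M; ++r) {
    if (e[r] < 0) e[r] = 0;
    if (n[r] < 0) n[r] = 0;
  }
}

// E[log p(theta)] - E[log q(theta)] summed over nodes, for q = Beta(a,b)
static double beta_terms(const std::vector<double> &a, const std::vector<double> &b,
                         double a0, double b0) {
  double val = 0.0;
  for (size_t r = 0; r < a.size(); ++r) {
    double dab = R::digamma(a[r] + b[r]);
    double El = R::digamma(a[r]) - dab;
    double El1 = R::digamma(b[r]) - dab;
    val += R::lbeta(a[r], b[r]) - R::lbeta(a0, b0) +
           (a0 - a[r]) * El + (b0 - b[r]) * El1;
  }
  return val;
}

// per-snapshot part of the bound (expected edge log-likelihood under the
// given node params, assignment entropy, uniform assignment prior); the
// Beta prior/entropy terms are added separately so they can be counted
// once when parameters are shared across snapshots
static double elbo_data(const NumericMatrix &A, const NumericMatrix &tau,
                        const IntegerMatrix &lca, int G,
                        const std::vector<double> &a, const std::vector<double> &b) {
  const int M = 2 * G - 1;
  std::vector<double> e(M), n(M);
  compute_stats(A, tau, lca, G, e, n);
  double val = 0.0;
  for (int r = 0; r < M; ++r) {
    double dab = R::digamma(a[r] + b[r]);
    val += e[r] * (R::digamma(a[r]) - dab) + n[r] * (R::digamma(b[r]) - dab);
  }
  const int N = tau.nrow();
  for (int i = 0; i < N; ++i)
    for (int u = 0; u < G; ++u) {
      double t = tau(i, u);
      if (t > 0) val -= t * std::log(t);
    }
  val -= N * std::log((double)G);  // uniform leaf prior on assignments
  return val;
}

// Fisher-Yates permutation of 0..n-1 using R's RNG
static void rand_perm(std::vector<int> &ord) {
  const int n = (int)ord.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// Coordinate descent for a snapshot series (T = 1, lambda = 0 is the
// static fit). Per global sweep and snapshot: tree-parameter update from
// the current expected counts, then one randomized asynchronous pass of
// coupled assignment updates. Objective traced: J = sum_t [ -ELBO_t +
// lambda * sum_{s in N(t)} KL(q_t || q_s) ] over shared active vertices.
// A warm-start phase of `warm_sweeps` sweeps multiplies the assignment
// field by `warm_mult` (> 1 sharpens the softmax toward hard moves); it
// breaks the symmetry of random initializations away from the
// all-in-one-leaf fixed point. The objective trace starts after it.
// With `share = true` one set of Beta node parameters is maintained from
// the counts summed over all snapshots (group-group interactions constant
// over the series); otherwise each snapshot keeps its own parameters.
// [[Rcpp::export]]
List cpp_fit_series(List A_list, List tau_list, List glob_list,
                    IntegerMatrix lca, int G, List nbr_list,
                    double lambda, double a0, double b0,
                    double tol, int max_sweeps,
                    int warm_sweeps, double warm_mult, bool share) {
  const int T = A_list.size();
  const int M = 2 * G - 1;
  std::vector<NumericMatrix> A(T), tau(T);
  std::vector<std::vector<int>> glob(T), nbr(T);
  int n_global = 0;
  for (int t = 0; t < T; ++t) {
    A[t] = as<NumericMatrix>(A_list[t]);
    tau[t] = clone(as<NumericMatrix>(tau_list[t]));
    IntegerVector g = glob_list[t];
    glob[t].assign(g.begin(), g.end());
    for (int k = 0; k < (int)glob[t].size(); ++k)
      if (glob[t][k] > n_global) n_global = glob[t][k];
    IntegerVector nb = nbr_list[t];
    nbr[t].assign(nb.begin(), nb.end());  // 1-based snapshot indices
  }
  // local row of global vertex v in snapshot t, or -1
  std::vector<std::vector<int>> loc(T, std::vector<int>(n_global + 1, -1));
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < (int)glob[t].size(); ++k) loc[t][glob[t][k]] = k;

  std::vector<std::vector<double>> av(T, std::vector<double>(M, a0)),
      bv(T, std::vector<double>(M, b0));
  std::vector<double> trace;
  bool converged = false;
  int sweeps_done = 0;
  const double TAU_FLOOR = 1e-12;

  std::vector<double> e(M), n(M), El(M), El1(M);
  const int total_sweeps = warm_sweeps + max_sweeps;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    const bool warm = sweep < warm_sweeps;
    const double mult = warm ? warm_mult : 1.0;
    std::vector<double> ElMs((size_t)G * G), El1Ms((size_t)G * G);
    if (share) {
      // one conjugate update from the counts summed over all snapshots
      std::vector<double> esum(M, 0.0), nsum(M, 0.0);
      for (int t = 0; t < T; ++t) {
        compute_stats(A[t], tau[t], lca, G, e, n);
        for (int r = 0; r < M; ++r) { esum[r] += e[r]; nsum[r] += n[r]; }
      }
      for (int r = 0; r < M; ++r) {
        double ar = a0 + esum[r], br = b0 + nsum[r];
        for (int t = 0; t < T; ++t) { av[t][r] = ar; bv[t][r] = br; }
        double dab = R::digamma(ar + br);
        El[r] = R::digamma(ar) - dab;
        El1[r] = R::digamma(br) - dab;
      }
      for (int u = 0; u < G; ++u)
        for (int v = 0; v < G; ++v) {
          int r = lca(u, v) - 1;
          ElMs[(size_t)u * G + v] = El[r];
          El1Ms[(size_t)u * G + v] = El1[r];
        }
    }
    for (int t = 0; t < T; ++t) {
      const int N = A[t].nrow();
      std::vector<double> ElM, El1M;
      if (share) {
        ElM = ElMs; El1M = El1Ms;
      } else {
        compute_stats(A[t], tau[t], lca, G, e, n);
        for (int r = 0; r < M; ++r) {
          av[t][r] = a0 + e[r];
          bv[t][r] = b0 + n[r];
          double dab = R::digamma(av[t][r] + bv[t][r]);
          El[r] = R::digamma(av[t][r]) - dab;
          El1[r] = R::digamma(bv[t][r]) - dab;
        }
        // leaf-pair expectation matrices via the LCA map
        ElM.resize((size_t)G * G); El1M.resize((size_t)G * G);
        for (int u = 0; u < G; ++u)
          for (int v = 0; v < G; ++v) {
            int r = lca(u, v) - 1;
            ElM[(size_t)u * G + v] = El[r];
            El1M[(size_t)u * G + v] = El1[r];
          }
      }
      // running A %*% tau and colSums(tau)
      std::vector<double> At((size_t)N * G, 0.0), cs(G, 0.0);
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < N; ++j) {
          double aa = A[t](i, j);
          if (aa != 0.0)
            for (int u = 0; u < G; ++u) At[(size_t)i * G + u] += aa * tau[t](j, u);
        }
      for (int i = 0; i < N; ++i)
        for (int u = 0; u < G; ++u) cs[u] += tau[t](i, u);

      std::vector<int> ord(N);
      rand_perm(ord);
      std::vector<double> field(G), newtau(G), oldtau(G);
      for (int k = 0; k < N; ++k) {
        int i = ord[k];
        int gi = glob[t][i];
        // coupled neighbors where this vertex is active
        int K = 0;
        std::vector<double> lognbr(G, 0.0);
        if (lambda > 0) {
          for (int s1 : nbr[t]) {
            int s = s1 - 1;
            int li = loc[s][gi];
            if (li >= 0) {
              ++K;
              for (int u = 0; u < G; ++u) {
                double ts = tau[s](li, u);
                lognbr[u] += std::log(ts > TAU_FLOOR ? ts : TAU_FLOOR);
              }
            }
          }
        }
        double fmax = -1e300;
        for (int u = 0; u < G; ++u) {
          double f = 0.0;
          for (int v = 0; v < G; ++v) {
            double d = At[(size_t)i * G + v];
            double m = cs[v] - tau[t](i, v);
            f += ElM[(size_t)u * G + v] * d + El1M[(size_t)u * G + v] * (m - d);
          }
          if (lambda > 0) f = (f + lambda * lognbr[u]) / (1.0 + lambda * K);
          f *= mult;
          field[u] = f;
          if (f > fmax) fmax = f;
        }
        double Z = 0.0;
        for (int u = 0; u < G; ++u) {
          newtau[u] = std::exp(field[u] - fmax);
          Z += newtau[u];
        }
        double Z2 = 0.0;
        for (int u = 0; u < G; ++u) {
          newtau[u] /= Z;
          if (newtau[u] < TAU_FLOOR) newtau[u] = TAU_FLOOR;
          Z2 += newtau[u];
        }
        for (int u = 0; u < G; ++u) {
          oldtau[u] = tau[t](i, u);
          newtau[u] /= Z2;
          tau[t](i, u) = newtau[u];
        }
        // rank-1 refresh of At and cs
        for (int u = 0; u < G; ++u) {
          double d = newtau[u] - oldtau[u];
          if (d != 0.0) {
            cs[u] += d;
            for (int j = 0; j < N; ++j) {
              double aa = A[t](j, i);
              if (aa != 0.0) At[(size_t)j * G + u] += aa * d;
            }
          }
        }
      }
    }
    if (warm) continue;  // warm phase is initialization; not traced
    // objective after the full global sweep
    double J = 0.0;
    if (share) J -= beta_terms(av[0], bv[0], a0, b0);
    for (int t = 0; t < T; ++t) {
      J -= elbo_data(A[t], tau[t], lca, G, av[t], bv[t]);
      if (!share) J -= beta_terms(av[t], bv[t], a0, b0);
      if (lambda > 0) {
        for (int s1 : nbr[t]) {
          int s = s1 - 1;
          for (int k = 0; k < (int)glob[t].size(); ++k) {
            int li = loc[s][glob[t][k]];
            if (li < 0) continue;
            double kl = 0.0;
            for (int u = 0; u < G; ++u) {
              double p = tau[t](k, u), q = tau[s](li, u);
              if (p > 0) kl += p * (std::log(p) - std::log(q > TAU_FLOOR ? q : TAU_FLOOR));
            }
            J += lambda * kl;
          }
        }
      }
    }
    trace.push_back(J);
    sweeps_done = sweep + 1;
    if (trace.size() > 1) {
      double prev = trace[trace.size() - 2];
      if (std::fabs(prev - J) < tol * (1.0 + std::fabs(J))) {
        converged = true;
        break;
      }
    }
  }
  // synchronize tree parameters with the final memberships
  NumericVector elbos(T);
  List a_out(T), b_out(T), tau_out(T);
  double elbo_beta = 0.0;
  if (share) {
    std::vector<double> esum(M, 0.0), nsum(M, 0.0);
    for (int t = 0; t < T; ++t) {
      compute_stats(A[t], tau[t], lca, G, e, n);
      for (int r = 0; r < M; ++r) { esum[r] += e[r]; nsum[r] += n[r]; }
    }
    for (int r = 0; r < M; ++r) {
      double ar = a0 + esum[r], br = b0 + nsum[r];
      for (int t = 0; t < T; ++t) { av[t][r] = ar; bv[t][r] = br; }
    }
    elbo_beta = beta_terms(av[0], bv[0], a0, b0);
    for (int t = 0; t < T; ++t)
      elbos[t] = elbo_data(A[t], tau[t], lca, G, av[t], bv[t]);
  } else {
    for (int t = 0; t < T; ++t) {
      compute_stats(A[t], tau[t], lca, G, e, n);
      for (int r = 0; r < M; ++r) {
        av[t][r] = a0 + e[r];
        bv[t][r] = b0 + n[r];
      }
      elbos[t] = elbo_data(A[t], tau[t], lca, G, av[t], bv[t]) +
                 beta_terms(av[t], bv[t], a0, b0);
    }
  }
  for (int t = 0; t < T; ++t) {
    a_out[t] = NumericVector(av[t].begin(), av[t].end());
    b_out[t] = NumericVector(bv[t].begin(), bv[t].end());
    tau_out[t] = tau[t];
  }
  return List::create(_["tau"] = tau_out, _["a"] = a_out, _["b"] = b_out,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["elbo"] = elbos, _["elbo_beta"] = elbo_beta,
                      _["converged"] = converged,
                      _["sweeps"] = sweeps_done);
}

// hard-assignment sufficient statistics
static void hard_stats(const NumericMatrix &A, const std::vector<int> &z,
                       const IntegerMatrix &lca, int G,
                       std::vector<double> &e, std::vector<double> &n) {
  const int N = A.nrow();
  std::fill(e.begin(), e.end(), 0.0);
  std::fill(n.begin(), n.end(), 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      int r = lca(z[i] - 1, z[j] - 1) - 1;
      if (A(i, j) != 0.0) e[r] += 1.0; else n[r] += 1.0;
    }
}

static double hard_loglik(const std::vector<double> &e, const std::vector<double> &n,
                          double a0, double b0) {
  double s = 0.0;
  for (size_t r = 0; r < e.size(); ++r)
    s += R::lbeta(e[r] + a0, n[r] + b0) - R::lbeta(a0, b0);
  return s;
}

// Collapsed Metropolis-Hastings over hard leaf assignments. One step =
// one single-vertex reassignment proposal; acceptance uses the collapsed
// Beta-Bernoulli marginal likelihood, with counts updated incrementally.
// [[Rcpp::export]]
List cpp_mcmc(NumericMatrix A, int G, IntegerMatrix lca,
              int steps, int burn_in, int thin,
              double a0, double b0, IntegerVector init,
              bool keep_samples, bool check) {
  const int N = A.nrow();
  const int M = 2 * G - 1;
  std::vector<int> z(init.begin(), init.end());
  std::vector<int> cnt(G, 0);
  for (int i = 0; i < N; ++i) cnt[z[i] - 1]++;
  std::vector<double> e(M), n(M);
  hard_stats(A, z, lca, G, e, n);
  double ll = hard_loglik(e, n, a0, b0);

  NumericMatrix comem(N, N);
  long nsamp = 0, accepted = 0;
  std::vector<std::vector<int>> samples;
  std::vector<double> deg(G), de(M), dn(M);
  std::vector<char> intouch(M, 0);
  std::vector<int> touched;
  touched.reserve(2 * G);

  for (int step = 1; step <= steps; ++step) {
    int i = (int)std::floor(unif_rand() * N);
    if (i >= N) i = N - 1;
    int u = z[i];
    int v = 1 + (int)std::floor(unif_rand() * (G - 1));
    if (v >= u) ++v;  // uniform over the other G-1 leaves
    // edges from i into each leaf
    std::fill(deg.begin(), deg.end(), 0.0);
    for (int j = 0; j < N; ++j)
      if (j != i && A(i, j) != 0.0) deg[z[j] - 1] += 1.0;
    touched.clear();
    auto touch = [&](int node) {
      if (!intouch[node]) { intouch[node] = 1; touched.push_back(node); }
    };
    for (int w = 1; w <= G; ++w) {
      double others = cnt[w - 1] - (w == u ? 1.0 : 0.0);
      double dw = deg[w - 1];
      int r1 = lca(u - 1, w - 1) - 1;
      touch(r1); de[r1] -= dw; dn[r1] -= (others - dw);
      int r2 = lca(v - 1, w - 1) - 1;
      touch(r2); de[r2] += dw; dn[r2] += (others - dw);
    }
    double dll = 0.0;
    for (int r : touched) {
      if (de[r] != 0.0 || dn[r] != 0.0)
        dll += R::lbeta(e[r] + de[r] + a0, n[r] + dn[r] + b0) -
               R::lbeta(e[r] + a0, n[r] + b0);
    }
    bool accept = dll >= 0.0 || std::log(unif_rand()) < dll;
    if (accept) {
      for (int r : touched) { e[r] += de[r]; n[r] += dn[r]; }
      cnt[u - 1]--; cnt[v - 1]++;
      z[i] = v;
      ll += dll;
      ++accepted;
    }
    for (int r : touched) { de[r] = 0.0; dn[r] = 0.0; intouch[r] = 0; }
    if (check && step % 1000 == 0) {
      std::vector<double> e2(M), n2(M);
      hard_stats(A, z, lca, G, e2, n2);
      for (int r = 0; r < M; ++r)
        if (std::fabs(e2[r] - e[r]) > 1e-8 || std::fabs(n2[r] - n[r]) > 1e-8)
          stop("incremental count update diverged from recomputation");
    }
    if (step > burn_in && (step - burn_in) % thin == 0) {
      ++nsamp;
      for (int i1 = 0; i1 < N; ++i1)
        for (int j1 = i1 + 1; j1 < N; ++j1)
          if (z[i1] == z[j1]) { comem(i1, j1) += 1.0; }
      if (keep_samples) samples.push_back(z);
    }
  }
  if (nsamp > 0)
    for (int i1 = 0; i1 < N; ++i1)
      for (int j1 = i1 + 1; j1 < N; ++j1) {
        comem(i1, j1) /= nsamp;
        comem(j1, i1) = comem(i1, j1);
      }
  for (int i1 = 0; i1 < N; ++i1) comem(i1, i1) = NA_REAL;
  IntegerMatrix smp(keep_samples ? (int)samples.size() : 0, N);
  if (keep_samples)
    for (int s = 0; s < (int)samples.size(); ++s)
      for (int j = 0; j < N; ++j) smp(s, j) = samples[s][j];
  return List::create(_["comembership"] = comem, _["n_samples"] = (double)nsamp,
                      _["acceptance_rate"] = steps > 0 ? (double)accepted / steps : NA_REAL,
                      _["final_assignment"] = IntegerVector(z.begin(), z.end()),
                      _["e"] = NumericVector(e.begin(), e.end()),
                      _["n"] = NumericVector(n.begin(), n.end()),
                      _["log_likelihood"] = ll,
                      _["samples"] = smp);
}
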