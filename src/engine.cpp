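// Simulation engine for coordinated Q-learning on coordination graphs.
// All randomness goes through R's RNG (unif_rand), so set.seed() on the R
// side makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// argmax with uniform random tie-breaking among entries within tol of max
int argmax_tie(const double* x, int m, double tol = 1e-12) {
  double best = x[0];
  for (int a = 1; a < m; ++a) if (x[a] > best) best = x[a];
  int nties = 0;
  for (int a = 0; a < m; ++a) if (x[a] >= best - tol) ++nties;
  if (nties == 1) {
    for (int a = 0; a < m; ++a) if (x[a] >= best - tol) return a;
  }
  int pick = (int)std::floor(unif_rand() * nties);
  if (pick >= nties) pick = nties - 1;
  for (int a = 0; a < m; ++a) {
    if (x[a] >= best - tol && pick-- == 0) return a;
  }
  return m - 1; // unreachable
}

// Max-plus on the active subgraph. Q is E*m*m with Q[e*m*m + au*m + av] for
// canonical edge e = (u, v), u < v. mu is 2E*m: row 2e = message u -> v
// (indexed by v's action), row 2e+1 = v -> u. Messages are mean-centred.
//
// sequential = true runs Gauss-Seidel sweeps over the directed active
// messages in a fresh random order each iteration (each message computed
// from the latest incoming messages); false runs synchronous Jacobi
// iterations. Returns iterations executed; S (n*m) is left holding the
// per-agent sums of incoming messages.
int maxplus_run(int n, int m, const std::vector<int>& eu,
                const std::vector<int>& ev, const std::vector<char>& active,
                const std::vector<double>& Q, int deadline, double tol,
                std::vector<double>& mu, std::vector<double>& S,
                long long& msgs_sent, bool& converged,
                bool sequential = true, bool warm_start = false) {
  const int E = (int)eu.size();
  if (!warm_start) std::fill(mu.begin(), mu.end(), 0.0);
  int nact = 0;
  for (int e = 0; e < E; ++e) if (active[e]) ++nact;
  converged = false;
  std::fill(S.begin(), S.end(), 0.0);
  if (nact == 0) return 0;

  // S_i(a) = sum of incoming messages to i over active edges
  for (int e = 0; e < E; ++e) {
    if (!active[e]) continue;
    const double* in_u = &mu[(size_t)(2 * e + 1) * m]; // v -> u
    const double* in_v = &mu[(size_t)(2 * e) * m];     // u -> v
    double* Su = &S[(size_t)eu[e] * m];
    double* Sv = &S[(size_t)ev[e] * m];
    for (int a = 0; a < m; ++a) { Su[a] += in_u[a]; Sv[a] += in_v[a]; }
  }

  int iters = 0;
  std::vector<double> val(m);

  if (sequential) {
    std::vector<int> dir; // directed active messages: 2e = u->v, 2e+1 = v->u
    dir.reserve(2 * nact);
    for (int e = 0; e < E; ++e)
      if (active[e]) { dir.push_back(2 * e); dir.push_back(2 * e + 1); }
    for (int it = 0; it < deadline; ++it) {
      for (int x = (int)dir.size() - 1; x > 0; --x) { // Fisher-Yates
        int y = (int)std::floor(unif_rand() * (x + 1));
        if (y > x) y = x;
        std::swap(dir[x], dir[y]);
      }
      double delta = 0.0;
      for (size_t d = 0; d < dir.size(); ++d) {
        const int row = dir[d];
        const int e = row / 2;
        const bool fwd = (row % 2 == 0); // u -> v ?
        const int src = fwd ? eu[e] : ev[e];
        const int dst = fwd ? ev[e] : eu[e];
        const double* q = &Q[(size_t)e * m * m];
        const double* Ssrc = &S[(size_t)src * m];
        const double* back = &mu[(size_t)(fwd ? 2 * e + 1 : 2 * e) * m];
        double mean = 0.0;
        for (int b = 0; b < m; ++b) {
          double best = -INFINITY;
          for (int a = 0; a < m; ++a) {
            const double qv = fwd ? q[a * m + b] : q[b * m + a];
            const double cand = qv + Ssrc[a] - back[a];
            if (cand > best) best = cand;
          }
          val[b] = best;
          mean += best;
        }
        mean /= m;
        double* out = &mu[(size_t)row * m];
        double* Sdst = &S[(size_t)dst * m];
        for (int b = 0; b < m; ++b) {
          const double nv = val[b] - mean;
          const double dd = std::fabs(nv - out[b]);
          if (dd > delta) delta = dd;
          Sdst[b] += nv - out[b];
          out[b] = nv;
        }
      }
      msgs_sent += 2LL * nact;
      ++iters;
      if (delta < tol) { converged = true; break; }
    }
    return iters;
  }

  // synchronous (Jacobi) schedule
  std::vector<double> mu_new(mu.size(), 0.0);
  for (int it = 0; it < deadline; ++it) {
    // S from the previous iteration's messages
    std::fill(S.begin(), S.end(), 0.0);
    for (int e = 0; e < E; ++e) {
      if (!active[e]) continue;
      const double* in_u = &mu[(size_t)(2 * e + 1) * m];
      const double* in_v = &mu[(size_t)(2 * e) * m];
      double* Su = &S[(size_t)eu[e] * m];
      double* Sv = &S[(size_t)ev[e] * m];
      for (int a = 0; a < m; ++a) { Su[a] += in_u[a]; Sv[a] += in_v[a]; }
    }
    double delta = 0.0;
    for (int e = 0; e < E; ++e) {
      if (!active[e]) continue;
      const double* q = &Q[(size_t)e * m * m];
      const double* Su = &S[(size_t)eu[e] * m];
      const double* Sv = &S[(size_t)ev[e] * m];
      const double* muv = &mu[(size_t)(2 * e) * m];     // u -> v (prev)
      const double* mvu = &mu[(size_t)(2 * e + 1) * m]; // v -> u (prev)
      double mean = 0.0;
      for (int av = 0; av < m; ++av) {
        double best = -INFINITY;
        for (int au = 0; au < m; ++au) {
          const double cand = q[au * m + av] + Su[au] - mvu[au];
          if (cand > best) best = cand;
        }
        val[av] = best;
        mean += best;
      }
      mean /= m;
      double* out = &mu_new[(size_t)(2 * e) * m];
      for (int av = 0; av < m; ++av) out[av] = val[av] - mean;
      mean = 0.0;
      for (int au = 0; au < m; ++au) {
        double best = -INFINITY;
        for (int av = 0; av < m; ++av) {
          const double cand = q[au * m + av] + Sv[av] - muv[av];
          if (cand > best) best = cand;
        }
        val[au] = best;
        mean += best;
      }
      mean /= m;
      double* out2 = &mu_new[(size_t)(2 * e + 1) * m];
      for (int au = 0; au < m; ++au) out2[au] = val[au] - mean;
    }
    for (int e = 0; e < E; ++e) {
      if (!active[e]) continue;
      for (int a = 0; a < 2 * m; ++a) {
        const size_t idx = (size_t)(2 * e) * m + a;
        const double dd = std::fabs(mu_new[idx] - mu[idx]);
        if (dd > delta) delta = dd;
        mu[idx] = mu_new[idx];
      }
    }
    msgs_sent += 2LL * nact;
    ++iters;
    if (delta < tol) { converged = true; break; }
  }
  // refresh S from the final messages
  std::fill(S.begin(), S.end(), 0.0);
  for (int e = 0; e < E; ++e) {
    if (!active[e]) continue;
    const double* in_u = &mu[(size_t)(2 * e + 1) * m];
    const double* in_v = &mu[(size_t)(2 * e) * m];
    double* Su = &S[(size_t)eu[e] * m];
    double* Sv = &S[(size_t)ev[e] * m];
    for (int a = 0; a < m; ++a) { Su[a] += in_u[a]; Sv[a] += in_v[a]; }
  }
  return iters;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_maxplus(int n, int m, IntegerMatrix edges, LogicalVector active,
                 NumericVector q, int deadline, double tol, bool sequential) {
  const int E = edges.nrow();
  std::vector<int> eu(E), ev(E);
  std::vector<char> act(E);
  for (int e = 0; e < E; ++e) {
    eu[e] = edges(e, 0); ev[e] = edges(e, 1); act[e] = active[e] ? 1 : 0;
  }
  std::vector<double> Q(q.begin(), q.end());
  std::vector<double> mu((size_t)2 * E * m, 0.0);
  std::vector<double> S((size_t)n * m, 0.0);
  long long sent = 0;
  bool conv = false;
  int iters = maxplus_run(n, m, eu, ev, act, Q, deadline, tol, mu, S, sent,
                          conv, sequential, false);
  NumericMatrix mu_out(2 * E, m);
  for (int r = 0; r < 2 * E; ++r)
    for (int a = 0; a < m; ++a) mu_out(r, a) = mu[(size_t)r * m + a];
  return List::create(_["mu"] = mu_out, _["iterations"] = iters,
                      _["converged"] = conv,
                      _["messages_sent"] = (double)sent);
}

//' @noRd
// [[Rcpp::export]]
List cpp_run_coordinated(int n, int m, IntegerMatrix edges,
                         NumericMatrix payoff,
                         double alpha_init, double alpha_delta,
                         double alpha_floor, double eps_init,
                         double eps_delta, double eps_floor, double gamma,
                         int deadline, double tol, bool sequential,
                         bool warm_start, int strategy, double cs_delta,
                         double cs_decay, double cs_floor, double smoothing,
                         int rounds, int window, bool early_stop) {
  const int E = edges.nrow();
  std::vector<int> eu(E), ev(E);
  for (int e = 0; e < E; ++e) { eu[e] = edges(e, 0); ev[e] = edges(e, 1); }

  // adjacency with per-entry edge index
  std::vector<std::vector<int> > adj(n), adjE(n);
  for (int e = 0; e < E; ++e) {
    adj[eu[e]].push_back(ev[e]); adjE[eu[e]].push_back(e);
    adj[ev[e]].push_back(eu[e]); adjE[ev[e]].push_back(e);
  }

  std::vector<double> Q((size_t)E * m * m, 0.0);
  std::vector<double> mu((size_t)2 * E * m, 0.0);
  std::vector<double> S((size_t)n * m, 0.0);

  // neighbour-model joint counts per directed adjacency entry
  std::vector<size_t> cnt_off(n + 1, 0);
  for (int i = 0; i < n; ++i)
    cnt_off[i + 1] = cnt_off[i] + adj[i].size() * (size_t)(m * m);
  std::vector<double> cnt(cnt_off[n], 0.0);

  // CS membership per directed adjacency entry: csmem[i][pos]
  std::vector<std::vector<char> > csmem(n);
  for (int i = 0; i < n; ++i) csmem[i].assign(adj[i].size(), 1);
  std::vector<char> active(E, 1);

  const double target = Rcpp::max(payoff); // optimal per-edge payoff
  double cur_delta = cs_delta;

  std::vector<int> a_star(n, 0), a_exec(n, 0);
  std::vector<double> score(m);
  long long msgs_cum = 0;
  int converged_round = NA_INTEGER, streak = 0;
  int rounds_run = 0;

  NumericMatrix met(rounds, 8);

  for (int t = 0; t < rounds; ++t) {
    const double alpha = std::max(alpha_floor, alpha_init - t * alpha_delta);
    const double eps = std::max(eps_floor, eps_init - t * eps_delta);

    // --- coordination-set selection -----------------------------------
    if (strategy == 1 || strategy == 2) {
      for (int i = 0; i < n; ++i)
        for (size_t p = 0; p < adj[i].size(); ++p)
          csmem[i][p] = unif_rand() < cur_delta ? 1 : 0;
    } else if (strategy == 3) {
      for (int i = 0; i < n; ++i) {
        const int d = (int)adj[i].size();
        if (d == 0) continue;
        // per-neighbour per-action caches: best-response and expected Q
        std::vector<double> tmax((size_t)d * m), texp((size_t)d * m);
        for (int p = 0; p < d; ++p) {
          const int e = adjE[i][p];
          const bool fwd = (eu[e] == i);
          const double* q = &Q[(size_t)e * m * m];
          const double* c = &cnt[cnt_off[i] + (size_t)p * m * m];
          for (int a = 0; a < m; ++a) {
            double tot = 0.0, mx = -INFINITY, ev_ = 0.0;
            for (int b = 0; b < m; ++b) tot += c[a * m + b] + smoothing;
            for (int b = 0; b < m; ++b) {
              const double qv = fwd ? q[a * m + b] : q[b * m + a];
              if (qv > mx) mx = qv;
              ev_ += (c[a * m + b] + smoothing) / tot * qv;
            }
            tmax[(size_t)p * m + a] = mx;
            texp[(size_t)p * m + a] = ev_;
          }
        }
        std::vector<double> cur(m, 0.0), pv0(m, 0.0);
        for (int a = 0; a < m; ++a)
          for (int p = 0; p < d; ++p) {
            cur[a] += tmax[(size_t)p * m + a];
            pv0[a] += texp[(size_t)p * m + a];
          }
        double mx_full = cur[0], mx0 = pv0[0];
        for (int a = 1; a < m; ++a) {
          if (cur[a] > mx_full) mx_full = cur[a];
          if (pv0[a] > mx0) mx0 = pv0[a];
        }
        const double pl_full = mx_full - mx0;
        for (int p = 0; p < d; ++p) csmem[i][p] = 1;
        if (cur_delta >= 1.0) { // drop everyone unconditionally
          for (int p = 0; p < d; ++p) csmem[i][p] = 0;
          continue;
        }
        if (cur_delta == 0.0 && pl_full > 0.0) continue; // keep everyone
        const double budget = cur_delta * pl_full + 1e-12;
        std::vector<char> dropped(d, 0);
        for (int step = 0; step < d; ++step) {
          int best_p = -1;
          double best_pl = INFINITY;
          for (int p = 0; p < d; ++p) {
            if (dropped[p]) continue;
            double mx = -INFINITY;
            for (int a = 0; a < m; ++a) {
              const double v = cur[a] - tmax[(size_t)p * m + a] +
                               texp[(size_t)p * m + a];
              if (v > mx) mx = v;
            }
            const double pl = mx_full - mx;
            if (pl < best_pl) { best_pl = pl; best_p = p; }
          }
          if (best_p < 0 || best_pl > budget) break;
          dropped[best_p] = 1;
          csmem[i][best_p] = 0;
          for (int a = 0; a < m; ++a)
            cur[a] += texp[(size_t)best_p * m + a] -
                      tmax[(size_t)best_p * m + a];
        }
      }
    }
    int nact = E;
    if (strategy != 0) {
      nact = 0;
      for (int e = 0; e < E; ++e) active[e] = 0;
      for (int i = 0; i < n; ++i)
        for (size_t p = 0; p < adj[i].size(); ++p)
          if (csmem[i][p]) active[adjE[i][p]] = 1;
      for (int e = 0; e < E; ++e) if (active[e]) ++nact;
    }

    // --- max-plus joint action selection ------------------------------
    long long sent = 0;
    bool mp_conv = false;
    int iters = maxplus_run(n, m, eu, ev, active, Q, deadline, tol, mu, S,
                            sent, mp_conv, sequential, warm_start);
    msgs_cum += sent;

    std::vector<char> hasact(n, 0);
    for (int e = 0; e < E; ++e)
      if (active[e]) { hasact[eu[e]] = 1; hasact[ev[e]] = 1; }

    for (int i = 0; i < n; ++i) {
      const double* row;
      if (hasact[i]) {
        row = &S[(size_t)i * m];
      } else if (!adj[i].empty()) {
        // isolated this round: greedy on the expected Q under the
        // empirical neighbour model
        std::fill(score.begin(), score.end(), 0.0);
        for (size_t p = 0; p < adj[i].size(); ++p) {
          const int e = adjE[i][p];
          const bool fwd = (eu[e] == i);
          const double* q = &Q[(size_t)e * m * m];
          const double* c = &cnt[cnt_off[i] + p * (size_t)(m * m)];
          for (int a = 0; a < m; ++a) {
            double tot = 0.0, ev_ = 0.0;
            for (int b = 0; b < m; ++b) tot += c[a * m + b] + smoothing;
            for (int b = 0; b < m; ++b) {
              const double qv = fwd ? q[a * m + b] : q[b * m + a];
              ev_ += (c[a * m + b] + smoothing) / tot * qv;
            }
            score[a] += ev_;
          }
        }
        row = &score[0];
      } else {
        std::fill(score.begin(), score.end(), 0.0);
        row = &score[0];
      }
      // sticky argmax: keep the previous round's coordinated choice while
      // it remains within tolerance of the maximum (stabilises the early
      // symmetry breaking among equally-valued norms)
      double best = row[0];
      for (int a = 1; a < m; ++a) if (row[a] > best) best = row[a];
      if (!(t > 0 && row[a_star[i]] >= best - 1e-9)) {
        a_star[i] = argmax_tie(row, m);
      }
    }

    // --- greedy evaluation (the policy with exploration switched off) --
    double greedy_pay = 0.0;
    for (int e = 0; e < E; ++e)
      greedy_pay += payoff(a_star[eu[e]], a_star[ev[e]]);
    greedy_pay = E > 0 ? greedy_pay / E : 0.0;
    std::vector<int> tally(m, 0);
    for (int i = 0; i < n; ++i) ++tally[a_star[i]];
    int mode = 0;
    for (int a = 0; a < m; ++a) if (tally[a] > mode) mode = tally[a];
    const double adoption = (double)mode / n;

    const bool at_target = greedy_pay >= target - 1e-9;
    streak = at_target ? streak + 1 : 0;
    if (streak >= window && converged_round == NA_INTEGER)
      converged_round = t - window + 2; // 1-based first round of the window

    // --- act with exploration, observe rewards, learn ------------------
    for (int i = 0; i < n; ++i) {
      if (unif_rand() < eps) {
        int a = (int)std::floor(unif_rand() * m);
        if (a >= m) a = m - 1;
        a_exec[i] = a;
      } else {
        a_exec[i] = a_star[i];
      }
    }
    double train_pay = 0.0;
    for (int e = 0; e < E; ++e) {
      const double r = payoff(a_exec[eu[e]], a_exec[ev[e]]);
      train_pay += r;
      double* q = &Q[(size_t)e * m * m];
      const double future = q[a_star[eu[e]] * m + a_star[ev[e]]];
      double& entry = q[a_exec[eu[e]] * m + a_exec[ev[e]]];
      entry = (1.0 - alpha) * entry + alpha * (r + gamma * future);
    }
    train_pay = E > 0 ? train_pay / E : 0.0;

    for (int i = 0; i < n; ++i)
      for (size_t p = 0; p < adj[i].size(); ++p)
        cnt[cnt_off[i] + p * (size_t)(m * m) +
            (size_t)a_exec[i] * m + a_exec[adj[i][p]]] += 1.0;

    met(t, 0) = t + 1;
    met(t, 1) = train_pay;
    met(t, 2) = greedy_pay;
    met(t, 3) = adoption;
    met(t, 4) = nact;
    met(t, 5) = iters;
    met(t, 6) = (double)sent;
    met(t, 7) = (double)msgs_cum;
    rounds_run = t + 1;

    if (strategy == 2) cur_delta = std::max(cs_floor, cur_delta - cs_decay);
    if (early_stop && converged_round != NA_INTEGER && streak >= window)
      break;
  }

  NumericMatrix met_out(rounds_run, 8);
  for (int t = 0; t < rounds_run; ++t)
    for (int c = 0; c < 8; ++c) met_out(t, c) = met(t, c);

  NumericVector q_out((size_t)E * m * m);
  for (size_t x = 0; x < Q.size(); ++x) q_out[x] = Q[x];
  IntegerVector a_out(n);
  for (int i = 0; i < n; ++i) a_out[i] = a_star[i] + 1;

  return List::create(
      _["metrics"] = met_out,
      _["converged_round"] = converged_round,
      _["total_messages"] = (double)msgs_cum,
      _["rounds_run"] = rounds_run,
      _["final_greedy_action"] = a_out,
      _["edge_q"] = q_out);
}
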