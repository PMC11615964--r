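#include <Rcpp.h>
#include <algorithm>
#include "belief_math.h"

using namespace Rcpp;
using namespace beliefgame;

// Observables for one round, measured against the current round's dominant
// singleton (the modal max-mass singleton over agents, ties to lowest
// bitmask).
struct Observables {
  double L1, R, rhoR, r_local;
};

static int adhered_singleton(const double* m, int n2) {
  // index of the max-mass singleton element (0..2n-1), ties to lowest bitmask
  int best = 0;
  double bm = m[(1 << 0) - 1];
  for (int e = 1; e < n2; ++e) {
    double v = m[(1 << e) - 1];
    if (v > bm) { bm = v; best = e; }
  }
  return best;
}

static Observables compute_observables(const std::vector<std::vector<double> >& mass,
                                       int n_verbs,
                                       const std::vector<int>& community,
                                       int n_comm) {
  int N = mass.size();
  int n2 = 2 * n_verbs;
  std::vector<int> adhere(N);
  std::vector<int> counts(n2, 0);
  for (int i = 0; i < N; ++i) {
    adhere[i] = adhered_singleton(mass[i].data(), n2);
    counts[adhere[i]]++;
  }
  int b1 = 0;
  for (int e = 1; e < n2; ++e)
    if (counts[e] > counts[b1]) b1 = e;

  Observables obs;
  int conv = 0, reg = 0;
  double Rsum = 0.0;
  for (int i = 0; i < N; ++i) {
    double mb1 = mass[i][(1 << b1) - 1];
    if (mb1 >= 1.0 - STABLE_TOL) conv++;
    double others = 0.0;
    for (int e = 0; e < n2; ++e)
      if (e != b1) others += mass[i][(1 << e) - 1];
    Rsum += mb1 - others;
    if (adhere[i] < n_verbs) reg++;
  }
  obs.L1 = (double)conv / N;
  obs.R = Rsum / N;
  obs.rhoR = (double)reg / N;

  obs.r_local = NA_REAL;
  if (n_comm > 0) {
    double acc = 0.0;
    for (int k = 1; k <= n_comm; ++k) {
      std::vector<int> ccount(n2, 0);
      int nk = 0;
      for (int i = 0; i < N; ++i)
        if (community[i] == k) { ccount[adhere[i]]++; nk++; }
      if (nk == 0) continue;
      int b1k = 0;
      for (int e = 1; e < n2; ++e)
        if (ccount[e] > ccount[b1k]) b1k = e;
      double s = 0.0;
      for (int i = 0; i < N; ++i) {
        if (community[i] != k) continue;
        double mb = mass[i][(1 << b1k) - 1];
        double others = 0.0;
        for (int e = 0; e < n2; ++e)
          if (e != b1k) others += mass[i][(1 << e) - 1];
        s += mb - others;
      }
      acc += s / nk;
    }
    obs.r_local = acc / n_comm;
  }
  return obs;
}

// Run the naming-game dynamics.
//
// edges: M x 2 integer matrix of 1-based endpoints of an undirected simple
//        graph; mass0: N x S matrix of initial beliefs; community: length-N
//        integer vector of 1-based community ids, or length 0 when no
//        partition is known.
//
// Per round (all random draws use R's RNG, in a fixed order):
//  1. each edge, in edge-list order, is activated with probability f; an
//     activated edge is social with probability ps (a direction is then drawn
//     with equal probability and the hearer records the speaker) or a
//     self-learning edge otherwise;
//  2. every agent with a non-empty learning set folds its round-start belief
//     with the speakers' round-start beliefs, ordered by descending weight
//     (neighbour degree share, ties to lowest id), each discounted by
//     c = w/(1+w-r) with r from the in-group recursive similarity followed by
//     the reliability mapping;
//  3. both endpoints of each self-learning edge reinforce the regular form of
//     a uniformly chosen verb at rate alpha (skipped for agents committed to
//     that verb's irregular form);
//  4. agents that are not stable and engaged in fewer than eta learning
//     events this round forget with probability pf: a beta-fraction of the
//     largest non-Theta focal mass moves to Theta.
//
// Termination: all agents stable, or no agent's max-mass proposition changed
// for stall_window consecutive rounds, or t_max rounds.
// [[Rcpp::export]]
List cpp_run(IntegerMatrix edges, IntegerVector node_degree,
             NumericMatrix mass0, int n_verbs,
             double f, double ps, double alpha, double pf, double beta,
             int eta, double r_max, double r_eta, double r_fair,
             int t_max, int stall_window, bool record,
             IntegerVector community) {
  int N = mass0.nrow();
  int S = mass0.ncol();
  int M = edges.nrow();
  int n2 = 2 * n_verbs;

  // neighbourhood degree sums for the weights w_ij = d_j / sum_{l in G(i)} d_l
  std::vector<double> nbr_deg_sum(N, 0.0);
  for (int m = 0; m < M; ++m) {
    int u = edges(m, 0) - 1, v = edges(m, 1) - 1;
    nbr_deg_sum[u] += node_degree[v];
    nbr_deg_sum[v] += node_degree[u];
  }

  std::vector<std::vector<double> > mass(N, std::vector<double>(S));
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < S; ++s) mass[i][s] = mass0(i, s);

  std::vector<int> comm;
  int n_comm = 0;
  if (community.size() == N) {
    comm.assign(community.begin(), community.end());
    for (int i = 0; i < N; ++i) n_comm = std::max(n_comm, comm[i]);
  } else {
    comm.assign(N, 0);
  }

  std::vector<int> prev_argmax(N);
  for (int i = 0; i < N; ++i) prev_argmax[i] = argmax_subset(mass[i].data(), S);

  std::vector<std::vector<int> > learnset(N);
  std::vector<int> learn_count(N, 0);
  std::vector<int> self_nodes;
  std::vector<double> snapshot_buf;
  std::vector<std::vector<double> > snap(N, std::vector<double>(S));

  int n_rec_cols = 8;
  NumericMatrix traj(record ? t_max : 0, n_rec_cols);

  int t = 0, stall = 0;
  std::string reason = "t_max";
  int full = S;  // bitmask of Theta

  for (t = 1; t <= t_max; ++t) {
    // round-start snapshot: social folds read these, never intra-round updates
    for (int i = 0; i < N; ++i) snap[i] = mass[i];
    for (int i = 0; i < N; ++i) { learnset[i].clear(); learn_count[i] = 0; }
    self_nodes.clear();

    int n_social = 0, n_self = 0, n_forget = 0;

    for (int m = 0; m < M; ++m) {
      if (unif_rand() >= f) continue;
      int u = edges(m, 0) - 1, v = edges(m, 1) - 1;
      if (unif_rand() < ps) {
        int speaker, hearer;
        if (unif_rand() < 0.5) { speaker = u; hearer = v; }
        else { speaker = v; hearer = u; }
        learnset[hearer].push_back(speaker);
      } else {
        self_nodes.push_back(u);
        self_nodes.push_back(v);
      }
    }

    // social learning, one ordered fold per hearer
    for (int i = 0; i < N; ++i) {
      if (learnset[i].empty()) continue;
      std::vector<int>& src = learnset[i];
      std::sort(src.begin(), src.end(), [&](int a, int b) {
        if (node_degree[a] != node_degree[b])
          return node_degree[a] > node_degree[b];
        return a < b;
      });
      int K = src.size();
      std::vector<double> s_ego(K);       // s(m_i, m_jk)
      std::vector<double> pair_sum(K, 0.0);  // sum over a<b<=k of s(m_ja,m_jb)
      for (int k = 0; k < K; ++k)
        s_ego[k] = cosine_sim(snap[i].data(), snap[src[k]].data(), S);
      double run_pairs = 0.0;
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < k; ++a)
          run_pairs += cosine_sim(snap[src[a]].data(), snap[src[k]].data(), S);
        pair_sum[k] = run_pairs;
      }

      std::vector<double> a = snap[i];
      double ua = 0.0;
      std::vector<double> b((size_t)S);
      bool ok = true;
      for (int k = 0; k < K; ++k) {
        double rp;
        if (k == 0) rp = s_ego[0];
        else rp = s_ego[k] / 2.0 + pair_sum[k] / ((double)(k + 1) * k);
        double r = map_reliability(rp, r_fair, r_eta, r_max);
        double w = node_degree[src[k]] / nbr_deg_sum[i];
        double c = combined_coefficient(w, r);
        for (int s = 0; s < S; ++s) b[s] = c * snap[src[k]][s];
        if (!wer_step(a, ua, b.data(), 1.0 - c, S)) { ok = false; break; }
      }
      if (ok) {
        redistribute_unassigned(a, ua);
        mass[i] = a;
      }  // total conflict: keep prior (cannot occur with c < 1 sources)
      learn_count[i] += 1;
      n_social++;
    }

    // self-learning, after social learning, in activation order
    for (size_t q = 0; q < self_nodes.size(); ++q) {
      int i = self_nodes[q];
      int verb = (int)(unif_rand() * n_verbs);
      if (verb >= n_verbs) verb = n_verbs - 1;
      int Rbit = (1 << verb) - 1;
      int Ibit = (1 << (n_verbs + verb)) - 1;
      double mI = mass[i][Ibit];
      if (mI >= 1.0 - STABLE_TOL) continue;  // committed irregular: no self-learning
      mass[i][Rbit] += alpha * mI;
      mass[i][Ibit] = (1.0 - alpha) * mI;
      learn_count[i] += 1;
      n_self++;
    }

    // forgetting for under-engaged, non-committed agents
    for (int i = 0; i < N; ++i) {
      if (learn_count[i] >= eta) continue;
      if (is_stable_mass(mass[i].data(), S)) continue;
      if (unif_rand() >= pf) continue;
      int bf = -1;
      double bm = 0.0;
      for (int s = 1; s <= S; ++s) {
        if (s == full) continue;
        if (mass[i][s - 1] > bm) { bm = mass[i][s - 1]; bf = s; }
      }
      if (bf < 0) continue;  // all mass already on Theta
      double moved = beta * mass[i][bf - 1];
      mass[i][full - 1] += moved;
      mass[i][bf - 1] -= moved;
      n_forget++;
    }

    bool all_stable = true;
    bool any_change = false;
    for (int i = 0; i < N; ++i) {
      if (!is_stable_mass(mass[i].data(), S)) all_stable = false;
      int am = argmax_subset(mass[i].data(), S);
      if (am != prev_argmax[i]) any_change = true;
      prev_argmax[i] = am;
    }
    stall = any_change ? 0 : stall + 1;

    if (record) {
      Observables obs = compute_observables(mass, n_verbs, comm, n_comm);
      traj(t - 1, 0) = t;
      traj(t - 1, 1) = obs.L1;
      traj(t - 1, 2) = obs.R;
      traj(t - 1, 3) = obs.rhoR;
      traj(t - 1, 4) = obs.r_local;
      traj(t - 1, 5) = n_social;
      traj(t - 1, 6) = n_self;
      traj(t - 1, 7) = n_forget;
    }

    if (all_stable) { reason = "all_stable"; break; }
    if (stall >= stall_window) { reason = "stalled"; break; }
  }
  if (t > t_max) t = t_max;

  NumericMatrix out(N, S);
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < S; ++s) out(i, s) = mass[i][s];

  Observables fin = compute_observables(mass, n_verbs, comm, n_comm);

  List res = List::create(
      _["mass"] = out, _["t"] = t, _["termination"] = reason,
      _["L1"] = fin.L1, _["R"] = fin.R, _["rho_R"] = fin.rhoR,
      _["r_local"] = fin.r_local);
  if (record) {
    res["trajectory"] = traj(Range(0, std::min(t, t_max) - 1), Range(0, n_rec_cols - 1));
  }
  return res;
}
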