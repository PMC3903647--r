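#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated-annealing minimum-set kernel under Marxan semantics:
// objective = unit_cost * |S| + fpf * total shortfall (targets pre-capped at
// attainable maxima) + beta * max(0, cost - cost_threshold). Single-unit
// toggle proposals over unlocked units; adaptive initial temperature from
// probe moves; geometric cooling; greedy repair then random-order trim.
// All randomness comes from R's RNG (seeded by the caller).

static inline double thr_term(double cost, double cost_threshold, double beta) {
  if (cost_threshold < 0) return 0.0;
  double over = cost - cost_threshold;
  return over > 0 ? beta * over : 0.0;
}

// [[Rcpp::export(name = ".anneal_kernel")]]
List anneal_kernel(int n_units,
                   IntegerVector unit_ptr,   // 0-based CSR offsets, length n_units+1
                   IntegerVector feat_idx,   // 0-based feature ids per unit
                   IntegerVector targets,    // capped targets per feature
                   LogicalVector locked,
                   double fpf,
                   double unit_cost,
                   double cost_threshold,    // < 0: no threshold
                   double beta,
                   int n_iterations,
                   int n_temp_decreases,
                   double t_final_frac,
                   int n_probe,
                   double init_prob,
                   int audit_every) {
  const int n_feat = targets.size();
  std::vector<char> in_sol(n_units, 0);
  std::vector<int> rep(n_feat, 0);
  std::vector<int> unlocked;
  unlocked.reserve(n_units);
  for (int u = 0; u < n_units; ++u) if (!locked[u]) unlocked.push_back(u);

  double cost = 0.0, penalty = 0.0;

  // toggle bookkeeping ------------------------------------------------------
  auto delta_obj = [&](int u) -> double {
    double dcost = in_sol[u] ? -unit_cost : unit_cost;
    double dpen = 0.0;
    for (int k = unit_ptr[u]; k < unit_ptr[u + 1]; ++k) {
      int f = feat_idx[k];
      if (in_sol[u]) {            // removing: shortfall grows if rep <= T
        if (rep[f] <= targets[f]) dpen += fpf;
      } else {                    // adding: shortfall shrinks if rep < T
        if (rep[f] < targets[f]) dpen -= fpf;
      }
    }
    double dthr = thr_term(cost + dcost, cost_threshold, beta) -
                  thr_term(cost, cost_threshold, beta);
    return dcost + dpen + dthr;
  };
  auto apply_toggle = [&](int u, double dO_pen_part_unused) {
    (void)dO_pen_part_unused;
    if (in_sol[u]) {
      for (int k = unit_ptr[u]; k < unit_ptr[u + 1]; ++k) {
        int f = feat_idx[k];
        if (rep[f] <= targets[f]) penalty += fpf;
        rep[f]--;
      }
      cost -= unit_cost;
      in_sol[u] = 0;
    } else {
      for (int k = unit_ptr[u]; k < unit_ptr[u + 1]; ++k) {
        int f = feat_idx[k];
        if (rep[f] < targets[f]) penalty -= fpf;
        rep[f]++;
      }
      cost += unit_cost;
      in_sol[u] = 1;
    }
  };
  auto penalty_from_scratch = [&]() -> double {
    double p = 0.0;
    for (int f = 0; f < n_feat; ++f)
      if (rep[f] < targets[f]) p += fpf * (targets[f] - rep[f]);
    return p;
  };

  // initial state: locked units plus a random subset of the rest -----------
  for (int u = 0; u < n_units; ++u) {
    bool take = locked[u] || (init_prob > 0 && unif_rand() < init_prob);
    if (take) {
      in_sol[u] = 1;
      cost += unit_cost;
      for (int k = unit_ptr[u]; k < unit_ptr[u + 1]; ++k) rep[feat_idx[k]]++;
    }
  }
  penalty = penalty_from_scratch();

  // adaptive initial temperature from probe moves ---------------------------
  double t0 = 0.0;
  if (!unlocked.empty()) {
    for (int i = 0; i < n_probe; ++i) {
      int u = unlocked[(int)(unif_rand() * unlocked.size())];
      double d = std::fabs(delta_obj(u));
      if (d > t0) t0 = d;
    }
  }
  if (t0 <= 0) t0 = 1.0;
  double t_final = t_final_frac * t0;
  double ratio = (n_temp_decreases > 1)
    ? std::pow(t_final / t0, 1.0 / (n_temp_decreases - 1)) : 1.0;
  int iters_per_temp = n_iterations / n_temp_decreases;
  if (iters_per_temp < 1) iters_per_temp = 1;

  // annealing ---------------------------------------------------------------
  double temp = t0, audit_max_diff = 0.0;
  long accepted = 0;
  if (!unlocked.empty()) {
    for (int it = 0; it < n_iterations; ++it) {
      if (it > 0 && it % iters_per_temp == 0) temp *= ratio;
      int u = unlocked[(int)(unif_rand() * unlocked.size())];
      double dO = delta_obj(u);
      bool accept = dO <= 0;
      if (!accept && temp > 0) accept = unif_rand() < std::exp(-dO / temp);
      if (accept) {
        apply_toggle(u, 0);
        ++accepted;
        if (audit_every > 0 && accepted % audit_every == 0) {
          double diff = std::fabs(penalty - penalty_from_scratch());
          if (diff > audit_max_diff) audit_max_diff = diff;
        }
      }
    }
  }

  // greedy repair: best shortfall reduction per cost, respecting threshold --
  for (;;) {
    double totshort = 0.0;
    for (int f = 0; f < n_feat; ++f)
      if (rep[f] < targets[f]) totshort += targets[f] - rep[f];
    if (totshort <= 0) break;
    if (cost_threshold >= 0 && cost + unit_cost > cost_threshold + 1e-9) break;
    int best_u = -1, best_gain = 0;
    for (int u = 0; u < n_units; ++u) {
      if (in_sol[u]) continue;
      int gain = 0;
      for (int k = unit_ptr[u]; k < unit_ptr[u + 1]; ++k)
        if (rep[feat_idx[k]] < targets[feat_idx[k]]) ++gain;
      if (gain > best_gain) { best_gain = gain; best_u = u; }
    }
    if (best_u < 0) break;
    apply_toggle(best_u, 0);
  }

  // trim: drop redundant unlocked units in random order until stable --------
  bool removed = true;
  while (removed) {
    removed = false;
    std::vector<int> sel;
    for (int u : unlocked) if (in_sol[u]) sel.push_back(u);
    // Fisher-Yates with R's RNG
    for (int i = (int)sel.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(sel[i], sel[j]);
    }
    for (int u : sel) {
      bool redundant = true;
      for (int k = unit_ptr[u]; k < unit_ptr[u + 1]; ++k)
        if (rep[feat_idx[k]] - 1 < targets[feat_idx[k]]) { redundant = false; break; }
      if (redundant) { apply_toggle(u, 0); removed = true; }
    }
  }

  IntegerVector selected;
  {
    std::vector<int> sel;
    for (int u = 0; u < n_units; ++u) if (in_sol[u]) sel.push_back(u + 1);
    selected = wrap(sel);
  }
  double thr = thr_term(cost, cost_threshold, beta);
  return List::create(
    _["selected"] = selected,
    _["cost_term"] = cost,
    _["penalty_term"] = penalty_from_scratch(),
    _["threshold_term"] = thr,
    _["objective"] = cost + penalty_from_scratch() + thr,
    _["audit_max_diff"] = audit_max_diff,
    _["t0"] = t0,
    _["accepted"] = (double)accepted);
}
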