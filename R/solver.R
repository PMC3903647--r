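#' Solver configuration
#'
#' Defaults follow the standard Marxan-style configuration for monitoring-
#' network selection: 100 restarts, feature penalty factor 100, 1,000,000
#' iterations with 10,000 temperature decreases per run, adaptive initial
#' temperature and cooling, uniform unit cost, no boundary-length term
#' (dispersed stations give more independent monitoring data).
#'
#' @param n_runs Number of independent annealing runs.
#' @param n_iterations Toggle proposals per run.
#' @param n_temp_decreases Geometric cooling steps per run (must not exceed
#'   `n_iterations`).
#' @param fpf Feature penalty factor: objective cost of one missing
#'   occurrence of a feature.
#' @param unit_cost Cost of selecting one planning unit.
#' @param cost_threshold Optional cap on total solution cost; exceeding it is
#'   penalized at rate `beta = 10 * fpf * sum(targets)` per cost unit.
#' @param locked_in Integer unit positions forced into every solution
#'   (Marxan status 2), the mechanism for nested network expansion.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param init_prob Probability that an unlocked unit starts selected.
#' @param t_final_frac Final temperature as a fraction of the adaptive
#'   initial temperature.
#' @param n_probe Probe toggles used to set the initial temperature.
#' @param audit_every Accepted moves between from-scratch audits of the
#'   incremental objective bookkeeping (0 disables).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_runs = 100L, n_iterations = 1000000L,
                          n_temp_decreases = 10000L, fpf = 100,
                          unit_cost = 1, cost_threshold = NULL,
                          locked_in = integer(0), seed = 1L,
                          init_prob = 0.5, t_final_frac = 0.02,
                          n_probe = 1000L, audit_every = 10000L) {
  if (n_temp_decreases > n_iterations)
    stop("`n_temp_decreases` must not exceed `n_iterations`", call. = FALSE)
  if (fpf <= 0 || unit_cost <= 0)
    stop("`fpf` and `unit_cost` must be positive", call. = FALSE)
  if (!is.null(cost_threshold) && cost_threshold <= 0)
    stop("`cost_threshold` must be positive when set", call. = FALSE)
  structure(list(n_runs = as.integer(n_runs),
                 n_iterations = as.integer(n_iterations),
                 n_temp_decreases = as.integer(n_temp_decreases),
                 fpf = fpf, unit_cost = unit_cost,
                 cost_threshold = cost_threshold,
                 locked_in = as.integer(locked_in), seed = as.integer(seed),
                 init_prob = init_prob, t_final_frac = t_final_frac,
                 n_probe = as.integer(n_probe),
                 audit_every = as.integer(audit_every)),
            class = "solver_config")
}

#' Wrap a bare incidence matrix as a feature_incidence
#'
#' Convenience for solver-level work on abstract instances that do not come
#' from a grid: units are numbered 1..n and features named from the matrix
#' columns (or `f1..fk`).
#'
#' @param m Logical (or 0/1) matrix, units in rows, features in columns.
#' @return A `feature_incidence`.
#' @export
as_feature_incidence <- function(m) {
  m <- m > 0
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  features <- data.frame(species_id = colnames(m), kind = "F",
                         scenario = "none", stringsAsFactors = FALSE)
  structure(list(units = seq_len(nrow(m)), features = features,
                 incidence = m, dim = c(nrow(m), 1L)),
            class = "feature_incidence")
}

# Targets capped at each feature's attainable maximum (best-effort
# semantics); the cap keeps penalties discriminating when some features have
# fewer incident units than their target.
capped_targets <- function(inc, targets) {
  as.integer(pmin(targets, colSums(inc$incidence)))
}

resolve_targets <- function(inc, tt) {
  if (is.numeric(tt)) {
    if (length(tt) != ncol(inc$incidence))
      stop("target vector length does not match feature count", call. = FALSE)
    as.integer(tt)
  } else feature_targets(tt, inc)
}

threshold_beta <- function(cfg, targets_capped) {
  if (is.null(cfg$cost_threshold)) 0 else 10 * cfg$fpf * sum(targets_capped)
}

#' Objective decomposition of a candidate station set
#'
#' Computes, from scratch, `cost_term = unit_cost * |S|`, `penalty_term =
#' fpf * sum of shortfalls` against targets capped at their attainable
#' maxima, and, when a cost threshold is set, `threshold_term =
#' beta * max(0, cost - threshold)`. No spatial-compactness term enters the
#' objective.
#'
#' @param selected Integer unit positions (indices into `inc$units`).
#' @param inc A `feature_incidence`.
#' @param tt A `target_table` or per-feature integer targets.
#' @param cfg A [solver_config()].
#' @return List with `cost_term`, `penalty_term`, `threshold_term`,
#'   `objective`, and the per-feature `representation` and `shortfall`
#'   (against capped targets).
#' @export
objective <- function(selected, inc, tt, cfg = solver_config()) {
  targets <- resolve_targets(inc, tt)
  tc <- capped_targets(inc, targets)
  rep_f <- if (length(selected))
    colSums(inc$incidence[selected, , drop = FALSE]) else
    rep(0, ncol(inc$incidence))
  shortfall <- pmax(0, tc - rep_f)
  cost <- cfg$unit_cost * length(selected)
  pen <- cfg$fpf * sum(shortfall)
  beta <- threshold_beta(cfg, tc)
  thr <- if (is.null(cfg$cost_threshold)) 0 else
    beta * max(0, cost - cfg$cost_threshold)
  list(cost_term = cost, penalty_term = pen, threshold_term = thr,
       objective = cost + pen + thr,
       representation = stats::setNames(as.numeric(rep_f), colnames(inc$incidence)),
       shortfall = stats::setNames(as.numeric(shortfall), colnames(inc$incidence)))
}

# CSR layout of the incidence matrix for the C++ kernel (0-based).
incidence_csr <- function(inc) {
  n_u <- nrow(inc$incidence)
  idx <- lapply(seq_len(n_u), function(u) which(inc$incidence[u, ]) - 1L)
  lens <- lengths(idx)
  list(unit_ptr = c(0L, cumsum(lens)), feat_idx = as.integer(unlist(idx)))
}

make_solution <- function(selected, inc, targets, cfg) {
  selected <- sort(as.integer(selected))
  ob <- objective(selected, inc, targets, cfg)
  rep_f <- ob$representation
  raw_short <- pmax(0, resolve_targets(inc, targets) - rep_f)
  thr_ok <- is.null(cfg$cost_threshold) ||
    ob$cost_term <= cfg$cost_threshold + 1e-9
  structure(list(selected = selected, cells = inc$units[selected],
                 objective = ob$objective, cost_term = ob$cost_term,
                 penalty_term = ob$penalty_term,
                 threshold_term = ob$threshold_term,
                 shortfalls = stats::setNames(as.numeric(raw_short),
                                              colnames(inc$incidence)),
                 feasible = ob$penalty_term == 0 && thr_ok),
            class = "sn_solution")
}

#' @export
print.sn_solution <- function(x, ...) {
  cat(sprintf("<sn_solution> %d units, objective %.6g (cost %.6g, penalty %.6g, threshold %.6g), %s\n",
              length(x$selected), x$objective, x$cost_term, x$penalty_term,
              x$threshold_term, if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' One simulated-annealing run
#'
#' Starts from the locked-in units plus a random subset, proposes uniform
#' single-unit toggles (locked units are never touched), accepts improving
#' moves always and worsening moves with probability `exp(-dO / T)` under a
#' geometric temperature schedule whose initial temperature is the largest
#' `|dO|` observed over probe toggles from the initial state. After
#' annealing, a greedy repair pass adds the unit with the best shortfall
#' reduction per cost until no attainable shortfall remains (respecting the
#' cost threshold), then redundant unlocked units are removed in random
#' order.
#'
#' @param inc A `feature_incidence`.
#' @param tt A `target_table` or per-feature integer targets.
#' @param cfg A [solver_config()].
#' @param run_seed Seed for this run.
#' @return An `sn_solution`.
#' @export
anneal_once <- function(inc, tt, cfg = solver_config(), run_seed = cfg$seed) {
  targets <- resolve_targets(inc, tt)
  tc <- capped_targets(inc, targets)
  n_u <- nrow(inc$incidence)
  locked <- seq_len(n_u) %in% cfg$locked_in
  if (!is.null(cfg$cost_threshold) &&
      sum(locked) * cfg$unit_cost > cfg$cost_threshold + 1e-9)
    stop("infeasible lock-in: locked cost exceeds the cost threshold",
         call. = FALSE)
  csr <- incidence_csr(inc)
  beta <- threshold_beta(cfg, tc)
  res <- withr::with_seed(run_seed, .anneal_kernel(
    n_u, csr$unit_ptr, csr$feat_idx, tc, locked,
    cfg$fpf, cfg$unit_cost,
    if (is.null(cfg$cost_threshold)) -1 else cfg$cost_threshold,
    beta, cfg$n_iterations, cfg$n_temp_decreases, cfg$t_final_frac,
    cfg$n_probe, cfg$init_prob, cfg$audit_every))
  sol <- make_solution(res$selected, inc, targets, cfg)
  attr(sol, "audit_max_diff") <- res$audit_max_diff
  attr(sol, "run_seed") <- run_seed
  sol
}

#' Ensemble of annealing runs
#'
#' Runs [anneal_once()] `cfg$n_runs` times with per-run seeds derived
#' deterministically from the master seed, collects per-unit selection
#' frequencies (a proxy for irreplaceability), and picks the best solution:
#' lowest objective, then fewest units, then earliest run.
#'
#' @inheritParams anneal_once
#' @return An object of class `sn_ensemble` with fields `best`, `per_run`,
#'   `selection_frequency` (integer vector over unit positions) and
#'   `best_run`.
#' @export
run_ensemble <- function(inc, tt, cfg = solver_config()) {
  if (cfg$n_runs < 1L) stop("`n_runs` must be at least 1", call. = FALSE)
  run_seeds <- withr::with_seed(cfg$seed,
    sample.int(.Machine$integer.max, cfg$n_runs))
  per_run <- lapply(run_seeds, function(s) anneal_once(inc, tt, cfg, s))
  freq <- integer(nrow(inc$incidence))
  for (sol in per_run) freq[sol$selected] <- freq[sol$selected] + 1L
  ord <- order(vapply(per_run, `[[`, 0, "objective"),
               vapply(per_run, function(s) length(s$selected), 0L),
               seq_along(per_run))
  structure(list(best = per_run[[ord[1]]], per_run = per_run,
                 selection_frequency = freq, best_run = ord[1],
                 cfg = cfg),
            class = "sn_ensemble")
}

#' @export
print.sn_ensemble <- function(x, ...) {
  cat(sprintf("<sn_ensemble> %d runs; best (run %d): %d units, objective %.6g\n",
              length(x$per_run), x$best_run, length(x$best$selected),
              x$best$objective))
  invisible(x)
}

#' Exact small-instance solver (branch and bound)
#'
#' Provably minimizes the same objective as the annealer over all unit
#' subsets, used as an independent optimality oracle. Units are explored in
#' decreasing-coverage order with an admissible lower bound built from the
#' unavoidable shortfall (features whose remaining coverage cannot reach the
#' target) plus the cheapest conceivable repair of the coverable shortfall.
#'
#' @param inc A `feature_incidence`.
#' @param tt A `target_table` or per-feature integer targets.
#' @param cfg A [solver_config()] (`fpf`, `unit_cost`, `cost_threshold` are
#'   used).
#' @param max_units Refuse instances larger than this (default 25).
#' @return An `sn_solution` with attribute `optimal = TRUE`.
#' @export
exact_oracle <- function(inc, tt, cfg = solver_config(), max_units = 25L) {
  n_u <- nrow(inc$incidence)
  if (n_u > max_units)
    stop("instance has ", n_u, " units; exact_oracle is limited to ",
         max_units, call. = FALSE)
  targets <- resolve_targets(inc, tt)
  tc <- capped_targets(inc, targets)
  m <- inc$incidence
  ord <- order(-rowSums(m[, tc > 0, drop = FALSE]))
  beta <- threshold_beta(cfg, tc)
  thr <- function(cost) if (is.null(cfg$cost_threshold)) 0 else
    beta * max(0, cost - cfg$cost_threshold)
  maxcov <- max(1, rowSums(m[, tc > 0, drop = FALSE]))
  rate <- min(cfg$unit_cost / maxcov, cfg$fpf)
  # suffix coverage: for unit rank i, how many of units i..n cover feature f
  n_f <- ncol(m)
  suffix <- matrix(0L, n_u + 1L, n_f)
  for (i in n_u:1) suffix[i, ] <- suffix[i + 1L, ] + m[ord[i], ]

  best <- new.env(parent = emptyenv())
  best$obj <- Inf; best$sel <- integer(0)

  consider <- function(sel_mask, cost, r) {
    short <- pmax(0, tc - r)
    obj <- cost + thr(cost) + cfg$fpf * sum(short)
    if (obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && sum(sel_mask) < length(best$sel))) {
      best$obj <- obj
      best$sel <- which(sel_mask)
    }
  }

  recurse <- function(i, sel_mask, cost, r) {
    if (i > n_u) { consider(sel_mask, cost, r); return(invisible()) }
    need <- pmax(0, tc - r)
    avail <- suffix[i, ]
    unavoidable <- pmax(0, need - avail)
    coverable <- sum(pmin(need, avail))
    bound <- cost + thr(cost) + cfg$fpf * sum(unavoidable) + rate * coverable
    if (bound >= best$obj - 1e-12) {
      # the stop-here completion may still beat the incumbent
      consider(sel_mask, cost, r)
      return(invisible())
    }
    u <- ord[i]
    sel_mask[u] <- TRUE
    recurse(i + 1L, sel_mask, cost + cfg$unit_cost, r + m[u, ])
    sel_mask[u] <- FALSE
    recurse(i + 1L, sel_mask, cost, r)
  }
  recurse(1L, logical(n_u), 0, numeric(n_f))
  sol <- make_solution(best$sel, inc, targets, cfg)
  attr(sol, "optimal") <- TRUE
  sol
}
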