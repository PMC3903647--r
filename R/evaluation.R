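#' Distribution-only targets for a comparison network
#'
#' The conventional design ignores predicted range shifts and targets only
#' each species' current predicted distribution, for the climatic and the
#' full model. Target values are set to the number of stations of the matched
#' optimized network that fall inside each species' currently suitable area,
#' so the comparison network is asked to do exactly what the optimized one
#' achieved on current distributions.
#'
#' @param net A `monitoring_network` (the matched optimized network).
#' @param climatic_bins,full_bins Named lists (species id) of present-day
#'   `binary_map`s under the climatic and full models.
#' @return Data frame with one row per (species, model) feature: columns
#'   `species_id`, `kind` (`"CurClim"` or `"CurFull"`), `target`.
#' @export
distribution_only_targets <- function(net, climatic_bins, full_bins) {
  count_in <- function(b) {
    p <- b$presence[net$cells]
    sum(p, na.rm = TRUE)
  }
  data.frame(
    species_id = rep(names(climatic_bins), 2),
    kind = rep(c("CurClim", "CurFull"), each = length(climatic_bins)),
    target = c(vapply(climatic_bins, count_in, 0),
               vapply(full_bins, count_in, 0)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Incidence structure over current-distribution features
#'
#' Builds the planning-unit incidence for the 2 x S current-distribution
#' features used by comparison networks: one climatic-model and one
#' full-model presence feature per species.
#'
#' @inheritParams distribution_only_targets
#' @return A `feature_incidence` with feature kinds `CurClim` and `CurFull`.
#' @export
build_current_incidence <- function(climatic_bins, full_bins) {
  mask <- !is.na(climatic_bins[[1]]$presence)
  units <- which(mask)
  cols <- c(lapply(climatic_bins, function(b) b$presence[units]),
            lapply(full_bins, function(b) b$presence[units]))
  features <- data.frame(
    species_id = rep(names(climatic_bins), 2),
    kind = rep(c("CurClim", "CurFull"), each = length(climatic_bins)),
    scenario = "none", stringsAsFactors = FALSE)
  incidence <- do.call(cbind, cols)
  colnames(incidence) <- paste(features$species_id, features$kind,
                               features$scenario, sep = "|")
  structure(list(units = units, features = features, incidence = incidence,
                 dim = dim(mask)),
            class = "feature_incidence")
}

#' Build a size-capped distribution-only comparison network
#'
#' Runs the solver on current-distribution features only, with a cost
#' threshold equal to the station count of the matched optimized network, so
#' both networks spend the same monitoring effort. The full ensemble is
#' retained: every run is evaluated, not just the best.
#'
#' @param dist_targets Data frame from [distribution_only_targets()].
#' @param inc_current A `feature_incidence` from [build_current_incidence()].
#' @param size_cap Station count of the matched optimized network.
#' @param cfg A [solver_config()]; `cost_threshold` is overridden by
#'   `size_cap * unit_cost`.
#' @return An `sn_ensemble`.
#' @export
build_comparison_network <- function(dist_targets, inc_current, size_cap,
                                     cfg = solver_config()) {
  key <- paste(dist_targets$species_id, dist_targets$kind)
  idx <- match(paste(inc_current$features$species_id,
                     inc_current$features$kind), key)
  if (anyNA(idx))
    stop("distribution targets do not cover every current feature",
         call. = FALSE)
  targets <- as.integer(dist_targets$target[idx])
  ccfg <- cfg
  ccfg$cost_threshold <- size_cap * cfg$unit_cost
  run_ensemble(inc_current, targets, ccfg)
}

#' Score an ensemble against the stratified change-class targets
#'
#' For each run, the unmet fraction is the share of stratified features whose
#' representation falls below the target. Targets are taken as printed — no
#' attainability capping — because the comparison measures failure against
#' the original design targets. Results are aggregated overall, by class kind
#' (G/M/L/Full) and by species x class, each as median/min/max over runs.
#'
#' @param ens An `sn_ensemble` (typically a comparison network).
#' @param inc The stratified `feature_incidence` (units must be the same
#'   planning-unit universe as the ensemble's).
#' @param tt The stratified `target_table` (or per-feature integer targets).
#' @return An object of class `evaluation_report`: `per_run_unmet_fraction`,
#'   `overall` (median/min/max), `by_class` and `by_species_class` data
#'   frames, `met_matrix` (runs x features), `n_runs`.
#' @export
evaluate_against_stratified_targets <- function(ens, inc, tt) {
  targets <- resolve_targets(inc, tt)
  n_f <- ncol(inc$incidence)
  met <- matrix(NA, length(ens$per_run), n_f,
                dimnames = list(NULL, colnames(inc$incidence)))
  for (i in seq_along(ens$per_run)) {
    sel <- ens$per_run[[i]]$selected
    rep_f <- if (length(sel))
      colSums(inc$incidence[sel, , drop = FALSE]) else rep(0, n_f)
    met[i, ] <- rep_f >= targets
  }
  unmet <- rowMeans(!met)
  mmm <- function(x) c(median = stats::median(x), min = min(x), max = max(x))
  agg_by <- function(groups) {
    out <- lapply(unique(groups), function(g) {
      fr <- rowMeans(!met[, groups == g, drop = FALSE])
      data.frame(group = g, t(mmm(fr)), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  by_class <- agg_by(inc$features$kind)
  names(by_class)[1] <- "kind"
  by_sp_cls <- agg_by(paste(inc$features$species_id, inc$features$kind))
  names(by_sp_cls)[1] <- "species_class"
  structure(list(per_run_unmet_fraction = unmet,
                 overall = mmm(unmet),
                 by_class = by_class,
                 by_species_class = by_sp_cls,
                 met_matrix = met,
                 n_runs = length(ens$per_run)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d runs; unmet fraction median %.3f (min %.3f, max %.3f)\n",
              x$n_runs, x$overall[["median"]], x$overall[["min"]],
              x$overall[["max"]]))
  invisible(x)
}

#' Tidy per-run, per-feature evaluation table
#'
#' @param report An `evaluation_report`.
#' @param inc The `feature_incidence` it was computed on.
#' @param tt The targets used.
#' @return Data frame with columns `run`, `feature`, `species_id`, `kind`,
#'   `scenario`, `target`, `met`.
#' @export
evaluation_table <- function(report, inc, tt) {
  targets <- resolve_targets(inc, tt)
  n_f <- ncol(inc$incidence)
  data.frame(
    run = rep(seq_len(report$n_runs), each = n_f),
    feature = rep(colnames(inc$incidence), report$n_runs),
    species_id = rep(inc$features$species_id, report$n_runs),
    kind = rep(inc$features$kind, report$n_runs),
    scenario = rep(inc$features$scenario, report$n_runs),
    target = rep(targets, report$n_runs),
    met = as.vector(t(report$met_matrix)),
    stringsAsFactors = FALSE
  )
}
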