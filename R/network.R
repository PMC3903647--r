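#' Design the nested monitoring networks MN1, MN2, MN3
#'
#' Solves the stratified minimum-set problem three times with level-specific
#' targets: MN1 from scratch; MN2 with the MN1 best-solution stations locked
#' in (Marxan status 2), so the network can expand without losing earlier
#' campaigns; MN3 with the MN2 stations locked in. Lock-in makes
#' MN1 \eqn{\subseteq} MN2 \eqn{\subseteq} MN3 a hard guarantee.
#'
#' @param inc A `feature_incidence`.
#' @param statuses Named character vector mapping species id to `"LC"` or
#'   `"DD"`.
#' @param cfg A [solver_config()]; its `locked_in` is taken as the MN1 base
#'   lock-in (normally empty). Per-level master seeds are derived from
#'   `cfg$seed`.
#' @return Named list of three `monitoring_network` objects (`MN1`, `MN2`,
#'   `MN3`), each with `level`, `stations` (unit positions), `cells` (linear
#'   cell indices), `ensemble`, `targets`.
#' @export
design_nested <- function(inc, statuses, cfg = solver_config()) {
  locked <- cfg$locked_in
  seeds <- withr::with_seed(cfg$seed, sample.int(.Machine$integer.max, 3L))
  nets <- list()
  for (i in seq_along(c("MN1", "MN2", "MN3"))) {
    level <- c("MN1", "MN2", "MN3")[i]
    tt <- build_targets(statuses, level)
    lcfg <- cfg
    lcfg$locked_in <- locked
    lcfg$seed <- seeds[i]
    ens <- run_ensemble(inc, tt, lcfg)
    nets[[level]] <- structure(
      list(level = level, stations = ens$best$selected,
           cells = inc$units[ens$best$selected],
           ensemble = ens, targets = tt),
      class = "monitoring_network")
    locked <- ens$best$selected
  }
  nets
}

#' @export
print.monitoring_network <- function(x, ...) {
  cat(sprintf("<monitoring_network> %s: %d stations, best objective %.6g\n",
              x$level, length(x$stations), x$ensemble$best$objective))
  invisible(x)
}

#' Full-model coverage check for a network
#'
#' Future projections rest on climate alone, so the design requires at least
#' one quarter of the monitoring stations to fall inside areas currently
#' suitable under the full (habitat-aware) model. The Full features enforce
#' this through their targets; this diagnostic verifies it per species and
#' for the union of species' full-model areas.
#'
#' @param net A `monitoring_network`.
#' @param full_bins Named list (species id) of full-model `binary_map`s.
#' @param min_fraction Required fraction (default 0.25).
#' @return List with `per_species` (named fractions), `union_fraction`,
#'   `pass` (union fraction >= `min_fraction`) and `min_fraction`.
#' @export
quarter_check <- function(net, full_bins, min_fraction = 0.25) {
  cells <- net$cells
  n <- length(cells)
  per_sp <- vapply(full_bins, function(b)
    if (n == 0) 0 else mean(b$presence[cells], na.rm = TRUE), 0)
  in_union <- rep(FALSE, n)
  for (b in full_bins)
    in_union <- in_union | (!is.na(b$presence[cells]) & b$presence[cells])
  uf <- if (n == 0) 0 else mean(in_union)
  list(per_species = per_sp, union_fraction = uf,
       pass = uf >= min_fraction, min_fraction = min_fraction)
}

#' Write the stations of nested networks as CSV
#'
#' One row per unique station cell with its grid position, the first level
#' at which it was selected, and one incidence flag per feature.
#'
#' @param nets List of `monitoring_network`s as returned by
#'   [design_nested()].
#' @param inc The `feature_incidence` the networks were designed on.
#' @param path Output CSV path.
#' @return The station data frame, invisibly.
#' @export
write_stations <- function(nets, inc, path) {
  all_st <- sort(unique(unlist(lapply(nets, `[[`, "stations"))))
  first_level <- vapply(all_st, function(u) {
    for (net in nets) if (u %in% net$stations) return(net$level)
    NA_character_
  }, "")
  rc <- cell_to_rowcol(inc$units[all_st], inc$dim)
  df <- data.frame(unit = all_st, cell = inc$units[all_st],
                   row = rc[, 1], col = rc[, 2],
                   level_first_selected = first_level,
                   stringsAsFactors = FALSE)
  flags <- inc$incidence[all_st, , drop = FALSE]
  df <- cbind(df, as.data.frame(flags + 0L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
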