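#' Build the planning-unit by feature incidence structure
#'
#' Planning units are the valid grid cells; features are the representable
#' attributes the monitoring network must capture: one (species, change-class,
#' scenario) combination per change class G (likely gain), M (likely
#' maintain), L (likely loss), plus one full-model suitability feature per
#' species. In `"per_scenario"` mode (default) each scenario contributes its
#' own G/M/L features, each carrying the full target, so the network supports
#' the shift hypothesis under either scenario; in `"union"` mode a cell is
#' incident to a species' G/M/L feature if it carries that class under any
#' scenario.
#'
#' @param class_maps List of `change_class_map`s covering every species x
#'   scenario combination, all on one grid.
#' @param full_bins Named list (by species id) of full-model `binary_map`s.
#' @param scenario_mode `"per_scenario"` or `"union"`.
#' @return An object of class `feature_incidence`: integer vector `units`
#'   (linear cell indices), data frame `features` (`species_id`, `kind`,
#'   `scenario`), logical matrix `incidence` (units x features), and the grid
#'   dimension `dim`.
#' @export
build_incidence <- function(class_maps, full_bins,
                            scenario_mode = c("per_scenario", "union")) {
  scenario_mode <- match.arg(scenario_mode)
  mask <- !is.na(class_maps[[1]]$classes)
  for (m in class_maps)
    if (!identical(unname(!is.na(m$classes)), unname(mask)))
      stop("class maps do not share one grid/mask", call. = FALSE)
  for (b in full_bins)
    if (!identical(unname(!is.na(b$presence)), unname(mask)))
      stop("full-model maps do not share the class maps' grid/mask", call. = FALSE)
  units <- which(mask)
  species <- unique(vapply(class_maps, `[[`, "", "species_id"))
  scenarios <- unique(vapply(class_maps, `[[`, "", "scenario_id"))
  kinds <- c(G = "gain", M = "maintain", L = "loss")

  map_of <- function(sp, sc) {
    for (m in class_maps)
      if (m$species_id == sp && m$scenario_id == sc) return(m)
    stop("missing class map for ", sp, " / ", sc, call. = FALSE)
  }

  feats <- list(); cols <- list()
  for (sp in species) {
    for (k in names(kinds)) {
      if (scenario_mode == "per_scenario") {
        for (sc in scenarios) {
          feats[[length(feats) + 1L]] <- c(sp, k, sc)
          cols[[length(cols) + 1L]] <-
            class_is(map_of(sp, sc), kinds[[k]])[units]
        }
      } else {
        inc <- rep(FALSE, length(units))
        for (sc in scenarios)
          inc <- inc | class_is(map_of(sp, sc), kinds[[k]])[units]
        feats[[length(feats) + 1L]] <- c(sp, k, "union")
        cols[[length(cols) + 1L]] <- inc
      }
    }
    feats[[length(feats) + 1L]] <- c(sp, "Full", "none")
    cols[[length(cols) + 1L]] <- full_bins[[sp]]$presence[units]
  }
  features <- as.data.frame(do.call(rbind, feats), stringsAsFactors = FALSE)
  names(features) <- c("species_id", "kind", "scenario")
  if (anyDuplicated(features)) stop("duplicate features", call. = FALSE)
  incidence <- do.call(cbind, cols)
  colnames(incidence) <- paste(features$species_id, features$kind,
                               features$scenario, sep = "|")
  structure(list(units = units, features = features, incidence = incidence,
                 dim = dim(mask)),
            class = "feature_incidence")
}

#' @export
print.feature_incidence <- function(x, ...) {
  cat(sprintf("<feature_incidence> %d units x %d features (%d incidences)\n",
              length(x$units), nrow(x$features), sum(x$incidence)))
  invisible(x)
}

# Station targets per conservation status and network level. A species'
# target applies uniformly to each of its G/M/L/Full features; levels double
# then double again so networks can expand with volunteer commitment.
STATUS_TARGETS <- list(LC = c(MN1 = 3L, MN2 = 6L, MN3 = 12L),
                       DD = c(MN1 = 5L, MN2 = 10L, MN3 = 20L))

#' Representation targets per feature for one network level
#'
#' Least Concern species get 3/6/12 stations per feature at levels
#' MN1/MN2/MN3; Data Deficient species, with higher conservation concern,
#' get 5/10/20.
#'
#' @param statuses Named character vector mapping species id to `"LC"` or
#'   `"DD"`.
#' @param level `"MN1"`, `"MN2"` or `"MN3"`.
#' @return An object of class `target_table`: data frame with one row per
#'   (species, kind) and columns `species_id`, `status`, `kind`, `target`;
#'   attribute `level`.
#' @export
build_targets <- function(statuses, level = c("MN1", "MN2", "MN3")) {
  level <- match.arg(level)
  if (length(statuses) == 0L) stop("`statuses` is empty", call. = FALSE)
  bad <- setdiff(unique(statuses), names(STATUS_TARGETS))
  if (length(bad)) stop("unknown status code: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  kinds <- c("G", "M", "L", "Full")
  tt <- data.frame(
    species_id = rep(names(statuses), each = length(kinds)),
    status = rep(unname(statuses), each = length(kinds)),
    kind = rep(kinds, times = length(statuses)),
    stringsAsFactors = FALSE
  )
  tt$target <- vapply(tt$status, function(s) STATUS_TARGETS[[s]][[level]], 0L)
  structure(tt, class = c("target_table", "data.frame"), level = level)
}

#' Full target table across all network levels
#'
#' @param statuses Named character vector mapping species id to status.
#' @return Data frame with one row per species and one column per
#'   (level, kind) combination, mirroring the standard published layout.
#' @export
target_table_wide <- function(statuses) {
  out <- data.frame(species_id = names(statuses), status = unname(statuses),
                    stringsAsFactors = FALSE)
  for (lev in c("MN1", "MN2", "MN3"))
    for (k in c("G", "M", "L", "Full"))
      out[[paste(lev, k, sep = "_")]] <-
        vapply(out$status, function(s) STATUS_TARGETS[[s]][[lev]], 0L)
  out
}

#' Align a target table to an incidence structure
#'
#' @param tt A `target_table`.
#' @param inc A `feature_incidence`.
#' @return Integer vector of targets, one per feature of `inc` (matched on
#'   species and kind; scenario copies share the species' target).
#' @export
feature_targets <- function(tt, inc) {
  key <- paste(tt$species_id, tt$kind)
  idx <- match(paste(inc$features$species_id, inc$features$kind), key)
  if (anyNA(idx))
    stop("target table does not cover every feature", call. = FALSE)
  as.integer(tt$target[idx])
}

#' Attainability of targets given the incidence structure
#'
#' A feature whose incident-unit count falls short of its target can never be
#' fully represented; the solver treats such targets as best-effort (capped at
#' the attainable maximum) and this report flags them.
#'
#' @param inc A `feature_incidence`.
#' @param tt A `target_table` (or integer vector of per-feature targets).
#' @return Data frame per feature: `feature`, `species_id`, `kind`,
#'   `scenario`, `target`, `n_incident`, `attainable`, `max_attainable`.
#' @export
coverage_report <- function(inc, tt) {
  targets <- if (is.numeric(tt)) as.integer(tt) else feature_targets(tt, inc)
  n_inc <- colSums(inc$incidence)
  data.frame(
    feature = colnames(inc$incidence),
    species_id = inc$features$species_id,
    kind = inc$features$kind,
    scenario = inc$features$scenario,
    target = targets,
    n_incident = as.integer(n_inc),
    attainable = n_inc >= targets,
    max_attainable = as.integer(pmin(n_inc, targets)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write Marxan-dialect input files
#'
#' Emits `pu.dat` (`id,cost,status`; status 2 marks locked-in units),
#' `spec.dat` (`id,target,spf,name`) and `puvspr.dat` (`species,pu,amount`,
#' sorted by planning unit), the file dialect consumed by the Marxan family
#' of reserve-selection tools.
#'
#' @param inc A `feature_incidence`.
#' @param tt A `target_table` or per-feature integer targets.
#' @param dir Output directory.
#' @param spf Feature penalty factor written to `spec.dat`.
#' @param locked_in Integer unit positions (indices into `inc$units`) to mark
#'   with status 2.
#' @return `dir`, invisibly.
#' @export
write_marxan_inputs <- function(inc, tt, dir, spf = 100,
                                locked_in = integer(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  targets <- if (is.numeric(tt)) as.integer(tt) else feature_targets(tt, inc)
  n_u <- length(inc$units)
  pu <- data.frame(id = seq_len(n_u), cost = 1,
                   status = ifelse(seq_len(n_u) %in% locked_in, 2L, 0L))
  utils::write.csv(pu, file.path(dir, "pu.dat"), row.names = FALSE, quote = FALSE)
  sp <- data.frame(id = seq_len(nrow(inc$features)), target = targets,
                   spf = spf, name = colnames(inc$incidence))
  utils::write.csv(sp, file.path(dir, "spec.dat"), row.names = FALSE, quote = FALSE)
  idx <- which(inc$incidence, arr.ind = TRUE)
  pv <- data.frame(species = idx[, 2], pu = idx[, 1], amount = 1)
  pv <- pv[order(pv$pu, pv$species), ]
  utils::write.csv(pv, file.path(dir, "puvspr.dat"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
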