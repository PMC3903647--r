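#' Suitability threshold from training presences
#'
#' The binary cut-off is the 10th percentile of the suitability values at the
#' training-presence cells, computed by linear interpolation between order
#' statistics (the default sample-quantile definition): with sorted values
#' \eqn{v_1 \le \dots \le v_n} and position \eqn{p = 0.10 (n - 1)}, the
#' threshold is \eqn{v_{\lfloor p \rfloor + 1} + (p - \lfloor p \rfloor)
#' (v_{\lfloor p \rfloor + 2} - v_{\lfloor p \rfloor + 1})}. The convention
#' assumes up to 10% of presence records may be unreliable, so at most
#' \eqn{\lceil 0.1 n \rceil} training presences fall strictly below the
#' threshold.
#'
#' @param grid A [suitability_grid()].
#' @param presences Integer vector of linear cell indices (>= 2, all valid).
#' @param percentile Percentile of training presences below the cut-off;
#'   fixed at 10 in the standard design.
#' @return An object of class `sn_threshold` with fields `tau`, `percentile`,
#'   `n_presences`.
#' @export
threshold_from_presences <- function(grid, presences, percentile = 10) {
  if (length(presences) < 2L)
    stop("at least 2 training presences are required", call. = FALSE)
  v <- grid$values[presences]
  if (anyNA(v))
    stop("training presences fall on nodata cells", call. = FALSE)
  tau <- unname(stats::quantile(v, percentile / 100, type = 7))
  structure(list(tau = tau, percentile = percentile,
                 n_presences = length(presences)),
            class = "sn_threshold")
}

#' Binary presence/absence map
#'
#' Reclassifies a continuous suitability surface into a binary map: a valid
#' cell is suitable iff its value is greater than or equal to the threshold
#' (the threshold value itself counts as suitable). Nodata is preserved.
#'
#' @param grid A [suitability_grid()].
#' @param th An `sn_threshold` or a bare numeric threshold in `[0, 1]`.
#' @param provenance Optional named list recording species/model/period.
#' @return An object of class `binary_map` with logical matrix `presence`
#'   (`NA` = nodata).
#' @export
binarize <- function(grid, th, provenance = NULL) {
  tau <- if (inherits(th, "sn_threshold")) th$tau else th
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  structure(list(presence = grid$values >= tau, tau = tau,
                 provenance = provenance),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %d suitable of %d valid cells (tau = %.4f)\n",
              sum(x$presence, na.rm = TRUE), sum(!is.na(x$presence)), x$tau))
  invisible(x)
}

CHANGE_CLASSES <- c("unsuitable", "loss", "maintain", "gain")

#' Classify per-cell change in climatic suitability
#'
#' Compares present and future binary maps of one species under one scenario:
#' cells suitable now but not in the future are "likely loss", suitable in
#' both are "likely maintain", unsuitable now but suitable in the future are
#' "likely gain"; cells suitable in neither are "unsuitable" and carry no
#' range-shift hypothesis.
#'
#' @param present,future `binary_map`s on the same grid and mask.
#' @param species_id,scenario_id Labels carried in the result.
#' @return An object of class `change_class_map` with a character matrix
#'   `classes` taking values `unsuitable`, `loss`, `maintain`, `gain`
#'   (`NA` = nodata).
#' @export
classify_change <- function(present, future, species_id = NULL,
                            scenario_id = NULL) {
  stopifnot_same_mask(present, future)
  p <- present$presence; f <- future$presence
  cls <- matrix(NA_character_, nrow(p), ncol(p))
  cls[!p & !f] <- "unsuitable"
  cls[p & !f] <- "loss"
  cls[p & f] <- "maintain"
  cls[!p & f] <- "gain"
  structure(list(classes = cls, species_id = species_id,
                 scenario_id = scenario_id),
            class = "change_class_map")
}

#' @export
print.change_class_map <- function(x, ...) {
  tab <- table(x$classes[!is.na(x$classes)])
  cat(sprintf("<change_class_map> %s / %s: %s\n",
              x$species_id %||% "?", x$scenario_id %||% "?",
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Logical matrix of cells carrying the given class.
class_is <- function(ccm, cls) {
  m <- !is.na(ccm$classes) & ccm$classes == cls
  dim(m) <- dim(ccm$classes)
  m
}

#' Per-cell species richness change
#'
#' For a set of single-scenario change-class maps sharing one grid, computes
#' per cell the number of species gaining suitability minus the number losing
#' it. Negative values flag loss hotspots, positive values gain areas.
#'
#' @param class_maps List of `change_class_map`s, all from the same scenario.
#' @return Numeric matrix of signed species counts (`NA` = nodata).
#' @export
richness_delta <- function(class_maps) {
  scens <- unique(vapply(class_maps, function(m) m$scenario_id %||% NA_character_, ""))
  if (length(scens) > 1L)
    stop("class maps mix scenarios: ", paste(scens, collapse = ", "), call. = FALSE)
  d <- NULL
  for (m in class_maps) {
    g <- class_is(m, "gain") - class_is(m, "loss")
    g[is.na(m$classes)] <- NA_real_
    d <- if (is.null(d)) g else d + g
  }
  d
}

#' Threshold and classify every species of a landscape
#'
#' For each species, computes the 10th-percentile training-presence threshold
#' separately for the climatic and full model (thresholds belong to a fitted
#' model, so future projections reuse the present climatic threshold),
#' binarizes all surfaces, and classifies change per scenario.
#'
#' @param land A `landscape`.
#' @return List with `climatic_bins` and `full_bins` (named by species),
#'   `class_maps` (flat list over species x scenario), and `thresholds`
#'   (per species, `climatic` and `full`).
#' @export
classify_landscape <- function(land) {
  climatic_bins <- list(); full_bins <- list()
  thresholds <- list(); class_maps <- list()
  for (sp in land$species) {
    th_c <- threshold_from_presences(sp$present_climatic, sp$presences)
    th_f <- threshold_from_presences(sp$present_full, sp$presences)
    pb <- binarize(sp$present_climatic, th_c,
                   provenance = list(species = sp$species_id,
                                     model = "climatic", period = "present"))
    fb <- binarize(sp$present_full, th_f,
                   provenance = list(species = sp$species_id,
                                     model = "full", period = "present"))
    climatic_bins[[sp$species_id]] <- pb
    full_bins[[sp$species_id]] <- fb
    thresholds[[sp$species_id]] <- list(climatic = th_c, full = th_f)
    for (sc in names(sp$future_climatic)) {
      futb <- binarize(sp$future_climatic[[sc]], th_c,
                       provenance = list(species = sp$species_id,
                                         model = "climatic", period = "future",
                                         scenario = sc))
      class_maps[[length(class_maps) + 1L]] <-
        classify_change(pb, futb, species_id = sp$species_id, scenario_id = sc)
    }
  }
  list(climatic_bins = climatic_bins, full_bins = full_bins,
       class_maps = class_maps, thresholds = thresholds)
}

#' Fraction of valid cells in a class for at least one species
#'
#' @param class_maps List of `change_class_map`s for one scenario.
#' @param cls Change class (`"gain"`, `"loss"`, `"maintain"`).
#' @return Fraction of valid cells carrying `cls` for >= 1 species.
#' @export
class_union_fraction <- function(class_maps, cls) {
  any_cls <- NULL
  for (m in class_maps) {
    g <- class_is(m, cls)
    any_cls <- if (is.null(any_cls)) g else any_cls | g
  }
  sum(any_cls) / sum(!is.na(class_maps[[1]]$classes))
}

#' Write a change-class map as an integer-coded ESRI ASCII grid
#'
#' Codes: 0 unsuitable, 1 loss, 2 maintain, 3 gain, -9999 nodata. A JSON
#' legend with the code table and provenance is written alongside.
#'
#' @param ccm A `change_class_map`.
#' @param path Output `.asc` path; the legend goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_change_map <- function(ccm, path) {
  code <- matrix(NA_real_, nrow(ccm$classes), ncol(ccm$classes))
  for (i in seq_along(CHANGE_CLASSES))
    code[!is.na(ccm$classes) & ccm$classes == CHANGE_CLASSES[i]] <- i - 1
  write_asc(code, path, digits = 1)
  legend <- list(codes = as.list(stats::setNames(0:3, CHANGE_CLASSES)),
                 nodata = -9999,
                 species_id = ccm$species_id, scenario_id = ccm$scenario_id)
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
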