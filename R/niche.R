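#' Cell-agreement between two binary predictions
#'
#' Percentage of valid cells on which two binary maps agree (both present or
#' both absent), plus the percentages predicted suitable by only the first or
#' only the second map. The three percentages sum to 100 over a shared mask.
#'
#' @param a,b `binary_map`s on the same grid and mask.
#' @return List with `percent_agreement`, `pct_only_a`, `pct_only_b`.
#' @export
percent_agreement <- function(a, b) {
  stopifnot_same_mask(a, b)
  pa <- a$presence; pb <- b$presence
  ok <- !is.na(pa)
  n <- sum(ok)
  list(percent_agreement = 100 * sum(pa[ok] == pb[ok]) / n,
       pct_only_a = 100 * sum(pa[ok] & !pb[ok]) / n,
       pct_only_b = 100 * sum(!pa[ok] & pb[ok]) / n)
}

normalized_surface <- function(g) {
  v <- g$values[!is.na(g$values)]
  tot <- sum(v)
  if (tot <= 0) stop("suitability surface has no positive mass", call. = FALSE)
  v / tot
}

#' Schoener's D niche overlap
#'
#' Both surfaces are normalized to probability surfaces over the shared valid
#' cells; \eqn{D = 1 - \frac{1}{2}\sum_i |p_i - q_i|}. D is symmetric, lies
#' in `[0, 1]`, equals 1 for identical (up to scale) surfaces and 0 for
#' disjoint supports.
#'
#' @param a,b `suitability_grid`s on the same mask, each with positive total.
#' @return Numeric scalar in `[0, 1]`.
#' @export
schoener_D <- function(a, b) {
  stopifnot_same_mask(a, b)
  p <- normalized_surface(a)
  q <- normalized_surface(b)
  1 - 0.5 * sum(abs(p - q))
}

#' Standardized Levins' niche breadth
#'
#' With the surface normalized to a probability distribution p over its n
#' valid cells, \eqn{B_{std} = (1/\sum p_i^2 - 1) / (n - 1)}: 1 for a uniform
#' surface (maximal breadth), 0 when all mass sits on one cell.
#'
#' @param a A `suitability_grid` with at least 2 valid cells and positive
#'   total.
#' @return Numeric scalar in `[0, 1]`.
#' @export
niche_breadth <- function(a) {
  p <- normalized_surface(a)
  n <- length(p)
  if (n < 2) stop("niche breadth needs at least 2 valid cells", call. = FALSE)
  (1 / sum(p^2) - 1) / (n - 1)
}

#' Model-comparison statistics for every species of a landscape
#'
#' Compares each species' present climatic and full-model surfaces: binary
#' cell agreement (thresholded at each model's own 10th-percentile
#' training-presence value), Schoener's D on the continuous surfaces, and
#' Levins' standardized niche breadth of each model.
#'
#' @param land A `landscape`.
#' @return Data frame with one row per species: `species_id`,
#'   `percent_agreement`, `pct_only_climatic`, `pct_only_full`, `D`,
#'   `breadth_climatic`, `breadth_full`.
#' @export
niche_comparison_table <- function(land) {
  rows <- lapply(land$species, function(sp) {
    th_c <- threshold_from_presences(sp$present_climatic, sp$presences)
    th_f <- threshold_from_presences(sp$present_full, sp$presences)
    pa <- percent_agreement(binarize(sp$present_climatic, th_c),
                            binarize(sp$present_full, th_f))
    data.frame(species_id = sp$species_id,
               percent_agreement = pa$percent_agreement,
               pct_only_climatic = pa$pct_only_a,
               pct_only_full = pa$pct_only_b,
               D = schoener_D(sp$present_climatic, sp$present_full),
               breadth_climatic = niche_breadth(sp$present_climatic),
               breadth_full = niche_breadth(sp$present_full),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
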