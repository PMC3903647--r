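#' Grid specification for a synthetic landscape
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in abstract units.
#' @param nodata_fraction Proportion of cells in `[0, 1)` masked as nodata;
#'   the mask is drawn once per landscape and shared by every grid of it.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 60L, n_cols = 60L, cell_size = 1,
                      nodata_fraction = 0.05) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (nodata_fraction < 0 || nodata_fraction >= 1)
    stop("`nodata_fraction` must lie in [0, 1)", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 nodata_fraction = nodata_fraction),
            class = "grid_spec")
}

#' Configuration of one simulated species
#'
#' Each species responds to a single synthetic environmental field through a
#' logistic niche response centred on `niche_center` with half-width
#' `niche_width` (both on the field's `[0, 1]` scale). Future climates shift
#' the field under the species' feet by an integer number of cells per
#' scenario, so the suitable band migrates spatially while keeping its local
#' texture — the mechanism that produces coherent gain fringes ahead of the
#' moving band and broad loss areas behind it.
#'
#' @param species_id Short label.
#' @param status Conservation status, `"LC"` or `"DD"`.
#' @param niche_center Niche optimum on the environmental-field scale.
#' @param niche_width Niche half-width (> 0); suitability is 0.5 at
#'   `|field - center| == niche_width`.
#' @param shift Named list of integer `c(rows, cols)` displacement vectors,
#'   one per scenario; positive columns move the suitable band towards the
#'   low-field (western) edge.
#' @param n_presences Number of training-presence records to draw.
#' @return An object of class `species_config`.
#' @export
species_config <- function(species_id, status = c("LC", "DD"),
                           niche_center, niche_width,
                           shift = list(A2a = c(0L, 0L), B2a = c(0L, 0L)),
                           n_presences = 60L) {
  status <- match.arg(status)
  if (niche_width <= 0) stop("`niche_width` must be positive", call. = FALSE)
  structure(list(species_id = species_id, status = status,
                 niche_center = niche_center, niche_width = niche_width,
                 shift = lapply(shift, as.integer),
                 n_presences = as.integer(n_presences)),
            class = "species_config")
}

#' Default seven-species configuration
#'
#' Seven species with the conservation statuses of the study design (three
#' Least Concern, four Data Deficient): five narrow-niche specialists whose
#' suitable bands tile the middle and eastern part of the gradient and whose
#' large scenario shifts push those bands almost entirely off the western map
#' edge (extensive likely-loss, gain reduced to a narrow western fringe), and
#' two broad-niche generalists whose bands reach the western edge already, so
#' their shifted range mostly overlaps the present one (extensive
#' likely-maintain, gain clipped by the edge). Scenario A2a shifts further
#' than B2a, so gain extent is slightly larger under B2a.
#'
#' @return List of seven [species_config()] objects.
#' @export
default_species_configs <- function() {
  cfg <- function(id, st, ct, w, a2, b2) {
    species_config(id, st, niche_center = ct, niche_width = w,
                   shift = list(A2a = c(0L, a2), B2a = c(0L, b2)))
  }
  list(
    cfg("Mdau", "LC", 0.330, 0.095, 24L, 22L),
    cfg("Pkuh", "LC", 0.390, 0.240, 12L, 10L),
    cfg("Hsav", "DD", 0.460, 0.095, 33L, 31L),
    cfg("Nlei", "DD", 0.710, 0.095, 52L, 50L),
    cfg("Eser", "LC", 0.410, 0.260, 14L, 12L),
    cfg("Bbar", "DD", 0.815, 0.080, 58L, 56L),
    cfg("Tten", "DD", 0.585, 0.095, 41L, 39L)
  )
}

# Separable Gaussian blur with edge renormalization; sigma in cells.
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  conv1 <- function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1L & j <= n
      M[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    M
  }
  conv1(nrow(m)) %*% m %*% t(conv1(ncol(m)))
}

logistic_niche <- function(env, center, width) {
  stats::plogis((width - abs(env - center)) / (0.2 * width))
}

#' Generate a seeded multi-species synthetic landscape
#'
#' Builds one smooth environmental field (planar west-east gradient plus
#' Gaussian-smoothed noise) on a domain extended eastwards by the largest
#' scenario shift, evaluates each species' logistic niche response on the
#' present window to obtain present climatic suitability, and on the shifted
#' window for each future scenario. The present "full model" surface is the
#' climatic surface attenuated outside a smooth synthetic habitat mask, so
#' full-model suitability is a restriction of climatic suitability. Training
#' presences are drawn proportional to full-model suitability. Identical
#' `(spec, configs, seed)` give bit-identical output.
#'
#' @param spec A [grid_spec()].
#' @param configs List of [species_config()]; all shift scenarios must agree
#'   across species.
#' @param seed Integer seed governing every random element.
#' @param smoothing Gaussian smoothing length of the noise component, cells.
#' @param noise_weight Weight of the noise component relative to the unit
#'   planar gradient.
#' @return An object of class `landscape`: the spec, the shared valid mask,
#'   the habitat weight surface, and one entry per species with grids
#'   `present_climatic`, `future_climatic` (per scenario), `present_full`,
#'   and `presences` (linear cell indices).
#' @export
generate_landscape <- function(spec, configs = default_species_configs(),
                               seed = 1L, smoothing = 6, noise_weight = 0.05) {
  if (!inherits(spec, "grid_spec")) stop("`spec` must be a grid_spec", call. = FALSE)
  if (length(configs) < 1L) stop("at least one species config is required", call. = FALSE)
  nr <- spec$n_rows; nc <- spec$n_cols
  shifts <- do.call(rbind, lapply(configs, function(cf)
    do.call(rbind, cf$shift)))
  max_dr <- max(0L, shifts[, 1]); min_dr <- min(0L, shifts[, 1])
  max_dc <- max(0L, shifts[, 2]); min_dc <- min(0L, shifts[, 2])
  er <- nr + max_dr - min_dr; ec <- nc + max_dc - min_dc
  r0 <- -min_dr; c0 <- -min_dc  # offset of the present window in the extended field

  withr::with_seed(seed, {
    noise <- gaussian_smooth(matrix(stats::rnorm(er * ec), er, ec), smoothing)
    noise <- noise / stats::sd(noise)
    xg <- matrix((col(matrix(0, er, ec)) - 1 - c0) / (nc - 1), er, ec)
    yg <- matrix((row(matrix(0, er, ec)) - 1 - r0) / (nr - 1), er, ec)
    # fixed scale (no per-realization normalization): the planar part spans
    # [0, 1] across the present window, so niche centers keep a stable
    # spatial meaning across seeds
    env_ext <- 0.85 * xg + 0.10 * yg + noise_weight * noise

    hab_noise <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), smoothing)
    hab_noise <- hab_noise / stats::sd(hab_noise)
    habitat <- stats::plogis((hab_noise - 0.1) / 0.3)

    mask <- matrix(TRUE, nr, nc)
    n_nodata <- round(spec$nodata_fraction * nr * nc)
    if (n_nodata > 0) mask[sample.int(nr * nc, n_nodata)] <- FALSE

    window <- function(dr, dc)
      env_ext[r0 + dr + seq_len(nr), c0 + dc + seq_len(nc)]
    as_grid <- function(m) {
      m[!mask] <- NA_real_
      suitability_grid(m, cell_size = spec$cell_size)
    }

    species <- lapply(configs, function(cf) {
      pc <- logistic_niche(window(0L, 0L), cf$niche_center, cf$niche_width)
      fut <- lapply(cf$shift, function(s)
        as_grid(logistic_niche(window(s[1], s[2]), cf$niche_center, cf$niche_width)))
      pf <- pc * habitat
      g_pc <- as_grid(pc); g_pf <- as_grid(pf)
      pres_seed <- sample.int(.Machine$integer.max, 1L)
      presences <- sample_presences(g_pf, cf$n_presences, seed = pres_seed)
      list(species_id = cf$species_id, status = cf$status, config = cf,
           present_climatic = g_pc, future_climatic = fut,
           present_full = g_pf, presences = presences)
    })
    names(species) <- vapply(species, `[[`, "", "species_id")

    structure(list(spec = spec, mask = mask, habitat = habitat,
                   scenarios = names(configs[[1]]$shift),
                   species = species, seed = seed),
              class = "landscape")
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d grid, %d valid cells, %d species, scenarios: %s\n",
              x$spec$n_rows, x$spec$n_cols, sum(x$mask),
              length(x$species), paste(x$scenarios, collapse = ", ")))
  invisible(x)
}

#' Species conservation statuses of a landscape
#'
#' @param land A `landscape`.
#' @return Named character vector mapping species id to status.
#' @export
species_statuses <- function(land) {
  vapply(land$species, `[[`, "", "status")
}

#' Draw training presences from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability, restricted to valid cells with positive suitability.
#'
#' @param grid A [suitability_grid()].
#' @param n Number of presences to draw.
#' @param seed Integer seed.
#' @return Integer vector of `n` distinct linear cell indices.
#' @export
sample_presences <- function(grid, n, seed = 1L) {
  pos <- which(!is.na(grid$values) & grid$values > 0)
  if (length(pos) < n)
    stop("only ", length(pos), " cells with positive suitability; cannot draw ",
         n, " presences", call. = FALSE)
  withr::with_seed(seed,
    pos[sample.int(length(pos), n, prob = grid$values[pos])])
}

#' Write a landscape to disk
#'
#' Emits one ESRI ASCII grid per species, model and period, a presence CSV
#' (`species_id,row,col`, 1-based, row 1 at the top), and a YAML manifest.
#'
#' @param land A `landscape`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(land, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sp in land$species) {
    base <- file.path(dir, sp$species_id)
    write_asc(sp$present_climatic, paste0(base, "_present_climatic.asc"))
    write_asc(sp$present_full, paste0(base, "_present_full.asc"))
    files <- c(files, paste0(sp$species_id, "_present_climatic.asc"),
               paste0(sp$species_id, "_present_full.asc"))
    for (sc in names(sp$future_climatic)) {
      write_asc(sp$future_climatic[[sc]], paste0(base, "_future_", sc, ".asc"))
      files <- c(files, paste0(sp$species_id, "_future_", sc, ".asc"))
    }
  }
  pres <- do.call(rbind, lapply(land$species, function(sp) {
    rc <- cell_to_rowcol(sp$presences, c(land$spec$n_rows, land$spec$n_cols))
    data.frame(species_id = sp$species_id, row = rc[, 1], col = rc[, 2])
  }))
  utils::write.csv(pres, file.path(dir, "presences.csv"), row.names = FALSE)
  manifest <- list(
    n_rows = land$spec$n_rows, n_cols = land$spec$n_cols,
    cell_size = land$spec$cell_size, seed = land$seed,
    scenarios = as.list(land$scenarios),
    species = lapply(land$species, function(sp)
      list(species_id = sp$species_id, status = sp$status,
           n_presences = length(sp$presences))),
    grids = as.list(files)
  )
  yaml::write_yaml(manifest, file.path(dir, "landscape.yaml"))
  invisible(dir)
}
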