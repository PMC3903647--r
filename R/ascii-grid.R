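#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` whitespace-
#' separated rows, top row first. Nodata cells become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A [suitability_grid()] with attributes `xllcorner`, `yllcorner` and
#'   `nodata_value` preserved for round-tripping.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: too few lines", call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ESRI ASCII header at line ", i, call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) stop("expected ", nr, " data rows, found ", length(body), call. = FALSE)
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(rows) != nc)) stop("ragged rows in ESRI ASCII grid", call. = FALSE)
  m <- do.call(rbind, rows)
  m[m == hdr$nodata_value] <- NA_real_
  g <- suitability_grid(m, cell_size = hdr$cellsize)
  attr(g, "xllcorner") <- hdr$xllcorner
  attr(g, "yllcorner") <- hdr$yllcorner
  attr(g, "nodata_value") <- hdr$nodata_value
  g
}

#' Write an ESRI ASCII grid
#'
#' @param x A [suitability_grid()] or numeric matrix (`NA` = nodata).
#' @param path Output path.
#' @param nodata_value Sentinel written for `NA` cells.
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(x, path, nodata_value = -9999, digits = 6) {
  m <- if (inherits(x, "suitability_grid")) x$values else x
  cs <- if (inherits(x, "suitability_grid")) x$cell_size else 1
  xll <- attr(x, "xllcorner"); if (is.null(xll)) xll <- 0
  yll <- attr(x, "yllcorner"); if (is.null(yll)) yll <- 0
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %s", format(xll)),
    sprintf("yllcorner %s", format(yll)),
    sprintf("cellsize %s", format(cs)),
    sprintf("NODATA_value %s", format(nodata_value))
  )
  mm <- m
  mm[is.na(mm)] <- nodata_value
  rows <- apply(signif(mm, digits), 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
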