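#' Suitability grid
#'
#' A continuous habitat-suitability surface for one species under one model
#' (climatic or full) and one period, on a regular grid. Cells carry values in
#' `[0, 1]`; nodata cells are `NA`. All grids of one landscape share the same
#' nodata mask, so cell indices are comparable across species, models and
#' periods.
#'
#' @param values Numeric matrix of suitability values in `[0, 1]`, with `NA`
#'   marking nodata cells (row 1 is the top row of the raster).
#' @param cell_size Cell edge length in abstract length units.
#' @return An object of class `suitability_grid`.
#' @export
suitability_grid <- function(values, cell_size = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, cell_size = cell_size),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  d <- dim(x$values)
  nv <- sum(!is.na(x$values))
  cat(sprintf("<suitability_grid> %d x %d cells (%d valid), range [%.3f, %.3f]\n",
              d[1], d[2], nv,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.suitability_grid <- function(x) dim(x$values)

#' Valid-cell mask of a grid
#'
#' @param x A `suitability_grid` or `binary_map`.
#' @return Logical matrix, `TRUE` where the cell carries data.
#' @export
valid_mask <- function(x) UseMethod("valid_mask")

#' @export
valid_mask.suitability_grid <- function(x) !is.na(x$values)

#' @export
valid_mask.binary_map <- function(x) !is.na(x$presence)

#' @export
valid_mask.matrix <- function(x) !is.na(x)

#' Linear cell indices of valid cells
#'
#' Cell indices are 1-based column-major linear indices into the grid matrix,
#' the same indices `which()` returns; row 1 is the top of the raster.
#'
#' @param x A grid-like object with a valid mask.
#' @return Integer vector of valid cell indices.
#' @export
valid_cells <- function(x) which(valid_mask(x))

#' Convert between linear cell indices and (row, col)
#'
#' @param idx Integer vector of linear cell indices.
#' @param dim Grid dimension `c(n_rows, n_cols)`.
#' @return `cell_to_rowcol()`: two-column integer matrix with columns `row`,
#'   `col`; `rowcol_to_cell()`: integer vector of linear indices.
#' @export
cell_to_rowcol <- function(idx, dim) {
  cbind(row = ((idx - 1L) %% dim[1]) + 1L,
        col = ((idx - 1L) %/% dim[1]) + 1L)
}

#' @rdname cell_to_rowcol
#' @param row,col Integer vectors of 1-based row and column positions.
#' @export
rowcol_to_cell <- function(row, col, dim) {
  as.integer((col - 1L) * dim[1] + row)
}

stopifnot_same_mask <- function(a, b) {
  if (!identical(dim(valid_mask(a)), dim(valid_mask(b))) ||
      !identical(unname(valid_mask(a)), unname(valid_mask(b))))
    stop("grids do not share the same dimensions and nodata mask", call. = FALSE)
  invisible(TRUE)
}
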