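#' Planar raster grid
#'
#' A minimal georeferenced 2-D field on a planar, metre-based coordinate
#' system. Row 1 is the northern edge; a cell's value refers to its centre.
#' `x0`, `y0` give the lower-left corner of the grid (metres); cells are
#' square with side `cell`. Missing data are `NA` in `values`.
#'
#' @param values numeric matrix (rows = north to south).
#' @param cell cell size in metres (> 0).
#' @param x0,y0 lower-left corner coordinates in metres.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell, x0 = 0, y0 = 0) {
  values <- as.matrix(values)
  stopifnot(is.numeric(cell), length(cell) == 1L, cell > 0)
  storage.mode(values) <- "double"
  structure(
    list(x0 = as.numeric(x0), y0 = as.numeric(y0), cell = as.numeric(cell),
         n_rows = nrow(values), n_cols = ncol(values), values = values),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell, x$x0, x$y0))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d missing\n", min(v), max(v),
                sum(is.na(x$values))))
  } else cat("  all cells missing\n")
  invisible(x)
}

#' Empty grid template
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell cell size (m).
#' @param x0,y0 lower-left corner (m).
#' @param fill initial cell value.
#' @export
grid_template <- function(n_rows, n_cols, cell, x0 = 0, y0 = 0, fill = NA_real_) {
  raster_grid(matrix(fill, n_rows, n_cols), cell = cell, x0 = x0, y0 = y0)
}

#' Copy a grid's geometry with new values
#' @param grid a `raster_grid` supplying the geometry.
#' @param values matrix or vector (recycled) of new cell values.
#' @export
grid_like <- function(grid, values) {
  if (!is.matrix(values)) values <- matrix(values, grid$n_rows, grid$n_cols)
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  raster_grid(values, cell = grid$cell, x0 = grid$x0, y0 = grid$y0)
}

#' Cell-centre coordinates
#'
#' @param grid a `raster_grid`.
#' @return list with `x` (length `n_cols`) and `y` (length `n_rows`, north to
#'   south, matching row order of `values`).
#' @export
grid_axes <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$n_cols) - 0.5) * grid$cell,
       y = grid$y0 + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell)
}

#' All cell centres as a data frame
#' @param grid a `raster_grid`.
#' @return data.frame with row, col, x, y and value columns in column-major
#'   order, so `value` equals `as.vector(grid$values)` and row i corresponds
#'   to linear cell index i as used by [grid_cell_of()].
#' @export
grid_coords <- function(grid) {
  ax <- grid_axes(grid)
  data.frame(
    row = rep(seq_len(grid$n_rows), times = grid$n_cols),
    col = rep(seq_len(grid$n_cols), each = grid$n_rows),
    x = rep(ax$x, each = grid$n_rows),
    y = rep(ax$y, times = grid$n_cols),
    value = as.vector(grid$values))
}

#' Map planar coordinates to grid cells
#'
#' @param grid a `raster_grid`.
#' @param x,y coordinates (m).
#' @return data.frame with `row`, `col` (NA when outside the extent) and
#'   `cell`, a linear index `(col - 1) * n_rows + row`.
#' @export
grid_cell_of <- function(grid, x, y) {
  col <- floor((x - grid$x0) / grid$cell) + 1L
  row <- grid$n_rows - floor((y - grid$y0) / grid$cell)
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col, cell = (col - 1L) * grid$n_rows + row)
}

#' Grid values at point locations
#' @param grid a `raster_grid`.
#' @param x,y coordinates (m).
#' @return vector of cell values; NA outside the extent.
#' @export
grid_value_at <- function(grid, x, y) {
  rc <- grid_cell_of(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Centre coordinates of linear cell indices
#' @param grid a `raster_grid`.
#' @param cell linear cell indices as returned by [grid_cell_of()].
#' @export
grid_xy_of <- function(grid, cell) {
  row <- ((cell - 1L) %% grid$n_rows) + 1L
  col <- ((cell - 1L) %/% grid$n_rows) + 1L
  data.frame(x = grid$x0 + (col - 0.5) * grid$cell,
             y = grid$y0 + (grid$n_rows - row + 0.5) * grid$cell)
}

#' Test two grids for alignment
#'
#' Aligned means identical origin, cell size and shape, so cell-wise
#' arithmetic is meaningful.
#' @param a,b `raster_grid` objects.
#' @export
grids_aligned <- function(a, b) {
  isTRUE(all.equal(c(a$x0, a$y0, a$cell), c(b$x0, b$y0, b$cell))) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!grids_aligned(a, b)) stop("misaligned ", what, call. = FALSE)
  invisible(TRUE)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text raster interchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows north to south).
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @param digits significant digits written (default 10).
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols), paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$x0, digits = 15)),
    paste("yllcorner", format(grid$y0, digits = 15)),
    paste("cellsize", format(grid$cell, digits = 15)),
    "NODATA_value -9999"), con)
  v <- grid$values
  v[is.na(v)] <- -9999
  writeLines(apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#' @param path file path.
#' @return a `raster_grid` (the NODATA value becomes `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nd <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nd] <- NA_real_
  raster_grid(m, cell = hdr$cellsize, x0 = hdr$xllcorner, y0 = hdr$yllcorner)
}
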