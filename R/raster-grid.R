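#' Planar raster grid
#'
#' A minimal single-CRS raster container used throughout the package: a
#' numeric (or integer) matrix with row 1 at the north/top edge, plus a
#' planar-metric origin and square cell size. All landscape layers in a
#' [landscape_stack()] share one such grid, so no resampling or reprojection
#' is ever needed.
#'
#' Cells are half-open intervals `[x0, x1) x [y0, y1)`: a point on the
#' shared edge of two cells belongs to the cell on its right (x) or above
#' (y). Points with `x == xmax` or `y == ymax` fall outside the grid.
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xmin,ymin coordinates (m) of the grid's lower-left corner.
#' @param res cell size in metres (> 0); cells are square.
#' @return An object of class `"sc_grid"`.
#' @export
sc_grid <- function(values, xmin = 0, ymin = 0, res = 10) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(res) || length(res) != 1L || res <= 0) {
    stop("`res` must be a single positive number")
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         nx = ncol(values), ny = nrow(values)),
    class = "sc_grid"
  )
}

#' @export
print.sc_grid <- function(x, ...) {
  cat(sprintf("<sc_grid> %d x %d cells @ %g m  extent x:[%g, %g) y:[%g, %g)\n",
              x$ny, x$nx, x$res,
              x$xmin, x$xmin + x$nx * x$res,
              x$ymin, x$ymin + x$ny * x$res))
  invisible(x)
}

grid_xmax <- function(g) g$xmin + g$nx * g$res
grid_ymax <- function(g) g$ymin + g$ny * g$res

#' Row/column indices of the cells containing points
#'
#' Vectorised point-in-cell lookup under the half-open cell convention.
#' Out-of-extent points get `NA` indices.
#'
#' @param g an [sc_grid()].
#' @param x,y point coordinates in metres.
#' @return A list with integer vectors `row`, `col` (NA outside the extent).
#' @export
grid_cell <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$res) + 1
  iy  <- floor((y - g$ymin) / g$res)      # 0-based from the south edge
  row <- g$ny - iy
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > g$nx | row < 1 | row > g$ny
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Raster values at points
#'
#' @inheritParams grid_cell
#' @return Vector of cell values; `NA` for out-of-extent points.
#' @export
grid_extract <- function(g, x, y) {
  rc <- grid_cell(g, x, y)
  out <- g$values[rep(NA_integer_, length(x))] # typed NA vector
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Centre coordinates of every cell
#'
#' @param g an [sc_grid()].
#' @return A list with matrices `x` and `y` shaped like `g$values`.
#' @keywords internal
grid_centres <- function(g) {
  cx <- g$xmin + (seq_len(g$nx) - 0.5) * g$res
  cy <- grid_ymax(g) - (seq_len(g$ny) - 0.5) * g$res
  list(x = matrix(cx, g$ny, g$nx, byrow = TRUE),
       y = matrix(cy, g$ny, g$nx))
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text interchange format readable by every GIS. `NODATA` cells are
#' written as -9999.
#'
#' @param g an [sc_grid()].
#' @param path output file.
#' @export
write_ascii_grid <- function(g, path) {
  hdr <- c(
    sprintf("ncols %d", g$nx),
    sprintf("nrows %d", g$ny),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$res),
    "NODATA_value -9999"
  )
  v <- g$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any GIS.
#' @return An [sc_grid()]; -9999 becomes `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA
  sc_grid(v, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
          res = val[["cellsize"]])
}
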