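#' Terrain derivatives of a digital elevation model
#'
#' Computes per-cell slope, aspect and a terrain ruggedness index (TRI) from
#' an elevation grid. Slope and aspect use Horn's 3x3 weighted
#' finite-difference stencil (the de facto GIS standard), with edge cells
#' handled by edge replication. The TRI of a cell is
#' `sqrt(sum((z_c - z_n)^2))` over its (up to 8) existing neighbours;
#' border cells use only the neighbours they have, so no relief is ever
#' fabricated beyond the data.
#'
#' Aspect is stored as the compass bearing (degrees clockwise from north,
#' in `[0, 360)`) of the direction of steepest *ascent*; cells with zero
#' gradient have `NA` aspect. Storing the upslope direction (rather than
#' the conventional downslope aspect) fixes the sign convention used by the
#' energetics module: a movement bearing equal to the stored aspect means
#' climbing straight uphill.
#'
#' @param elevation an [sc_grid()] of elevations in metres (>= 3x3 cells).
#' @return An object of class `"terrain_layers"`: list of `sc_grid`s
#'   `slope` (degrees, >= 0), `aspect` (degrees, upslope direction, `NA` on
#'   flats) and `tri` (metres, >= 0).
#' @export
terrain_layers <- function(elevation) {
  stopifnot(inherits(elevation, "sc_grid"))
  z <- elevation$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("elevation grid must be at least 3x3")
  if (any(!is.finite(z))) {
    bad <- which(!is.finite(z), arr.ind = TRUE)
    stop("non-finite elevation at ", nrow(bad), " cell(s), first at row ",
         bad[1, 1], ", col ", bad[1, 2])
  }
  ny <- nrow(z); nx <- ncol(z); res <- elevation$res

  # pad by edge replication for the Horn stencil
  zp <- z[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  sh <- function(dr, dc) zp[seq_len(ny) + 1 + dr, seq_len(nx) + 1 + dc]
  # compass neighbours; row 1 is north, so dr = -1 moves north
  nN <- sh(-1, 0); nS <- sh(1, 0); nE <- sh(0, 1); nW <- sh(0, -1)
  nNE <- sh(-1, 1); nNW <- sh(-1, -1); nSE <- sh(1, 1); nSW <- sh(1, -1)

  dzdx <- ((nNE + 2 * nE + nSE) - (nNW + 2 * nW + nSW)) / (8 * res)
  dzdy <- ((nNE + 2 * nN + nNW) - (nSE + 2 * nS + nSW)) / (8 * res)

  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(dzdx, dzdy) * 180 / pi) %% 360  # upslope bearing
  aspect[dzdx == 0 & dzdy == 0] <- NA_real_

  # TRI over existing neighbours only: NA-pad, sum squared differences
  zn <- z[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  zn[1, ] <- NA; zn[ny + 2, ] <- NA; zn[, 1] <- NA; zn[, nx + 2] <- NA
  shn <- function(dr, dc) zn[seq_len(ny) + 1 + dr, seq_len(nx) + 1 + dc]
  ss <- matrix(0, ny, nx)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    d2 <- (z - shn(dr, dc))^2
    d2[is.na(d2)] <- 0
    ss <- ss + d2
  }
  tri <- sqrt(ss)

  mk <- function(v) sc_grid(v, elevation$xmin, elevation$ymin, res)
  structure(list(slope = mk(slope), aspect = mk(aspect), tri = mk(tri)),
            class = "terrain_layers")
}

#' Terrain ruggedness index
#'
#' Convenience wrapper returning only the TRI layer; see [terrain_layers()]
#' for the definition.
#'
#' @inheritParams terrain_layers
#' @return An [sc_grid()] of TRI values (m).
#' @export
tri <- function(elevation) terrain_layers(elevation)$tri

#' Extract raster covariates at point locations
#'
#' Looks up, for each point, the value of every landscape and terrain layer
#' from the cell containing the point (no interpolation; half-open cell
#' convention, see [sc_grid()]). Out-of-extent points are dropped, with the
#' count recorded in the `"n_excluded"` attribute.
#'
#' @param x,y point coordinates (metres), equal length.
#' @param stack a [landscape_stack()].
#' @param terrain optional [terrain_layers()]; computed from
#'   `stack$elevation` when omitted.
#' @return A data.frame with one row per in-extent point: `point_id` (index
#'   into the input), `road`, `water` (0/1), `cover` (factor), `tri`,
#'   `slope`, `aspect`, `elevation`. Attribute `n_excluded` counts dropped
#'   points.
#' @export
extract_covariates <- function(x, y, stack, terrain = NULL) {
  stopifnot(inherits(stack, "landscape_stack"), length(x) == length(y))
  if (is.null(terrain)) terrain <- terrain_layers(stack$elevation)
  rc <- grid_cell(stack$cover, x, y)
  ok <- !is.na(rc$row)
  idx <- cbind(rc$row[ok], rc$col[ok])
  out <- data.frame(
    point_id = which(ok),
    road = stack$road$values[idx],
    water = stack$water$values[idx],
    cover = factor(COVER_LEVELS[stack$cover$values[idx]],
                   levels = COVER_LEVELS),
    tri = terrain$tri$values[idx],
    slope = terrain$slope$values[idx],
    aspect = terrain$aspect$values[idx],
    elevation = stack$elevation$values[idx]
  )
  attr(out, "n_excluded") <- sum(!ok)
  out
}
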