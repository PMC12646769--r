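#' @importFrom stats rnorm runif rgamma quantile fft sd symnum
NULL

# Cover classes share one integer coding across the package.
COVER_LEVELS <- c("scrub", "glade", "riverine", "bare", "blackcotton")

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic landscape generator
#'
#' Describes a patchy savannah-like landscape: five cover classes (dense
#' acacia scrub, open glades, riverine strips, bare soil and black-cotton
#' soil), a sparse network of narrow unpaved roads, a buffered river, and a
#' smooth digital elevation model. Defaults emulate a semi-arid study area
#' where roads are rare linear features (well under 3% of the area) and
#' relief is gentle.
#'
#' @param n_cells cells per side of the (square) grid.
#' @param res cell size in metres.
#' @param patch_scale mean habitat patch diameter in metres (smoothing
#'   length of the categorical random field).
#' @param class_weights named numeric; area weights for the non-riverine
#'   classes `scrub`, `glade`, `bare`, `blackcotton`. Must sum to 1.
#'   Riverine cover is carved out afterwards along the river.
#' @param n_roads number of straight road transects.
#' @param road_halfwidth half-width of the road surface, metres (roads are
#'   mapped as corridors extending this far to either side of a centre
#'   line).
#' @param water_halfwidth half-width of the river's open-water buffer,
#'   metres.
#' @param riverine_halfwidth half-width of the riverine vegetation strip,
#'   metres (wider than the water itself).
#' @param dem_scale correlation length of the elevation field, metres.
#' @param dem_amplitude standard deviation of the elevation field, metres;
#'   0 gives a perfectly flat landscape.
#' @param base_elevation mean elevation, metres above sea level.
#' @param seed integer seed fixing all randomness in the generator.
#' @return A list of class `"landscape_config"`.
#' @export
landscape_config <- function(n_cells = 800, res = 10,
                             patch_scale = 300,
                             class_weights = c(scrub = 0.55, glade = 0.15,
                                               bare = 0.08, blackcotton = 0.22),
                             n_roads = 8, road_halfwidth = 15,
                             water_halfwidth = 15, riverine_halfwidth = 30,
                             dem_scale = 900, dem_amplitude = 60,
                             base_elevation = 1600,
                             seed = 1L) {
  stopifnot(res > 0, n_cells >= 8, patch_scale > 0,
            road_halfwidth >= 0, water_halfwidth >= 0,
            riverine_halfwidth >= 0, dem_scale > 0, dem_amplitude >= 0)
  need <- c("scrub", "glade", "bare", "blackcotton")
  if (!all(need %in% names(class_weights))) {
    stop("`class_weights` must name all of: ", paste(need, collapse = ", "))
  }
  class_weights <- class_weights[need]
  if (abs(sum(class_weights) - 1) > 1e-8) {
    stop("`class_weights` must sum to 1")
  }
  if (n_cells * res < 4 * (patch_scale)) {
    stop("grid too small for the requested patch scale")
  }
  structure(as.list(environment()), class = "landscape_config")
}

# Smooth Gaussian random field on an ny x nx grid, unit variance, generated
# by FFT convolution of white noise with a (circularly wrapped) Gaussian
# kernel of the given length scale (in cells).
smooth_field <- function(ny, nx, scale_cells) {
  noise <- matrix(rnorm(ny * nx), ny, nx)
  if (scale_cells <= 0.5) return(noise)
  iy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  ix <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  ker <- exp(-outer(iy^2, ix^2, "+") / (2 * scale_cells^2))
  ker <- ker / sum(ker)
  f <- Re(fft(fft(noise) * fft(ker), inverse = TRUE)) / (ny * nx)
  (f - mean(f)) / sd(f)
}

# Distance from points to a segment (x1,y1)-(x2,y2), vectorised over points.
dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

# Rasterise a buffered polyline: 1 where a cell centre lies within
# `halfwidth` of any segment.
rasterise_polyline <- function(g, verts, halfwidth) {
  cc <- grid_centres(g)
  hit <- matrix(FALSE, g$ny, g$nx)
  if (nrow(verts) >= 2 && halfwidth > 0) {
    for (i in seq_len(nrow(verts) - 1)) {
      d <- dist_to_segment(cc$x, cc$y, verts[i, 1], verts[i, 2],
                           verts[i + 1, 1], verts[i + 1, 2])
      hit <- hit | (d <= halfwidth)
    }
  }
  hit
}

# A random straight transect across the full grid extent: a line at a
# uniform angle through a uniformly placed interior point, clipped by
# extending well past the extent (rasterisation clips implicitly).
random_transect <- function(g) {
  ang <- runif(1, 0, pi)
  cx <- runif(1, g$xmin, grid_xmax(g))
  cy <- runif(1, g$ymin, grid_ymax(g))
  span <- 2 * (grid_xmax(g) - g$xmin + grid_ymax(g) - g$ymin)
  rbind(c(cx - span * cos(ang), cy - span * sin(ang)),
        c(cx + span * cos(ang), cy + span * sin(ang)))
}

# A gently wiggling west-to-east river polyline.
random_river <- function(g, n_knots = 6) {
  xs <- seq(g$xmin, grid_xmax(g), length.out = n_knots)
  ymid <- runif(1, g$ymin + 0.25 * (grid_ymax(g) - g$ymin),
                g$ymin + 0.75 * (grid_ymax(g) - g$ymin))
  ys <- ymid + cumsum(rnorm(n_knots, 0, 0.05 * (grid_ymax(g) - g$ymin)))
  cbind(xs, pmin(grid_ymax(g) - g$res, pmax(g$ymin, ys)))
}

#' Generate a synthetic landscape stack
#'
#' Produces four aligned raster layers on one grid: categorical habitat
#' cover (5 classes), binary road presence, binary open water, and a smooth
#' elevation model. Cover patches come from a thresholded smoothed Gaussian
#' random field; roads are straight buffered transects; the river is a
#' buffered polyline whose wider buffer becomes riverine cover. The whole
#' stack is a deterministic function of the config (including its seed).
#'
#' @param config a [landscape_config()].
#' @return An object of class `"landscape_stack"`: a list with `sc_grid`
#'   layers `cover` (integer codes, see `attr(,"levels")`), `road`, `water`,
#'   `elevation`, plus `road_fraction` (share of cells that are road),
#'   `river` (the polyline) and the `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    n <- config$n_cells
    g0 <- sc_grid(matrix(0, n, n), xmin = 0, ymin = 0, res = config$res)

    # cover classes from one smoothed field, quantile-cut by area weights
    fld <- smooth_field(n, n, config$patch_scale / config$res / 2)
    w <- config$class_weights
    # order classes along the field so black cotton forms a coherent block
    ord <- c("blackcotton", "scrub", "glade", "bare")
    qs <- quantile(fld, cumsum(w[ord])[-length(w)])
    code <- match(ord, COVER_LEVELS)
    cov <- matrix(code[1], n, n)
    for (i in 2:length(ord)) cov[fld > qs[i - 1]] <- code[i]

    # roads
    road <- matrix(FALSE, n, n)
    if (config$n_roads > 0) {
      for (k in seq_len(config$n_roads)) {
        road <- road | rasterise_polyline(g0, random_transect(g0),
                                          config$road_halfwidth)
      }
    }

    # river: open water plus a wider riverine vegetation strip
    river <- random_river(g0)
    water <- rasterise_polyline(g0, river, config$water_halfwidth)
    rivzone <- rasterise_polyline(g0, river, config$riverine_halfwidth)
    cov[rivzone] <- match("riverine", COVER_LEVELS)

    # elevation
    if (config$dem_amplitude > 0) {
      dem <- config$base_elevation +
        config$dem_amplitude * smooth_field(n, n, config$dem_scale / config$res)
    } else {
      dem <- matrix(config$base_elevation, n, n)
    }

    cover_g <- sc_grid(cov, 0, 0, config$res)
    attr(cover_g, "levels") <- COVER_LEVELS
    structure(list(
      cover = cover_g,
      road = sc_grid(road * 1L, 0, 0, config$res),
      water = sc_grid(water * 1L, 0, 0, config$res),
      elevation = sc_grid(dem, 0, 0, config$res),
      road_fraction = mean(road),
      river = river,
      config = config
    ), class = "landscape_stack")
  })
}

#' @export
print.landscape_stack <- function(x, ...) {
  tab <- table(factor(COVER_LEVELS[x$cover$values], levels = COVER_LEVELS))
  cat(sprintf("<landscape_stack> %d x %d @ %g m; road fraction %.3f\n",
              x$cover$ny, x$cover$nx, x$cover$res, x$road_fraction))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Write all landscape layers as ESRI ASCII grids
#'
#' @param stack a [landscape_stack()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_landscape <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("cover", "road", "water", "elevation")) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
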