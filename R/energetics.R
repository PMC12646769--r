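#' Locomotion energetics model for a walking galliform
#'
#' Physiological constants from treadmill respirometry of a walking
#' guineafowl: a stationary oxygen-consumption rate, and linear
#' speed-to-VO2 relationships on level terrain and at 10% and 20%
#' inclines. Oxygen volumes convert to energy at `j_per_ml` J per ml O2.
#' Experienced percent grade is binned to the nearest measured incline:
#' below 5% counts as level, 5-15% as the 10% incline, 15-25% as the 20%
#' incline; downhill movement is costed as level. Grades of 25% or more
#' would round to an incline with no measured relationship and raise an
#' error.
#'
#' @param stationary_rate stationary VO2 (ml O2 kg-1 min-1).
#' @param level,incline10,incline20 `c(slope, intercept)` of
#'   `VO2 = slope * v + intercept` (VO2 in ml O2 kg-1 min-1, v in m s-1).
#' @param j_per_ml energy equivalent of oxygen (J ml-1 O2).
#' @param bin_edges percent-grade edges between level/10% and 10%/20%.
#' @param max_grade largest representable percent grade (exclusive).
#' @return A list of class `"energetics_model"`.
#' @export
energetics_model <- function(stationary_rate = 19.1,
                             level = c(slope = 24.0, intercept = 27.2),
                             incline10 = c(slope = 30.7, intercept = 27.6),
                             incline20 = c(slope = 47.7, intercept = 21.3),
                             j_per_ml = 20.1,
                             bin_edges = c(5, 15),
                             max_grade = 25) {
  stopifnot(stationary_rate > 0, j_per_ml > 0, all(bin_edges > 0),
            bin_edges[1] < bin_edges[2])
  structure(list(stationary_rate = stationary_rate,
                 level = level, incline10 = incline10,
                 incline20 = incline20, j_per_ml = j_per_ml,
                 bin_edges = bin_edges, max_grade = max_grade),
            class = "energetics_model")
}

#' Slope experienced along a movement bearing
#'
#' The incline an animal actually walks up (or down) depends on its
#' bearing relative to the terrain's upslope direction:
#' `theta' = atan(tan(theta) * cos(dpsi))`, where `dpsi` is the angular
#' difference between the upslope aspect and the movement bearing. Walking
#' straight upslope (`dpsi = 0`) gives `theta' = theta`; contouring
#' (`dpsi = 90`) gives 0; walking downslope gives a negative experienced
#' slope.
#'
#' @param theta terrain slope, degrees in `[0, 90)`.
#' @param dpsi angular difference upslope-aspect minus bearing, degrees.
#' @return Experienced slope in degrees (vectorised); `|theta'| <= theta`.
#' @export
experienced_slope <- function(theta, dpsi) {
  if (any(theta < 0 | theta >= 90, na.rm = TRUE)) {
    stop("terrain slope must lie in [0, 90) degrees")
  }
  atan(tan(theta * pi / 180) * cos(dpsi * pi / 180)) * 180 / pi
}

#' Bin an experienced slope into a measured incline class
#'
#' Converts the experienced slope to percent grade
#' (`PG = 100 * tan(theta')`) and rounds it to the nearest measured
#' incline: `PG < 5` (including all downhill grades) is level, `5 <= PG <
#' 15` the 10% incline, `15 <= PG < 25` the 20% incline. `PG >= 25` has no
#' measured cost relationship and raises an error.
#'
#' @param theta_prime experienced slope, degrees (vectorised).
#' @param model an [energetics_model()] (for the bin edges).
#' @return Integer vector of incline labels: 0, 10 or 20 (percent).
#' @export
incline_class <- function(theta_prime, model = energetics_model()) {
  pg <- tan(theta_prime * pi / 180) * 100
  if (any(pg >= model$max_grade, na.rm = TRUE)) {
    stop("experienced grade of ", round(max(pg, na.rm = TRUE), 1),
         "% exceeds the steepest measured incline relationship (",
         model$max_grade, "%)")
  }
  out <- integer(length(pg))
  out[pg >= model$bin_edges[1]] <- 10L
  out[pg >= model$bin_edges[2]] <- 20L
  out[is.na(pg)] <- NA_integer_
  out
}

#' Per-minute oxygen consumption of the model
#'
#' @param v speed (m s-1), vectorised.
#' @param incline incline labels from [incline_class()] (0/10/20).
#' @param moving logical; stationary seconds use the flat rate regardless
#'   of `v`.
#' @param model an [energetics_model()].
#' @return VO2 in ml O2 kg-1 min-1.
#' @export
vo2_rate <- function(v, incline = 0L, moving = TRUE,
                     model = energetics_model()) {
  if (any(v < 0, na.rm = TRUE)) stop("speed must be non-negative")
  n <- max(length(v), length(incline), length(moving))
  v <- rep_len(v, n); incline <- rep_len(incline, n)
  moving <- rep_len(moving, n)
  sl <- ifelse(incline >= 20, model$incline20[["slope"]],
               ifelse(incline >= 10, model$incline10[["slope"]],
                      model$level[["slope"]]))
  ic <- ifelse(incline >= 20, model$incline20[["intercept"]],
               ifelse(incline >= 10, model$incline10[["intercept"]],
                      model$level[["intercept"]]))
  ifelse(moving, sl * v + ic, model$stationary_rate)
}

#' Per-second energy expenditure
#'
#' Converts the per-minute oxygen consumption to J kg-1 s-1:
#' `VO2 / 60 * j_per_ml`.
#'
#' @inheritParams vo2_rate
#' @return Energy in J kg-1 s-1.
#' @export
energy_per_second <- function(v, incline = 0L, moving = TRUE,
                              model = energetics_model()) {
  vo2_rate(v, incline, moving, model) / 60 * model$j_per_ml
}

#' Habitat label of a net displacement
#'
#' A displacement is labelled `road` if both its endpoints lie on road
#' cells (roads override the cover they cross); otherwise it gets the
#' shared cover class of its endpoints, or `NA` (excluded) when the
#' endpoints lie in different covers or off the raster. Assumes continuous
#' habitat between the endpoints, which is reasonable at a 50 m scale.
#'
#' @param disp an `"sc_displacements"` table.
#' @param landscape a [landscape_stack()].
#' @return Character vector of habitat labels (`NA` = excluded).
#' @export
label_displacement_habitat <- function(disp, landscape) {
  road_s <- grid_extract(landscape$road, disp$x_start, disp$y_start)
  road_e <- grid_extract(landscape$road, disp$x_end, disp$y_end)
  cov_s <- grid_extract(landscape$cover, disp$x_start, disp$y_start)
  cov_e <- grid_extract(landscape$cover, disp$x_end, disp$y_end)
  out <- rep(NA_character_, nrow(disp))
  both_on <- !is.na(road_s) & !is.na(road_e)
  out[both_on & road_s == 1 & road_e == 1] <- "road"
  same <- both_on & is.na(out) & !is.na(cov_s) & cov_s == cov_e
  out[same] <- COVER_LEVELS[cov_s[same]]
  out
}

#' Cost of transport of displacements with per-second energies attached
#'
#' `CoT = sum(per-second energies) / true displacement distance`, in
#' J kg-1 m-1.
#'
#' @param energy_sum summed per-second energy over the displacement
#'   (J kg-1).
#' @param d_true realised displacement distance (m, >= closing radius).
#' @return CoT values.
#' @export
compute_cot <- function(energy_sum, d_true) {
  if (any(d_true <= 0)) stop("displacement distance must be positive")
  energy_sum / d_true
}

#' Full energetics pass over a track's 50 m displacements
#'
#' For every second inside every net displacement: speed from consecutive
#' 1 Hz fixes, moving state from the HMM (seconds inherit their 10 s
#' window's state), experienced incline from the DEM slope/aspect and the
#' movement bearing, per-second energy from the physiological model. Sums
#' within displacements and divides by the true distance to get the CoT,
#' and labels each displacement's habitat.
#'
#' @param disp an `"sc_displacements"` table (with its `"hires"`
#'   attribute).
#' @param hmm an `"sc_hmm"` fitted on the same track.
#' @param landscape a [landscape_stack()].
#' @param terrain optional [terrain_layers()].
#' @param model an [energetics_model()].
#' @return The displacement table augmented with `habitat`, `energy_sum`
#'   (J kg-1), `cot` (J kg-1 m-1) and `n_moving` seconds; rows with no
#'   habitat label are retained with `habitat = NA` so callers can count
#'   exclusions.
#' @export
displacement_energetics <- function(disp, hmm, landscape, terrain = NULL,
                                    model = energetics_model()) {
  stopifnot(inherits(disp, "sc_displacements"), inherits(hmm, "sc_hmm"))
  if (is.null(terrain)) terrain <- terrain_layers(landscape$elevation)
  hi <- attr(disp, "hires")
  n <- nrow(hi)
  # per-second kinematics at fix i (the second from fix i to fix i+1)
  dx <- c(diff(hi$x), NA); dy <- c(diff(hi$y), NA)
  dt <- c(diff(hi$t), NA)
  v <- ifelse(dt == 1, sqrt(dx^2 + dy^2), NA)
  bearing_deg <- (atan2(dx, dy) * 180 / pi) %% 360
  slope <- grid_extract(terrain$slope, hi$x, hi$y)
  aspect <- grid_extract(terrain$aspect, hi$x, hi$y)
  dpsi <- aspect - bearing_deg          # NA on flats -> treated level
  theta_p <- ifelse(is.na(dpsi) | is.na(slope), 0,
                    experienced_slope(ifelse(is.na(slope), 0, slope),
                                      ifelse(is.na(dpsi), 0, dpsi)))
  moving <- hmm$second_moving[seq_len(n)]
  moving[is.na(moving)] <- FALSE
  theta_p[!moving] <- 0                 # incline irrelevant when stationary
  inc <- incline_class(theta_p, model)
  e <- rep(NA_real_, n)
  ok <- !is.na(v)
  e[ok] <- energy_per_second(v[ok], inc[ok], moving[ok], model)

  energy_sum <- numeric(nrow(disp))
  n_moving <- integer(nrow(disp))
  for (i in seq_len(nrow(disp))) {
    idx <- disp$row_start[i]:(disp$row_end[i] - 1)
    energy_sum[i] <- sum(e[idx])
    n_moving[i] <- sum(moving[idx])
  }
  disp$habitat <- label_displacement_habitat(disp, landscape)
  disp$energy_sum <- energy_sum
  disp$n_moving <- n_moving
  disp$cot <- compute_cot(energy_sum, disp$d_true)
  disp
}

#' Per-stage linear models of the cost of transport by habitat
#'
#' For each movement stage with at least two habitat levels (each with at
#' least `min_n` displacements), fits an ordinary least-squares model
#' `CoT ~ habitat` with the reference level first (roads by default, so
#' each coefficient is the CoT premium of that habitat over roads), and
#' computes all pairwise habitat contrasts with Wald tests from the OLS
#' covariance.
#'
#' @param records displacement table from [displacement_energetics()];
#'   rows with `NA` habitat are dropped.
#' @param reference reference habitat level.
#' @param min_n minimum displacements per habitat level.
#' @param cluster if `TRUE`, report per-individual cluster-robust
#'   standard errors (CR0 sandwich over `records$individual`) alongside
#'   the OLS ones in an extra `se_cluster` column.
#' @return A named list (one entry per stage) of lists with `fit` (the
#'   `lm`), `coefs` (term/estimate/se/t/p/CI) and `contrasts` (pairwise
#'   differences); stages with a single habitat are skipped with a
#'   warning.
#' @export
cot_models <- function(records, reference = "road", min_n = 2,
                       cluster = FALSE) {
  records <- records[!is.na(records$habitat), , drop = FALSE]
  out <- list()
  for (st in unique(records$stage)) {
    rs <- records[records$stage == st, , drop = FALSE]
    keep <- names(which(table(rs$habitat) >= min_n))
    rs <- rs[rs$habitat %in% keep, , drop = FALSE]
    if (length(unique(rs$habitat)) < 2) {
      warning("stage '", st, "' has fewer than two usable habitat levels; ",
              "skipped")
      next
    }
    levs <- unique(rs$habitat)
    if (reference %in% levs) {
      levs <- c(reference, setdiff(levs, reference))
    }
    rs$habitat <- factor(rs$habitat, levels = levs)
    fit <- stats::lm(cot ~ habitat, data = rs)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], t = sm[, 3], p = sm[, 4],
                        lo = ci[, 1], hi = ci[, 2], row.names = NULL)
    if (cluster && "individual" %in% names(rs)) {
      coefs$se_cluster <- cluster_se(fit, rs$individual)
    }
    out[[st]] <- list(fit = fit, coefs = coefs,
                      contrasts = pairwise_contrasts(fit, levs))
  }
  out
}

# all pairwise habitat contrasts from an lm of cot ~ habitat
pairwise_contrasts <- function(fit, levs) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  # cell means: reference = intercept, others = intercept + dummy
  cell <- function(h) {
    v <- rep(0, length(b)); v[1] <- 1
    nm <- paste0("habitat", h)
    if (nm %in% names(b)) v[names(b) == nm] <- 1
    v
  }
  prs <- utils::combn(levs, 2)
  res <- apply(prs, 2, function(pr) {
    d <- cell(pr[1]) - cell(pr[2])
    est <- sum(d * b)
    se <- sqrt(drop(t(d) %*% V %*% d))
    z <- est / se
    c(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(a = prs[1, ], b = prs[2, ], t(res), row.names = NULL)
}

# CR0 cluster-robust standard errors for an lm
cluster_se <- function(fit, cl) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cl)) {
    idx <- which(cl == g)
    sg <- crossprod(X[idx, , drop = FALSE], u[idx])
    meat <- meat + tcrossprod(sg)
  }
  sqrt(diag(bread %*% meat %*% bread))
}
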