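#' Generate alternative steps for one observed step
#'
#' Samples `m` control endpoints from the movement kernel of the step's
#' (individual, stage) key: length from the fitted gamma, direction from
#' the previous step's bearing plus a von Mises turning angle. Steps whose
#' predecessor was dropped have no previous bearing; their alternatives
#' use length-only sampling with uniform direction (flagged
#' `angle_class = "uniform"`). Endpoints falling outside the raster are
#' resampled up to `max_resample` rounds, after which the stratum is kept
#' with fewer alternatives.
#'
#' @param step one row of the retained-step table.
#' @param dist one row of [fit_step_distributions()] matching the step's
#'   key.
#' @param m number of alternative steps.
#' @param extent optional list `xmin`, `xmax`, `ymin`, `ymax` to resample
#'   against (e.g. the landscape extent).
#' @param max_resample resampling rounds for out-of-extent endpoints.
#' @return A data.frame of `m + 1` rows (case first): `is_case`, `x`, `y`,
#'   `L`, plus the step's metadata.
#' @export
generate_alternatives <- function(step, dist, m = 20, extent = NULL,
                                  max_resample = 100) {
  if (m <= 0) stop("`m` must be a positive count")
  has_angle <- !is.na(step$turn_angle)
  draw <- function(n) {
    len <- rgamma(n, shape = dist$shape, scale = dist$scale)
    if (has_angle) {
      prev_bearing <- step$bearing - step$turn_angle
      ang <- prev_bearing + rvonmises(n, dist$mu, dist$kappa)
    } else {
      ang <- runif(n, -pi, pi)
    }
    cbind(x = step$x_start + len * sin(ang),
          y = step$y_start + len * cos(ang), L = len)
  }
  pts <- draw(m)
  if (!is.null(extent)) {
    inside <- function(p) p[, "x"] >= extent$xmin & p[, "x"] < extent$xmax &
      p[, "y"] >= extent$ymin & p[, "y"] < extent$ymax
    ok <- inside(pts)
    tries <- 0
    while (any(!ok) && tries < max_resample) {
      pts[!ok, ] <- draw(sum(!ok))
      ok <- inside(pts)
      tries <- tries + 1
    }
    pts <- pts[ok, , drop = FALSE]  # give up on stubborn endpoints
  }
  out <- data.frame(
    is_case = c(1L, rep(0L, nrow(pts))),
    x = c(step$x_end, pts[, "x"]),
    y = c(step$y_end, pts[, "y"]),
    L = c(step$L, pts[, "L"]),
    individual = step$individual,
    stage = step$stage,
    step_id = step$step_id,
    angle_class = if (has_angle) "turn" else "uniform"
  )
  out
}

#' Assemble step-selection strata with endpoint covariates
#'
#' For every retained observed step, generates `m` alternatives from the
#' matching movement kernel, extracts raster covariates at all endpoints
#' and assembles the matched stratum (1 case + controls). Terrain
#' ruggedness enters z-scored over all endpoints used in the analysis
#' (scaling recorded in attributes); binary covariates enter as 0/1 and
#' cover as dummies against the scrub reference.
#'
#' @param steps retained-step table (possibly several individuals).
#' @param dists kernel table from [fit_step_distributions()].
#' @param landscape a [landscape_stack()].
#' @param terrain optional [terrain_layers()].
#' @param m alternatives per stratum.
#' @param seed RNG seed for alternative generation.
#' @return A data.frame of class `"sc_strata"`: `stratum_id`, `is_case`,
#'   `x`, `y`, `road`, `water`, `glade`, `riverine`, `bare`,
#'   `blackcotton`, `cover`, `tri_z`, `stage`, `individual`,
#'   `angle_class`. Attributes: `tri_center`, `tri_scale`, `n_lost`
#'   (endpoints dropped as irrecoverably off-raster).
#' @export
make_strata <- function(steps, dists, landscape, terrain = NULL, m = 20,
                        seed = 1L) {
  stopifnot(nrow(steps) > 0)
  if (is.null(terrain)) terrain <- terrain_layers(landscape$elevation)
  g <- landscape$cover
  extent <- list(xmin = g$xmin, xmax = grid_xmax(g),
                 ymin = g$ymin, ymax = grid_ymax(g))
  key <- paste(steps$individual, steps$stage)
  dkey <- paste(dists$individual, dists$stage)
  if (!all(key %in% dkey)) {
    stop("no fitted kernel for key(s): ",
         paste(unique(key[!key %in% dkey]), collapse = "; "))
  }
  with_seed(seed, {
    parts <- vector("list", nrow(steps))
    for (i in seq_len(nrow(steps))) {
      d <- dists[dkey == key[i], , drop = FALSE][1, ]
      s <- generate_alternatives(steps[i, ], d, m = m, extent = extent)
      s$stratum_id <- i
      parts[[i]] <- s
    }
    tab <- do.call(rbind, parts)
    cov <- extract_covariates(tab$x, tab$y, landscape, terrain)
    n_lost <- attr(cov, "n_excluded")
    tab <- tab[cov$point_id, , drop = FALSE]
    tri_c <- mean(cov$tri)
    tri_s <- sd(cov$tri)
    if (!is.finite(tri_s) || tri_s == 0) tri_s <- 1
    out <- data.frame(
      stratum_id = tab$stratum_id,
      is_case = tab$is_case,
      x = tab$x, y = tab$y,
      road = cov$road, water = cov$water,
      glade = as.numeric(cov$cover == "glade"),
      riverine = as.numeric(cov$cover == "riverine"),
      bare = as.numeric(cov$cover == "bare"),
      blackcotton = as.numeric(cov$cover == "blackcotton"),
      cover = as.character(cov$cover),
      tri_z = (cov$tri - tri_c) / tri_s,
      stage = tab$stage, individual = tab$individual,
      angle_class = tab$angle_class
    )
    rownames(out) <- NULL
    class(out) <- c("sc_strata", "data.frame")
    attr(out, "tri_center") <- tri_c
    attr(out, "tri_scale") <- tri_s
    attr(out, "n_lost") <- n_lost
    out
  })
}

#' Post-hoc removal of steps in excluded habitat classes
#'
#' Mirrors the decision to drop all steps (observed and alternative) in
#' habitats essentially unused by the reference animals, so the reference
#' level is represented wherever a coefficient is estimated. A stratum
#' whose *case* endpoint is in a dropped class is removed entirely (a case
#' cannot be compared without itself); alternatives in dropped classes are
#' removed from the remaining strata; strata left with fewer than 2 steps
#' are removed.
#'
#' @param strata an `"sc_strata"` table.
#' @param drop_classes cover class names to drop.
#' @return Filtered `"sc_strata"`; attribute `"filter_log"` records
#'   strata/step counts before and after.
#' @export
filter_habitat_posthoc <- function(strata,
                                   drop_classes = c("blackcotton", "bare")) {
  n0 <- c(strata = length(unique(strata$stratum_id)), steps = nrow(strata))
  bad_case <- unique(strata$stratum_id[strata$is_case == 1 &
                                         strata$cover %in% drop_classes])
  out <- strata[!(strata$stratum_id %in% bad_case), , drop = FALSE]
  out <- out[!(out$cover %in% drop_classes), , drop = FALSE]
  sz <- table(out$stratum_id)
  small <- names(sz)[sz < 2]
  out <- out[!(out$stratum_id %in% as.numeric(small)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sc_strata", "data.frame")
  for (a in c("tri_center", "tri_scale")) attr(out, a) <- attr(strata, a)
  attr(out, "filter_log") <- list(
    before = n0,
    after = c(strata = length(unique(out$stratum_id)), steps = nrow(out)),
    strata_dropped_by_case = length(bad_case),
    strata_dropped_too_small = length(small))
  out
}

#' Build a step-selection design matrix
#'
#' Three parameterisations of the habitat-by-stage model. Covariates are
#' `road`, `water`, `glade`, `riverine` and `tri_z` (cover dummies are
#' against the scrub reference; stage main effects are absorbed by the
#' strata and therefore omitted):
#'
#' * `within_stage`: one coefficient per covariate per movement stage
#'   (nested coding); each tests selection vs. 0 *within* that stage.
#' * `vs_resident`: covariate main effects (resident reference) plus
#'   covariate-by-stage interactions; each interaction tests the
#'   difference from residents.
#' * `two_level`: as `vs_resident` but with a two-level transient/resident
#'   factor, pooling active-dispersal and local-transience days.
#'
#' @param strata an `"sc_strata"` table.
#' @param variant `"within_stage"`, `"vs_resident"` or `"two_level"`.
#' @param covariates covariate column names to include.
#' @return List with the design matrix `X` (named columns), `case`,
#'   `stratum` and `variant`.
#' @export
build_design <- function(strata, variant = c("within_stage", "vs_resident",
                                             "two_level"),
                         covariates = c("road", "water", "glade",
                                        "riverine", "tri_z")) {
  variant <- match.arg(variant)
  stages <- c("resident", "local_transience", "active_dispersal")
  if (!all(strata$stage %in% stages)) {
    stop("unknown stage label(s): ",
         paste(setdiff(unique(strata$stage), stages), collapse = ", "))
  }
  Z <- as.matrix(strata[, covariates, drop = FALSE])
  X <- switch(
    variant,
    within_stage = {
      cols <- lapply(stages, function(s) Z * (strata$stage == s))
      out <- do.call(cbind, cols)
      colnames(out) <- as.vector(outer(covariates, stages, paste, sep = ":"))
      out
    },
    vs_resident = {
      loc <- Z * (strata$stage == "local_transience")
      act <- Z * (strata$stage == "active_dispersal")
      colnames(loc) <- paste0(covariates, ":local_transience")
      colnames(act) <- paste0(covariates, ":active_dispersal")
      cbind(Z, loc, act)
    },
    two_level = {
      tr <- Z * (strata$stage != "resident")
      colnames(tr) <- paste0(covariates, ":transient")
      cbind(Z, tr)
    })
  # a column with no within-stratum variation anywhere carries no
  # information for the conditional likelihood (it cancels from every
  # stratum) and would only make the fit rank deficient: drop it up front
  sid <- as.integer(factor(strata$stratum_id))
  nsz <- as.vector(table(sid))
  ssq <- rowsum(X^2, sid) - rowsum(X, sid)^2 / nsz
  keep <- colSums(ssq) > 1e-10
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    message("dropping term(s) with no within-stratum variation: ",
            paste(dropped, collapse = ", "))
  }
  list(X = X[, keep, drop = FALSE], case = strata$is_case,
       stratum = strata$stratum_id, variant = variant,
       dropped = dropped)
}

#' Fit a step-selection model
#'
#' Convenience wrapper: [build_design()] then [fit_clr()].
#'
#' @inheritParams build_design
#' @param ... passed to [fit_clr()].
#' @return An `"sc_clr_fit"` with the variant recorded in `$variant`.
#' @export
fit_ssa <- function(strata, variant = "within_stage",
                    covariates = c("road", "water", "glade", "riverine",
                                   "tri_z"), ...) {
  d <- build_design(strata, variant, covariates)
  X <- d$X
  # aliased (collinear after within-stratum centring) terms cannot be
  # separated by the data; drop them rather than abort the pipeline
  sid <- as.integer(factor(d$stratum))
  Xc <- X - rowsum(X, sid)[sid, , drop = FALSE] /
    as.vector(table(sid))[sid]
  qd <- qr(Xc)
  if (qd$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)),
                                   qd$pivot[seq_len(qd$rank)])]
    message("dropping aliased term(s): ", paste(aliased, collapse = ", "))
    X <- X[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
    d$dropped <- c(d$dropped, aliased)
  }
  fit <- fit_clr(X, d$case, d$stratum, ...)
  fit$variant <- d$variant
  fit$dropped <- d$dropped
  fit
}
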