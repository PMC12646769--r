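#' Configuration for the synthetic track simulator
#'
#' Describes how a simulated bird moves in each movement stage (`resident`,
#' `local_transience`, `active_dispersal`) and habitat. Five-minute steps
#' have gamma-distributed lengths and von Mises turning angles; at each
#' 5-min decision the walker samples `n_candidates` candidate endpoints
#' from that kernel and picks one with probability proportional to
#' `exp(beta' x)` of the endpoint covariates — the standard step-selection
#' data-generating mechanism, so planted coefficients are recoverable by a
#' conditional logistic regression. One-hertz positions are then laid along
#' the chosen step at a habitat-dependent walking speed with lateral
#' wiggle; once the endpoint is reached the bird stands still until the
#' next decision.
#'
#' Covariates entering the linear predictor (in this order): `road`,
#' `water` (0/1), `glade`, `riverine` (cover dummies, scrub reference) and
#' `tri_z` (terrain ruggedness, z-scored over the landscape). Default
#' planted coefficients follow the qualitative pattern of a terrestrial
#' disperser that exploits roads and open glades when making large
#' displacements while residents avoid roads; magnitudes are chosen to be
#' comfortably detectable at desk-scale sample sizes.
#'
#' @param step_shape,step_scale named numeric (one entry per stage): gamma
#'   shape and scale (m) of 5-min step lengths.
#' @param kappa named numeric per stage: von Mises concentration of 5-min
#'   turning angles (larger = straighter daily paths).
#' @param kappa_mult named numeric per habitat: multiplier on the stage
#'   concentration applied when the step starts in that habitat. A large
#'   road multiplier makes movement along roads straighter (the linearity
#'   of the feature channels movement), which is what lets road-following
#'   bouts emerge.
#' @param drift named numeric per stage: strength of the day-level goal
#'   bias. On each day the walker draws a goal point in the central part
#'   of the landscape and candidate weights gain
#'   `exp(drift * cos(bearing - goal bearing))`; a positive drift on
#'   active-dispersal days is what makes large, directed roost-to-roost
#'   displacements (the defining feature of active dispersal), while 0
#'   leaves undirected wandering.
#' @param beta named list per stage of numeric vectors (named `road`,
#'   `water`, `glade`, `riverine`, `tri_z`): planted selection
#'   coefficients.
#' @param speed named numeric per habitat (m/s): reference walking speed;
#'   an extra `road` entry overrides the cover class on road cells. The
#'   5-min step-length kernel is scaled by `speed / speed_ref` for the
#'   habitat at the step's start, so faster habitats yield longer steps —
#'   the mechanism by which open, linear features permit faster movement.
#'   The scaling is stratum-constant (all candidates share the start
#'   habitat), so it does not bias selection estimates. Realised
#'   per-second speed is the drawn step length divided by the step's
#'   walking time (see `rest_range`), so faster habitats produce genuinely
#'   faster 1 Hz movement at an unchanged resting fraction.
#' @param speed_ref reference speed (m/s) at which the step-length kernel
#'   applies unscaled.
#' @param rest_range range of the per-step resting fraction (drawn
#'   uniformly, independent of habitat): each 5-min step is walked in the
#'   first `1 - rest` share of the interval and the bird stands at the
#'   endpoint for the remainder, as foraging walkers do.
#' @param v_cap maximum sustained walking speed (m/s); steps too long for
#'   the walking window are walked faster up to this cap.
#' @param wiggle named numeric per habitat (m): lateral path wiggle scale;
#'   smaller = straighter fine-scale movement.
#' @param speed_cv coefficient of variation of per-second speed.
#' @param roost_return per-metre attraction strength pulling resident and
#'   local-transience birds back toward the morning roost after midday
#'   (candidate weights gain a factor `exp(-roost_return * dist_to_roost)`).
#' @param day_start,day_end duty cycle in hours of day (GPS tags record
#'   only during daylight, 06:00 to 19:00 by default).
#' @param step_seconds decision interval (s).
#' @param n_candidates candidate endpoints per decision.
#' @return A list of class `"walker_config"`.
#' @export
walker_config <- function(
    step_shape = c(resident = 1.2, local_transience = 1.3,
                   active_dispersal = 1.6),
    step_scale = c(resident = 35, local_transience = 50,
                   active_dispersal = 45),
    kappa = c(resident = 0.3, local_transience = 0.5, active_dispersal = 2),
    kappa_mult = c(scrub = 1, glade = 1, riverine = 1, bare = 1,
                   blackcotton = 1, road = 6),
    drift = c(resident = 0, local_transience = 0, active_dispersal = 0.8),
    beta = list(
      resident = c(road = -0.5, water = 0, glade = 0.4,
                   riverine = -0.1, tri_z = -0.10),
      local_transience = c(road = 0.25, water = 0, glade = 0.6,
                           riverine = -0.35, tri_z = -0.10),
      active_dispersal = c(road = 1.5, water = 0, glade = 0.5,
                           riverine = -0.4, tri_z = -0.10)),
    speed = c(scrub = 0.45, glade = 0.60, riverine = 0.40, bare = 0.60,
              blackcotton = 0.50, road = 0.90),
    wiggle = c(scrub = 8, glade = 4, riverine = 9, bare = 4,
               blackcotton = 6, road = 1),
    speed_ref = 0.45,
    rest_range = c(0.1, 0.4),
    v_cap = 1.3,
    speed_cv = 0.15,
    roost_return = 0.004,
    day_start = 6, day_end = 19,
    step_seconds = 300,
    n_candidates = 50) {
  stages <- c("resident", "local_transience", "active_dispersal")
  stopifnot(all(stages %in% names(step_shape)),
            all(stages %in% names(step_scale)),
            all(stages %in% names(kappa)),
            all(stages %in% names(beta)),
            all(stages %in% names(drift)), all(drift >= 0),
            all(step_shape > 0), all(step_scale > 0), all(kappa > 0),
            all(speed > 0), all(wiggle >= 0),
            length(rest_range) == 2, all(rest_range >= 0),
            all(rest_range < 1), v_cap > 0,
            day_end > day_start, step_seconds > 0, n_candidates >= 1)
  structure(as.list(environment()), class = "walker_config")
}

SSA_COVARS <- c("road", "water", "glade", "riverine", "tri_z")

#' Draw from the von Mises distribution
#'
#' Best-Fisher rejection sampler; reduces to uniform angles as
#' `kappa -> 0`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    th <- runif(n, -pi, pi)
    return(((th + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  (((mu + out) + pi) %% (2 * pi)) - pi
}

# Reflect coordinates into [lo, hi) (mirror folding; handles any overshoot).
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  v <- (v - lo) %% (2 * w)
  v <- ifelse(v >= w, 2 * w - v, v)
  # a point folded exactly onto hi maps to hi - 0 => keep strictly inside
  pmin(lo + v, hi - 1e-9)
}

# Candidate covariate matrix (columns SSA_COVARS) at endpoint coordinates.
candidate_covars <- function(stack, terr, tri_mean, tri_sd, x, y) {
  rc <- grid_cell(stack$cover, x, y)
  idx <- cbind(rc$row, rc$col)
  cov_code <- stack$cover$values[idx]
  cbind(road = stack$road$values[idx],
        water = stack$water$values[idx],
        glade = as.numeric(cov_code == 2L),
        riverine = as.numeric(cov_code == 3L),
        tri_z = (terr$tri$values[idx] - tri_mean) / tri_sd)
}

#' Simulate a dual-stage GPS track on a synthetic landscape
#'
#' Runs the step-selection-consistent movement model described in
#' [walker_config()] for one individual over `n_days` days, returning a
#' 1 Hz track covering the tag duty cycle each day. The bird roosts where
#' it ends each day and resumes there the next morning. Walkers that would
#' leave the landscape are reflected at the boundary.
#'
#' @param landscape a [landscape_stack()].
#' @param walker a [walker_config()].
#' @param stage_schedule character vector, one stage label per day, each in
#'   `resident`, `local_transience`, `active_dispersal`.
#' @param individual id string for the output.
#' @param start numeric `c(x, y)` start position (m); defaults to the
#'   landscape centre. Must lie inside the raster extent.
#' @param seed integer seed.
#' @return A data.frame of class `"sc_track"`, columns `individual`, `t`
#'   (seconds from 00:00 of day 1), `x`, `y`, `res_flag` (all `"hi"`),
#'   `day`, `stage`. Attributes: `beta` (the planted coefficients),
#'   `decisions` (the 5-min decision table with chosen/candidate metadata).
#' @export
simulate_track <- function(landscape, walker, stage_schedule,
                           individual = "bird01", start = NULL, seed = 1L) {
  stopifnot(inherits(landscape, "landscape_stack"),
            inherits(walker, "walker_config"))
  stages <- c("resident", "local_transience", "active_dispersal")
  if (!all(stage_schedule %in% stages)) {
    stop("stage_schedule entries must be one of: ",
         paste(stages, collapse = ", "))
  }
  g <- landscape$cover
  xmax <- grid_xmax(g); ymax <- grid_ymax(g)
  if (is.null(start)) {
    start <- c((g$xmin + xmax) / 2, (g$ymin + ymax) / 2)
  }
  if (is.na(grid_cell(g, start[1], start[2])$row[1])) {
    stop("walker start position lies outside the raster extent")
  }
  terr <- terrain_layers(landscape$elevation)
  tri_mean <- mean(terr$tri$values)
  tri_sd <- sd(terr$tri$values)
  if (!is.finite(tri_sd) || tri_sd == 0) tri_sd <- 1

  n_days <- length(stage_schedule)
  dt <- walker$step_seconds
  steps_per_day <- floor((walker$day_end - walker$day_start) * 3600 / dt)
  day_len <- steps_per_day * dt

  with_seed(seed, {
    fixes <- vector("list", n_days)
    decisions <- vector("list", n_days)
    pos <- start
    for (d in seq_len(n_days)) {
      stage <- stage_schedule[d]
      bvec <- walker$beta[[stage]][SSA_COVARS]
      shp <- walker$step_shape[[stage]]
      scl <- walker$step_scale[[stage]]
      kap <- walker$kappa[[stage]]
      t0 <- (d - 1) * 86400 + walker$day_start * 3600
      roost <- pos
      drift <- walker$drift[[stage]]
      if (drift > 0) {
        # day goal: a random point in the central 60% of the landscape,
        # keeping multi-day dispersers away from the reflecting edges
        gx <- runif(1, g$xmin + 0.2 * (xmax - g$xmin),
                    g$xmin + 0.8 * (xmax - g$xmin))
        gy <- runif(1, g$ymin + 0.2 * (ymax - g$ymin),
                    g$ymin + 0.8 * (ymax - g$ymin))
        goal_bearing <- atan2(gx - pos[1], gy - pos[2])
      }
      bearing <- NA_real_
      day_xy <- matrix(NA_real_, day_len + 1, 2)
      day_xy[1, ] <- pos
      dec <- vector("list", steps_per_day)
      for (s in seq_len(steps_per_day)) {
        m <- walker$n_candidates
        hab0 <- habitat_at(landscape, pos[1], pos[2])
        len_mult <- walker$speed[[hab0]] / walker$speed_ref
        len <- rgamma(m, shape = shp, scale = scl) * len_mult
        if (is.na(bearing)) {
          ang <- runif(m, -pi, pi)
        } else {
          ang <- bearing + rvonmises(m, 0, kap * walker$kappa_mult[[hab0]])
        }
        ex <- reflect_into(pos[1] + len * sin(ang), g$xmin, xmax)
        ey <- reflect_into(pos[2] + len * cos(ang), g$ymin, ymax)
        X <- candidate_covars(landscape, terr, tri_mean, tri_sd, ex, ey)
        lp <- as.vector(X %*% bvec)
        if (stage != "active_dispersal" && walker$roost_return > 0 &&
            s > steps_per_day / 2) {
          lp <- lp - walker$roost_return *
            sqrt((ex - roost[1])^2 + (ey - roost[2])^2)
        }
        if (drift > 0) lp <- lp + drift * cos(ang - goal_bearing)
        w <- exp(lp - max(lp))
        pick <- sample.int(m, 1L, prob = w)
        new_pos <- c(ex[pick], ey[pick])
        seg <- interpolate_step(pos, new_pos, dt, landscape, walker)
        day_xy[(s - 1) * dt + 1 + seq_len(dt), ] <- seg
        dec[[s]] <- c(step = s, x = new_pos[1], y = new_pos[2],
                      chosen_road = X[pick, "road"],
                      cand_road_frac = mean(X[, "road"]),
                      pick = pick)
        bearing <- atan2(new_pos[1] - pos[1], new_pos[2] - pos[2])
        pos <- new_pos
      }
      fixes[[d]] <- data.frame(
        individual = individual,
        t = t0 + 0:day_len,
        x = day_xy[, 1], y = day_xy[, 2],
        res_flag = "hi", day = d, stage = stage
      )
      decisions[[d]] <- cbind(day = d, do.call(rbind, dec))
    }
    out <- do.call(rbind, fixes)
    rownames(out) <- NULL
    class(out) <- c("sc_track", "data.frame")
    attr(out, "beta") <- walker$beta
    attr(out, "decisions") <- as.data.frame(do.call(rbind, decisions))
    out
  })
}

# 1 Hz positions along one 5-min step: walk the straight chord during the
# step's walking window (rest fraction drawn uniformly from rest_range,
# independent of habitat), with a Brownian-bridge lateral wiggle, then
# stand at the endpoint for the remaining seconds. Walking pace is the
# chord length over the walking time, capped at v_cap. Returns a dt x 2
# matrix of positions at seconds 1..dt (second 0 is the start position).
interpolate_step <- function(p0, p1, dt, landscape, walker) {
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  L <- sqrt(dx^2 + dy^2)
  if (L <= 0) {
    return(matrix(rep(p1, each = dt), dt, 2))
  }
  rest <- runif(1, walker$rest_range[1], walker$rest_range[2])
  walk_time <- max(ceiling((1 - rest) * dt), ceiling(L / walker$v_cap), 2)
  walk_time <- min(walk_time, dt)
  v <- L / walk_time
  sp <- pmax(0.05, v * (1 + walker$speed_cv * rnorm(dt)))
  s <- cumsum(sp)
  arrive <- which(s >= L)[1]
  if (is.na(arrive)) {
    s <- s * (L / s[dt])   # jitter left the bird short: stretch to arrive
    arrive <- dt
  }
  frac <- pmin(1, s / L)
  # lateral wiggle: Brownian bridge pinned to 0 at both ends of the chord
  hab <- habitat_at(landscape, p0[1], p0[2])
  wig <- walker$wiggle[[hab]]
  bb <- cumsum(rnorm(dt))
  bb <- (bb - frac * bb[arrive]) * (wig / sqrt(max(arrive, 2)))
  bb[frac >= 1] <- 0
  ux <- dx / L; uy <- dy / L           # unit along-chord
  px <- -uy; py <- ux                  # unit perpendicular
  x <- p0[1] + frac * dx + bb * px
  y <- p0[2] + frac * dy + bb * py
  g <- landscape$cover
  cbind(reflect_into(x, g$xmin, grid_xmax(g)),
        reflect_into(y, g$ymin, grid_ymax(g)))
}

# Habitat key for the speed/wiggle tables: road overrides cover.
habitat_at <- function(landscape, x, y) {
  rc <- grid_cell(landscape$cover, x, y)
  if (is.na(rc$row[1])) return("scrub")
  if (landscape$road$values[rc$row[1], rc$col[1]] > 0) return("road")
  COVER_LEVELS[landscape$cover$values[rc$row[1], rc$col[1]]]
}

#' Thin a 1 Hz track to the dual-rate GPS duty cycle
#'
#' Real tags record continuously at 1 Hz only while batteries are well
#' charged (up to 4.5 h per day) and otherwise fall back to one position
#' every 5 min. This thins a fully continuous simulated track to that
#' regime: each selected day keeps a contiguous 1 Hz window of
#' `hi_res_hours_per_day` starting at the duty-cycle start, and 5-min fixes
#' elsewhere; non-selected days are entirely low-resolution.
#'
#' @param track an `"sc_track"` at 1 Hz.
#' @param hi_res_hours_per_day hours of continuous 1 Hz recording per
#'   hi-res day; 0 gives a pure 5-min track, and a value covering the whole
#'   duty cycle returns the input unchanged.
#' @param hi_res_days which days (indices) get a hi-res window; default all.
#' @param lo_res_seconds low-resolution fix interval (s).
#' @return An `"sc_track"` with `res_flag` set to `"hi"`/`"lo"`.
#' @export
emit_dual_rate <- function(track, hi_res_hours_per_day = 4.5,
                           hi_res_days = NULL, lo_res_seconds = 300) {
  stopifnot(inherits(track, "sc_track"), hi_res_hours_per_day >= 0)
  days <- unique(track$day)
  if (is.null(hi_res_days)) hi_res_days <- days
  keep <- logical(nrow(track))
  flag <- rep("lo", nrow(track))
  for (d in days) {
    di <- which(track$day == d)
    tt <- track$t[di]
    t0 <- min(tt)
    hi_span <- if (d %in% hi_res_days) hi_res_hours_per_day * 3600 else 0
    in_hi <- hi_span > 0 & tt <= t0 + hi_span
    on_grid <- (tt - t0) %% lo_res_seconds == 0
    keep[di] <- in_hi | on_grid
    flag[di][in_hi] <- "hi"
  }
  out <- track[keep, , drop = FALSE]
  out$res_flag <- flag[keep]
  rownames(out) <- NULL
  class(out) <- c("sc_track", "data.frame")
  for (a in c("beta", "decisions")) attr(out, a) <- attr(track, a)
  out
}
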