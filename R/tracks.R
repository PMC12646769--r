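#' Read GPS tracks from CSV
#'
#' Expects the package's track schema: columns `individual_id`, `timestamp`
#' (ISO-8601, UTC), `x`, `y` (projected metres), optionally
#' `resolution_flag` (`hi`/`lo`) and `true_stage`. Returns one track per
#' individual, time-sorted; timestamps must be strictly increasing within
#' an individual.
#'
#' @param path CSV file.
#' @return A named list of `"sc_track"` data.frames (one per individual)
#'   with numeric `t` in seconds from the earliest date's midnight.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("track file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(ts))) stop("unparseable timestamp at row ", which(is.na(ts))[1])
  origin <- as.POSIXct(format(min(ts), "%Y-%m-%d"), tz = "UTC")
  tsec <- as.numeric(difftime(ts, origin, units = "secs"))
  out <- list()
  for (id in unique(df$individual_id)) {
    sel <- df$individual_id == id
    o <- order(tsec[sel])
    tt <- tsec[sel][o]
    dup <- which(diff(tt) <= 0)
    if (length(dup)) {
      stop("non-increasing/duplicated timestamp for individual '", id,
           "' at sorted row ", dup[1] + 1)
    }
    tr <- data.frame(
      individual = id, t = tt,
      x = df$x[sel][o], y = df$y[sel][o],
      res_flag = if ("resolution_flag" %in% names(df))
        df$resolution_flag[sel][o] else "hi",
      day = floor(tt / 86400) + 1,
      stage = if ("true_stage" %in% names(df)) df$true_stage[sel][o]
      else NA_character_
    )
    class(tr) <- c("sc_track", "data.frame")
    attr(tr, "origin") <- origin
    out[[id]] <- tr
  }
  out
}

#' Write tracks to CSV
#'
#' Inverse of [read_tracks()]; timestamps are written as ISO-8601 from the
#' track's origin date (attribute `"origin"`, default 2019-09-07).
#'
#' @param tracks an `"sc_track"` or list of them.
#' @param path output CSV.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "sc_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    origin <- attr(tr, "origin")
    if (is.null(origin)) origin <- as.POSIXct("2019-09-07", tz = "UTC")
    data.frame(
      individual_id = tr$individual,
      timestamp = format(origin + tr$t, "%Y-%m-%dT%H:%M:%S"),
      x = tr$x, y = tr$y,
      resolution_flag = tr$res_flag,
      true_stage = if ("stage" %in% names(tr)) tr$stage else NA
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Discretize a track into 5-minute steps
#'
#' Divides a (possibly mixed-resolution) track into consecutive
#' fixed-duration steps anchored at the track's first fix, then drops steps
#' whose net displacement is below `min_step` so the analysis reflects
#' where the animal moved rather than when. A retained step only carries a
#' turning angle when its immediate predecessor window was also retained;
#' dropped or missing windows break the angle chain.
#'
#' @param track an `"sc_track"`.
#' @param min_step minimum retained net displacement (m).
#' @param window step duration (s).
#' @param tol how close (s) a fix must be to a window boundary to anchor
#'   it; boundaries with no fix within `tol` are gaps.
#' @return A data.frame of retained steps: `individual`, `step_id` (window
#'   index), `t_start`, `t_end`, `x_start`, `y_start`, `x_end`, `y_end`,
#'   `L` (m), `bearing` (radians, from north), `turn_angle` (radians or
#'   `NA`), `stage`, `day`. Attributes `n_windows` (candidate steps) and
#'   `n_retained` report the filter funnel.
#' @export
discretize_5min <- function(track, min_step = 10, window = 300, tol = 60) {
  stopifnot(inherits(track, "sc_track"))
  if (nrow(track) < 2 || diff(range(track$t)) < 2 * window) {
    stop("track must span at least two step windows")
  }
  t0 <- track$t[1]
  kmax <- floor((track$t[nrow(track)] - t0) / window)
  bounds <- t0 + (0:kmax) * window
  # nearest fix to each boundary, within tol
  pos <- findInterval(bounds, track$t, all.inside = TRUE)
  cand <- cbind(pos, pmin(pos + 1, nrow(track)))
  derr <- abs(matrix(track$t[cand], ncol = 2) - bounds)
  pickcol <- max.col(-derr, ties.method = "first")
  fix_at <- cand[cbind(seq_along(bounds), pickcol)]
  fix_at[derr[cbind(seq_along(bounds), pickcol)] > tol] <- NA

  k <- which(!is.na(fix_at[-length(fix_at)]) & !is.na(fix_at[-1]))
  if (!length(k)) {
    out <- empty_steps()
    attr(out, "n_windows") <- 0L; attr(out, "n_retained") <- 0L
    return(out)
  }
  i0 <- fix_at[k]; i1 <- fix_at[k + 1]
  L <- sqrt((track$x[i1] - track$x[i0])^2 + (track$y[i1] - track$y[i0])^2)
  bearing <- atan2(track$x[i1] - track$x[i0], track$y[i1] - track$y[i0])
  steps <- data.frame(
    individual = track$individual[i0], step_id = k,
    t_start = track$t[i0], t_end = track$t[i1],
    x_start = track$x[i0], y_start = track$y[i0],
    x_end = track$x[i1], y_end = track$y[i1],
    L = L, bearing = bearing, turn_angle = NA_real_,
    stage = if ("stage" %in% names(track)) track$stage[i0] else NA_character_,
    day = floor(track$t[i0] / 86400) + 1
  )
  n_windows <- nrow(steps)
  retained <- steps[steps$L >= min_step, , drop = FALSE]
  if (nrow(retained) > 1) {
    prev <- c(NA, retained$step_id[-nrow(retained)])
    contiguous <- !is.na(prev) & retained$step_id == prev + 1
    ta <- retained$bearing - c(NA, retained$bearing[-nrow(retained)])
    retained$turn_angle <- ifelse(contiguous,
                                  ((ta + pi) %% (2 * pi)) - pi, NA_real_)
  }
  rownames(retained) <- NULL
  attr(retained, "n_windows") <- n_windows
  attr(retained, "n_retained") <- nrow(retained)
  retained
}

empty_steps <- function() {
  data.frame(individual = character(0), step_id = integer(0),
             t_start = numeric(0), t_end = numeric(0),
             x_start = numeric(0), y_start = numeric(0),
             x_end = numeric(0), y_end = numeric(0), L = numeric(0),
             bearing = numeric(0), turn_angle = numeric(0),
             stage = character(0), day = numeric(0))
}

#' Extract morning and evening roosts per day
#'
#' The tags run dawn to dusk, so the first and last fixes of a duty day
#' bracket where the bird slept. Days whose first or last fix falls more
#' than `slack_min` minutes inside the duty-cycle boundaries are flagged
#' incomplete and are excluded from day classification downstream.
#'
#' @param track an `"sc_track"`.
#' @param day_start,day_end duty cycle, hours of day.
#' @param slack_min tolerance (minutes) on duty-cycle coverage.
#' @return A data.frame: `individual`, `day`, `morning_x/y`, `evening_x/y`,
#'   `complete`, plus the day's total path length `P` (m, summed over all
#'   available fixes) and its stage label (modal over fixes).
#' @export
extract_roosts <- function(track, day_start = 6, day_end = 19,
                           slack_min = 30) {
  stopifnot(inherits(track, "sc_track"))
  days <- sort(unique(track$day))
  out <- lapply(days, function(d) {
    sel <- track$day == d
    tt <- track$t[sel]; xx <- track$x[sel]; yy <- track$y[sel]
    tod <- (tt - (d - 1) * 86400) / 3600
    complete <- (min(tod) <= day_start + slack_min / 60) &&
      (max(tod) >= day_end - slack_min / 60)
    P <- sum(sqrt(diff(xx)^2 + diff(yy)^2))
    st <- if ("stage" %in% names(track)) {
      names(sort(table(track$stage[sel]), decreasing = TRUE))[1]
    } else NA_character_
    data.frame(individual = track$individual[sel][1], day = d,
               morning_x = xx[1], morning_y = yy[1],
               evening_x = xx[length(xx)], evening_y = yy[length(yy)],
               complete = complete, P = P, stage = st)
  })
  do.call(rbind, out)
}

#' Classify days as active dispersal vs local/resident movement
#'
#' A day counts as active dispersal when the roost-to-roost displacement
#' `D` exceeds `d_hard` metres outright, or exceeds `d_soft` with a daily
#' straightness index (`D` over total path length) above `s_min` —
#' capturing large, directed displacements. Everything else is `local` for
#' transient birds and `resident` for residents.
#'
#' @param D roost-to-roost displacement (m), vectorised.
#' @param S straightness index in `[0, 1]`, vectorised.
#' @param resident logical; is the bird a non-dispersing resident?
#' @param d_hard,d_soft,s_min classification thresholds.
#' @return Character vector: `"active_dispersal"`, `"local"` or
#'   `"resident"`.
#' @export
classify_day <- function(D, S, resident = FALSE,
                         d_hard = 1500, d_soft = 1200, s_min = 0.3) {
  stopifnot(all(S >= 0 & S <= 1 | is.na(S)))
  active <- (D > d_hard) | (D > d_soft & S > s_min)
  ifelse(active, "active_dispersal", ifelse(resident, "resident", "local"))
}

#' Summarise and classify each tracking day
#'
#' Combines [extract_roosts()] and [classify_day()]: for each day after
#' the first, the displacement `D` is the distance between the previous
#' and current evening roosts, `P` the day's total path length and
#' `S = D/P` the straightness index. Incomplete days (and days following
#' one) get `NA` classification.
#'
#' @param track an `"sc_track"`.
#' @param resident logical; passed to [classify_day()].
#' @param ... thresholds passed to [classify_day()] / [extract_roosts()].
#' @return The roost table augmented with `D`, `S` and `classification`.
#' @export
day_summaries <- function(track, resident = FALSE, ...) {
  ro <- extract_roosts(track)
  n <- nrow(ro)
  ro$D <- NA_real_
  if (n >= 2) {
    ro$D[-1] <- sqrt(diff(ro$evening_x)^2 + diff(ro$evening_y)^2)
  }
  if (any(ro$P == 0 & !is.na(ro$D) & ro$D > 0)) {
    stop("day with zero path length but positive displacement: corrupt track")
  }
  ro$S <- ifelse(ro$P > 0, pmin(1, ro$D / ro$P), NA_real_)
  ok <- !is.na(ro$D) & ro$complete & c(FALSE, ro$complete[-n])
  ro$classification <- NA_character_
  ro$classification[ok] <- classify_day(ro$D[ok], ro$S[ok],
                                        resident = resident, ...)
  ro
}

#' Detect settlement from a run of stable roosts
#'
#' A disperser has settled once it uses the same roosting site for
#' `window` consecutive days; the settlement date is back-dated to the
#' first day of that run. "Same site" means all evening roosts of the run
#' lie within `radius` metres of their centroid.
#'
#' @param roosts a roost table from [extract_roosts()] (or
#'   [day_summaries()]), one individual.
#' @param radius site tolerance (m).
#' @param window run length (days).
#' @return The `day` value on which the settled run starts, or `NA` if the
#'   bird never settles.
#' @export
detect_settlement <- function(roosts, radius = 200, window = 14) {
  n <- nrow(roosts)
  if (n < window) return(NA_integer_)
  for (i in seq_len(n - window + 1)) {
    idx <- i:(i + window - 1)
    if (any(diff(roosts$day[idx]) != 1)) next  # run must be consecutive days
    cx <- mean(roosts$evening_x[idx]); cy <- mean(roosts$evening_y[idx])
    r <- sqrt((roosts$evening_x[idx] - cx)^2 +
                (roosts$evening_y[idx] - cy)^2)
    if (all(r <= radius)) return(roosts$day[i])
  }
  NA_integer_
}

#' Cut a 1 Hz track into 50 m net displacements
#'
#' Starting from the first high-resolution fix, walks forward until the
#' straight-line distance from the segment's start first reaches `radius`
#' metres; that fix closes the displacement and the next fix starts a new
#' one. Because sampling is discrete the realised ("true") distance
#' slightly overshoots the radius; it is stored and used as the
#' denominator of the cost of transport. Unclosed trailing segments are
#' discarded. Displacements never span gaps in 1 Hz coverage.
#'
#' @param track an `"sc_track"`; only fixes with `res_flag == "hi"` are
#'   used.
#' @param radius closing radius (m).
#' @return A data.frame of class `"sc_displacements"`: `individual`,
#'   `t_start`, `t_end`, `x_start`, `y_start`, `x_end`, `y_end`, `d_true`
#'   (m), `n_seconds`, `stage`, `day`, and `row_start`/`row_end` indexing
#'   the hi-res subset returned as attribute `"hires"`.
#' @export
net_displacements_50m <- function(track, radius = 50) {
  stopifnot(inherits(track, "sc_track"))
  hi <- track[track$res_flag == "hi", , drop = FALSE]
  rownames(hi) <- NULL
  recs <- list()
  if (nrow(hi) >= 2) {
    # contiguous 1 Hz runs
    brk <- c(0, which(diff(hi$t) != 1), nrow(hi))
    for (s in seq_len(length(brk) - 1)) {
      lo <- brk[s] + 1; up <- brk[s + 1]
      i <- lo
      while (i < up) {
        # expanding search window for the closing fix
        j <- NA_integer_
        w0 <- i + 1
        while (is.na(j) && w0 <= up) {
          w1 <- min(up, w0 + 1999)
          dd <- sqrt((hi$x[w0:w1] - hi$x[i])^2 + (hi$y[w0:w1] - hi$y[i])^2)
          hitpos <- which(dd >= radius)
          if (length(hitpos)) j <- w0 + hitpos[1] - 1
          w0 <- w1 + 1
        }
        if (is.na(j)) break  # unclosed tail
        recs[[length(recs) + 1]] <- data.frame(
          individual = hi$individual[i],
          t_start = hi$t[i], t_end = hi$t[j],
          x_start = hi$x[i], y_start = hi$y[i],
          x_end = hi$x[j], y_end = hi$y[j],
          d_true = sqrt((hi$x[j] - hi$x[i])^2 + (hi$y[j] - hi$y[i])^2),
          n_seconds = hi$t[j] - hi$t[i],
          stage = if ("stage" %in% names(hi)) hi$stage[i] else NA_character_,
          day = floor(hi$t[i] / 86400) + 1,
          row_start = i, row_end = j
        )
        i <- j + 1
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else data.frame(
    individual = character(0), t_start = numeric(0), t_end = numeric(0),
    x_start = numeric(0), y_start = numeric(0), x_end = numeric(0),
    y_end = numeric(0), d_true = numeric(0), n_seconds = numeric(0),
    stage = character(0), day = numeric(0),
    row_start = integer(0), row_end = integer(0))
  rownames(out) <- NULL
  class(out) <- c("sc_displacements", "data.frame")
  attr(out, "hires") <- hi
  out
}
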