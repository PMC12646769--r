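#' Pipeline configuration
#'
#' One object holding every threshold and module parameter of the
#' simulate / discretize / classify / step-selection / energetics
#' pipeline, with the analysis defaults baked in: 10 m minimum step, 50 m
#' displacement radius, 1500 m / 1200 m / 0.3 day-classification
#' thresholds, 14-day settlement window, 20 alternative steps per stratum.
#' Round-trips losslessly through JSON (see [write_pipeline_config()]).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_dispersers,n_residents number of simulated birds of each kind.
#' @param n_days simulated days per bird.
#' @param p_active probability that a disperser's transience day is an
#'   active-dispersal day (the rest are local prospecting).
#' @param hi_res_hours contiguous 1 Hz hours on a hi-res day.
#' @param hi_res_every a hi-res window occurs every this many days
#'   (batteries recharge between continuous bouts).
#' @param m alternative steps per stratum.
#' @param min_step minimum retained 5-min step length (m).
#' @param disp_radius net-displacement closing radius (m).
#' @param d_hard,d_soft,s_min day-classification thresholds (m, m, ratio).
#' @param settle_radius,settle_window settlement rule (m, days).
#' @param drop_classes cover classes removed post hoc before refitting.
#' @param reference_habitat reference level of the CoT models.
#' @param variants step-selection model variants to fit.
#' @param landscape a [landscape_config()].
#' @param walker a [walker_config()].
#' @param out_dir output directory or `NULL` for in-memory results only.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_dispersers = 3, n_residents = 4,
                            n_days = 12, p_active = 0.5,
                            hi_res_hours = 4.5, hi_res_every = 2,
                            m = 20, min_step = 10, disp_radius = 50,
                            d_hard = 1500, d_soft = 1200, s_min = 0.3,
                            settle_radius = 200, settle_window = 14,
                            drop_classes = c("blackcotton", "bare"),
                            reference_habitat = "road",
                            variants = c("within_stage", "vs_resident",
                                         "two_level"),
                            landscape = landscape_config(seed = seed),
                            walker = walker_config(),
                            out_dir = NULL) {
  stopifnot(min_step > 0, disp_radius > 0, d_hard > d_soft, s_min > 0,
            m >= 1, n_days >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' JSON round-trip of a [pipeline_config()] (including the nested
#' landscape and walker configs).
#'
#' @param config a `"pipeline_config"`.
#' @param path JSON file.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_all(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

unclass_all <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_all)
  } else if (!is.null(names(x)) && length(x) > 1) {
    as.list(x)   # keep element names through JSON (objects, not arrays)
  } else x
}

#' @rdname write_pipeline_config
#' @return `read_pipeline_config()` returns the restored
#'   `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON objects come back as named lists of scalars: re-vectorise them
  revec <- function(x) {
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE))) {
      unlist(x)
    } else x
  }
  lj <- lapply(j$landscape, revec)
  lc <- do.call(landscape_config,
                lj[names(lj) %in% names(formals(landscape_config))])
  wj <- lapply(j$walker, revec)
  wj$beta <- lapply(j$walker$beta, unlist)
  wc <- do.call(walker_config,
                wj[names(wj) %in% names(formals(walker_config))])
  top <- lapply(j, revec)
  top <- top[names(top) %in% names(formals(pipeline_config))]
  top$landscape <- lc
  top$walker <- wc
  do.call(pipeline_config, top)
}

#' Simulate the full synthetic scenario of a configuration
#'
#' Generates the landscape and one dual-rate track per bird. Residents
#' follow an all-resident schedule; dispersers draw each transience day as
#' active dispersal with probability `p_active` (at least one day of each
#' type is forced so all three stages exist).
#'
#' @param config a [pipeline_config()].
#' @return List with `landscape`, `tracks` (named list of `"sc_track"`),
#'   `is_resident` (named logical).
#' @export
simulate_scenario <- function(config) {
  landscape <- generate_landscape(config$landscape)
  g <- landscape$cover
  ids <- c(sprintf("disp%02d", seq_len(config$n_dispersers)),
           sprintf("res%02d", seq_len(config$n_residents)))
  is_res <- c(rep(FALSE, config$n_dispersers),
              rep(TRUE, config$n_residents))
  names(is_res) <- ids
  tracks <- list()
  for (i in seq_along(ids)) {
    bird_seed <- (config$seed * 1000L + i) %% .Machine$integer.max
    sched <- with_seed(bird_seed, {
      if (is_res[i]) rep("resident", config$n_days)
      else {
        s <- ifelse(runif(config$n_days) < config$p_active,
                    "active_dispersal", "local_transience")
        s[1] <- "active_dispersal"; s[2] <- "local_transience"
        s
      }
    })
    start <- with_seed(bird_seed + 7L, c(
      runif(1, g$xmin + 0.2 * (grid_xmax(g) - g$xmin),
            g$xmin + 0.8 * (grid_xmax(g) - g$xmin)),
      runif(1, g$ymin + 0.2 * (grid_ymax(g) - g$ymin),
            g$ymin + 0.8 * (grid_ymax(g) - g$ymin))))
    tr <- simulate_track(landscape, config$walker, sched,
                         individual = ids[i], start = start,
                         seed = bird_seed)
    tracks[[ids[i]]] <- emit_dual_rate(
      tr, config$hi_res_hours,
      hi_res_days = seq(1, config$n_days, by = config$hi_res_every))
  }
  list(landscape = landscape, tracks = tracks, is_resident = is_res)
}

#' Run the full analysis pipeline
#'
#' simulate -> discretize -> classify days -> step-selection analysis
#' (all requested variants, before and after the post-hoc habitat filter)
#' -> HMM + energetics -> per-stage CoT models, with a manifest of row
#' counts at every filtering stage. Movement stages entering the analyses
#' come from the day classifier, not from the simulator's ground truth,
#' so the pipeline is exercised end-to-end.
#'
#' @param config a [pipeline_config()].
#' @param scenario optionally, a pre-built [simulate_scenario()] result
#'   (so callers can reuse one simulation across analyses).
#' @return A list of class `"sc_pipeline_result"`: `landscape`, `tracks`,
#'   `day_class`, `steps`, `dists`, `strata`, `strata_filtered`, `fits`
#'   (per variant: fit + RSS table), `records` (displacement/CoT table),
#'   `cot` (per-stage models), `manifest`. If `config$out_dir` is set the
#'   tables are also written there as CSV (plus `manifest.json` and
#'   `report.md`).
#' @export
run_pipeline <- function(config, scenario = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(scenario)) scenario <- simulate_scenario(config)
  landscape <- scenario$landscape
  terr <- terrain_layers(landscape$elevation)
  tracks <- scenario$tracks
  is_res <- scenario$is_resident

  # day classification per bird; assign analysis stages by day
  day_class <- list()
  steps_all <- list()
  n_windows <- 0L
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    ds <- day_summaries(tr, resident = is_res[[id]],
                        d_hard = config$d_hard, d_soft = config$d_soft,
                        s_min = config$s_min)
    day_class[[id]] <- ds
    st <- discretize_5min(tr, min_step = config$min_step)
    n_windows <- n_windows + attr(st, "n_windows")
    # analysis stage = classified stage of the step's day
    cls <- ds$classification[match(st$day, ds$day)]
    cls[!is.na(cls) & cls == "local"] <- "local_transience"
    st$stage <- cls
    steps_all[[id]] <- st[!is.na(st$stage), , drop = FALSE]
  }
  steps <- do.call(rbind, steps_all)
  rownames(steps) <- NULL

  dists <- fit_step_distributions(steps)
  strata <- make_strata(steps, dists, landscape, terr, m = config$m,
                        seed = config$seed + 101L)
  strata_f <- filter_habitat_posthoc(strata, config$drop_classes)

  fits <- list()
  for (v in config$variants) {
    fit <- fit_ssa(strata_f, variant = v)
    fits[[v]] <- list(fit = fit, rss = rss_report(fit))
  }

  # energetics: one HMM per bird, displacements pooled
  rec_list <- list()
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    disp <- net_displacements_50m(tr, radius = config$disp_radius)
    if (nrow(disp) == 0) next
    hmm <- tryCatch(
      fit_hmm(tr, seed = config$seed + 211L + match(id, names(tracks))),
      error = function(e) NULL)
    if (is.null(hmm)) next
    rec <- displacement_energetics(disp, hmm, landscape, terr)
    ds <- day_class[[id]]
    cls <- ds$classification[match(rec$day, ds$day)]
    cls[!is.na(cls) & cls == "local"] <- "local_transience"
    rec$stage <- cls
    rec_list[[id]] <- rec[!is.na(rec$stage), , drop = FALSE]
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  cot <- if (is.null(records) || nrow(records) == 0) list() else
    suppressWarnings(cot_models(records,
                                reference = config$reference_habitat))

  fl <- attr(strata_f, "filter_log")
  cfg_txt <- paste(deparse(unclass_all(config)), collapse = "")
  manifest <- list(
    seed = config$seed,
    config_hash = sum(utf8ToInt(cfg_txt) * seq_along(utf8ToInt(cfg_txt))) %%
      1e9,
    counts = list(
      raw_fixes = sum(vapply(tracks, nrow, 0L)),
      candidate_windows = n_windows,
      retained_steps = nrow(steps),
      strata = length(unique(strata$stratum_id)),
      strata_posthoc = fl$after[["strata"]],
      displacements = if (is.null(records)) 0L else nrow(records),
      displacements_same_habitat =
        if (is.null(records)) 0L else sum(!is.na(records$habitat))
    )
  )

  out <- list(landscape = landscape, tracks = tracks,
              day_class = day_class, steps = steps, dists = dists,
              strata = strata, strata_filtered = strata_f, fits = fits,
              records = records, cot = cot, manifest = manifest,
              config = config)
  class(out) <- "sc_pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Filter-funnel table from a pipeline manifest
#'
#' Counts at each stage of the pipeline: raw fixes, candidate 5-min
#' windows, retained steps, strata before and after the post-hoc habitat
#' filter, displacements, and same-habitat displacements.
#'
#' @param manifest the `manifest` element of a pipeline result (or a list
#'   read back from `manifest.json`).
#' @return A two-column data.frame `stage`, `count`.
#' @export
report_counts <- function(manifest) {
  cc <- manifest$counts
  data.frame(stage = names(cc), count = as.numeric(unlist(cc)),
             row.names = NULL)
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape(res$landscape, file.path(dir, "landscape"))
  write_tracks(res$tracks, file.path(dir, "tracks.csv"))
  utils::write.csv(do.call(rbind, res$day_class),
                   file.path(dir, "day_summaries.csv"), row.names = FALSE)
  utils::write.csv(res$steps, file.path(dir, "steps.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$strata_filtered),
                   file.path(dir, "strata.csv"), row.names = FALSE)
  for (v in names(res$fits)) {
    utils::write.csv(res$fits[[v]]$rss,
                     file.path(dir, paste0("ssa_", v, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$records)) {
    rec <- res$records
    utils::write.csv(
      data.frame(individual = rec$individual, stage = rec$stage,
                 t_start = rec$t_start, t_end = rec$t_end,
                 habitat = rec$habitat, d_true_m = rec$d_true,
                 energy_J_per_kg = rec$energy_sum,
                 cot_J_per_kg_m = rec$cot),
      file.path(dir, "displacements.csv"), row.names = FALSE)
  }
  for (st in names(res$cot)) {
    utils::write.csv(res$cot[[st]]$coefs,
                     file.path(dir, paste0("cot_", st, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report(res), file.path(dir, "report.md"))
  invisible(dir)
}

# markdown summary: RSS tables per variant and CoT coefficient tables
render_report <- function(res) {
  ln <- c("# Pipeline report", "",
          "## Filter funnel", "",
          knit_table(report_counts(res$manifest)), "")
  for (v in names(res$fits)) {
    ln <- c(ln, paste0("## Relative selection strength (", v, ")"), "",
            knit_table(res$fits[[v]]$rss[, c("term", "rss", "rss_lo",
                                             "rss_hi", "p", "stars")]), "")
  }
  for (st in names(res$cot)) {
    ln <- c(ln, paste0("## Cost of transport: ", st), "",
            knit_table(res$cot[[st]]$coefs), "")
  }
  ln
}

knit_table <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                         "|"))
  c(hdr, sep, rows)
}
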