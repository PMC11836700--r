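#' Configuration for an end-to-end pipeline run
#'
#' Bundles the synthetic-cohort configuration, the analysis thresholds and
#' the cost-model constants.  Thresholds default to the values used
#' throughout the package: day classification at 1500 m / 1200 m / 0.3,
#' 50 m displacement segments, coverage rules of >50% (speed) and >95%
#' (straightness), and a 2 h minimum of high-resolution data for daily
#' energy.
#'
#' @param sim a [sim_config()] describing the synthetic cohort (ignored when
#'   `fixes` is supplied).
#' @param fixes optional pre-existing fix table (as from [read_fixes()] or
#'   [simulate_cohort()], with a `context` column).
#' @param dem optional [dem_grid()]; by default terrain is simulated to cover
#'   the cohort extent.
#' @param seed seed for analysis-stage randomness (HMM restarts, matched-day
#'   draws).
#' @param net_threshold_high,net_threshold_low,ratio_threshold day
#'   classification thresholds (m, m, ratio).
#' @param segment_threshold displacement segment length (m).
#' @param coverage_speed,coverage_straightness strict window coverage minima.
#' @param min_hires_hours minimum hours of 1 Hz data for daily energy.
#' @param window_length analysis window length (s).
#' @param terrain_relief relief of the simulated terrain (m).
#' @param cost_params a [cost_model_params()].
#' @param hmm_restarts EM restarts for [fit_hmm()].
#' @param enforce_classification drop days whose rule-based day type
#'   disagrees with the generator context (large for `group-large` and
#'   `lone-disperser`, normal for `group-normal`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), fixes = NULL, dem = NULL, seed = 1L,
                       net_threshold_high = 1500, net_threshold_low = 1200,
                       ratio_threshold = 0.3, segment_threshold = 50,
                       coverage_speed = 0.5, coverage_straightness = 0.95,
                       min_hires_hours = 2, window_length = 300L,
                       terrain_relief = 30, cost_params = cost_model_params(),
                       hmm_restarts = 10L, enforce_classification = TRUE) {
  stopifnot(net_threshold_high > 0, net_threshold_low > 0, ratio_threshold > 0,
            segment_threshold > 0, min_hires_hours > 0)
  structure(list(sim = sim, fixes = fixes, dem = dem, seed = as.integer(seed),
                 net_threshold_high = net_threshold_high,
                 net_threshold_low = net_threshold_low,
                 ratio_threshold = ratio_threshold,
                 segment_threshold = segment_threshold,
                 coverage_speed = coverage_speed,
                 coverage_straightness = coverage_straightness,
                 min_hires_hours = min_hires_hours,
                 window_length = as.integer(window_length),
                 terrain_relief = terrain_relief,
                 cost_params = cost_params,
                 hmm_restarts = as.integer(hmm_restarts),
                 enforce_classification = enforce_classification),
            class = "run_config")
}

#' Run the full trajectory-energetics pipeline
#'
#' Orchestrates simulate (or ingest) -> split resolutions -> smooth speeds ->
#' classify days -> bin and decode behavioural states -> per-second costs ->
#' displacement segments and daily energy -> movement metrics -> mixed-model
#' context contrasts.  Deterministic given the seeds in `config`.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, stage outputs are persisted
#'   as CSV/JSON plus a manifest and a structured log.
#' @param verbose print stage progress.
#' @return An object of class `movecot_run`: list with `classification`,
#'   `daily` (metrics + energy), `windows`, `segments`, `hmm`, `contrasts`
#'   (list of `context_contrasts`), `raw_cot_ratios`, `manifest` and `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  logline <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    logline <<- c(logline, msg)
    if (verbose) message(msg)
  }

  # --- stage 1: data ---------------------------------------------------------
  if (is.null(config$fixes)) {
    note("simulate: cohort seed ", config$sim$seed)
    cohort <- simulate_cohort(config$sim)
    fixes <- cohort$fixes
    manifest <- cohort$manifest
  } else {
    fixes <- config$fixes
    manifest <- list(source = "external fixes")
    if (!"context" %in% names(fixes)) stop("fixes must carry a context column")
  }
  note("simulate: ", nrow(fixes), " fixes, ",
       length(unique(fixes$individual)), " individuals")

  dem <- config$dem
  if (is.null(dem)) {
    pad <- 500
    xr <- range(fixes$x); yr <- range(fixes$y)
    nc <- max(3, ceiling((diff(xr) + 2 * pad) / 30))
    nr <- max(3, ceiling((diff(yr) + 2 * pad) / 30))
    dem <- simulate_terrain(config$seed, nr, nc, cell_size = 30,
                            relief = config$terrain_relief,
                            xll = xr[1] - pad, yll = yr[1] - pad)
    note("terrain: simulated ", nr, " x ", nc, " grid, relief ",
         config$terrain_relief, " m")
  }
  dem <- compute_slope_aspect(dem)

  # --- stage 2: per-day preprocessing ---------------------------------------
  key <- paste(fixes$individual, fixes$date)
  per_day <- split(fixes, factor(key, levels = unique(key)))
  day_sec <- config$sim$day_seconds %||% 46800L
  tracks <- lapply(per_day, function(df) {
    smooth_speeds(split_resolutions(df, day_seconds = day_sec,
                                    context = df$context[1]))
  })
  note("preprocess: ", length(tracks), " individual-days")

  # --- stage 3: day classification ------------------------------------------
  classification <- do.call(rbind, lapply(tracks, classify_day,
                                          net_threshold_high = config$net_threshold_high,
                                          net_threshold_low = config$net_threshold_low,
                                          ratio_threshold = config$ratio_threshold))
  rownames(classification) <- NULL
  n_before <- length(tracks)
  if (config$enforce_classification && nrow(classification) > 0) {
    expected <- ifelse(classification$context == "group-normal", "normal", "large")
    ok_key <- paste(classification$individual, classification$date)[classification$label == expected]
    keep <- names(tracks) %in% ok_key
    tracks <- tracks[keep]
    note("classify-days: ", n_before - length(tracks),
         " day(s) dropped (day type disagrees with context), ",
         length(tracks), " retained")
  }

  # --- stage 4: behavioural states ------------------------------------------
  bins <- do.call(rbind, lapply(tracks, bin_10s))
  rownames(bins) <- NULL
  note("fit-hmm: ", nrow(bins), " ten-second bins")
  hmm <- fit_hmm(bins, seed = config$seed, n_restarts = config$hmm_restarts)
  decoded <- decode_states(hmm, bins)
  dec_by_day <- split(decoded, paste(decoded$individual, decoded$date))
  tracks <- lapply(tracks, function(tr) {
    k <- paste(tr$individual, tr$date)
    dd <- dec_by_day[[k]]
    if (is.null(dd)) { tr$state <- rep(NA_integer_, nrow(tr$fixes)); tr$moving <- tr$state >= 2L; tr }
    else expand_states_to_seconds(dd, tr)
  })

  # --- stage 5: energetics ---------------------------------------------------
  tracks <- lapply(tracks, annotate_costs, dem = dem, params = config$cost_params)

  # --- stage 6: segments, daily energy --------------------------------------
  segs <- do.call(rbind, c(
    lapply(tracks, function(tr) suppressMessages(segment_net(tr, config$segment_threshold))),
    lapply(tracks, function(tr) suppressMessages(segment_cumulative(tr, config$segment_threshold)))))
  rownames(segs) <- NULL
  segs$hour <- segs$t_start %/% 3600L
  note("cot: ", sum(segs$type == "net"), " net and ",
       sum(segs$type == "cumulative"), " cumulative segments")
  denergy <- do.call(rbind, lapply(tracks, function(tr) {
    suppressMessages(daily_energy(tr, min_hours = config$min_hires_hours,
                                  day_seconds = day_sec))
  }))
  rownames(denergy) <- NULL
  note("daily-energy: ", nrow(denergy), " day(s) with >= ",
       config$min_hires_hours, " h of 1 Hz data")

  # --- stage 7: movement metrics --------------------------------------------
  daily <- do.call(rbind, lapply(tracks, daily_metrics))
  rownames(daily) <- NULL
  windows <- do.call(rbind, lapply(tracks, window_metrics,
                                   length = config$window_length,
                                   coverage_speed = config$coverage_speed,
                                   coverage_straightness = config$coverage_straightness))
  rownames(windows) <- NULL
  note("metrics: ", nrow(daily), " daily rows, ", nrow(windows), " window rows")

  # --- stage 8: contrasts ----------------------------------------------------
  wspeed <- windows[windows$metric == "speed", ]
  wstraight <- windows[windows$metric == "straightness", ]
  contrasts <- list()
  safe_fit <- function(name, expr) {
    res <- tryCatch(suppressWarnings(expr), error = function(e) {
      note("stats: ", name, " failed: ", conditionMessage(e)); NULL })
    if (!is.null(res)) contrasts[[name]] <<- res
  }
  safe_fit("track_length",
           fit_context_lmm(daily, "track_length", random = "individual"))
  safe_fit("daily_straightness",
           fit_straightness_beta(daily, "straightness", random = "individual"))
  safe_fit("window_speed",
           fit_context_lmm(transform(wspeed, value = value), "value",
                           random = c("individual", "hour")))
  safe_fit("window_straightness",
           fit_straightness_beta(wstraight, "value", random = c("individual", "hour")))
  safe_fit("cot_net",
           fit_context_lmm(segs[segs$type == "net", ], "cot",
                           random = c("individual", "hour")))
  safe_fit("cot_cumulative",
           fit_context_lmm(segs[segs$type == "cumulative", ], "cot",
                           random = c("individual", "hour")))
  safe_fit("daily_energy",
           fit_context_lmm(denergy, "daily_energy", random = "individual",
                           log_response = FALSE))
  note("stats: ", length(contrasts), " contrast model(s) fitted")

  # raw mean cot ratios, labelled, alongside the model-derived back-transforms
  raw_ratio <- function(type, a, b) {
    s <- segs[segs$type == type, ]
    mean(s$cot[s$context == a]) / mean(s$cot[s$context == b])
  }
  raw_cot_ratios <- data.frame(
    type = rep(c("net", "cumulative"), each = 2),
    contrast = rep(c("group-large vs group-normal", "lone-disperser vs group-large"), 2),
    raw_mean_ratio = c(raw_ratio("net", "group-large", "group-normal"),
                       raw_ratio("net", "lone-disperser", "group-large"),
                       raw_ratio("cumulative", "group-large", "group-normal"),
                       raw_ratio("cumulative", "lone-disperser", "group-large")),
    stringsAsFactors = FALSE)

  run <- structure(list(config = config, manifest = manifest,
                        classification = classification,
                        daily = daily, daily_energy = denergy,
                        windows = windows, segments = segs,
                        hmm = hmm, contrasts = contrasts,
                        raw_cot_ratios = raw_cot_ratios, log = logline),
                   class = "movecot_run")
  if (!is.null(out_dir)) persist_run(run, out_dir)
  run
}

persist_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(run$classification, "day_classification.csv")
  w(run$daily, "daily_metrics.csv")
  w(run$daily_energy, "daily_energy.csv")
  w(run$windows, "window_metrics.csv")
  w(run$segments, "segments.csv")
  w(run$raw_cot_ratios, "raw_cot_ratios.csv")
  report_contrasts(unname(run$contrasts),
                   csv = file.path(out_dir, "contrasts.csv"),
                   json = file.path(out_dir, "contrasts.json"))
  if (!is.null(run$manifest$seed)) {
    write_manifest(run$manifest, file.path(out_dir, "manifest.txt"))
  }
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.movecot_run <- function(x, ...) {
  cat("movecot pipeline run\n")
  cat("  days:", nrow(x$classification), "classified;",
      nrow(x$daily), "with daily metrics\n")
  cat("  segments:", sum(x$segments$type == "net"), "net /",
      sum(x$segments$type == "cumulative"), "cumulative\n")
  for (nm in names(x$contrasts)) {
    cat("--", nm, "--\n")
    print(x$contrasts[[nm]])
  }
  invisible(x)
}
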