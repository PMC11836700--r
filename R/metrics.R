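#' Daily track length from the 5 min series
#'
#' Sum of consecutive 5 min displacements, the measure available for every
#' bird on every day regardless of high-resolution coverage.
#'
#' @param track a `day_track`.
#' @return Track length in metres, or `NA` with a message when fewer than two
#'   5 min fixes exist.
#' @export
daily_track_length <- function(track) {
  stopifnot(inherits(track, "day_track"))
  fm <- track$five_min
  if (nrow(fm) < 2) {
    message("daily track length undefined (< 2 five-min fixes): ",
            track$individual, " ", format(track$date))
    return(NA_real_)
  }
  sum(step_lengths(fm$x, fm$y))
}

#' Straightness index of a point sequence
#'
#' Net displacement (first to last point) divided by the cumulative
#' displacement (summed consecutive step lengths).  1 for a perfectly
#' straight path; undefined (NA) when the cumulative displacement is zero.
#'
#' @param x,y planar coordinates in metres.
#' @return Straightness in `[0, 1]`, or `NA`.
#' @export
straightness_index <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  cum <- sum(step_lengths(x, y))
  if (cum == 0) return(NA_real_)
  sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2) / cum
}

#' Daily movement metrics for one track
#'
#' One observation per individual per day: daily track length and day-level
#' straightness (roost-to-roost distance over the 5 min track length).
#'
#' @param track a `day_track`.
#' @return data.frame with one row (`individual`, `date`, `context`,
#'   `track_length`, `straightness`), or zero rows when undefined.
#' @export
daily_metrics <- function(track) {
  stopifnot(inherits(track, "day_track"))
  fm <- track$five_min
  if (nrow(fm) < 2) return(data.frame(individual = character(0),
                                      date = as.Date(character(0)),
                                      context = character(0),
                                      track_length = numeric(0),
                                      straightness = numeric(0)))
  data.frame(individual = track$individual, date = track$date,
             context = track$context,
             track_length = daily_track_length(track),
             straightness = straightness_index(fm$x, fm$y),
             stringsAsFactors = FALSE)
}

#' Windowed speed-while-moving and straightness
#'
#' For each qualifying analysis window, computes (i) the mean smoothed speed
#' over seconds decoded to moving states 2-4 (windows must strictly exceed
#' `coverage_speed` high-resolution coverage; windows with no moving seconds
#' yield no speed observation) and (ii) the straightness index over the
#' window's 1 Hz positions (coverage strictly above `coverage_straightness`).
#'
#' @param track a `day_track` processed by [smooth_speeds()] and
#'   [expand_states_to_seconds()].
#' @param length window length in seconds (see [make_windows()]).
#' @param coverage_speed,coverage_straightness strict minimum coverages.
#' @return data.frame with one row per window and metric: `individual`,
#'   `date`, `context`, `window_start`, `length`, `hour`, `metric`
#'   (`speed` or `straightness`), `value`.
#' @export
window_metrics <- function(track, length = 300L, coverage_speed = 0.5,
                           coverage_straightness = 0.95) {
  stopifnot(inherits(track, "day_track"))
  if (is.null(track$state)) stop("track has no decoded states")
  empty <- data.frame(individual = character(0), date = as.Date(character(0)),
                      context = character(0), window_start = integer(0),
                      length = integer(0), hour = integer(0),
                      metric = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  ws <- make_windows(track, length, coverage_min = 0)
  fx <- track$fixes
  idx <- which(!is.na(fx$block))
  if (length(idx) == 0 || nrow(ws) == 0) return(empty)
  cov <- setNames(ws$coverage, ws$start)
  row_for <- function(w, metric, value) data.frame(
    individual = track$individual, date = track$date, context = track$context,
    window_start = w, length = length, hour = w %/% 3600L,
    metric = metric, value = value, stringsAsFactors = FALSE)
  out <- list()
  # speed-while-moving: mean smoothed speed over moving seconds per window
  mv <- idx[!is.na(track$moving[idx]) & track$moving[idx] & !is.na(track$v[idx])]
  if (length(mv) > 0) {
    wmv <- fx$t[mv] %/% length * length
    spd <- tapply(track$v[mv], wmv, mean)
    w <- as.integer(names(spd))
    keep <- cov[as.character(w)] > coverage_speed
    if (any(keep)) out[[1L]] <- row_for(w[keep], "speed", as.numeric(spd)[keep])
  }
  # straightness: net over cumulative displacement within each window
  n <- nrow(fx)
  i <- idx[idx < n]
  same_block <- fx$block[i + 1L] == fx$block[i]
  same_window <- (fx$t[i] %/% length) == (fx$t[i + 1L] %/% length)
  step_ok <- i[same_block %in% TRUE & same_window]
  if (length(step_ok) > 0) {
    d <- sqrt((fx$x[step_ok + 1L] - fx$x[step_ok])^2 +
                (fx$y[step_ok + 1L] - fx$y[step_ok])^2)
    wstep <- fx$t[step_ok] %/% length * length
    cum <- tapply(d, wstep, sum)
    wid_fix <- fx$t[idx] %/% length * length
    first <- tapply(idx, wid_fix, min)
    last <- tapply(idx, wid_fix, max)
    w <- as.integer(names(cum))
    net <- sqrt((fx$x[last[names(cum)]] - fx$x[first[names(cum)]])^2 +
                  (fx$y[last[names(cum)]] - fx$y[first[names(cum)]])^2)
    keep <- cov[as.character(w)] > coverage_straightness & cum > 0
    if (any(keep)) {
      out[[length(out) + 1L]] <- row_for(w[keep], "straightness",
                                         as.numeric(net / cum)[keep])
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$metric, res$window_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Recompute windowed metrics over a grid of temporal resolutions
#'
#' Sensitivity analysis of the windowed speed and straightness measures:
#' [window_metrics()] is applied at each requested window length with the
#' same coverage rules.
#'
#' @param tracks list of processed `day_track` objects.
#' @param lengths window lengths in seconds.
#' @param ... passed to [window_metrics()].
#' @return data.frame of windowed metrics across all lengths.
#' @export
sensitivity_grid <- function(tracks, lengths = c(30L, 60L, 120L, 300L, 600L,
                                                 900L, 1800L, 3600L), ...) {
  out <- list()
  for (len in lengths) {
    res <- lapply(tracks, window_metrics, length = len, ...)
    out[[length(out) + 1L]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
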