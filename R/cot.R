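segment_frame <- function() {
  data.frame(individual = character(0), date = as.Date(character(0)),
             context = character(0), type = character(0), block = integer(0),
             t_start = integer(0), t_end = integer(0), distance = numeric(0),
             energy = numeric(0), cot = numeric(0), stringsAsFactors = FALSE)
}

segment_block <- function(track, b, type, threshold) {
  i0 <- track$blocks[b, 1]; i1 <- track$blocks[b, 2]
  x <- track$fixes$x[i0:i1]; y <- track$fixes$y[i0:i1]
  L <- length(x)
  if (L < 2L) return(segment_frame())
  if (type == "net") {
    ends <- cpp_segment_net(x, y, threshold)
  } else {
    ends <- cpp_segment_cum(step_lengths(x, y), threshold)
  }
  if (length(ends) == 0) {
    message("block never reaches ", threshold, " m ", type, " displacement: ",
            track$individual, " ", format(track$date), " block ", b)
    return(segment_frame())
  }
  starts <- c(1L, ends[-length(ends)])
  cost <- track$cost[i0:i1]
  cs <- cumsum(c(0, ifelse(is.na(cost), 0, cost)))
  n_na <- function(a, z) sum(is.na(cost[a:(z - 1L)]))
  dist <- numeric(length(ends))
  energy <- numeric(length(ends))
  keep <- logical(length(ends))
  csl <- cumsum(c(0, step_lengths(x, y)))
  for (s in seq_along(ends)) {
    a <- starts[s]; z <- ends[s]
    dist[s] <- if (type == "net") {
      sqrt((x[z] - x[a])^2 + (y[z] - y[a])^2)
    } else {
      csl[z] - csl[a]
    }
    # energy over the half-open interval [start fix, crossing fix): the
    # crossing fix opens the next segment and its interval cost belongs there
    energy[s] <- cs[z] - cs[a]
    keep[s] <- n_na(a, z) == 0
  }
  if (any(!keep)) {
    message(sum(!keep), " segment(s) dropped for missing per-second costs")
  }
  out <- data.frame(individual = track$individual, date = track$date,
                    context = track$context, type = type, block = b,
                    t_start = track$fixes$t[i0 + starts - 1L],
                    t_end = track$fixes$t[i0 + ends - 1L],
                    distance = dist, energy = energy,
                    cot = energy / dist, stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Partition a track into 50 m net-displacement segments
#'
#' Starting from the first fix of each high-resolution block, a segment ends
#' at the first fix at net (straight-line) distance of at least `threshold`
#' metres from the segment's start fix; that crossing fix opens the next
#' segment.  The trailing incomplete segment is discarded.  Segment energy is
#' the sum of per-second costs over the seconds spanned (from the start fix
#' up to, but not including, the crossing fix, whose own interval belongs to
#' the next segment), and the cost of transport is energy divided by the true
#' achieved distance.  Segments never span block boundaries.
#'
#' @param track a `day_track` annotated by [annotate_costs()].
#' @param threshold displacement threshold in metres.
#' @return data.frame with one row per segment: `individual`, `date`,
#'   `context`, `type`, `block`, `t_start`, `t_end`, `distance` (m),
#'   `energy` (J kg^-1), `cot` (J kg^-1 m^-1).
#' @export
segment_net <- function(track, threshold = 50) {
  stopifnot(inherits(track, "day_track"), threshold > 0)
  if (is.null(track$cost)) stop("track has no costs; run annotate_costs()")
  res <- lapply(seq_len(nrow(track$blocks)), segment_block,
                track = track, type = "net", threshold = threshold)
  out <- do.call(rbind, c(list(segment_frame()), res))
  rownames(out) <- NULL
  out
}

#' Partition a track into 50 m cumulative-displacement segments
#'
#' As [segment_net()], but a segment closes at the step that brings the
#' running sum of step lengths to at least `threshold` metres.
#'
#' @inheritParams segment_net
#' @return data.frame as in [segment_net()] with `type = "cumulative"`.
#' @export
segment_cumulative <- function(track, threshold = 50) {
  stopifnot(inherits(track, "day_track"), threshold > 0)
  if (is.null(track$cost)) stop("track has no costs; run annotate_costs()")
  res <- lapply(seq_len(nrow(track$blocks)), segment_block,
                track = track, type = "cumulative", threshold = threshold)
  out <- do.call(rbind, c(list(segment_frame()), res))
  rownames(out) <- NULL
  out
}

#' Standardized daily energy expenditure
#'
#' Averages the per-second costs over the day's available high-resolution
#' seconds and multiplies by the 46 800 s of a 13 h tracking day.  Days with
#' fewer than `min_hours` hours of high-resolution data are excluded.
#'
#' @param track a `day_track` annotated by [annotate_costs()].
#' @param min_hours minimum hours of high-resolution data for inclusion.
#' @param day_seconds standardizing day length in seconds.
#' @return data.frame with one row (`individual`, `date`, `context`,
#'   `mean_cost`, `daily_energy`, `hires_hours`) or zero rows when the day is
#'   excluded.
#' @export
daily_energy <- function(track, min_hours = 2, day_seconds = 46800) {
  stopifnot(inherits(track, "day_track"))
  if (is.null(track$cost)) stop("track has no costs; run annotate_costs()")
  cost <- track$cost[!is.na(track$cost)]
  hires_hours <- length(cost) / 3600
  if (hires_hours < min_hours) {
    message("day excluded from daily energy (", sprintf("%.2f", hires_hours),
            " h < ", min_hours, " h): ", track$individual, " ", format(track$date))
    return(data.frame(individual = character(0), date = as.Date(character(0)),
                      context = character(0), mean_cost = numeric(0),
                      daily_energy = numeric(0), hires_hours = numeric(0),
                      stringsAsFactors = FALSE))
  }
  m <- mean(cost)
  data.frame(individual = track$individual, date = track$date,
             context = track$context, mean_cost = m,
             daily_energy = m * day_seconds, hires_hours = hires_hours,
             stringsAsFactors = FALSE)
}
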