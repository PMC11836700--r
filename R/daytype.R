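#' Classify a day as a large-displacement or normal day
#'
#' Computes the roost-to-roost distance (net displacement between the first
#' and last daily fix of the 5 min series), the daily track length (sum of
#' consecutive 5 min displacements) and their ratio, then labels the day
#' `large` when the roost-to-roost distance exceeds 1500 m, or exceeds
#' 1200 m with a straightness ratio above 0.3; otherwise `normal`.  All
#' inequalities are strict.
#'
#' @param track a `day_track` from [split_resolutions()].
#' @param net_threshold_high,net_threshold_low,ratio_threshold classification
#'   thresholds in metres / ratio units.
#' @return data.frame with one row: `individual`, `date`, `context`,
#'   `roost_to_roost`, `track_length`, `ratio`, `label`; or zero rows when
#'   the day has fewer than two 5 min fixes (unclassifiable).
#' @export
classify_day <- function(track, net_threshold_high = 1500,
                         net_threshold_low = 1200, ratio_threshold = 0.3) {
  stopifnot(inherits(track, "day_track"))
  fm <- track$five_min
  if (nrow(fm) < 2) {
    message("day with < 2 five-min fixes is unclassifiable: ",
            track$individual, " ", format(track$date))
    return(data.frame(individual = character(0), date = as.Date(character(0)),
                      context = character(0), roost_to_roost = numeric(0),
                      track_length = numeric(0), ratio = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  n <- nrow(fm)
  r2r <- sqrt((fm$x[n] - fm$x[1])^2 + (fm$y[n] - fm$y[1])^2)
  len <- sum(step_lengths(fm$x, fm$y))
  ratio <- if (len > 0) r2r / len else NA_real_
  large <- (r2r > net_threshold_high) ||
    (r2r > net_threshold_low && !is.na(ratio) && ratio > ratio_threshold)
  data.frame(individual = track$individual, date = track$date,
             context = track$context,
             roost_to_roost = r2r, track_length = len, ratio = ratio,
             label = if (large) "large" else "normal",
             stringsAsFactors = FALSE)
}

#' Draw matched normal days for each individual
#'
#' For each individual with `N` large-displacement days, samples `N` of its
#' normal days uniformly without replacement (all of them, with a warning,
#' when fewer than `N` are available).  Individuals flagged as dispersers
#' contribute only their large days and receive no matched sample.
#'
#' @param classifications data.frame of per-day rows as returned by
#'   [classify_day()] (rows bound together).
#' @param seed integer seed making the draw reproducible.
#' @param disperser_individuals character vector of individual ids treated as
#'   lone dispersers.
#' @return The input rows that enter the analysis: all large days plus the
#'   matched normal days, with a `matched` logical column marking the latter.
#' @export
sample_matched_days <- function(classifications, seed,
                                disperser_individuals = character(0)) {
  stopifnot(is.data.frame(classifications))
  set.seed(seed)
  out <- list()
  for (id in sort(unique(classifications$individual))) {
    rows <- classifications[classifications$individual == id, , drop = FALSE]
    large <- rows[rows$label == "large", , drop = FALSE]
    if (nrow(large) > 0) {
      large$matched <- FALSE
      out[[length(out) + 1L]] <- large
    }
    if (id %in% disperser_individuals) next
    n_large <- nrow(large)
    if (n_large == 0) next
    normal <- rows[rows$label == "normal", , drop = FALSE]
    take <- min(n_large, nrow(normal))
    if (take < n_large) {
      warning("individual ", id, ": only ", take, " normal day(s) available to match ",
              n_large, " large day(s)")
    }
    if (take > 0) {
      pick <- sample(seq_len(nrow(normal)), take)
      matched <- normal[sort(pick), , drop = FALSE]
      matched$matched <- TRUE
      out[[length(out) + 1L]] <- matched
    }
  }
  if (length(out) == 0) {
    cbind(classifications[0, , drop = FALSE], matched = logical(0))
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
}
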