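#' Split one individual-day of fixes into analysis resolutions
#'
#' Separates a time-sorted fix table into (i) high-resolution blocks -
#' maximal runs of consecutive 1 Hz fixes (inter-fix gap <= `gap_tol` s) of
#' at least `min_block_len` fixes - and (ii) the 5 min series, which takes
#' for each 5 min slot the fix recorded at the slot's tenth second (available
#' both from burst data and by subsampling 1 Hz data).
#'
#' @param fixes data.frame for a single individual-day with columns
#'   `individual`, `date`, `t` (integer seconds since day start), `x`, `y`.
#' @param day_seconds length of the tracking day in seconds (13 h default).
#' @param slot_interval 5 min slot length in seconds.
#' @param gap_tol maximal inter-fix gap (s) within a continuous block.
#' @param min_block_len minimum number of fixes for a run to count as a
#'   high-resolution block; the default (30) excludes 10-fix bursts.
#' @param context optional context label carried through the pipeline.
#' @return An object of class `day_track`: list with `individual`, `date`,
#'   `context`, `fixes` (with a `block` id column, `NA` outside blocks),
#'   `blocks` (two-column matrix of first/last fix indices), `five_min`
#'   (data.frame `slot`, `t`, `x`, `y`) and `v` (per-fix smoothed speed,
#'   filled by [smooth_speeds()]).
#' @export
split_resolutions <- function(fixes, day_seconds = 46800L, slot_interval = 300L,
                              gap_tol = 1L, min_block_len = 30L, context = NA_character_) {
  stopifnot(all(c("t", "x", "y") %in% names(fixes)))
  fixes <- fixes[order(fixes$t), , drop = FALSE]
  rownames(fixes) <- NULL
  n <- nrow(fixes)
  block <- rep(NA_integer_, n)
  blocks <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("first", "last")))
  if (n > 0) {
    newrun <- c(TRUE, diff(fixes$t) > gap_tol)
    run_id <- cumsum(newrun)
    runs <- split(seq_len(n), run_id)
    keep <- vapply(runs, length, 1L) >= min_block_len
    runs <- runs[keep]
    if (length(runs) > 0) {
      blocks <- cbind(first = vapply(runs, min, 1L), last = vapply(runs, max, 1L))
      rownames(blocks) <- NULL
      for (b in seq_along(runs)) block[runs[[b]]] <- b
    }
  }
  fixes$block <- block
  # 5 min series: the fix at each slot's tenth second (offset 9)
  slot_t <- seq(0L, day_seconds - 1L, by = slot_interval) + 9L
  idx <- match(slot_t, fixes$t)
  five_min <- data.frame(slot = seq_along(slot_t) - 1L, t = slot_t,
                         x = fixes$x[idx], y = fixes$y[idx])
  five_min <- five_min[!is.na(idx), , drop = FALSE]
  rownames(five_min) <- NULL
  structure(list(individual = if (n > 0) fixes$individual[1] else NA_character_,
                 date = if (n > 0) fixes$date[1] else as.Date(NA),
                 context = context,
                 fixes = fixes, blocks = blocks, five_min = five_min,
                 v = rep(NA_real_, n),
                 day_seconds = as.integer(day_seconds)),
            class = "day_track")
}

#' @export
print.day_track <- function(x, ...) {
  cat("day_track:", x$individual, format(x$date), "\n")
  cat("  ", nrow(x$fixes), "fixes,", nrow(x$blocks), "high-resolution block(s),",
      nrow(x$five_min), "five-min slots\n")
  invisible(x)
}

#' Smooth per-second speeds over a rolling 5 s window
#'
#' Within each high-resolution block, the speed at second `t` is the mean
#' per-second displacement over the centred window `[t - 2, t + 2]`,
#' truncated to the seconds available at block edges.  The speed is indexed
#' by the fix opening each one-second interval, so a block of `L` fixes
#' yields `L - 1` speed values.
#'
#' @param track a `day_track` from [split_resolutions()].
#' @param window window width in seconds (odd; default 5).
#' @return The track with its `v` element filled (`NA` at fixes without a
#'   following interval or outside blocks).
#' @export
smooth_speeds <- function(track, window = 5L) {
  stopifnot(inherits(track, "day_track"))
  half <- (window - 1L) %/% 2L
  v <- rep(NA_real_, nrow(track$fixes))
  for (b in seq_len(nrow(track$blocks))) {
    i0 <- track$blocks[b, 1]; i1 <- track$blocks[b, 2]
    if (i1 - i0 < 1L) next
    d <- step_lengths(track$fixes$x[i0:i1], track$fixes$y[i0:i1])
    m <- length(d)
    cs <- c(0, cumsum(d))
    lo <- pmax(seq_len(m) - half, 1L)
    hi <- pmin(seq_len(m) + half, m)
    v[i0:(i1 - 1L)] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  track$v <- v
  track
}

#' Build coverage-filtered analysis windows
#'
#' Tiles the tracking day into fixed windows aligned to the day start and
#' retains those whose fraction of seconds covered by high-resolution data
#' strictly exceeds `coverage_min`.  A second is covered when both the fix
#' opening it and the following fix belong to the same block.
#'
#' @param track a `day_track`.
#' @param length window length in seconds; one of 30, 60, 120, 300, 600,
#'   900, 1800, 3600.
#' @param coverage_min minimum high-resolution coverage (strict inequality;
#'   0 retains all windows).
#' @return data.frame with columns `start`, `length`, `coverage`.
#' @export
make_windows <- function(track, length = 300L, coverage_min = 0.95) {
  stopifnot(inherits(track, "day_track"))
  allowed <- c(30L, 60L, 120L, 300L, 600L, 900L, 1800L, 3600L)
  if (!length %in% allowed) {
    stop("invalid window length; must be one of ", paste(allowed, collapse = ", "))
  }
  day_s <- track$day_seconds
  covered <- rep(FALSE, day_s)
  for (b in seq_len(nrow(track$blocks))) {
    t0 <- track$fixes$t[track$blocks[b, 1]]
    t1 <- track$fixes$t[track$blocks[b, 2]]
    if (t1 > t0) covered[(t0 + 1L):t1] <- TRUE  # interval seconds t0 .. t1-1
  }
  starts <- seq(0L, day_s - length, by = length)
  cov <- vapply(starts, function(s) mean(covered[(s + 1L):(s + length)]), 1)
  out <- data.frame(start = starts, length = length, coverage = cov)
  if (coverage_min > 0) out <- out[out$coverage > coverage_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}
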