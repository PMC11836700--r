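# Build a day_track from raw coordinates sampled at 1 Hz starting at second
# t0.  min_block_len is lowered so short hand-built tracks form blocks.
make_track <- function(x, y, t0 = 0L, individual = "a", date = as.Date("2020-01-01"),
                       context = "group-large", min_block_len = 2L) {
  fixes <- data.frame(individual = individual, date = date,
                      t = t0 + seq_along(x) - 1L, x = x, y = y,
                      regime = "hires", stringsAsFactors = FALSE)
  split_resolutions(fixes, min_block_len = min_block_len, context = context)
}

# Straight constant-speed track heading east.
straight_track <- function(n, v = 1, ...) {
  make_track(x = v * (seq_len(n) - 1), y = rep(0, n), ...)
}

# A day_track whose 5 min series walks out `out` metres and back `back`
# metres along the x axis (roost-to-roost = out - back, track length =
# out + back).
five_min_day <- function(out, back, n_slots = 40, ...) {
  n_out <- ceiling(n_slots / 2); n_back <- n_slots - n_out
  xs <- c(seq(0, out, length.out = n_out + 1),
          seq(out, out - back, length.out = n_back + 1)[-1])
  t <- (seq_along(xs) - 1L) * 300L + 9L
  fixes <- data.frame(individual = "a", date = as.Date("2020-01-01"),
                      t = t, x = xs, y = 0, regime = "burst",
                      stringsAsFactors = FALSE)
  split_resolutions(fixes, min_block_len = 30L, ...)
}

# Mark every interval second as a given state and fill speeds, skipping the
# HMM: convenient for testing energetics and segmentation in isolation.
force_states <- function(track, state = 2L) {
  track <- smooth_speeds(track)
  st <- rep(NA_integer_, nrow(track$fixes))
  for (b in seq_len(nrow(track$blocks))) {
    i0 <- track$blocks[b, 1]; i1 <- track$blocks[b, 2]
    if (i1 > i0) st[i0:(i1 - 1L)] <- state
  }
  track$state <- st
  track$moving <- st >= 2L
  track
}

# Tiny HMM with well-separated emissions for decode tests.
toy_hmm <- function(sep = 1) {
  trans <- matrix(c(.8, .1, .05, .05,
                    .1, .7, .15, .05,
                    .05, .15, .7, .1,
                    .05, .05, .2, .7), 4, 4, byrow = TRUE)
  means <- cbind(seq(0, by = sep, length.out = 4), rep(-1, 4))
  sds <- cbind(rep(0.1, 4), rep(0.5, 4))
  list(trans = trans, means = means, sds = sds)
}
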