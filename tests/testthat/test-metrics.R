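test_that("straightness index matches simple geometry", {
  expect_equal(straightness_index(c(0, 50, 100), c(0, 0, 0)), 1)
  # right angle of two 50 m legs
  expect_equal(straightness_index(c(0, 50, 50), c(0, 0, 50)),
               sqrt(2) * 50 / 100, tolerance = 1e-12)
  # closed loop: zero
  expect_equal(straightness_index(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)), 0)
  # degenerate: all points identical -> undefined
  expect_true(is.na(straightness_index(c(0, 0), c(0, 0))))
})

test_that("straightness and track length are invariant to rigid motions", {
  set.seed(4)
  x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
  th <- 1.1
  xr <- cos(th) * x - sin(th) * y + 500
  yr <- sin(th) * x + cos(th) * y - 200
  expect_equal(straightness_index(x, y), straightness_index(xr, yr),
               tolerance = 1e-12)
})

test_that("daily track length sums 5 min displacements", {
  # straight 6 km day over 40 slots
  tr <- five_min_day(out = 6000, back = 0)
  expect_equal(daily_track_length(tr), 6000, tolerance = 1e-9)
  # out-and-back 3 km each way: length 6000, net 0
  tr2 <- five_min_day(out = 3000, back = 3000)
  expect_equal(daily_track_length(tr2), 6000, tolerance = 1e-9)
  expect_equal(daily_metrics(tr2)$straightness, 0, tolerance = 1e-9)
  # 5 min subsampling of a straight constant-speed 1 Hz day equals the 1 Hz
  # path length
  cfg <- sim_config()
  x <- 0.5 * (0:46799)
  fixes <- data.frame(individual = "a", date = as.Date("2020-01-01"),
                      t = 0:46799, x = x, y = 0, regime = "hires",
                      stringsAsFactors = FALSE)
  tr3 <- split_resolutions(fixes)
  span <- range(tr3$five_min$t)
  len_1hz <- sum(abs(diff(x[(span[1]:span[2]) + 1L])))
  expect_equal(daily_track_length(tr3) / len_1hz, 1, tolerance = 0.001)
})

test_that("window speed averages smoothed speed over moving seconds only", {
  # 600 s: first 300 moving at 1.2 m/s, last 300 stationary
  n <- 601
  x <- c(seq(0, by = 1.2, length.out = 301), rep(360, 300))
  tr <- smooth_speeds(make_track(x, rep(0, n), min_block_len = 30L))
  st <- rep(NA_integer_, n); st[1:300] <- 4L; st[301:600] <- 1L
  tr$state <- st; tr$moving <- st >= 2L
  w <- window_metrics(tr, length = 300L)
  spd <- w[w$metric == "speed", ]
  # first window fully moving at 1.2; second has no moving seconds
  expect_equal(spd$window_start, 0L)
  expect_equal(spd$value, 1.2, tolerance = 0.01)
  # all-stationary window yields no observation
  expect_false(300L %in% spd$window_start)
  # half moving at 1.0 / half stationary: mean over moving seconds only
  x2 <- c(seq(0, by = 1, length.out = 151), rep(150, 150))
  tr2 <- smooth_speeds(make_track(x2, rep(0, 301), min_block_len = 30L))
  st2 <- rep(NA_integer_, 301); st2[1:148] <- 4L; st2[149:300] <- 1L
  tr2$state <- st2; tr2$moving <- st2 >= 2L
  w2 <- window_metrics(tr2, length = 300L)
  expect_equal(w2$value[w2$metric == "speed"], 1, tolerance = 0.02)
})

test_that("windowed straightness uses within-window displacements", {
  # straight constant-speed full block: straightness 1 at every length
  tr <- smooth_speeds(straight_track(3600, v = 1))
  tr$state <- c(rep(4L, 3599), NA); tr$moving <- tr$state >= 2L
  for (len in c(30L, 300L, 900L)) {
    w <- window_metrics(tr, length = len)
    s <- w$value[w$metric == "straightness"]
    expect_true(all(abs(s - 1) < 1e-9))
  }
})

test_that("windowed straightness is scale-dependent on nested random walks", {
  # straight at the 1 s scale but doubling back over minutes: windows below
  # the turning scale are near-straight, windows above it are tortuous
  set.seed(6)
  n <- 7200
  h <- 2.2 * sin(2 * pi * (0:(n - 1)) / 900)
  x <- cumsum(0.5 * sin(h)); y <- cumsum(0.5 * cos(h))
  tr <- smooth_speeds(make_track(x, y))
  tr$state <- c(rep(4L, n - 1), NA); tr$moving <- tr$state >= 2L
  med <- sapply(c(30L, 300L, 3600L), function(len) {
    w <- window_metrics(tr, length = len)
    mean(w$value[w$metric == "straightness"])
  })
  expect_true(all(diff(med) < 0))
  expect_gt(med[1], 0.95)
})

test_that("the sensitivity grid recomputes metrics per window length", {
  cfg <- sim_config()
  d <- simulate_day(cfg, "group-large", seed = 44, regime = "hires")
  tr <- smooth_speeds(split_resolutions(d$fixes, context = "group-large"))
  b <- bin_10s(tr)
  fit <- suppressWarnings(fit_hmm(b, seed = 1, n_restarts = 1))
  tr <- expand_states_to_seconds(decode_states(fit, b), tr)
  grid <- sensitivity_grid(list(tr), lengths = c(300L, 900L, 3600L))
  counts <- table(grid$length[grid$metric == "straightness"])
  expect_equal(names(counts), c("300", "900", "3600"))
  # counts per length are non-increasing in window length
  expect_true(all(diff(as.integer(counts)) <= 0))
  # each computation matches a brute-force oracle on the same seconds
  g300 <- grid[grid$length == 300L & grid$metric == "straightness", ]
  w0 <- g300$window_start[5]
  idx <- which(tr$fixes$t >= w0 & tr$fixes$t < w0 + 300)
  oracle <- straightness_index(tr$fixes$x[idx], tr$fixes$y[idx])
  expect_equal(g300$value[5], oracle, tolerance = 1e-12)
})
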