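test_that("10 s binning floors to complete bins and sums distances", {
  # 96 fixes = 95 steps -> 9 bins of 10 steps
  tr <- straight_track(96, v = 1)
  b <- bin_10s(tr)
  expect_equal(nrow(b), 9)
  expect_equal(b$distance, rep(10, 9))
  expect_equal(b$turn_sum, rep(0, 9))
  # fewer than 11 fixes cannot form a bin
  expect_equal(nrow(bin_10s(straight_track(10))), 0)
})

test_that("zigzag turning sums nine right angles per bin", {
  # alternate east/north unit steps: every interior turn is 90 degrees
  n <- 41
  dx <- rep(c(1, 0), length.out = n - 1)
  dy <- rep(c(0, 1), length.out = n - 1)
  tr <- make_track(c(0, cumsum(dx)), c(0, cumsum(dy)))
  b <- bin_10s(tr)
  expect_equal(b$turn_sum, rep(9 * pi / 2, nrow(b)), tolerance = 1e-9)
  # zero-length steps contribute no turning
  xs <- c(0, 1, 1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  trs <- make_track(xs, rep(0, length(xs)))
  bs <- bin_10s(trs)
  expect_equal(bs$turn_sum, 0)
})

test_that("EM log-likelihood is non-decreasing and the fit is deterministic", {
  toy <- toy_hmm(sep = 1.2)
  sim <- simulate_hmm_bins(toy$trans, toy$means, toy$sds, 2000,
                           context = "group-large", seq_len = 500, seed = 3)
  # track the likelihood path of a single-restart fit
  lls <- c()
  m <- NULL
  for (it in c(1, 2, 5, 10, 20)) {
    f <- suppressWarnings(fit_hmm(sim$bins, seed = 1, n_restarts = 1, max_iter = it))
    lls <- c(lls, f$loglik)
  }
  expect_true(all(diff(lls) > -1e-8))
  f1 <- suppressWarnings(fit_hmm(sim$bins, seed = 7, n_restarts = 2))
  f2 <- suppressWarnings(fit_hmm(sim$bins, seed = 7, n_restarts = 2))
  expect_identical(f1$means, f2$means)
  expect_identical(f1$trans, f2$trans)
})

test_that("parameters are recovered from data simulated under a known model", {
  toy <- toy_hmm(sep = 1.2)
  sim <- simulate_hmm_bins(toy$trans, toy$means, toy$sds, 12000,
                           context = "group-large", seq_len = 1500, seed = 5)
  fit <- fit_hmm(sim$bins, seed = 2, n_restarts = 3)
  # states are relabelled by ascending mean distance, matching the truth order
  expect_equal(fit$means[, 1], toy$means[, 1], tolerance = 0.05)
  expect_lt(max(abs(fit$trans[["group-large"]] - toy$trans)), 0.05)
  expect_true(fit$converged)
})

test_that("decoding is accurate when emissions are well separated", {
  toy <- toy_hmm(sep = 2)  # 20 sigma apart on the distance dimension
  sim <- simulate_hmm_bins(toy$trans, toy$means, toy$sds, 5000,
                           context = "group-large", seq_len = 1000, seed = 9)
  fit <- fit_hmm(sim$bins, seed = 3, n_restarts = 2)
  dec <- decode_states(fit, sim$bins)
  expect_gt(mean(dec$state == sim$states), 0.99)
  post <- as.matrix(dec[paste0("post", 1:4)])
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
  expect_error(decode_states(fit, transform(sim$bins, context = "??")), "unseen")
})

test_that("uninformative emissions leave the stationary distribution", {
  toy <- toy_hmm()
  means <- matrix(c(1, 1, 1, 1, -1, -1, -1, -1), 4, 2)  # identical emissions
  sds <- matrix(0.5, 4, 2)
  sim <- simulate_hmm_bins(toy$trans, means, sds, 500,
                           context = "group-large", seq_len = 500, seed = 4)
  model <- structure(list(means = means, sds = sds,
                          trans = list("group-large" = toy$trans),
                          init = movecot:::stationary_dist(toy$trans),
                          loglik = NA_real_, converged = TRUE,
                          contexts = "group-large", n_states = 4L,
                          emission_offsets = c(distance = 0.1, turn = 0.01)),
                     class = "movecot_hmm")
  dec <- decode_states(model, sim$bins)
  post <- colMeans(as.matrix(dec[paste0("post", 1:4)]))
  expect_equal(unname(post), unname(movecot:::stationary_dist(toy$trans)), tolerance = 1e-9)
})

test_that("degenerate single-state data does not crash the fit", {
  bins <- data.frame(individual = "a", date = as.Date("2020-01-01"),
                     context = "group-large", block = 1L, bin = 1:200,
                     t_start = NA_integer_,
                     distance = rep(10, 200), turn_sum = rep(0.2, 200),
                     stringsAsFactors = FALSE)
  expect_no_error(fit <- suppressWarnings(fit_hmm(bins, seed = 1,
                                                  n_restarts = 1)))
  expect_s3_class(fit, "movecot_hmm")
  expect_true(all(is.finite(unlist(fit$trans))))
})

test_that("decoded bin states expand to every second of a block", {
  tr <- straight_track(96, v = 1)  # 9 bins + 5 remainder steps
  b <- bin_10s(tr)
  b$state <- rep(c(3L, 2L, 4L), each = 3)
  tr2 <- expand_states_to_seconds(b, tr)
  # first 10 steps inherit bin 1
  expect_equal(tr2$state[1:10], rep(3L, 10))
  # remainder steps (91..95) inherit the last bin's state
  expect_equal(tr2$state[91:95], rep(4L, 5))
  expect_true(is.na(tr2$state[96]))
  # moving mask is the complement of state-1 seconds
  b$state <- rep(c(1L, 4L, 1L), each = 3)
  tr3 <- expand_states_to_seconds(b, tr)
  expect_equal(unname(tr3$moving[1:90]), rep(rep(c(FALSE, TRUE, FALSE), each = 30)))
})
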