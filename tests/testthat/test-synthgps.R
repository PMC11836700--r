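test_that("terrain simulation is deterministic and respects the relief", {
  d1 <- simulate_terrain(7, 50, 60, cell_size = 30, relief = 25)
  d2 <- simulate_terrain(7, 50, 60, cell_size = 30, relief = 25)
  expect_identical(d1$elevation, d2$elevation)
  expect_equal(diff(range(d1$elevation)), 25)
  flat <- simulate_terrain(7, 20, 20, relief = 0)
  expect_true(all(flat$elevation == 0))
  expect_true(all(compute_slope_aspect(flat)$slope == 0))
  expect_error(simulate_terrain(7, 20, 20, cell_size = 0), "positive")
})

test_that("gentle terrain yields slopes below 45 degrees", {
  dem <- compute_slope_aspect(simulate_terrain(11, 100, 100, cell_size = 30,
                                               relief = 30))
  expect_true(all(dem$slope < 45))
  expect_true(all(dem$slope >= 0))
  expect_true(all(dem$aspect >= 0 & dem$aspect < 360))
})

test_that("degenerate state chains give the expected limiting tracks", {
  cfg <- sim_config(gps_noise_sd = 0)
  # all mass on the stationary state: zero net displacement
  P1 <- diag(4); P1[] <- 0; P1[, 1] <- 1
  cfg$transition_matrices[["group-large"]] <- P1
  d <- simulate_day(cfg, "group-large", seed = 3)
  expect_true(all(d$truth$state == 1L))
  expect_equal(max(abs(d$truth$x - d$truth$x[1])), 0)
  expect_equal(max(abs(d$truth$y - d$truth$y[1])), 0)
  # all mass on state 4 with no turning: straightness 1 everywhere
  cfg2 <- sim_config(gps_noise_sd = 0)
  P4 <- diag(4); P4[] <- 0; P4[, 4] <- 1
  cfg2$transition_matrices[["group-large"]] <- P4
  cfg2$context_straightness_params[["group-large"]] <- 1
  d4 <- simulate_day(cfg2, "group-large", seed = 3)
  expect_true(all(d4$truth$state == 4L))
  s <- straightness_index(d4$truth$x, d4$truth$y)
  expect_equal(s, 1, tolerance = 1e-9)
})

test_that("latent chains follow the context transition matrix", {
  cfg <- sim_config()
  d <- simulate_day(cfg, "group-large", seed = 5)
  # the chain steps every 10 s; compare empirical transition frequencies at
  # the chain scale against the matrix
  chain <- d$truth$state[seq(1, length(d$truth$state), by = 10)]
  P <- cfg$transition_matrices[["group-large"]]
  emp <- prop.table(table(factor(chain[-length(chain)], levels = 1:4),
                          factor(chain[-1], levels = 1:4)), 1)
  expect_lt(max(abs(emp - P)), 0.03)
})

test_that("unknown context labels are rejected", {
  expect_error(simulate_day(sim_config(), "flock-of-seagulls", seed = 1),
               "unknown context")
})

test_that("ground-truth moving speed scales with the speed multiplier", {
  mk <- function(mult) {
    cfg <- sim_config(gps_noise_sd = 0)
    cfg$context_speed_multipliers[["lone-disperser"]] <- mult
    sp <- c()
    for (s in 1:3) {
      d <- simulate_day(cfg, "lone-disperser", seed = 70 + s)
      mv <- d$truth$state >= 2
      step <- c(sqrt(diff(d$truth$x)^2 + diff(d$truth$y)^2), 0)
      sp <- c(sp, step[mv])
    }
    sp
  }
  s1 <- mk(1); s2 <- mk(1.27)
  expect_gt(length(s1), 1e5)
  expect_equal(mean(s2) / mean(s1), 1.27, tolerance = 0.01)
})

test_that("days span the 13 h window with the configured regimes", {
  cfg <- sim_config()
  d <- simulate_day(cfg, "group-normal", seed = 2, regime = "hires")
  expect_equal(nrow(d$fixes), 46800)
  expect_true(all(d$fixes$t >= 0 & d$fixes$t < 46800))
  b <- simulate_day(cfg, "group-normal", seed = 2, regime = "burst")
  expect_true(all(b$fixes$t >= 0 & b$fixes$t < 46800))
  # exactly burst_length fixes per burst_interval
  per_slot <- table(b$fixes$t %/% cfg$burst_interval)
  expect_true(all(per_slot == cfg$burst_length))
  expect_equal(length(per_slot), 46800 / cfg$burst_interval)
})

test_that("cohorts are reproducible and carry analytic imposed effects", {
  cfg <- sim_config(seed = 9, n_individuals_per_context = 1,
                    n_days_per_individual = 1)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$fixes, c2$fixes)
  expect_lte(max(table(paste(c1$fixes$individual, c1$fixes$date))), 46800)
  expect_equal(c1$manifest$imposed_speed_ratio_disperser_vs_large, 1.272,
               tolerance = 0.001)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(state_speed_means = c(0, 0.5, 0.4, 0.9)))
  expect_error(sim_config(context_speed_multipliers = c(
    "group-normal" = 1, "group-large" = 1.1, "lone-disperser" = 1.2)),
    "reference")
  bad <- sim_config()$transition_matrices
  bad[["group-normal"]][1, 1] <- 0.5
  expect_error(sim_config(transition_matrices = bad), "stochastic")
})

test_that("manifests round-trip through the flat text format", {
  cfg <- sim_config(seed = 4, n_individuals_per_context = 1,
                    n_days_per_individual = 1)
  m <- simulate_cohort(cfg)$manifest
  path <- tempfile(fileext = ".txt")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_equal(as.numeric(m2$p44), unname(m$p44))
  expect_equal(as.numeric(m2$imposed_speed_ratio_disperser_vs_large),
               m$imposed_speed_ratio_disperser_vs_large, tolerance = 1e-12)
})
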