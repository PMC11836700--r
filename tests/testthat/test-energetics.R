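test_that("slope and aspect of an analytic tilted plane are exact", {
  # east-rising plane z = 0.1 * x: slope atan(0.1), aspect east (90 degrees)
  cs <- 30
  nr <- 20; nc <- 20
  xcent <- (seq_len(nc) - 0.5) * cs
  z <- matrix(rep(0.1 * xcent, each = nr), nr, nc)
  dem <- compute_slope_aspect(dem_grid(z, cell_size = cs))
  int_r <- 2:(nr - 1); int_c <- 2:(nc - 1)  # away from the padded edges
  expect_equal(dem$slope[int_r, int_c],
               matrix(atan(0.1) * 180 / pi, nr - 2, nc - 2), tolerance = 1e-9)
  expect_equal(dem$aspect[int_r, int_c], matrix(90, nr - 2, nc - 2),
               tolerance = 1e-9)
  # interior uniformity for an oblique plane
  ycent <- rev(seq_len(nr) - 0.5) * cs  # row 1 = north edge
  z2 <- outer(ycent, xcent, function(y, x) 0.03 * x + 0.04 * y)
  dem2 <- compute_slope_aspect(dem_grid(z2, cell_size = cs))
  expect_lt(diff(range(dem2$slope[int_r, int_c])), 1e-9)
  expect_equal(dem2$slope[5, 5], atan(0.05) * 180 / pi, tolerance = 1e-9)
  expect_equal(dem2$aspect[5, 5], atan2(0.03, 0.04) * 180 / pi, tolerance = 1e-9)
  expect_error(compute_slope_aspect(dem_grid(matrix(NA_real_, 3, 3))), "nodata")
})

test_that("experienced slope follows the bearing-aspect geometry", {
  expect_equal(experienced_slope(10, 0, 0), 10, tolerance = 1e-12)    # straight uphill
  expect_equal(experienced_slope(10, 90, 0), 0, tolerance = 1e-12)    # contouring
  expect_equal(experienced_slope(20, 60, 0),
               atan(tan(20 * pi / 180) * 0.5) * 180 / pi, tolerance = 1e-12)
  expect_equal(experienced_slope(20, 60, 0), 10.31408, tolerance = 1e-4)
  # even in delta-psi; sign flips when cos changes sign
  expect_equal(experienced_slope(15, 40, 0), experienced_slope(15, -40, 0))
  expect_equal(experienced_slope(15, 140, 0), -experienced_slope(15, 40, 0),
               tolerance = 1e-12)
  # magnitude never exceeds the terrain slope
  th <- runif(50, 0, 45); dp <- runif(50, 0, 360)
  expect_true(all(abs(experienced_slope(th, dp, 0)) <= th + 1e-12))
})

test_that("grade banding uses the printed half-open thresholds", {
  pg_to_theta <- function(pg) atan(pg / 100) * 180 / pi
  expect_equal(grade_band(pg_to_theta(4.9)), "level")
  expect_equal(grade_band(pg_to_theta(-12)), "level")     # downhill -> level
  expect_equal(grade_band(pg_to_theta(5)), "incline10")
  expect_equal(grade_band(pg_to_theta(14.999)), "incline10")
  expect_equal(grade_band(pg_to_theta(15)), "incline20")
  expect_equal(grade_band(pg_to_theta(16)), "incline20")
  expect_equal(grade_band(pg_to_theta(40)), "incline20")  # steep grades keep the 20% formula
})

test_that("per-second costs reproduce the published model constants", {
  p <- cost_model_params()
  expect_equal(per_second_cost(1, 0), 19.1 / 60 * 20.1)
  expect_equal(per_second_cost(1, 0), 6.3985, tolerance = 1e-4)
  expect_equal(per_second_cost(4, 1, "level"), (24.0 + 27.2) / 60 * 20.1)
  expect_equal(per_second_cost(4, 1, "level"), 17.152, tolerance = 1e-7)
  expect_equal(per_second_cost(2, 0, "level"), 27.2 / 60 * 20.1)
  expect_gt(per_second_cost(2, 0, "level"), per_second_cost(1, 0))
  expect_equal(per_second_cost(3, 0.8, "incline10"), (30.7 * 0.8 + 27.6) / 60 * 20.1)
  expect_equal(per_second_cost(3, 0.8, "incline20"), (47.7 * 0.8 + 21.3) / 60 * 20.1)
  expect_error(per_second_cost(2, -0.1), "negative")
})

test_that("moving cost is increasing in speed and band, per-metre cost decreasing", {
  v <- seq(0.5, 2.5, by = 0.25)
  lev <- per_second_cost(4, v, "level")
  expect_true(all(diff(lev) > 0))
  for (vv in v) {
    c3 <- c(per_second_cost(4, vv, "level"), per_second_cost(4, vv, "incline10"),
            per_second_cost(4, vv, "incline20"))
    expect_true(all(diff(c3) >= 0))
  }
  per_metre <- lev / v
  expect_true(all(diff(per_metre) < 0))
})

test_that("cost annotation picks bands from terrain and bearing", {
  # 10% east-rising plane, walking due east: every second in the 10% band
  cs <- 30; nr <- 10; nc <- 40
  xcent <- (seq_len(nc) - 0.5) * cs
  z <- matrix(rep(0.10 * xcent, each = nr), nr, nc)
  dem <- compute_slope_aspect(dem_grid(z, cell_size = cs))
  tr <- force_states(make_track(x = seq(60, 359), y = rep(150, 300)), state = 3L)
  tr <- annotate_costs(tr, dem)
  expect_true(all(tr$band[1:298] == "incline10"))
  expect_equal(tr$cost[1:298], rep((30.7 + 27.6) / 60 * 20.1, 298), tolerance = 1e-9)
  # walking due west on the same plane: downhill -> level relationship
  tr2 <- force_states(make_track(x = seq(1139, 840), y = rep(150, 300)), state = 3L)
  tr2 <- annotate_costs(tr2, dem)
  expect_true(all(tr2$band[1:298] == "level"))
  # stationary seconds cost the resting rate regardless of terrain
  tr3 <- force_states(make_track(x = seq(60, 159), y = rep(150, 100)), state = 1L)
  tr3 <- annotate_costs(tr3, dem)
  expect_equal(unique(tr3$cost[1:98]), 19.1 / 60 * 20.1)
})
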