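make_lmm_data <- function(n_ind = 8, n_obs = 20, effects = c("group-normal" = -0.1,
                                                            "lone-disperser" = 0.24),
                          ind_sd = 0.1, res_sd = 0.2, seed = 1) {
  set.seed(seed)
  ctx <- c("group-large", names(effects))
  rows <- list()
  for (cx in ctx) {
    for (i in seq_len(n_ind)) {
      id <- paste(cx, i)
      mu <- log(2) + (if (cx == "group-large") 0 else effects[[cx]]) + rnorm(1, 0, ind_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = id, context = cx, hour = sample(0:12, n_obs, TRUE),
        value = exp(mu + rnorm(n_obs, 0, res_sd)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("context LMM recovers imposed log-scale effects", {
  d <- make_lmm_data(n_ind = 12, n_obs = 30, seed = 42)
  # no hour effect is simulated, so the hour intercept is dropped with a warning
  expect_warning(res <- fit_context_lmm(d, "value", random = c("individual", "hour")),
                 "hour")
  expect_equal(nrow(res), 2)
  disp <- res[res$contrast == "lone-disperser vs group-large", ]
  expect_gt(disp$conf_hi, 0.24); expect_lt(disp$conf_lo, 0.24)
  expect_equal(disp$percent_diff, (exp(disp$estimate) - 1) * 100)
  norm <- res[res$contrast == "group-normal vs group-large", ]
  expect_lt(norm$estimate, 0)
  expect_lt(norm$p_value, 0.05)
})

test_that("estimates are invariant to row order and individual relabelling", {
  d <- make_lmm_data(seed = 7)
  r1 <- fit_context_lmm(d, "value")
  set.seed(99)
  d2 <- d[sample(nrow(d)), ]
  d2$individual <- paste0("relabel_", d2$individual)
  r2 <- fit_context_lmm(d2, "value")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-6)
  expect_equal(r1$se, r2$se, tolerance = 1e-6)
})

test_that("zero-variance random effects fall back to ordinary least squares", {
  set.seed(3)
  # individuals within a context share identical observation vectors, so the
  # between-individual variance component is exactly zero (a singular fit)
  vals <- list("group-large" = exp(rnorm(10, 0, 0.1)),
               "group-normal" = exp(rnorm(10, 0.2, 0.1)))
  d <- data.frame(individual = rep(letters[1:10], each = 10),
                  context = rep(c("group-large", "group-normal"), each = 50),
                  value = c(rep(vals[[1]], 5), rep(vals[[2]], 5)),
                  stringsAsFactors = FALSE)
  expect_warning(res <- fit_context_lmm(d, "value", random = "individual"),
                 "singular|least squares")
  ols <- lm(log(value) ~ factor(context, levels = c("group-large", "group-normal")),
            data = d)
  expect_equal(res$estimate, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_true(res$singular)
})

test_that("the boundary squeeze matches its closed form", {
  expect_equal(squeeze_proportion(1, 100), 0.995)
  expect_equal(squeeze_proportion(0, 100), 0.005)
  expect_equal(squeeze_proportion(0.5, 101), 0.5)
  y <- runif(50)
  expect_true(all(squeeze_proportion(y) > 0 & squeeze_proportion(y) < 1))
})

test_that("beta regression detects an imposed straightness shift", {
  set.seed(11)
  rows <- list()
  for (cx in c("group-large", "group-normal")) {
    for (i in 1:10) {
      mu <- plogis(qlogis(0.6) + (cx == "group-normal") * -0.8 + rnorm(1, 0, 0.15))
      phi <- 20
      rows[[length(rows) + 1L]] <- data.frame(
        individual = paste(cx, i), context = cx, hour = 6L,
        straightness = rbeta(30, mu * phi, (1 - mu) * phi),
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  res <- fit_straightness_beta(d, "straightness", random = "individual")
  expect_equal(nrow(res), 1)
  expect_lt(res$estimate, 0)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$conf_hi, -0.8 - 0.25); expect_lt(res$conf_lo, -0.8 + 0.25)
  # boundary-only responses are rejected with advice
  d$straightness <- 1
  expect_error(fit_straightness_beta(d, "straightness"), "boundary")
})

test_that("null contrasts are not significant", {
  d <- make_lmm_data(effects = c("group-normal" = 0), seed = 8)
  res <- fit_context_lmm(d, "value")
  expect_gt(res$p_value, 0.01)
  expect_lt(res$conf_lo, 0); expect_gt(res$conf_hi, 0)
})

test_that("reports round-trip through CSV and JSON", {
  d <- make_lmm_data(seed = 5)
  res <- fit_context_lmm(d, "value")
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  tab <- report_contrasts(list(res), csv = csv, json = json)
  back <- read.csv(csv)
  expect_equal(back$estimate, tab$estimate, tolerance = 1e-12)
  jb <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(jb$estimate, tab$estimate, tolerance = 1e-12)
  # percent differences are recomputable from exported coefficients
  expect_equal(jb$percent_diff, (exp(jb$estimate) - 1) * 100, tolerance = 1e-9)
  # empty input yields a header-only file
  empty_csv <- tempfile(fileext = ".csv")
  report_contrasts(list(), csv = empty_csv)
  expect_equal(nrow(read.csv(empty_csv)), 0)
})
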