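contrast_frame <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("context_contrasts", "data.frame")
  out
}

prep_context <- function(data, reference) {
  lev <- unique(as.character(data$context))
  if (!reference %in% lev) stop("reference level '", reference, "' not present")
  data$context <- factor(data$context,
                         levels = c(reference, sort(setdiff(lev, reference))))
  data$individual <- factor(data$individual)
  if ("hour" %in% names(data)) data$hour <- factor(data$hour)
  data
}

#' Linear mixed-model contrasts between movement contexts
#'
#' Fits, by maximum likelihood, a linear mixed model of a (optionally
#' log-transformed) response on the movement context, with random intercepts
#' for individual identity and - where the response is measured within the
#' day - for hour of day.  Contexts are treatment-coded with `group-large`
#' (group members making large displacements) as the reference.  Singular
#' fits are refit without the offending random intercept and flagged.
#'
#' @param data data.frame with columns `context`, `individual`, optionally
#'   `hour`, and the response.
#' @param response name of the response column.
#' @param random random-intercept grouping factors (subset of
#'   `c("individual", "hour")`).
#' @param log_response model `log(response)` (percent differences are then
#'   `(exp(beta) - 1) * 100`).
#' @param reference reference context level.
#' @return A `context_contrasts` data.frame with one row per non-reference
#'   context: estimate, standard error, df, 95% confidence limits, p-value
#'   and percent difference.  The fitted model is attached as attribute
#'   `"fit"`.
#' @export
fit_context_lmm <- function(data, response, random = c("individual"),
                            log_response = TRUE, reference = "group-large") {
  stopifnot(response %in% names(data))
  data <- prep_context(data, reference)
  data$.y <- if (log_response) log(data[[response]]) else data[[response]]
  data <- data[is.finite(data$.y), , drop = FALSE]
  terms <- paste0("(1 | ", random, ")")
  singular <- FALSE
  fit <- NULL
  while (length(terms) > 0) {
    form <- as.formula(paste(".y ~ context +", paste(terms, collapse = " + ")))
    fit <- lmerTest::lmer(form, data = data, REML = FALSE)
    if (!lme4::isSingular(fit)) break
    singular <- TRUE
    vc <- as.data.frame(lme4::VarCorr(fit))
    vc <- vc[vc$grp != "Residual", , drop = FALSE]
    worst <- vc$grp[which.min(vc$vcov)]
    terms <- terms[!grepl(paste0("\\b", worst, "\\b"), terms)]
    if (length(terms) == 0) {
      fit <- lm(.y ~ context, data = data)
      warning("all random intercepts singular; falling back to ordinary least squares")
    } else {
      warning("singular random intercept for '", worst, "' dropped")
    }
  }
  if (inherits(fit, "lm") && !inherits(fit, "merMod")) {
    sm <- summary(fit)$coefficients
    df <- fit$df.residual
    co <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; pv <- sm[, "Pr(>|t|)"]
    dfv <- setNames(rep(df, length(co)), rownames(sm))
  } else {
    sm <- summary(fit)$coefficients
    co <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    dfv <- sm[, "df"]; pv <- sm[, "Pr(>|t|)"]
  }
  lev <- levels(data$context)[-1]
  rows <- lapply(lev, function(l) {
    term <- paste0("context", l)
    est <- co[[term]]; s <- se[[term]]; d <- dfv[[term]]
    half <- qt(0.975, d) * s
    data.frame(response = response, model = "lmm",
               contrast = paste(l, "vs", reference),
               estimate = est, se = s, df = d,
               conf_lo = est - half, conf_hi = est + half,
               p_value = pv[[term]],
               percent_diff = if (log_response) (exp(est) - 1) * 100 else NA_real_,
               scale = if (log_response) "log" else "identity",
               singular = singular, stringsAsFactors = FALSE)
  })
  out <- contrast_frame(rows)
  attr(out, "fit") <- fit
  out
}

#' Beta-regression contrasts for straightness
#'
#' Mixed-effects beta regression (logit link) of a straightness index in
#' `[0, 1]` on the movement context, with random intercepts as in
#' [fit_context_lmm()].  Boundary values are handled with the standard
#' squeeze transform `(y * (n - 1) + 0.5) / n` before fitting.  The percent
#' difference column is on the odds scale (`(exp(beta) - 1) * 100`); a
#' response-scale ratio of marginal means is reported alongside.
#'
#' @inheritParams fit_context_lmm
#' @return A `context_contrasts` data.frame (z-based confidence intervals);
#'   the `glmmTMB` fit is attached as attribute `"fit"`.
#' @export
fit_straightness_beta <- function(data, response = "straightness",
                                  random = c("individual"),
                                  reference = "group-large") {
  stopifnot(response %in% names(data))
  data <- prep_context(data, reference)
  y <- data[[response]]
  data <- data[is.finite(y), , drop = FALSE]
  y <- y[is.finite(y)]
  stopifnot(all(y >= 0 & y <= 1))
  n <- length(y)
  if (all(y %in% c(0, 1))) stop("all straightness values on the boundary; inspect the input")
  data$.y <- squeeze_proportion(y, n)
  form <- as.formula(paste(".y ~ context +",
                           paste0("(1 | ", random, ")", collapse = " + ")))
  fit <- glmmTMB::glmmTMB(form, data = data, family = glmmTMB::beta_family())
  sm <- summary(fit)$coefficients$cond
  co <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; pv <- sm[, "Pr(>|z|)"]
  lev <- levels(data$context)[-1]
  b0 <- co[["(Intercept)"]]
  rows <- lapply(lev, function(l) {
    term <- paste0("context", l)
    est <- co[[term]]; s <- se[[term]]
    half <- qnorm(0.975) * s
    data.frame(response = response, model = "beta",
               contrast = paste(l, "vs", reference),
               estimate = est, se = s, df = NA_real_,
               conf_lo = est - half, conf_hi = est + half,
               p_value = pv[[term]],
               percent_diff = (exp(est) - 1) * 100,
               scale = "logit-odds",
               singular = FALSE,
               response_ratio_pct = (plogis(b0 + est) / plogis(b0) - 1) * 100,
               stringsAsFactors = FALSE)
  })
  out <- contrast_frame(rows)
  attr(out, "fit") <- fit
  out
}

#' Squeeze a proportion away from the 0/1 boundary
#'
#' `(y * (n - 1) + 0.5) / n`, the standard transform making boundary
#' proportions admissible for beta regression.
#'
#' @param y proportions in `[0, 1]`.
#' @param n sample size used in the transform (defaults to `length(y)`).
#' @return Squeezed proportions in `(0, 1)`.
#' @export
squeeze_proportion <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

#' @export
print.context_contrasts <- function(x, digits = 4, ...) {
  if (nrow(x) == 0) { cat("(no contrasts)\n"); return(invisible(x)) }
  cat("Context contrasts (coefficient [95% CI], model scale):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-14s %-32s % .4f [% .4f, % .4f]  p = %s",
                x$response[i], x$contrast[i], x$estimate[i],
                x$conf_lo[i], x$conf_hi[i], format.pval(x$p_value[i], digits = 3)))
    if (!is.na(x$percent_diff[i])) {
      cat(sprintf("  (%+.1f%% on the %s scale)", x$percent_diff[i], x$scale[i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Export contrast results
#'
#' Writes a bound table of contrasts as CSV and JSON.  Percent differences
#' are recomputable from the exported coefficients.
#'
#' @param results a `context_contrasts` data.frame, or a list of them (bound
#'   together; an empty list yields header-only files).
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return The bound data.frame, invisibly.
#' @export
report_contrasts <- function(results, csv = NULL, json = NULL) {
  if (is.data.frame(results)) results <- list(results)
  cols <- c("response", "model", "contrast", "estimate", "se", "df",
            "conf_lo", "conf_hi", "p_value", "percent_diff", "scale", "singular")
  tab <- if (length(results) == 0) {
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    do.call(rbind, lapply(results, function(r) {
      r <- as.data.frame(r)
      for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
      r[cols]
    }))
  }
  rownames(tab) <- NULL
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(tab, json, digits = NA, auto_unbox = TRUE)
  invisible(tab)
}
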