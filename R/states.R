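#' Summarize high-resolution blocks into 10 s state bins
#'
#' Splits every high-resolution block into consecutive, non-overlapping runs
#' of ten 1 s steps (a trailing remainder shorter than 10 steps is dropped)
#' and records, per bin, the distance moved (sum of the ten step lengths) and
#' the summed absolute turning angle (radians) over the nine step-to-step
#' transitions inside the bin.  Turns involving a zero-length step contribute
#' zero.
#'
#' @param track a `day_track` from [split_resolutions()].
#' @return data.frame with one row per bin: `individual`, `date`, `context`,
#'   `block`, `bin`, `t_start` (second opening the bin's first step),
#'   `distance` (m), `turn_sum` (rad).
#' @export
bin_10s <- function(track) {
  stopifnot(inherits(track, "day_track"))
  out <- list()
  for (b in seq_len(nrow(track$blocks))) {
    i0 <- track$blocks[b, 1]; i1 <- track$blocks[b, 2]
    x <- track$fixes$x[i0:i1]; y <- track$fixes$y[i0:i1]
    L <- length(x)
    n_bins <- (L - 1L) %/% 10L
    if (n_bins < 1L) next
    d <- step_lengths(x, y)
    # absolute turn between step j-1 and step j, j = 2 .. L-1
    turns <- turn_angles(x, y)
    bin_of_step <- rep(seq_len(n_bins), each = 10L)
    used <- seq_len(n_bins * 10L)
    dist <- as.numeric(tapply(d[used], bin_of_step, sum))
    # interior turns only: turn j belongs to bin of step j, except the first
    # step of each bin (whose turn crosses the bin boundary)
    jt <- seq(2L, n_bins * 10L)
    keep <- (jt - 1L) %% 10L != 0L
    jt <- jt[keep]
    tsum <- as.numeric(tapply(turns[jt - 1L], bin_of_step[jt], sum))
    out[[length(out) + 1L]] <- data.frame(
      individual = track$individual, date = track$date, context = track$context,
      block = b, bin = seq_len(n_bins),
      t_start = track$fixes$t[i0] + (seq_len(n_bins) - 1L) * 10L,
      distance = dist, turn_sum = tsum, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(individual = character(0), date = as.Date(character(0)),
                      context = character(0), block = integer(0), bin = integer(0),
                      t_start = integer(0), distance = numeric(0),
                      turn_sum = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Observation matrix on the emission scale.
hmm_obs <- function(bins, offsets = c(0.1, 0.01)) {
  cbind(log(bins$distance + offsets[1]), log(bins$turn_sum + offsets[2]))
}

# Sequence bookkeeping: rows must be ordered within sequences.
hmm_sequences <- function(bins) {
  key <- paste(bins$individual, bins$date, bins$block, sep = "\r")
  ord <- order(match(key, unique(key)), bins$bin)
  key <- key[ord]
  starts <- which(!duplicated(key))
  lens <- diff(c(starts, length(key) + 1L))
  list(order = ord, seq_start = starts, seq_len = lens,
       first_row = ord[starts])
}

hmm_logdens <- function(Y, means, sds) {
  Tn <- nrow(Y); K <- nrow(means)
  ld <- matrix(0, Tn, K)
  c2 <- log(2 * pi)
  for (k in seq_len(K)) {
    z1 <- (Y[, 1] - means[k, 1]) / sds[k, 1]
    z2 <- (Y[, 2] - means[k, 2]) / sds[k, 2]
    ld[, k] <- -c2 - log(sds[k, 1]) - log(sds[k, 2]) - 0.5 * (z1 * z1 + z2 * z2)
  }
  ld
}

#' Fit a four-state hidden Markov model with context-dependent transitions
#'
#' Fits, by direct-maximization EM (Baum-Welch), a hidden Markov model to
#' 10 s bins of distance and summed absolute turning angle.  Emissions are
#' independent Gaussians on `log(distance + 0.1)` and `log(turn_sum + 0.01)`
#' (log-normal step lengths handle the left-truncated, long-tailed
#' distribution of distances).  The movement context acts as a categorical
#' covariate on the transition matrix: each context receives its own
#' row-stochastic matrix, the saturated form of a multinomial-logit model per
#' origin state with `group-large` as the reference category.  Emission
#' parameters and the initial distribution are shared across contexts.
#'
#' The best of `n_restarts` EM runs (by log-likelihood) is returned, with
#' states relabelled by ascending mean distance so that state 1 is the
#' stationary state and state 4 the fastest.
#'
#' @param bins data.frame from [bin_10s()] (rows from many tracks bound
#'   together) with a non-missing `context` column.
#' @param n_states number of states (fixed at 4 for the energetic analysis).
#' @param seed integer seed controlling restarts.
#' @param n_restarts number of EM restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence threshold on the log-likelihood gain per
#'   observation.
#' @param reference reference context level.
#' @return An object of class `movecot_hmm`: emission `means` and `sds`
#'   (`n_states` x 2, log scale), per-context `trans` matrices, initial
#'   distribution `init`, `loglik`, `converged` flag and the context levels.
#' @export
fit_hmm <- function(bins, n_states = 4L, seed = 1L, n_restarts = 10L,
                    max_iter = 100L, tol = 1e-6, reference = "group-large") {
  stopifnot(nrow(bins) >= n_states)
  if (anyNA(bins$context)) stop("bins must carry a context label")
  ctx_levels <- unique(as.character(bins$context))
  if (reference %in% ctx_levels) {
    ctx_levels <- c(reference, sort(setdiff(ctx_levels, reference)))
  }
  sq <- hmm_sequences(bins)
  bins_o <- bins[sq$order, , drop = FALSE]
  Y <- hmm_obs(bins_o)
  Tn <- nrow(Y); K <- n_states
  ctx_seq <- match(as.character(bins_o$context[sq$seq_start]), ctx_levels)
  C <- length(ctx_levels)

  run_em <- function(means, sds, trans, init, iter_cap = max_iter) {
    ll_prev <- -Inf; converged <- FALSE
    for (it in seq_len(iter_cap)) {
      ld <- hmm_logdens(Y, means, sds)
      fb <- cpp_forward_backward(ld, sq$seq_start, sq$seq_len, ctx_seq, trans, init)
      g <- fb$gamma
      wk <- colSums(g)
      means <- crossprod(g, Y) / wk
      v <- crossprod(g, Y^2) / wk - means^2
      sds <- sqrt(pmax(v, 1e-8))
      xi <- fb$xi
      for (c in seq_len(C)) {
        rs <- rowSums(xi[, , c])
        Pm <- xi[, , c]
        for (k in seq_len(K)) {
          Pm[k, ] <- if (rs[k] > 1e-10) Pm[k, ] / rs[k] else trans[[c]][k, ]
        }
        trans[[c]] <- Pm
      }
      init <- fb$init_counts / sum(fb$init_counts)
      if (fb$loglik - ll_prev < tol * Tn && it > 1) {
        converged <- TRUE
        ll_prev <- fb$loglik
        break
      }
      ll_prev <- fb$loglik
    }
    list(means = means, sds = sds, trans = trans, init = init,
         loglik = ll_prev, converged = converged, occupancy = wk)
  }

  # short-run EM: every restart runs a capped number of iterations and only
  # the best (by log-likelihood) is polished to convergence
  short_cap <- if (n_restarts > 1) 15L else max_iter
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    qs <- stats::quantile(Y[, 1], probs = (seq_len(K) - 0.5) / K, names = FALSE)
    m1 <- qs + rnorm(K, 0, 0.15 * (r > 1) * sd(Y[, 1]))
    m2 <- rep(mean(Y[, 2]), K) + rnorm(K, 0, 0.15 * (r > 1) * sd(Y[, 2]))
    means <- cbind(sort(m1), m2)
    sds <- cbind(rep(max(sd(Y[, 1]) / 2, 0.05), K),
                 rep(max(sd(Y[, 2]), 0.05), K))
    trans <- rep(list(matrix(0.3 / (K - 1), K, K) + diag(0.7 - 0.3 / (K - 1), K)), C)
    init <- rep(1 / K, K)
    fit <- run_em(means, sds, trans, init, iter_cap = short_cap)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    best <- run_em(best$means, best$sds, best$trans, best$init)
  }
  if (!best$converged) {
    warning("EM did not converge within ", max_iter, " iterations; returning best iterate")
  }
  if (any(best$occupancy < 1)) {
    warning(sum(best$occupancy < 1), " state(s) have (near-)empty occupancy")
  }
  perm <- order(best$means[, 1])
  trans <- lapply(best$trans, function(P) {
    P2 <- P[perm, perm, drop = FALSE]
    dimnames(P2) <- list(paste0("s", 1:K), paste0("s", 1:K))
    P2
  })
  names(trans) <- ctx_levels
  structure(list(means = best$means[perm, , drop = FALSE],
                 sds = best$sds[perm, , drop = FALSE],
                 trans = trans,
                 init = best$init[perm] / sum(best$init[perm]),
                 loglik = best$loglik,
                 converged = best$converged,
                 contexts = ctx_levels,
                 n_states = K,
                 emission_offsets = c(distance = 0.1, turn = 0.01)),
            class = "movecot_hmm")
}

#' @export
print.movecot_hmm <- function(x, ...) {
  cat("Hidden Markov model:", x$n_states, "states,",
      length(x$contexts), "context(s), logLik =", format(x$loglik), "\n")
  md <- exp(x$means[, 1]) - x$emission_offsets[1]
  cat("  mean 10 s distance per state (m):",
      paste(sprintf("%.2f", md), collapse = ", "), "\n")
  for (ctx in x$contexts) {
    cat("  P(stay in state 4) [", ctx, "]: ",
        sprintf("%.3f", x$trans[[ctx]][4, 4]), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.movecot_hmm <- function(object, ...) {
  cat("Emission means (log scale):\n"); print(object$means)
  cat("Emission sds (log scale):\n"); print(object$sds)
  for (ctx in object$contexts) {
    cat("Transition matrix [", ctx, "]:\n", sep = "")
    print(round(object$trans[[ctx]], 3))
  }
  invisible(object)
}

#' Decode behavioural states by posterior (forward-backward) probability
#'
#' @param model a fitted [fit_hmm()] object.
#' @param bins data.frame from [bin_10s()] with a `context` column whose
#'   levels were seen during fitting.
#' @return `bins` with columns `state` (most probable state per bin) and
#'   `post1` .. `postK` (posterior state probabilities).
#' @export
decode_states <- function(model, bins) {
  stopifnot(inherits(model, "movecot_hmm"))
  unseen <- setdiff(unique(as.character(bins$context)), model$contexts)
  if (length(unseen) > 0) stop("unseen context label(s): ", paste(unseen, collapse = ", "))
  sq <- hmm_sequences(bins)
  bins_o <- bins[sq$order, , drop = FALSE]
  Y <- hmm_obs(bins_o, model$emission_offsets)
  ctx_seq <- match(as.character(bins_o$context[sq$seq_start]), model$contexts)
  ld <- hmm_logdens(Y, model$means, model$sds)
  fb <- cpp_forward_backward(ld, sq$seq_start, sq$seq_len, ctx_seq,
                             model$trans, model$init)
  g <- fb$gamma
  state <- max.col(g)
  post <- as.data.frame(g)
  names(post) <- paste0("post", seq_len(model$n_states))
  out <- cbind(bins_o, state = state, post)
  # restore input row order
  out[order(sq$order), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Expand decoded 10 s states to every second of a high-resolution block
#'
#' Each one-second step inherits the state of its 10 s bin; steps in the
#' trailing remainder (dropped during binning) inherit the last bin's state.
#' Individuals are considered moving when assigned to states 2-4.
#'
#' @param bins_decoded output of [decode_states()] for this track.
#' @param track the corresponding `day_track`.
#' @return The track with a per-fix `state` integer vector (state of the
#'   interval opened by each fix; `NA` outside blocks and for blocks without
#'   bins) and a logical `moving` vector (`state >= 2`).
#' @export
expand_states_to_seconds <- function(bins_decoded, track) {
  stopifnot(inherits(track, "day_track"))
  n <- nrow(track$fixes)
  state <- rep(NA_integer_, n)
  for (b in seq_len(nrow(track$blocks))) {
    i0 <- track$blocks[b, 1]; i1 <- track$blocks[b, 2]
    L <- i1 - i0 + 1L
    bb <- bins_decoded[bins_decoded$block == b &
                         bins_decoded$individual == track$individual &
                         bins_decoded$date == track$date, , drop = FALSE]
    n_bins <- nrow(bb)
    if (n_bins == 0) next
    bb <- bb[order(bb$bin), , drop = FALSE]
    step_bin <- pmin((seq_len(L - 1L) - 1L) %/% 10L + 1L, n_bins)
    state[i0:(i1 - 1L)] <- bb$state[step_bin]
  }
  track$state <- state
  track$moving <- state >= 2L
  track
}

#' Simulate 10 s bins from a known state model
#'
#' Generative counterpart of [fit_hmm()]'s model: samples a latent state
#' chain from a transition matrix and draws distance / turn-sum observations
#' from the log-scale Gaussian emission model.  Used by parameter-recovery
#' harnesses.
#'
#' @param trans row-stochastic transition matrix.
#' @param means,sds emission parameters (`K` x 2, log scale as in
#'   [fit_hmm()]).
#' @param n_bins total number of bins to simulate.
#' @param context context label stamped on the output.
#' @param seq_len length of each independent sequence (bins are grouped into
#'   blocks of this length).
#' @param seed integer seed.
#' @param offsets emission offsets (distance, turn).
#' @return list with `bins` (data.frame compatible with [fit_hmm()]) and
#'   `states` (true latent states).
#' @export
simulate_hmm_bins <- function(trans, means, sds, n_bins, context = "group-large",
                              seq_len = 1000L, seed = 1L,
                              offsets = c(0.1, 0.01)) {
  set.seed(seed)
  init <- stationary_dist(trans)
  states <- integer(0)
  blocks <- integer(0)
  remaining <- n_bins
  b <- 0L
  while (remaining > 0) {
    b <- b + 1L
    m <- min(seq_len, remaining)
    states <- c(states, cpp_sample_chain(m, trans, init))
    blocks <- c(blocks, rep(b, m))
    remaining <- remaining - m
  }
  d <- pmax(exp(rnorm(n_bins, means[states, 1], sds[states, 1])) - offsets[1], 0)
  tu <- pmax(exp(rnorm(n_bins, means[states, 2], sds[states, 2])) - offsets[2], 0)
  bins <- data.frame(individual = paste0("sim_", context), date = as.Date("2020-01-01"),
                     context = context, block = blocks,
                     bin = stats::ave(blocks, blocks, FUN = seq_along),
                     t_start = NA_integer_, distance = d, turn_sum = tu,
                     stringsAsFactors = FALSE)
  list(bins = bins, states = states)
}
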