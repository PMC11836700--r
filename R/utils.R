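# Internal geometry and matrix helpers.

# Euclidean distance between consecutive rows of (x, y); length n - 1.
step_lengths <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(0))
  sqrt(diff(x)^2 + diff(y)^2)
}

# Compass bearing (degrees, 0 = north, clockwise) of each step; length n - 1.
step_bearings <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(0))
  b <- atan2(diff(x), diff(y)) * 180 / pi
  (b + 360) %% 360
}

# Smallest absolute angle (radians) between successive step headings.
# Zero-length steps contribute an undefined heading; their turns are 0.
turn_angles <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  len <- sqrt(dx^2 + dy^2)
  ns <- length(dx)
  if (ns < 2L) return(numeric(0))
  h <- atan2(dx, dy)
  d <- diff(h)
  d <- atan2(sin(d), cos(d))          # wrap to (-pi, pi]
  undef <- len[-ns] == 0 | len[-1] == 0
  d[undef] <- 0
  abs(d)
}

# Stationary distribution of a row-stochastic matrix.
stationary_dist <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

check_stochastic <- function(P, tol = 1e-12) {
  is.matrix(P) && nrow(P) == ncol(P) && all(P >= 0) &&
    all(abs(rowSums(P) - 1) <= tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
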