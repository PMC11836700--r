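#' Cost-model parameters for guineafowl locomotion
#'
#' Banded linear relationships between speed and oxygen consumption measured
#' on treadmills at fixed inclines: `VO2 = a * v + b` in ml O2 kg^-1 min^-1
#' with `v` in m s^-1, for level terrain (a = 24.0, b = 27.2), a 10% incline
#' (30.7, 27.6) and a 20% incline (47.7, 21.3); a fixed stationary rate of
#' 19.1 ml O2 kg^-1 min^-1; and an energy equivalent of 20.1 J per ml O2.
#'
#' @param level,incline10,incline20 numeric `c(slope, intercept)` pairs.
#' @param stationary_rate resting oxygen consumption (ml O2 kg^-1 min^-1).
#' @param energy_per_ml_o2 conversion factor (J ml^-1 O2).
#' @return An object of class `cost_model_params`.
#' @export
cost_model_params <- function(level = c(24.0, 27.2),
                              incline10 = c(30.7, 27.6),
                              incline20 = c(47.7, 21.3),
                              stationary_rate = 19.1,
                              energy_per_ml_o2 = 20.1) {
  p <- list(bands = list(level = level, incline10 = incline10,
                         incline20 = incline20),
            stationary_rate = stationary_rate,
            energy_per_ml_o2 = energy_per_ml_o2)
  stopifnot(all(unlist(p$bands) > 0), stationary_rate > 0, energy_per_ml_o2 > 0)
  class(p) <- "cost_model_params"
  p
}

#' Derive slope and aspect layers from a DEM
#'
#' Horn's eight-neighbour finite-difference method: for each cell the east-
#' and north-facing elevation gradients are weighted sums of the surrounding
#' eight cells; slope is `atan(sqrt(gx^2 + gy^2))` in degrees and aspect is
#' the compass direction of steepest ascent (0 = north, clockwise).  Edge
#' cells use reflected padding.  Aspect is set to 0 (and is meaningless)
#' where slope is exactly zero.
#'
#' @param dem a [dem_grid()] (at least 3 x 3, not all `NA`).
#' @return The grid with `slope` and `aspect` matrices (degrees) filled.
#' @export
compute_slope_aspect <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  z <- dem$elevation
  if (all(is.na(z))) stop("all-nodata grid")
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("grid must be at least 3x3")
  # reflected padding
  zp <- rbind(z[2, ], z, z[nr - 1, ])
  zp <- cbind(zp[, 2], zp, zp[, nc - 1])
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  # neighbours: rows increase southwards, columns increase eastwards
  nw <- zp[i - 1, j - 1]; n_ <- zp[i - 1, j]; ne <- zp[i - 1, j + 1]
  w_ <- zp[i, j - 1];                         e_ <- zp[i, j + 1]
  sw <- zp[i + 1, j - 1]; s_ <- zp[i + 1, j]; se <- zp[i + 1, j + 1]
  cs <- dem$cell_size
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs)   # eastward gradient
  dzdy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cs)   # northward gradient
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(dzdx, dzdy) * 180 / pi + 360) %% 360          # steepest ascent
  aspect[slope == 0] <- 0
  dem$slope <- slope
  dem$aspect <- aspect
  dem
}

#' Slope experienced along a movement bearing
#'
#' `theta_prime = atan(tan(theta) * cos(delta_psi))` where `delta_psi` is the
#' circular difference between the terrain aspect (direction of steepest
#' ascent) and the movement bearing.  Positive values mean uphill movement.
#'
#' @param theta terrain slope in degrees, in `[0, 90)`.
#' @param aspect terrain aspect in degrees (steepest ascent, compass).
#' @param bearing movement bearing in degrees (compass).
#' @return Experienced slope in degrees (signed).
#' @export
experienced_slope <- function(theta, aspect, bearing) {
  stopifnot(all(theta >= 0 & theta < 90, na.rm = TRUE))
  dpsi <- (aspect - bearing) * pi / 180
  atan(tan(theta * pi / 180) * cos(dpsi)) * 180 / pi
}

#' Assign an incline band from the experienced slope
#'
#' The experienced slope is converted to percent grade `PG = 100 *
#' tan(theta_prime)`.  Downhill movement (negative grade) follows the level
#' relationship; grades below 5% are level, grades in `[5, 15)` use the 10%
#' incline relationship, and grades of 15% or more use the 20% relationship.
#'
#' @param theta_prime experienced slope in degrees (signed).
#' @return character vector of band labels: `level`, `incline10`,
#'   `incline20`.
#' @export
grade_band <- function(theta_prime) {
  pg <- tan(theta_prime * pi / 180) * 100
  band <- rep("level", length(pg))
  band[pg >= 5 & pg < 15] <- "incline10"
  band[pg >= 15] <- "incline20"
  band
}

#' Per-second metabolic cost
#'
#' Stationary seconds (state 1) cost the resting rate; moving seconds
#' (states 2-4) follow the band's linear speed relationship.  Rates in
#' ml O2 kg^-1 min^-1 are converted to J kg^-1 s^-1 by dividing by 60 and
#' multiplying by the energy equivalent of oxygen.
#'
#' @param state behavioural state (integer 1-4).
#' @param v smoothed speed in m s^-1 (>= 0).
#' @param band band label from [grade_band()].
#' @param params a [cost_model_params()].
#' @return Cost in J kg^-1 s^-1.
#' @export
per_second_cost <- function(state, v, band = "level", params = cost_model_params()) {
  stopifnot(inherits(params, "cost_model_params"))
  if (any(v < 0, na.rm = TRUE)) stop("negative speed")
  n <- max(length(state), length(v), length(band))
  state <- rep_len(state, n); v <- rep_len(v, n); band <- rep_len(band, n)
  a <- vapply(params$bands, `[`, 1, 1)[band]
  b <- vapply(params$bands, `[`, 1, 2)[band]
  vo2 <- ifelse(state == 1L, params$stationary_rate, a * v + b)
  unname(vo2 / 60 * params$energy_per_ml_o2)
}

#' Annotate a decoded track with per-second energetic costs
#'
#' For every one-second interval inside a high-resolution block, determines
#' the DEM cell containing the opening fix, the bearing of the step leaving
#' it, the experienced slope and incline band, and the metabolic cost given
#' the decoded state and smoothed speed.  Intervals without a decoded state
#' (blocks too short to bin) get `NA` cost.
#'
#' @param track a `day_track` that has been through [smooth_speeds()] and
#'   [expand_states_to_seconds()].
#' @param dem a [dem_grid()] with derived slope/aspect layers (when `NULL`,
#'   level terrain is assumed).
#' @param params a [cost_model_params()].
#' @return The track with per-fix `band` and `cost` vectors (interval
#'   convention: value at fix `i` describes the second between fixes `i` and
#'   `i + 1`; `NA` outside blocks).
#' @export
annotate_costs <- function(track, dem = NULL, params = cost_model_params()) {
  stopifnot(inherits(track, "day_track"))
  has_blocks <- nrow(track$blocks) > 0
  if (has_blocks && is.null(track$state)) {
    stop("track has no decoded states; run expand_states_to_seconds()")
  }
  if (has_blocks && all(is.na(track$v))) {
    stop("track has no smoothed speeds; run smooth_speeds()")
  }
  if (is.null(track$state)) track$state <- rep(NA_integer_, nrow(track$fixes))
  if (!is.null(dem) && is.null(dem$slope)) dem <- compute_slope_aspect(dem)
  n <- nrow(track$fixes)
  band <- rep(NA_character_, n)
  cost <- rep(NA_real_, n)
  for (b in seq_len(nrow(track$blocks))) {
    i0 <- track$blocks[b, 1]; i1 <- track$blocks[b, 2]
    if (i1 - i0 < 1L) next
    idx <- i0:(i1 - 1L)
    if (is.null(dem)) {
      bb <- rep("level", length(idx))
    } else {
      bear <- step_bearings(track$fixes$x[i0:i1], track$fixes$y[i0:i1])
      cell <- dem_cell_index(dem, track$fixes$x[idx], track$fixes$y[idx])
      th <- dem$slope[cell]
      asp <- dem$aspect[cell]
      th[is.na(th)] <- 0; asp[is.na(asp)] <- 0
      bb <- grade_band(experienced_slope(th, asp, bear))
    }
    band[idx] <- bb
    st <- track$state[idx]
    ok <- !is.na(st) & !is.na(track$v[idx])
    cost[idx[ok]] <- per_second_cost(st[ok], track$v[idx][ok], bb[ok], params)
  }
  track$band <- band
  track$cost <- cost
  track
}
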