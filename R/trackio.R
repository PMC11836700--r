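#' Read a Movebank-style GPS fix table
#'
#' Reads a delimited fix table with one row per GPS fix and returns a
#' per-individual, time-sorted data frame of planar fixes.  Expected columns
#' (Movebank dialect) are `individual-local-identifier`, `timestamp`
#' (ISO-8601, local clock), either `location-long`/`location-lat` or `x`/`y`
#' (planar metres), and optionally `regime` (`hires`, `burst` or `sparse`).
#' Geographic coordinates are projected to planar metres with a local
#' transverse-Mercator projection centred on the data extent (or the
#' projection supplied in `projection`).
#'
#' Rows with unparseable coordinates or timestamps are dropped with a message
#' reporting the count.  Duplicate (individual, timestamp) rows keep the
#' first occurrence with a warning.
#'
#' @param path path to a CSV file.
#' @param projection optional projection as returned by [local_projection()];
#'   ignored when the file already carries planar `x`/`y` columns.
#' @param day_start start of the tracking day, `"HH:MM"` local clock.
#' @return A data.frame with columns `individual`, `date` (Date), `t`
#'   (integer seconds since `day_start`), `x`, `y` (metres) and `regime`,
#'   sorted by individual and time.  The projection used (if any) is attached
#'   as attribute `"projection"`.
#' @export
read_fixes <- function(path, projection = NULL, day_start = "06:00") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need_id <- "individual-local-identifier"
  if (!need_id %in% names(raw)) stop("missing mandatory column: ", need_id)
  if (!"timestamp" %in% names(raw)) stop("missing mandatory column: timestamp")
  planar <- all(c("x", "y") %in% names(raw))
  geo <- all(c("location-long", "location-lat") %in% names(raw))
  if (!planar && !geo) {
    stop("missing mandatory column: location-long/location-lat (or x/y)")
  }
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS"))
  if (planar) {
    x <- suppressWarnings(as.numeric(raw$x))
    y <- suppressWarnings(as.numeric(raw$y))
  } else {
    lon <- suppressWarnings(as.numeric(raw[["location-long"]]))
    lat <- suppressWarnings(as.numeric(raw[["location-lat"]]))
    ok0 <- is.finite(lon) & is.finite(lat)
    if (is.null(projection)) {
      projection <- local_projection(mean(lon[ok0]), mean(lat[ok0]))
    }
    xy <- project_coords(lon, lat, projection)
    x <- xy$x; y <- xy$y
  }
  ok <- is.finite(x) & is.finite(y) & !is.na(ts)
  n_bad <- sum(!ok)
  if (n_bad > 0) message(n_bad, " row(s) with unparseable coordinates/timestamps dropped")
  regime <- if ("regime" %in% names(raw)) as.character(raw$regime) else "hires"
  regime <- rep_len(regime, nrow(raw))
  df <- data.frame(individual = as.character(raw[[need_id]]),
                   timestamp = ts, x = x, y = y, regime = regime,
                   stringsAsFactors = FALSE)[ok, , drop = FALSE]
  df <- df[order(df$individual, df$timestamp), , drop = FALSE]
  dup <- duplicated(df[c("individual", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (individual, timestamp) row(s); keeping first")
    df <- df[!dup, , drop = FALSE]
  }
  start_sec <- hm_to_sec(day_start)
  sec_of_day <- as.integer(round(as.numeric(df$timestamp) -
                                   as.numeric(trunc(df$timestamp, "days"))))
  out <- data.frame(individual = df$individual,
                    date = as.Date(trunc(df$timestamp, "days")),
                    t = sec_of_day - start_sec,
                    x = df$x, y = df$y, regime = df$regime,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "projection") <- projection
  out
}

#' Write a fix table in the Movebank-style CSV dialect
#'
#' Inverse of [read_fixes()]: writes `individual-local-identifier`,
#' `timestamp`, `x`, `y` (planar metres) and `regime` columns.
#'
#' @param fixes data.frame as returned by [read_fixes()] or
#'   [simulate_cohort()].
#' @param path output CSV path.
#' @param day_start start of the tracking day, `"HH:MM"` local clock.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path, day_start = "06:00") {
  ts <- as.POSIXct(paste(fixes$date, "00:00:00"), tz = "UTC") +
    hm_to_sec(day_start) + fixes$t
  out <- data.frame(`individual-local-identifier` = fixes$individual,
                    timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                    x = sprintf("%.6f", fixes$x),
                    y = sprintf("%.6f", fixes$y),
                    regime = fixes$regime,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

hm_to_sec <- function(hm) {
  p <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1]])
  p[1] * 3600L + p[2] * 60L
}

# --- projection ------------------------------------------------------------

#' Define a local transverse-Mercator projection
#'
#' Builds a planar metric projection (x = east, y = north, metres) centred on
#' `(lon0, lat0)` on the WGS84 ellipsoid with unit scale on the central
#' meridian.  Over a study extent of a few tens of kilometres the distance
#' distortion is far below 0.1%.
#'
#' @param lon0,lat0 projection origin in decimal degrees.
#' @return An object of class `tm_projection`.
#' @export
local_projection <- function(lon0, lat0) {
  stopifnot(is.finite(lon0), is.finite(lat0), abs(lat0) <= 90)
  structure(list(lon0 = lon0, lat0 = lat0, a = 6378137,
                 e2 = 0.00669437999014132), class = "tm_projection")
}

tm_meridian_arc <- function(phi, a, e2) {
  e4 <- e2^2; e6 <- e2^3
  a * ((1 - e2 / 4 - 3 * e4 / 64 - 5 * e6 / 256) * phi -
         (3 * e2 / 8 + 3 * e4 / 32 + 45 * e6 / 1024) * sin(2 * phi) +
         (15 * e4 / 256 + 45 * e6 / 1024) * sin(4 * phi) -
         (35 * e6 / 3072) * sin(6 * phi))
}

#' Project geographic coordinates to planar metres
#'
#' Forward transverse-Mercator projection (standard series expansion,
#' accurate to well under a millimetre within a few degrees of the central
#' meridian).
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param projection a `tm_projection` from [local_projection()].
#' @return data.frame with columns `x`, `y` in metres.
#' @seealso [unproject_coords()]
#' @export
project_coords <- function(lon, lat, projection) {
  stopifnot(inherits(projection, "tm_projection"))
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude out of range [-90, 90]")
  a <- projection$a; e2 <- projection$e2
  ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  dlam <- (lon - projection$lon0) * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  Tt <- tan(phi)^2
  Cc <- ep2 * cos(phi)^2
  A <- dlam * cos(phi)
  M <- tm_meridian_arc(phi, a, e2)
  M0 <- tm_meridian_arc(projection$lat0 * pi / 180, a, e2)
  x <- N * (A + (1 - Tt + Cc) * A^3 / 6 +
              (5 - 18 * Tt + Tt^2 + 72 * Cc - 58 * ep2) * A^5 / 120)
  y <- (M - M0 + N * tan(phi) * (A^2 / 2 +
         (5 - Tt + 9 * Cc + 4 * Cc^2) * A^4 / 24 +
         (61 - 58 * Tt + Tt^2 + 600 * Cc - 330 * ep2) * A^6 / 720))
  data.frame(x = x, y = y)
}

#' Inverse projection from planar metres to geographic coordinates
#'
#' @param x,y planar coordinates in metres.
#' @param projection a `tm_projection` from [local_projection()].
#' @return data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
unproject_coords <- function(x, y, projection) {
  stopifnot(inherits(projection, "tm_projection"))
  a <- projection$a; e2 <- projection$e2
  ep2 <- e2 / (1 - e2)
  M0 <- tm_meridian_arc(projection$lat0 * pi / 180, a, e2)
  M <- M0 + y
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  C1 <- ep2 * cos(phi1)^2
  T1 <- tan(phi1)^2
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- x / N1
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- projection$lon0 * pi / 180 +
    (D - (1 + 2 * T1 + C1) * D^3 / 6 +
       (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# --- DEM -------------------------------------------------------------------

#' Construct a DEM grid object
#'
#' @param elevation numeric matrix of elevations (metres); row 1 is the
#'   northern edge.
#' @param xll,yll planar coordinates (metres) of the lower-left corner of the
#'   grid.
#' @param cell_size cell size in metres (must be positive).
#' @return An object of class `dem_grid` with `NULL` slope/aspect layers
#'   until [compute_slope_aspect()] is called.
#' @export
dem_grid <- function(elevation, xll = 0, yll = 0, cell_size = 30) {
  stopifnot(is.matrix(elevation))
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell size must be positive")
  structure(list(elevation = elevation, xll = xll, yll = yll,
                 cell_size = cell_size, slope = NULL, aspect = NULL),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat("DEM grid:", nrow(x$elevation), "x", ncol(x$elevation),
      "cells,", x$cell_size, "m cells\n")
  rng <- range(x$elevation, na.rm = TRUE)
  cat("  elevation range:", sprintf("%.1f - %.1f m", rng[1], rng[2]), "\n")
  cat("  derived slope/aspect:", if (is.null(x$slope)) "unset" else "present", "\n")
  invisible(x)
}

#' Read a DEM from an ESRI ASCII grid file
#'
#' Parses the standard `ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/
#' `NODATA_value` header followed by `nrows` rows of elevations (first row =
#' northern edge).  NODATA cells are set to `NA`.
#'
#' @param path path to a `.asc` file.
#' @return A [dem_grid()] object.
#' @export
read_dem <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) stop("ESRI ASCII header missing field: ", k)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) stop("grid body has wrong number of rows")
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(vapply(rows, length, 1L) != hdr$ncols)) {
    stop("inconsistent row lengths in grid body")
  }
  m <- do.call(rbind, rows)
  m[m == nodata] <- NA_real_
  dem_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner, cell_size = hdr$cellsize)
}

#' Write a DEM to an ESRI ASCII grid file
#'
#' @param dem a [dem_grid()] object.
#' @param path output path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_dem <- function(dem, path, nodata = -9999) {
  stopifnot(inherits(dem, "dem_grid"))
  m <- dem$elevation
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(dem$xll, scientific = FALSE)),
           paste("yllcorner", format(dem$yll, scientific = FALSE)),
           paste("cellsize", format(dem$cell_size, scientific = FALSE)),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                               digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Map planar positions to (row, col) cell indices; half-open cell bounds,
# row 1 = north edge.  Positions outside the grid are clamped to the border.
dem_cell_index <- function(dem, x, y) {
  nr <- nrow(dem$elevation); nc <- ncol(dem$elevation)
  col <- floor((x - dem$xll) / dem$cell_size) + 1
  row_from_bottom <- floor((y - dem$yll) / dem$cell_size) + 1
  row <- nr - row_from_bottom + 1
  col <- pmin(pmax(col, 1), nc)
  row <- pmin(pmax(row, 1), nr)
  cbind(row = as.integer(row), col = as.integer(col))
}
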