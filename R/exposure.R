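## Individualized cumulative weighted ambient UVB exposure (CW-D-UVB).
##
## The exposure for a participant sampled on date t at grid cell c is
##   CWDUVB = sum_{x=1..window} D(c, t - x) * exp(-(ln 2 / half_life) * x)
## where x = 1 is the day before blood draw. Defaults: half-life 35 days,
## window 135 days (contributions beyond ~4 half-lives are negligible).

#' Weighting parameters for the cumulative UVB dose
#'
#' @param half_life_days half-life of the UVB effect on circulating
#'   vitamin D, in days. The weight of a dose x days before sampling is
#'   \code{exp(-(log(2)/half_life_days) * x)}.
#' @param window_days number of days before sampling that contribute
#'   (lags x = 1..window_days; the sampling day itself is excluded).
#' @return a list with class \code{"WeightingParams"}.
#' @examples
#' p <- weightingParams()
#' exposureWeights(p)[35] # one half-life: exactly 1/2
#' @export
weightingParams <- function(half_life_days = 35, window_days = 135) {
  stopifnot(half_life_days > 0, window_days >= 1)
  structure(list(half_life_days = as.numeric(half_life_days),
                 window_days = as.integer(window_days)),
            class = "WeightingParams")
}

#' @rdname weightingParams
#' @param params a \code{WeightingParams}.
#' @return \code{exposureWeights} returns the weight vector for lags
#'   \code{1..window_days}.
#' @export
exposureWeights <- function(params = weightingParams()) {
  x <- seq_len(params$window_days)
  exp(-(log(2) / params$half_life_days) * x)
}

## ---------------------------------------------------------------------------
## British National Grid <-> latitude/longitude.
## Airy 1830 ellipsoid, standard OSGB constants: scale on central meridian
## 0.9996012717, true origin 49N 2W, false easting 400000 m, false
## northing -100000 m.

.airy <- list(a = 6377563.396, b = 6356256.909)
.osgb <- list(F0 = 0.9996012717,
              lat0 = 49 * pi / 180, lon0 = -2 * pi / 180,
              E0 = 400000, N0 = -100000)

## meridional arc from lat0 to phi (metres, scaled by F0)
.meridArc <- function(phi, lat0 = .osgb$lat0) {
  a <- .airy$a; b <- .airy$b; F0 <- .osgb$F0
  n <- (a - b) / (a + b)
  dphi <- phi - lat0; sphi <- phi + lat0
  b * F0 * ((1 + n + 5 / 4 * n^2 + 5 / 4 * n^3) * dphi -
    (3 * n + 3 * n^2 + 21 / 8 * n^3) * sin(dphi) * cos(sphi) +
    (15 / 8 * n^2 + 15 / 8 * n^3) * sin(2 * dphi) * cos(2 * sphi) -
    (35 / 24 * n^3) * sin(3 * dphi) * cos(3 * sphi))
}

## Helmert parameters OSGB36 -> WGS84 (inverse of the standard
## WGS84 -> OSGB36 national set); s in ppm, rotations in arc-seconds.
.helmert_osgb36_to_wgs84 <- list(
  tx = 446.448, ty = -125.157, tz = 542.060,
  s = -20.4894e-6,
  rx = 0.1502 / 3600 * pi / 180,
  ry = 0.2470 / 3600 * pi / 180,
  rz = 0.8421 / 3600 * pi / 180
)

.geodToCart <- function(lat, lon, a, b) {
  e2 <- 1 - (b / a)^2
  nu <- a / sqrt(1 - e2 * sin(lat)^2)
  cbind(nu * cos(lat) * cos(lon),
        nu * cos(lat) * sin(lon),
        nu * (1 - e2) * sin(lat))
}

.cartToGeod <- function(xyz, a, b) {
  e2 <- 1 - (b / a)^2
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  p <- sqrt(x^2 + y^2)
  lat <- atan2(z, p * (1 - e2))
  for (k in 1:10) {
    nu <- a / sqrt(1 - e2 * sin(lat)^2)
    lat <- atan2(z + e2 * nu * sin(lat), p)
  }
  cbind(lat = lat, lon = atan2(y, x))
}

#' Convert British National Grid coordinates to latitude/longitude
#'
#' Inverse transverse Mercator on the Airy 1830 ellipsoid with the
#' standard Ordnance Survey constants (central-meridian scale
#' 0.9996012717, true origin 49N 2W, false origin at easting 400000 m,
#' northing -100000 m). The meridional arc is inverted iteratively to
#' below 1e-12 m. By default coordinates are returned on the OSGB36
#' datum; \code{datum = "WGS84"} additionally applies the national
#' seven-parameter Helmert transformation (the datum shift moves points
#' by ~100 m, far below a quarter-degree grid cell, so OSGB36 is the
#' default for grid lookup).
#'
#' @param easting,northing numeric vectors of OSGB coordinates in metres.
#' @param datum \code{"OSGB36"} (default) or \code{"WGS84"}.
#' @return data.frame with columns \code{lat}, \code{lon} in degrees.
#' @examples
#' osgbToLatLon(400000, -100000) # the true origin: 49N 2W
#' @export
osgbToLatLon <- function(easting, northing, datum = c("OSGB36", "WGS84")) {
  datum <- match.arg(datum)
  stopifnot(length(easting) == length(northing))
  ok <- easting >= -90000 & easting <= 810000 &
    northing >= -160000 & northing <= 1400000
  if (!all(ok))
    stop("coordinates outside the British National Grid extent: index ",
         paste(which(!ok), collapse = ", "))
  a <- .airy$a; b <- .airy$b; F0 <- .osgb$F0
  e2 <- 1 - (b / a)^2
  n_out <- length(easting)
  lat <- numeric(n_out); lon <- numeric(n_out)
  for (i in seq_len(n_out)) {
    E <- easting[i]; N <- northing[i]
    phi <- (N - .osgb$N0) / (a * F0) + .osgb$lat0
    for (it in 1:100) {
      M <- .meridArc(phi)
      dM <- N - .osgb$N0 - M
      if (abs(dM) < 1e-9) break  # metres; ~1e-14 rad, at double precision
      phi <- phi + dM / (a * F0)
    }
    s <- sin(phi); c1 <- cos(phi); t <- tan(phi)
    nu <- a * F0 / sqrt(1 - e2 * s^2)
    rho <- a * F0 * (1 - e2) * (1 - e2 * s^2)^(-1.5)
    eta2 <- nu / rho - 1
    VII <- t / (2 * rho * nu)
    VIII <- t / (24 * rho * nu^3) * (5 + 3 * t^2 + eta2 - 9 * t^2 * eta2)
    IX <- t / (720 * rho * nu^5) * (61 + 90 * t^2 + 45 * t^4)
    X <- 1 / (c1 * nu)
    XI <- 1 / (c1 * 6 * nu^3) * (nu / rho + 2 * t^2)
    XII <- 1 / (c1 * 120 * nu^5) * (5 + 28 * t^2 + 24 * t^4)
    XIIA <- 1 / (c1 * 5040 * nu^7) *
      (61 + 662 * t^2 + 1320 * t^4 + 720 * t^6)
    dE <- E - .osgb$E0
    lat[i] <- phi - VII * dE^2 + VIII * dE^4 - IX * dE^6
    lon[i] <- .osgb$lon0 + X * dE - XI * dE^3 + XII * dE^5 - XIIA * dE^7
  }
  if (datum == "WGS84") {
    xyz <- .geodToCart(lat, lon, a, b)
    h <- .helmert_osgb36_to_wgs84
    R <- matrix(c(1, -h$rz, h$ry,
                  h$rz, 1, -h$rx,
                  -h$ry, h$rx, 1), 3, 3, byrow = TRUE)
    xyz2 <- sweep((1 + h$s) * xyz %*% t(R), 2, c(h$tx, h$ty, h$tz), "+")
    ## WGS84 ellipsoid
    g <- .cartToGeod(xyz2, a = 6378137.0, b = 6356752.3142)
    lat <- g[, "lat"]; lon <- g[, "lon"]
  }
  data.frame(lat = lat * 180 / pi, lon = lon * 180 / pi)
}

#' Map a point to its grid cell
#'
#' Cells are half-open lower-left-anchored intervals, so a point exactly
#' on an interior boundary belongs to the higher-index cell. Indices are
#' 0-based; \code{cell} is the 1-based latitude-major column index into
#' the dose matrix of a \linkS4class{DailyDoseGrid}.
#'
#' @param lat,lon numeric vectors, degrees.
#' @param grid a \linkS4class{GridSpec}.
#' @return data.frame with \code{lat_idx}, \code{lon_idx} (0-based) and
#'   \code{cell} (1-based column index).
#' @export
latLonToCell <- function(lat, lon, grid) {
  s <- grid@cell_size_deg
  i <- floor((lat - grid@lat_min) / s + 1e-12)
  j <- floor((lon - grid@lon_min) / s + 1e-12)
  bad <- i < 0 | i >= grid@n_lat | j < 0 | j >= grid@n_lon
  if (any(bad))
    stop("point outside grid extent: index ",
         paste(which(bad), collapse = ", "))
  data.frame(lat_idx = as.integer(i), lon_idx = as.integer(j),
             cell = as.integer(i * grid@n_lon + j + 1L))
}

#' Extract the daily dose series preceding a sampling date
#'
#' Returns doses at lags x = 1..window_days before \code{sample_date}
#' (most recent first; the sampling day itself is excluded). Interior
#' missing days are linearly interpolated between the nearest observed
#' neighbours; missing days at the window edges carry the nearest
#' observed value. If more than \code{max_missing} of the window is
#' missing the participant is rejected.
#'
#' @param grid_data a \linkS4class{DailyDoseGrid}.
#' @param cell 1-based cell column index (see \code{\link{latLonToCell}}).
#' @param sample_date a \code{Date}.
#' @param params a \code{\link{weightingParams}}.
#' @param max_missing maximum tolerated missing fraction (default 0.1).
#' @param id participant identifier used in error messages.
#' @return list with \code{series} (length \code{window_days}),
#'   \code{n_days_observed}, \code{n_days_imputed}.
#' @export
dailySeries <- function(grid_data, cell, sample_date,
                        params = weightingParams(),
                        max_missing = 0.1, id = "?") {
  sample_date <- as.Date(sample_date)
  w <- params$window_days
  wanted <- sample_date - seq_len(w)
  d0 <- min(grid_data@dates); d1 <- max(grid_data@dates)
  if (min(wanted) < d0 || max(wanted) > d1)
    stop(sprintf(
      "participant %s: exposure window %s..%s extends outside grid coverage %s..%s",
      id, min(wanted), max(wanted), d0, d1))
  rows <- as.integer(wanted - d0) + 1L
  series <- grid_data@dose[rows, cell]
  miss <- is.na(series)
  n_miss <- sum(miss)
  if (n_miss > max_missing * w)
    stop(sprintf(
      "participant %s: %d of %d days missing in cell %d (limit %.0f%%)",
      id, n_miss, w, cell, 100 * max_missing))
  if (n_miss > 0) {
    obs <- which(!miss)
    if (length(obs) == 0L)
      stop(sprintf("participant %s: no observed doses in window", id))
    ## interior gaps: linear interpolation; edges: carry nearest value
    series[miss] <- approx(obs, series[obs], xout = which(miss),
                           method = "linear", rule = 2)$y
  }
  list(series = series, n_days_observed = w - n_miss, n_days_imputed = n_miss)
}

#' Cumulative weighted dose from a lagged series
#'
#' \code{sum(series * exp(-(log(2)/half_life) * x))} over lags
#' x = 1..window_days, where \code{series[1]} is the day before sampling.
#'
#' @param series non-negative dose vector of length
#'   \code{params$window_days}, most recent lag first.
#' @param params a \code{\link{weightingParams}}.
#' @return the cumulative weighted dose, kJ/m^2 (weighted).
#' @examples
#' # constant 1 kJ/m^2 over the default window: geometric series
#' cumulativeWeightedDose(rep(1, 135))
#' @export
cumulativeWeightedDose <- function(series, params = weightingParams()) {
  if (length(series) != params$window_days)
    stop("series length must equal window_days")
  if (any(!is.finite(series)) || any(series < 0))
    stop("doses must be finite and non-negative")
  sum(series * exposureWeights(params))
}

#' Compute CW-D-UVB exposures for a residence table
#'
#' For every participant, resolves the residence to a grid cell
#' (converting OSGB eastings/northings when latitude/longitude are not
#' given), extracts the lagged daily dose series before the sampling
#' date, and computes the cumulative weighted dose. Failures (residence
#' outside the grid, window outside coverage, too many missing days) are
#' collected per record and do not abort the run.
#'
#' @param residences data.frame with \code{participant_id},
#'   \code{sample_date} and either \code{easting}/\code{northing}
#'   (metres) or \code{lat}/\code{lon} (degrees).
#' @param grid_data a \linkS4class{DailyDoseGrid}.
#' @param params a \code{\link{weightingParams}}.
#' @param max_missing maximum missing fraction per window.
#' @param datum datum for the OSGB conversion, see
#'   \code{\link{osgbToLatLon}}.
#' @return list with \code{exposure} (data.frame \code{participant_id},
#'   \code{cwduvb}, \code{n_days_observed}, \code{n_days_imputed}) and
#'   \code{failures} (data.frame \code{participant_id}, \code{error}).
#' @export
buildExposureTable <- function(residences, grid_data,
                               params = weightingParams(),
                               max_missing = 0.1, datum = "OSGB36") {
  res <- as.data.frame(residences)
  has_ll <- all(c("lat", "lon") %in% colnames(res)) &&
    any(!is.na(res$lat))
  has_en <- all(c("easting", "northing") %in% colnames(res)) &&
    any(!is.na(res$easting))
  if (has_en && !has_ll) {
    ll <- osgbToLatLon(res$easting, res$northing, datum = datum)
    res$lat <- ll$lat; res$lon <- ll$lon
  } else if (!has_ll) {
    stop("residences need either lat/lon or easting/northing columns")
  }
  out <- vector("list", nrow(res)); fail <- list()
  for (k in seq_len(nrow(res))) {
    pid <- res$participant_id[k]
    r <- tryCatch({
      cell <- latLonToCell(res$lat[k], res$lon[k], grid_data@grid)$cell
      ds <- dailySeries(grid_data, cell, res$sample_date[k], params,
                        max_missing = max_missing, id = pid)
      data.frame(participant_id = pid,
                 cwduvb = cumulativeWeightedDose(ds$series, params),
                 n_days_observed = ds$n_days_observed,
                 n_days_imputed = ds$n_days_imputed)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      fail[[length(fail) + 1L]] <-
        data.frame(participant_id = pid, error = conditionMessage(r))
    } else out[[k]] <- r
  }
  list(
    exposure = do.call(rbind, out[!vapply(out, is.null, logical(1))]),
    failures = if (length(fail)) do.call(rbind, fail) else
      data.frame(participant_id = character(), error = character())
  )
}

#' @importFrom stats approx
NULL
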