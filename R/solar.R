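## Solar geometry: relative azimuths and candidate reference solar zenith
## angles for standardizing a flight box to a common illumination.

#' Relative azimuth between sun and sensor
#'
#' Folds the azimuth difference into \[0, 180\] degrees; the Ross and Li
#' kernels are even in relative azimuth, so the sign is irrelevant.
#'
#' @param phi_s,phi_v Solar and sensor azimuths in degrees, \[0, 360).
#' @return Relative azimuth in degrees, \[0, 180\].
#' @export
relative_azimuth <- function(phi_s, phi_v) {
  if (any(phi_s < 0 | phi_s >= 360 | phi_v < 0 | phi_v >= 360, na.rm = TRUE))
    stop("relative_azimuth: azimuths must lie in [0, 360)")
  d <- (phi_s - phi_v) %% 360
  pmin(d, 360 - d)
}

#' Solar declination (Spencer series)
#'
#' Fourier-series declination in terms of the fractional year; accuracy is
#' of order 0.1 degree, ample for choosing a reference illumination angle.
#'
#' @param date A `Date` (vectorized).
#' @return Declination in degrees.
#' @export
solar_declination <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  yr <- as.integer(strftime(date, "%Y"))
  ndays <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366, 365)
  g <- 2 * pi / ndays * (doy - 1 + 0.5)  # fractional year at local noon
  (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
     0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
     0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)) * 180 / pi
}

#' Solar zenith angle at local solar noon
#'
#' At solar noon the hour angle is zero and the zenith reduces to the
#' absolute difference between latitude and declination.
#'
#' @param date A `Date` (vectorized).
#' @param latitude Degrees, positive north, in \[-90, 90\].
#' @return Zenith in degrees.
#' @export
solar_noon_zenith <- function(date, latitude) {
  if (any(latitude < -90 | latitude > 90))
    stop("solar_noon_zenith: latitude must lie in [-90, 90]")
  abs(latitude - solar_declination(date))
}

#' Mean solar-noon zenith over a season
#'
#' Unweighted mean of the daily solar-noon zenith over every calendar day in
#' `[start, end]`, endpoints included.
#'
#' @param start,end `Date`s with `start <= end`.
#' @param latitude Degrees.
#' @return Mean zenith in degrees.
#' @export
seasonal_mean_zenith <- function(start, end, latitude) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("seasonal_mean_zenith: start must not exceed end")
  mean(solar_noon_zenith(seq(start, end, by = "day"), latitude))
}

#' Pooled mean observed solar zenith over a flightline group
#'
#' Mean of the per-pixel solar zenith over the valid pixels of every line,
#' so each line contributes in proportion to its valid-pixel count.
#'
#' @param group List of [observation_stack()]s.
#' @return Mean solar zenith in degrees.
#' @export
observed_mean_zenith <- function(group) {
  if (inherits(group, "observation_stack")) group <- list(group)
  if (length(group) == 0) stop("observed_mean_zenith: empty group")
  s <- 0; n <- 0
  for (obs in group) {
    v <- obs$solar_zenith[obs$valid_mask]
    s <- s + sum(v); n <- n + length(v)
  }
  if (n == 0) stop("observed_mean_zenith: no valid pixels in group")
  s / n
}

#' Specify how the reference solar zenith is chosen
#'
#' The four candidate references: solar noon on the acquisition date
#' (`flight_noon`), the growing-season mean of daily solar-noon zeniths
#' (`season_noon`), the pooled mean observed solar zenith of the flight box
#' (`observed_mean`, the recommended default), and solar noon on the summer
#' solstice (`solstice_noon`). `none` keeps each pixel's own solar zenith
#' (nadir-only correction); `fixed` uses a user-supplied angle.
#'
#' @param mode One of `"flight_noon"`, `"season_noon"`, `"observed_mean"`,
#'   `"solstice_noon"`, `"none"`, `"fixed"`.
#' @param latitude Degrees; flight-box mean of line-center latitudes.
#' @param date Acquisition date (for `flight_noon`; also fixes the year for
#'   `solstice_noon`).
#' @param season_start,season_end Season window (for `season_noon`).
#' @param fixed_value Degrees (for `fixed`).
#' @return An object of class `solar_reference`.
#' @export
solar_reference <- function(mode = c("observed_mean", "flight_noon",
                                     "season_noon", "solstice_noon",
                                     "none", "fixed"),
                            latitude = NULL, date = NULL,
                            season_start = NULL, season_end = NULL,
                            fixed_value = NULL) {
  mode <- match.arg(mode)
  if (!is.null(latitude) && (latitude < -90 || latitude > 90))
    stop("solar_reference: latitude must lie in [-90, 90]")
  structure(list(mode = mode, latitude = latitude,
                 date = if (is.null(date)) NULL else as.Date(date),
                 season_start = if (is.null(season_start)) NULL
                                else as.Date(season_start),
                 season_end = if (is.null(season_end)) NULL
                              else as.Date(season_end),
                 fixed_value = fixed_value),
            class = "solar_reference")
}

#' Resolve the reference solar zenith angle for a group
#'
#' @param spec A [solar_reference()].
#' @param group List of [observation_stack()]s (needed for
#'   `observed_mean`, and to default the solstice year).
#' @return Zenith in degrees, or `NULL` for mode `none` (the correction
#'   then keeps each pixel's own solar zenith).
#' @export
resolve_reference_zenith <- function(spec, group = NULL) {
  stopifnot(inherits(spec, "solar_reference"))
  need <- function(field) {
    if (is.null(spec[[field]]))
      stop(sprintf("solar_reference mode '%s' requires '%s'",
                   spec$mode, field))
    spec[[field]]
  }
  switch(spec$mode,
    none = NULL,
    fixed = need("fixed_value"),
    flight_noon = solar_noon_zenith(need("date"), need("latitude")),
    solstice_noon = {
      yr <- as.integer(strftime(need("date"), "%Y"))
      lat <- need("latitude")
      solstice <- as.Date(sprintf(
        if (lat >= 0) "%d-06-21" else "%d-12-21", yr))
      solar_noon_zenith(solstice, lat)
    },
    season_noon = seasonal_mean_zenith(need("season_start"),
                                       need("season_end"),
                                       need("latitude")),
    observed_mean = {
      if (is.null(group) || length(group) == 0)
        stop("solar_reference mode 'observed_mean' requires the group")
      observed_mean_zenith(group)
    })
}
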