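#' Solar elevation angle
#'
#' Computes the geometric elevation of the sun above the horizon for a given
#' location and UTC time, using the NOAA low-precision solar position
#' formulas (geometric mean longitude / anomaly, equation of center, apparent
#' longitude, corrected obliquity and the equation of time). Accuracy is well
#' within 0.5 degrees over the satellite-tag era, which is sufficient to
#' classify day, twilight and night periods.
#'
#' No atmospheric refraction correction is applied: day-period boundaries are
#' defined on the geometric angle (0 and -12 degrees).
#'
#' @param lat latitude in decimal degrees (positive north), |lat| <= 90.
#' @param lon longitude in decimal degrees (positive east).
#' @param time a POSIXct vector (UTC) of evaluation times.
#' @return Numeric vector of solar elevations in degrees.
#' @seealso [classify_day_period()]
#' @export
solar_elevation <- function(lat, lon, time) {
  if (any(abs(lat) > 90)) stop("latitude must be within [-90, 90]")
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct (UTC)")
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525

  L0 <- (280.46646 + T * (36000.76983 + T * 0.0003032)) %% 360
  M  <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e  <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  C  <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
        sin(2 * Mr) * (0.019993 - 0.000101 * T) +
        sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))

  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps  <- eps0 + 0.00256 * cos(deg2rad(omega))

  decl <- asin(sin(deg2rad(eps)) * sin(deg2rad(lambda)))

  y <- tan(deg2rad(eps) / 2)^2
  L0r <- deg2rad(L0)
  eqtime <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  )

  frac_day <- (jd + 0.5) %% 1          # fraction of UTC day
  tst <- (frac_day * 1440 + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180                  # hour angle, degrees

  latr <- deg2rad(lat)
  sin_el <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(deg2rad(ha))
  rad2deg(asin(clamp(sin_el, -1, 1)))
}

#' Classify period of day from solar elevation
#'
#' Day is a positive solar angle, twilight the closed interval from -12 to 0
#' degrees, and night anything below -12 degrees.
#'
#' @param elevation solar elevation(s) in degrees.
#' @return Character vector in `c("day", "twilight", "night")`.
#' @export
classify_day_period <- function(elevation) {
  if (any(!is.finite(elevation))) stop("elevation must be finite")
  ifelse(elevation > 0, "day", ifelse(elevation >= -12, "twilight", "night"))
}
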