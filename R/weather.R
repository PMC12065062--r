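# Daily weather handling, growing-season aggregation and FAO-56
# Penman-Monteith reference evapotranspiration (ET0).

#' Site metadata for reference evapotranspiration
#'
#' Bundles the site constants the FAO-56 daily chain needs: latitude (for
#' extraterrestrial radiation), elevation (clear-sky radiation and the
#' pressure fallback), anemometer height (logarithmic adjustment to 2 m),
#' surface albedo and the Angstrom sunshine-to-radiation coefficients.
#'
#' @param latitude decimal degrees, positive north; must lie in \[-90, 90\].
#' @param elevation metres above sea level.
#' @param wind_height anemometer height in metres (default 2, i.e. no
#'   adjustment).
#' @param albedo surface albedo of the reference grass crop; FAO-56 uses
#'   0.23.
#' @param angstrom_a,angstrom_b Angstrom regression coefficients relating
#'   relative sunshine duration to solar radiation; FAO-56 defaults 0.25 and
#'   0.50 where no local calibration exists.
#' @return an object of class `site_meta`.
#' @examples
#' site_meta(latitude = 40.068641, elevation = 220)
#' @export
site_meta <- function(latitude, elevation, wind_height = 2,
                      albedo = 0.23, angstrom_a = 0.25, angstrom_b = 0.50) {
  if (!is_finite_num(latitude) || latitude < -90 || latitude > 90)
    stopf("latitude must be a finite value in [-90, 90], got %s", latitude)
  if (!is_finite_num(elevation)) stopf("elevation must be finite")
  if (!is_finite_num(albedo) || albedo <= 0 || albedo >= 1)
    stopf("albedo must lie strictly between 0 and 1")
  if (!is_finite_num(wind_height) || wind_height <= 0)
    stopf("wind_height must be positive")
  structure(
    list(latitude = latitude, elevation = elevation,
         wind_height = wind_height, albedo = albedo,
         angstrom_a = angstrom_a, angstrom_b = angstrom_b),
    class = "site_meta")
}

#' Validate a daily weather table
#'
#' Checks the physical invariants of a daily weather record: `tmax >= tmin`,
#' relative humidities ordered and inside \[0, 100\], non-negative wind and
#' precipitation, finite values throughout. Sunshine hours are checked
#' against astronomical daylength inside [compute_et0()] where latitude is
#' known.
#'
#' @param weather data frame with columns `date`, `tmax_c`, `tmin_c`,
#'   `rhmax_pct`, `rhmin_pct`, `wind_ms`, `sunshine_h`, and optionally
#'   `pressure_kpa`, `wind_height_m`, `precip_mm`.
#' @return the validated data frame, invisibly usable in a pipe.
#' @export
validate_weather <- function(weather) {
  need_cols(weather, c("date", "tmax_c", "tmin_c", "rhmax_pct", "rhmin_pct",
                       "wind_ms", "sunshine_h"), "weather")
  num_cols <- intersect(names(weather),
                        c("tmax_c", "tmin_c", "rhmax_pct", "rhmin_pct",
                          "wind_ms", "sunshine_h", "pressure_kpa",
                          "wind_height_m", "precip_mm"))
  for (cc in num_cols) {
    if (!all(is.finite(weather[[cc]])))
      stopf("weather column '%s' contains non-finite values", cc)
  }
  bad <- which(weather$tmax_c < weather$tmin_c)
  if (length(bad) > 0L)
    stopf("tmax < tmin on %s", paste(weather$date[bad], collapse = ", "))
  if (any(weather$rhmax_pct > 100 | weather$rhmin_pct < 0))
    stopf("relative humidity outside [0, 100]")
  if (any(weather$rhmin_pct > weather$rhmax_pct))
    stopf("rhmin exceeds rhmax")
  if (any(weather$wind_ms < 0)) stopf("negative wind speed")
  if (any(weather$sunshine_h < 0)) stopf("negative sunshine hours")
  if ("precip_mm" %in% names(weather) && any(weather$precip_mm < 0))
    stopf("negative precipitation")
  weather
}

# saturation vapour pressure (kPa) at air temperature T (deg C)
svp <- function(temp_c) 0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))

# solar geometry for a latitude (rad) and day of year: inverse relative
# earth-sun distance, solar declination, sunset hour angle
solar_geometry <- function(lat_rad, doy) {
  dr  <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws  <- acos(pmin(1, pmax(-1, -tan(lat_rad) * tan(dec))))
  list(dr = dr, dec = dec, ws = ws)
}

#' Astronomical daylength
#'
#' Maximum possible sunshine duration (hours) for a latitude and day of
#' year.
#'
#' @param latitude decimal degrees.
#' @param doy day of year (1-366), vectorised.
#' @return hours of daylight.
#' @export
daylength <- function(latitude, doy) {
  g <- solar_geometry(latitude * pi / 180, doy)
  24 / pi * g$ws
}

#' FAO-56 Penman-Monteith daily reference evapotranspiration
#'
#' Computes grass-reference evapotranspiration (ET0, mm day^-1) from daily
#' weather by the full FAO-56 chain under the minimum-data route (sunshine
#' hours rather than measured radiation): mean saturation vapour pressure
#' from the temperature extremes, actual vapour pressure from the humidity
#' extremes, vapour-pressure-curve slope at mean temperature, psychrometric
#' constant from pressure (measured if supplied, otherwise the FAO-56
#' elevation approximation), extraterrestrial radiation from latitude and
#' day of year, solar radiation via the Angstrom formula, net shortwave with
#' albedo, net longwave with cloudiness and humidity corrections, soil heat
#' flux taken as zero at the daily scale, and wind adjusted logarithmically
#' to 2 m when measured at another height.
#'
#' @param weather daily weather table as in [validate_weather()].
#' @param site a [site_meta()] object.
#' @return data frame with one row per input day: `date`, `et0_mm`, and
#'   audit columns (`ra_mj`, `rs_mj`, `rn_mj`, `es_kpa`, `ea_kpa`,
#'   `delta_kpa_c`, `gamma_kpa_c`, `u2_ms`, `daylength_h`).
#' @references Allen, R. G., Pereira, L. S., Raes, D., & Smith, M. (1998).
#'   Crop evapotranspiration: guidelines for computing crop water
#'   requirements. FAO Irrigation and Drainage Paper 56.
#' @export
compute_et0 <- function(weather, site) {
  stopifnot(inherits(site, "site_meta"))
  weather <- validate_weather(weather)
  doy <- as.integer(strftime(as.Date(weather$date), "%j"))
  lat_rad <- site$latitude * pi / 180

  g <- solar_geometry(lat_rad, doy)
  N <- 24 / pi * g$ws
  over <- which(weather$sunshine_h > N + 1e-9)
  if (length(over) > 0L)
    stopf("sunshine exceeds astronomical daylength on %s",
          paste(weather$date[over], collapse = ", "))

  tmax <- weather$tmax_c; tmin <- weather$tmin_c
  tmean <- tmean_of(tmax, tmin)
  es <- (svp(tmax) + svp(tmin)) / 2
  ea <- (svp(tmin) * weather$rhmax_pct / 100 +
         svp(tmax) * weather$rhmin_pct / 100) / 2
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2

  pressure <- if ("pressure_kpa" %in% names(weather)) {
    weather$pressure_kpa
  } else {
    rep(101.3 * ((293 - 0.0065 * site$elevation) / 293)^5.26, nrow(weather))
  }
  gamma <- 0.000665 * pressure

  gsc <- 0.0820  # solar constant, MJ m-2 min-1
  ra <- 24 * 60 / pi * gsc * g$dr *
    (g$ws * sin(lat_rad) * sin(g$dec) + cos(lat_rad) * cos(g$dec) * sin(g$ws))
  rs  <- (site$angstrom_a + site$angstrom_b * weather$sunshine_h / N) * ra
  rso <- (0.75 + 2e-5 * site$elevation) * ra
  rns <- (1 - site$albedo) * rs
  sigma <- 4.903e-9  # Stefan-Boltzmann, MJ K-4 m-2 day-1
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * pmin(rs / rso, 1) - 0.35)
  rn <- rns - rnl
  gflux <- 0  # daily soil heat flux

  wh <- if ("wind_height_m" %in% names(weather)) weather$wind_height_m
        else rep(site$wind_height, nrow(weather))
  u2 <- ifelse(abs(wh - 2) < 1e-9, weather$wind_ms,
               weather$wind_ms * 4.87 / log(67.8 * wh - 5.42))

  et0 <- (0.408 * delta * (rn - gflux) +
          gamma * 900 / (tmean + 273) * u2 * (es - ea)) /
         (delta + gamma * (1 + 0.34 * u2))
  et0 <- pmax(et0, 0)

  data.frame(date = as.Date(weather$date), et0_mm = et0,
             ra_mj = ra, rs_mj = rs, rn_mj = rn,
             es_kpa = es, ea_kpa = ea, delta_kpa_c = delta,
             gamma_kpa_c = gamma, u2_ms = u2, daylength_h = N)
}

#' Define a season window
#'
#' @param start,end calendar dates (coerced with `as.Date`); `start` must
#'   not fall after `end`.
#' @param label optional text label, e.g. `"growing season 2021"`.
#' @return a `season_window` object.
#' @export
season_window <- function(start, end, label = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stopf("window dates must parse as dates")
  if (start > end) stopf("window start (%s) is after end (%s)", start, end)
  structure(list(start = start, end = end,
                 label = label %||% sprintf("%s..%s", start, end)),
            class = "season_window")
}

#' Aggregate weather over a season window
#'
#' Sums precipitation and averages temperature over a window. Two input
#' resolutions are supported, mirroring how climate summaries are printed:
#' a daily table (columns `date`, `precip_mm` and either `tmean_c` or
#' `tmax_c`/`tmin_c`) aggregated day by day, or a monthly climate table
#' (columns `year`, `month`, `temp_c`, `precip_mm`) in which monthly mean
#' temperatures are averaged and monthly precipitation totals summed over
#' the months the window spans. Values are returned at full precision;
#' rounding is a reporting decision.
#'
#' @param x daily or monthly weather table (see Details).
#' @param window a [season_window()]. For monthly input the window is
#'   interpreted as whole months.
#' @return one-row data frame: `label`, `precip_mm`, `tmean_c`, `n_units`.
#' @examples
#' m <- data.frame(year = 2022, month = 4:9,
#'                 temp_c = c(10.4, 19.2, 24, 24.1, 22.3, 18.8),
#'                 precip_mm = c(69.1, 95.5, 32, 63, 88.4, 57.4))
#' aggregate_season(m, season_window("2022-04-01", "2022-09-30"))
#' @export
aggregate_season <- function(x, window) {
  stopifnot(inherits(window, "season_window"))
  if ("date" %in% names(x)) {
    need_cols(x, c("date", "precip_mm"), "daily weather")
    d <- as.Date(x$date)
    keep <- d >= window$start & d <= window$end
    span <- seq(window$start, window$end, by = "day")
    if (!all(span %in% d))
      stopf("window not covered by daily series: missing %d day(s) starting %s",
            sum(!(span %in% d)), min(span[!(span %in% d)]))
    tmean <- if ("tmean_c" %in% names(x)) x$tmean_c
             else tmean_of(x$tmax_c, x$tmin_c)
    data.frame(label = window$label,
               precip_mm = sum(x$precip_mm[keep]),
               tmean_c = mean(tmean[keep]),
               n_units = sum(keep))
  } else {
    need_cols(x, c("year", "month", "temp_c", "precip_mm"), "monthly weather")
    y0 <- as.integer(format(window$start, "%Y"))
    m0 <- as.integer(format(window$start, "%m"))
    m1 <- as.integer(format(window$end, "%m"))
    y1 <- as.integer(format(window$end, "%Y"))
    if (y0 != y1)
      stopf("monthly aggregation expects a window within one calendar year")
    keep <- x$year == y0 & x$month >= m0 & x$month <= m1
    want <- m0:m1
    if (!all(want %in% x$month[keep]))
      stopf("window not covered by monthly series: missing month(s) %s of %d",
            paste(setdiff(want, x$month[keep]), collapse = ", "), y0)
    data.frame(label = window$label,
               precip_mm = sum(x$precip_mm[keep]),
               tmean_c = mean(x$temp_c[keep]),
               n_units = sum(keep))
  }
}
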