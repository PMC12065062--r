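# shared fixtures, built in code

# fully specified mid-July day used for the FAO-56 hand-calculation checks
reference_day <- function() {
  data.frame(date = "2021-07-15", tmax_c = 30, tmin_c = 18,
             rhmax_pct = 90, rhmin_pct = 50, wind_ms = 2,
             wind_height_m = 2, pressure_kpa = 101.3, sunshine_h = 10)
}

reference_site <- function() site_meta(latitude = 40.07, elevation = 220)

# random physically valid weather table, n days
random_weather <- function(n, seed) {
  withr::with_seed(seed, {
    tmin <- runif(n, -5, 22)
    rhmin <- runif(n, 20, 70)
    doy <- sample(1:365, n, replace = TRUE)
    data.frame(date = as.Date("2021-01-01") + doy - 1,
               tmax_c = tmin + runif(n, 1, 15), tmin_c = tmin,
               rhmax_pct = rhmin + runif(n, 5, 30), rhmin_pct = rhmin,
               wind_ms = runif(n, 0, 8), wind_height_m = 2,
               pressure_kpa = runif(n, 97, 103),
               sunshine_h = runif(n, 0, 8.5),
               precip_mm = rbinom(n, 1, 0.3) * runif(n, 0, 30))
  })
}

# long-format VWC table for one plot with constant profile theta
flat_vwc <- function(theta, days, plot_id = "P1", depths = c(30, 60, 90)) {
  stamps <- seq(as.POSIXct(paste(days[1], "00:00:00"), tz = "UTC"),
                as.POSIXct(paste(days[length(days)] + 1, "00:00:00"),
                           tz = "UTC"),
                by = "hour")
  expand <- expand.grid(timestamp = stamps, depth_cm = depths)
  data.frame(timestamp = expand$timestamp, plot_id = plot_id,
             depth_cm = expand$depth_cm, vwc = theta)
}
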