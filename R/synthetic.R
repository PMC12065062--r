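# Synthetic study generator: every pipeline input with known ground truth.
# The default scenario mirrors the field trial's shape — 6 plots (2 crops x
# 3 blocks), 3 seasons, 3 chambers per plot, profile sensors at 30/60/90 cm
# — and a central-Illinois climate (~19 C growing-season mean, ~600 mm
# growing-season precipitation; the drought preset runs ~28% drier).

#' Ground-truth parameters for the synthetic study
#'
#' One object collects every constant the generators use, so each generator
#' is a pure function of `(truth, seed)` and the truth log can be compared
#' against pipeline output.
#'
#' @param seed integer seed; all generators derive their streams from it.
#' @param years simulated seasons (calendar years).
#' @param scenario `"default"` (near-normal climate) or `"drought"`
#'   (precipitation scaled to ~72% of normal, the magnitude of a dry year
#'   at this site).
#' @param ... overrides for any element of the returned list (e.g.
#'   `sensor_jitter_sd = 0`, `precip_event_prob = 0` for noise-free or dry
#'   variants in tests).
#' @return a `truth_params` list; see the source for the full field set.
#' @export
truth_params <- function(seed = 1, years = 2020:2022,
                         scenario = c("default", "drought"), ...) {
  scenario <- match.arg(scenario)
  p <- list(
    seed = as.integer(seed), years = years, scenario = scenario,
    plots = data.frame(
      plot_id = c("C1", "C2", "C3", "S1", "S2", "S3"),
      crop = rep(c("corn", "switchgrass"), each = 3),
      block = rep(1:3, times = 2)),
    # site (central Illinois)
    latitude = 40.068641, elevation = 220,
    sim_start_md = "03-01", season_start_md = "04-01", season_end_md = "09-30",
    emergence_md = "04-25",
    # weather process
    temp_mean_annual = 11, temp_amplitude = 14, temp_peak_doy = 196,
    temp_halfrange = 5, temp_noise_sd = 1.5,
    precip_event_prob = 0.33,   # unconditional wet-day frequency
    precip_wet_persist = 0.55,  # P(wet | wet): first-order Markov occurrence
    precip_mean_mm = 10, precip_shape = 0.9,
    drought_factor = 0.72,
    wind_height_m = 10,
    # bucket model
    fc_mm = 340, tsm_start_offset_mm = 10, drainage_k = 0.08,
    wilting_mm = 200, stress_band_mm = 20,
    sensor_depths_cm = c(30, 60, 90),
    sensor_offset_sd = 0.01, sensor_jitter_sd = 5e-5,
    sensor_resolution = 1e-3,
    et_day_factor_sd = 0.10,
    # crop coefficient ramps (day-of-year nodes)
    kc = list(
      corn        = list(bare = 0.15, full = 0.65, ramp = c(140, 190),
                         decline = c(245, 273), late = 0.35),
      switchgrass = list(bare = 0.15, full = 0.60, ramp = c(120, 180),
                         decline = c(250, 273), late = 0.35)),
    # chamber flux schedules
    chambers_per_plot = 3,
    co2_base = c(corn = 2.0, switchgrass = 2.6),  # g C m-2 d-1 at 20 C
    co2_q10 = 2.0,
    n2o_base = 5e-4,                               # g N m-2 d-1
    n2o_fert = list(corn = list(md = "05-15", amp = 8e-3, decay_d = 10),
                    switchgrass = list(md = "04-30", amp = 2e-3, decay_d = 10)),
    flux_plot_sd = 0.15,                           # lognormal sd per plot-date
    chamber_noise_ppm = c(CO2 = 1, N2O = 0.005),
    chamber_c0_ppm = c(CO2 = 420, N2O = 0.33),
    sampling_interval_d = 7,
    # biomass truth (kg ha-1 dry AGB per crop-year index)
    agb_truth = list(corn = c(11500, 11000, 10200),
                     switchgrass = c(3800, 16500, 12400)),
    agb_plot_sd = 0.05,
    corn_grain_moisture_pct = 18, corn_plot_area_m2 = 2000,
    sg_quadrat_moisture_pct = 10, sg_quadrats = 3,
    harvest_index = 0.545,
    # leachate decline model (mg L-1)
    no3_corn_mean = c(`30` = 12, `90` = 8),
    no3_sg_reduction_pct = c(20, 60, 80),  # per year index, relative to corn
    no3_sdlog = 0.3, leachate_events = 8, samplers_per_plot = 2
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0L)
    stopf("unknown truth parameter(s): %s", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "truth_params")
}

md_date <- function(year, md) as.Date(sprintf("%d-%s", year, md))

#' Growing-season window for a simulated year
#' @param truth a [truth_params()] object.
#' @param year calendar year.
#' @return a [season_window()] spanning the configured season.
#' @export
truth_window <- function(truth, year) {
  season_window(md_date(year, truth$season_start_md),
                md_date(year, truth$season_end_md),
                label = sprintf("growing season %d", year))
}

kc_of <- function(kc, doy) {
  up <- pmin(pmax((doy - kc$ramp[1]) / diff(kc$ramp), 0), 1)
  down <- pmin(pmax((doy - kc$decline[1]) / diff(kc$decline), 0), 1)
  kc$bare + (kc$full - kc$bare) * up - (kc$full - kc$late) * down
}

#' Generate synthetic daily weather
#'
#' Seasonal sinusoid temperature with Gaussian day-to-day noise, Bernoulli
#' precipitation occurrence with gamma depths, humidity/sunshine/wind kept
#' inside physical ranges (wetter, duller, more humid on rain days).
#' Reproducible from `truth$seed`; the drought scenario thins rain events
#' by `drought_factor`.
#'
#' @param truth a [truth_params()] object.
#' @return daily weather covering `sim_start_md` to `season_end_md` of each
#'   simulated year, in the column layout [validate_weather()] expects.
#' @export
gen_weather <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  withr::with_seed(truth$seed + 11L, {
    out <- lapply(truth$years, function(yr) {
      days <- seq(md_date(yr, truth$sim_start_md),
                  md_date(yr, truth$season_end_md), by = "day")
      if (length(days) < 2L) stopf("degenerate simulation window in %d", yr)
      doy <- as.integer(strftime(days, "%j"))
      n <- length(days)
      tmean <- truth$temp_mean_annual + truth$temp_amplitude *
        cos(2 * pi * (doy - truth$temp_peak_doy) / 365)
      tmax <- tmean + truth$temp_halfrange + stats::rnorm(n, 0, truth$temp_noise_sd)
      tmin <- tmean - truth$temp_halfrange + stats::rnorm(n, 0, truth$temp_noise_sd)
      tmin <- pmin(tmin, tmax - 0.5)
      p_event <- truth$precip_event_prob *
        if (truth$scenario == "drought") truth$drought_factor else 1
      # first-order Markov wet/dry chain with unconditional frequency
      # p_event and wet-day persistence p11 (dry->wet rate derived)
      p11 <- min(truth$precip_wet_persist, 0.99)
      p01 <- p_event * (1 - p11) / (1 - p_event)
      rain <- logical(n)
      rain[1] <- stats::runif(1) < p_event
      for (i in 2:n)
        rain[i] <- stats::runif(1) < (if (rain[i - 1]) p11 else p01)
      depth <- ifelse(rain,
                      stats::rgamma(n, shape = truth$precip_shape,
                                    scale = truth$precip_mean_mm / truth$precip_shape),
                      0)
      rhmax <- pmin(99, 88 + 6 * rain + stats::rnorm(n, 0, 3))
      rhmin <- pmax(25, pmin(rhmax - 5, 52 + 15 * rain + stats::rnorm(n, 0, 5)))
      dl <- daylength(truth$latitude, doy)
      frac <- ifelse(rain, stats::runif(n, 0.05, 0.35), stats::runif(n, 0.55, 0.90))
      wind <- pmax(0.3, stats::rnorm(n, 2.2, 0.8))
      data.frame(date = days, tmax_c = tmax, tmin_c = tmin,
                 rhmax_pct = rhmax, rhmin_pct = rhmin,
                 wind_ms = wind, wind_height_m = truth$wind_height_m,
                 pressure_kpa = 100.1 + stats::rnorm(n, 0, 0.3),
                 sunshine_h = frac * dl, precip_mm = depth)
    })
    do.call(rbind, out)
  })
}

# daily true crop ET (mm) for every simulated day of one year
true_et_schedule <- function(truth, weather_year, crop) {
  site <- site_meta(truth$latitude, truth$elevation,
                    wind_height = truth$wind_height_m)
  pet <- compute_et0(weather_year, site)
  doy <- as.integer(strftime(pet$date, "%j"))
  kc <- kc_of(truth$kc[[crop]], doy)
  kc * pet$et0_mm
}

#' Generate profile soil-moisture sensor logs from a bucket model
#'
#' Evolves hourly total soil moisture per plot: precipitation recharges the
#' bucket (spread over daytime hours), the daily true ET is withdrawn on a
#' diurnal weight curve that is exactly zero between 0000 and 0400 h, and
#' drainage removes a fixed fraction per hour of any storage above field
#' capacity. TSM is disaggregated to sensor-depth VWC with fixed weights
#' (larger swings nearer the surface) chosen so trapezoidal re-integration
#' reproduces TSM exactly; each sensor then receives a constant calibration
#' offset plus per-reading jitter. ET is throttled linearly as storage
#' approaches the wilting point.
#'
#' @param truth a [truth_params()] object.
#' @param weather daily weather from [gen_weather()].
#' @return list: `vwc` (hourly sensor log: `timestamp`, `plot_id`,
#'   `depth_cm`, `vwc`), `truth_daily` (per plot-day: `true_et_mm`,
#'   `drainage_mm`, `precip_mm`, `tsm_midnight_mm`), `fc_mm`.
#' @export
gen_soil_moisture <- function(truth, weather) {
  stopifnot(inherits(truth, "truth_params"))
  if (truth$fc_mm >= 0.6 * max(truth$sensor_depths_cm) * 10)
    stopf("field capacity above saturation for the sensed profile")
  depths <- truth$sensor_depths_cm
  profile_mm <- max(depths) * 10
  # disaggregation weights: trapezoid weights v (mm per unit theta) and a
  # variation vector u with v.u = 1, amplitude decreasing with depth
  v <- numeric(length(depths))
  v[1] <- depths[1]
  gaps <- diff(depths)
  v[-length(v)] <- v[-length(v)] + gaps / 2
  v[-1] <- v[-1] + gaps / 2
  v <- v * 10                       # cm -> mm per unit theta
  u_raw <- rev(seq_along(depths))   # 3, 2, 1 for three sensors
  u <- u_raw / sum(u_raw * v)
  theta_base <- truth$fc_mm / profile_mm

  # diurnal ET weights: zero 0000-0400, sinusoidal bulge through the day
  w <- c(rep(0, 4), sin(pi * (4:23 - 4) / 20))
  w <- w / sum(w)

  withr::with_seed(truth$seed + 23L, {
    offsets <- matrix(stats::rnorm(nrow(truth$plots) * length(depths),
                                   0, truth$sensor_offset_sd),
                      nrow = nrow(truth$plots))
    vwc_parts <- list(); truth_parts <- list()
    for (yr in truth$years) {
      wx <- weather[format(as.Date(weather$date), "%Y") == as.character(yr), ]
      days <- as.Date(wx$date)
      nd <- length(days)
      for (pi_ in seq_len(nrow(truth$plots))) {
        plot_id <- truth$plots$plot_id[pi_]
        crop <- truth$plots$crop[pi_]
        et_day <- true_et_schedule(truth, wx, crop) *
          exp(stats::rnorm(nd, 0, truth$et_day_factor_sd))
        tsm <- truth$fc_mm + truth$tsm_start_offset_mm
        nh <- nd * 24 + 1  # through next midnight after the last day
        tsm_h <- numeric(nh); tsm_h[1] <- tsm
        et_applied <- numeric(nd); drain_day <- numeric(nd)
        for (d in seq_len(nd)) {
          for (h in 0:23) {
            if (h >= 8 && h <= 19) tsm <- tsm + wx$precip_mm[d] / 12
            if (tsm > truth$fc_mm) {
              dr <- truth$drainage_k * (tsm - truth$fc_mm)
              tsm <- tsm - dr
              drain_day[d] <- drain_day[d] + dr
            }
            stress <- min(1, max(0, (tsm - truth$wilting_mm) /
                                      truth$stress_band_mm))
            et_h <- et_day[d] * w[h + 1] * stress
            tsm <- tsm - et_h
            et_applied[d] <- et_applied[d] + et_h
            tsm_h[(d - 1) * 24 + h + 2] <- tsm
          }
        }
        stamps <- seq(as.POSIXct(paste(days[1], "00:00:00"), tz = "UTC"),
                      by = "hour", length.out = nh)
        theta <- sapply(seq_along(depths), function(k)
          theta_base + u[k] * (tsm_h - truth$fc_mm))
        jit <- matrix(stats::rnorm(nh * length(depths), 0,
                                   truth$sensor_jitter_sd), nrow = nh)
        theta_obs <- sweep(theta + jit, 2, offsets[pi_, ], "+")
        if (truth$sensor_resolution > 0)  # logger output is quantised
          theta_obs <- round(theta_obs / truth$sensor_resolution) *
            truth$sensor_resolution
        theta_obs <- pmin(pmax(theta_obs, 0.01), 0.60)
        vwc_parts[[length(vwc_parts) + 1L]] <- data.frame(
          timestamp = rep(stamps, times = length(depths)),
          plot_id = plot_id,
          depth_cm = rep(depths, each = nh),
          vwc = as.numeric(theta_obs))
        truth_parts[[length(truth_parts) + 1L]] <- data.frame(
          year = yr, plot_id = plot_id, date = days,
          true_et_mm = et_applied, drainage_mm = drain_day,
          precip_mm = wx$precip_mm,
          tsm_midnight_mm = tsm_h[seq(1, nh - 1, by = 24)])
      }
    }
    list(vwc = do.call(rbind, vwc_parts),
         truth_daily = do.call(rbind, truth_parts),
         fc_mm = truth$fc_mm)
  })
}

# true gas flux schedule (g element m-2 d-1) for one plot-date
true_flux <- function(truth, crop, date, tmean, rained_recently) {
  doy <- as.integer(strftime(date, "%j"))
  co2 <- truth$co2_base[[crop]] * truth$co2_q10^((tmean - 20) / 10)
  fert <- truth$n2o_fert[[crop]]
  fert_date <- md_date(as.integer(format(date, "%Y")), fert$md)
  dd <- as.numeric(date - fert_date)
  spike <- if (dd >= 0) fert$amp * exp(-dd / fert$decay_d) else 0
  n2o <- (truth$n2o_base + spike) * (1 + 2 * rained_recently)
  c(CO2 = unname(co2), N2O = unname(n2o))
}

#' Generate static-chamber concentration ramps
#'
#' For every sampling date (weekly from emergence through season end), plot,
#' chamber and gas, inverts the ideal-gas conversion to find the
#' concentration slope implied by the plot's true flux, then emits a 16-point
#' ramp (0-300 s at 20-s spacing) with Gaussian analyser noise. The true
#' plot-date fluxes are returned as the truth log.
#'
#' @param truth a [truth_params()] object.
#' @param geometry a [chamber_geometry()].
#' @param weather daily weather from [gen_weather()] (drives temperature
#'   and the rain response of the flux schedule).
#' @return list: `chambers` (long concentration table in the layout
#'   [estimate_fluxes()] expects) and `truth_flux` (per plot-date-gas true
#'   flux, g element m-2 d-1).
#' @export
gen_chamber_series <- function(truth, geometry, weather) {
  stopifnot(inherits(truth, "truth_params"), inherits(geometry, "chamber_geometry"))
  elapsed <- seq(0, 300, by = 20)
  withr::with_seed(truth$seed + 37L, {
    ch_parts <- list(); tr_parts <- list()
    for (yr in truth$years) {
      wx <- weather[format(as.Date(weather$date), "%Y") == as.character(yr), ]
      wx_dates <- as.Date(wx$date)
      samp <- seq(md_date(yr, truth$emergence_md),
                  md_date(yr, truth$season_end_md),
                  by = truth$sampling_interval_d)
      for (pi_ in seq_len(nrow(truth$plots))) {
        plot_id <- truth$plots$plot_id[pi_]
        crop <- truth$plots$crop[pi_]
        for (d in samp) {
          d <- as.Date(d, origin = "1970-01-01")
          i <- match(d, wx_dates)
          tmean <- tmean_of(wx$tmax_c[i], wx$tmin_c[i])
          rained <- any(wx$precip_mm[max(1, i - 2):i] > 1)
          base <- true_flux(truth, crop, d, tmean, rained)
          for (gas in c("CO2", "N2O")) {
            fx <- base[[gas]] * exp(stats::rnorm(1, 0, truth$flux_plot_sd))
            temp_k <- tmean + 273.15
            press_pa <- wx$pressure_kpa[i] * 1000
            headspace <- press_pa * geometry$volume_m3 /
              (GAS_CONSTANT * temp_k)
            slope <- fx / (ELEMENT_MASS[[gas]] * 86400) *
              geometry$area_m2 / headspace * 1e6
            for (ch in seq_len(truth$chambers_per_plot)) {
              ppm <- truth$chamber_c0_ppm[[gas]] + slope * elapsed +
                stats::rnorm(length(elapsed), 0, truth$chamber_noise_ppm[[gas]])
              ppm <- pmax(ppm, 1e-4)
              ch_parts[[length(ch_parts) + 1L]] <- data.frame(
                plot_id = plot_id, chamber_id = sprintf("%s-ch%d", plot_id, ch),
                date = d, gas = gas, elapsed_s = elapsed, ppm = ppm,
                air_temp_c = tmean, pressure_kpa = wx$pressure_kpa[i])
            }
            tr_parts[[length(tr_parts) + 1L]] <- data.frame(
              year = yr, plot_id = plot_id, date = d, gas = gas,
              true_flux_g_m2_d = fx)
          }
        }
      }
    }
    list(chambers = do.call(rbind, ch_parts),
         truth_flux = do.call(rbind, tr_parts))
  })
}

#' Generate pore-water nitrate samples with a stand-age decline
#'
#' Corn concentrations are stationary across years; switchgrass means sit
#' below corn by the configured year-indexed reduction (the emulated
#' pattern: modest in the establishment year, steep once the stand
#' matures). Samples are lognormal around the implied crop-depth-year mean,
#' so all values are positive.
#'
#' @param truth a [truth_params()] object.
#' @return list: `leachate` (sample table for [summarize_no3()]) and
#'   `truth_no3` (configured means and reductions per year and depth).
#' @export
gen_leachate_series <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  if (any(truth$no3_sg_reduction_pct < 0 | truth$no3_sg_reduction_pct > 100))
    stopf("configured reductions must lie in [0, 100] percent")
  withr::with_seed(truth$seed + 41L, {
    parts <- list(); tr <- list()
    for (yi in seq_along(truth$years)) {
      yr <- truth$years[yi]
      dates <- seq(md_date(yr, "05-10"), md_date(yr, truth$season_end_md),
                   length.out = truth$leachate_events)
      dates <- as.Date(round(as.numeric(dates)), origin = "1970-01-01")
      for (pi_ in seq_len(nrow(truth$plots))) {
        plot_id <- truth$plots$plot_id[pi_]
        crop <- truth$plots$crop[pi_]
        for (depth in as.integer(names(truth$no3_corn_mean))) {
          mu <- truth$no3_corn_mean[[as.character(depth)]]
          if (crop == "switchgrass")
            mu <- mu * (1 - truth$no3_sg_reduction_pct[yi] / 100)
          n <- length(dates) * truth$samplers_per_plot
          vals <- stats::rlnorm(n, log(mu) - truth$no3_sdlog^2 / 2,
                                truth$no3_sdlog)
          parts[[length(parts) + 1L]] <- data.frame(
            date = rep(dates, each = truth$samplers_per_plot),
            plot_id = plot_id, crop = crop, depth_cm = depth,
            no3n_mg_l = vals)
          tr[[length(tr) + 1L]] <- data.frame(
            year = yr, crop = crop, depth_cm = depth, true_mean_mg_l = mu,
            true_reduction_pct = if (crop == "switchgrass")
              truth$no3_sg_reduction_pct[yi] else 0)
        }
      }
    }
    list(leachate = do.call(rbind, parts),
         truth_no3 = unique(do.call(rbind, tr)))
  })
}

#' Generate harvest records
#'
#' Corn plots yield a combine-harvested fresh grain mass at the machine
#' moisture; switchgrass plots yield three 1-m2 quadrat bundles at oven
#' moisture. The underlying dry AGB truth per crop-year is recorded.
#'
#' @param truth a [truth_params()] object.
#' @return list: `biomass` (harvest records: `plot_id`, `crop`, `year`,
#'   `component`, `fresh_kg`, `moisture_pct`, `area_m2`) and `truth_agb`
#'   (per plot-year true dry AGB, kg ha^-1).
#' @export
gen_biomass <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  withr::with_seed(truth$seed + 43L, {
    parts <- list(); tr <- list()
    for (yi in seq_along(truth$years)) {
      yr <- truth$years[yi]
      for (pi_ in seq_len(nrow(truth$plots))) {
        plot_id <- truth$plots$plot_id[pi_]
        crop <- truth$plots$crop[pi_]
        agb <- truth$agb_truth[[crop]][yi] *
          exp(stats::rnorm(1, 0, truth$agb_plot_sd))
        if (crop == "corn") {
          grain_dry_ha <- agb * truth$harvest_index
          fresh_ha <- grain_dry_ha / (1 - truth$corn_grain_moisture_pct / 100)
          parts[[length(parts) + 1L]] <- data.frame(
            plot_id = plot_id, crop = crop, year = yr, component = "grain",
            fresh_kg = fresh_ha * truth$corn_plot_area_m2 / 10000,
            moisture_pct = truth$corn_grain_moisture_pct,
            area_m2 = truth$corn_plot_area_m2)
        } else {
          for (q in seq_len(truth$sg_quadrats)) {
            dry_q <- agb / 10000 * exp(stats::rnorm(1, 0, 0.08))
            parts[[length(parts) + 1L]] <- data.frame(
              plot_id = plot_id, crop = crop, year = yr, component = "biomass",
              fresh_kg = dry_q / (1 - truth$sg_quadrat_moisture_pct / 100),
              moisture_pct = truth$sg_quadrat_moisture_pct, area_m2 = 1)
          }
        }
        tr[[length(tr) + 1L]] <- data.frame(year = yr, plot_id = plot_id,
                                            crop = crop, true_agb_kg_ha = agb)
      }
    }
    list(biomass = do.call(rbind, parts), truth_agb = do.call(rbind, tr))
  })
}

#' Generate a complete synthetic scenario
#'
#' Runs every generator and optionally writes the input files
#' (`weather.csv`, `vwc.csv`, `chamber.csv`, `leachate.csv`, `biomass.csv`)
#' plus `truth.json` to a directory.
#'
#' @param seed integer seed.
#' @param scenario `"default"` or `"drought"`.
#' @param out_dir optional directory for the CSV/JSON files.
#' @param ... further overrides passed to [truth_params()].
#' @return invisible list with all generated tables, the truth logs and the
#'   `truth_params` object.
#' @export
synth_scenario <- function(seed = 1, scenario = "default", out_dir = NULL,
                           ...) {
  truth <- truth_params(seed = seed, scenario = scenario, ...)
  geometry <- chamber_geometry()
  weather <- gen_weather(truth)
  soil <- gen_soil_moisture(truth, weather)
  cham <- gen_chamber_series(truth, geometry, weather)
  leach <- gen_leachate_series(truth)
  biom <- gen_biomass(truth)
  res <- list(truth = truth, geometry = geometry, weather = weather,
              vwc = soil$vwc, truth_daily = soil$truth_daily,
              fc_mm = soil$fc_mm,
              chambers = cham$chambers, truth_flux = cham$truth_flux,
              leachate = leach$leachate, truth_no3 = leach$truth_no3,
              biomass = biom$biomass, truth_agb = biom$truth_agb)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(weather, file.path(out_dir, "weather.csv"),
                     row.names = FALSE)
    vwc_out <- res$vwc
    vwc_out$timestamp <- format(vwc_out$timestamp, "%Y-%m-%d %H:%M:%S",
                                tz = "UTC")
    utils::write.csv(vwc_out, file.path(out_dir, "vwc.csv"),
                     row.names = FALSE)
    utils::write.csv(res$chambers, file.path(out_dir, "chamber.csv"),
                     row.names = FALSE)
    utils::write.csv(res$leachate, file.path(out_dir, "leachate.csv"),
                     row.names = FALSE)
    utils::write.csv(res$biomass, file.path(out_dir, "biomass.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, scenario = scenario, fc_mm = res$fc_mm,
           truth_daily = soil$truth_daily, truth_flux = cham$truth_flux,
           truth_no3 = leach$truth_no3, truth_agb = biom$truth_agb),
      file.path(out_dir, "truth.json"), dataframe = "columns", digits = NA)
  }
  invisible(res)
}
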