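# Static-chamber trace-gas flux estimation: headspace concentration ramps
# -> OLS slope -> ideal-gas molar flux -> element-mass flux -> daily
# interpolation -> cumulative seasonal emission.

GAS_CONSTANT <- 8.314462618  # J mol-1 K-1

# grams of element per mole of gas: C in CO2, 2 x N in N2O
ELEMENT_MASS <- c(CO2 = 12.011, N2O = 2 * 14.007)

#' Static-chamber geometry
#'
#' @param diameter_m internal anchor diameter (m); the study design uses
#'   0.203 m PVC anchors.
#' @param height_m aboveground anchor height (m).
#' @param volume_m3 total headspace volume (m^3). The dome-shaped lid means
#'   the volume is not derivable from the cylinder alone, so it is a
#'   supplied constant (0.005 m^3 for the dome chambers used here).
#' @return a `chamber_geometry` object with the basal `area_m2` computed
#'   from the diameter.
#' @export
chamber_geometry <- function(diameter_m = 0.203, height_m = 0.065,
                             volume_m3 = 0.005) {
  if (!is_finite_num(diameter_m) || diameter_m <= 0)
    stopf("diameter must be positive")
  if (!is_finite_num(volume_m3) || volume_m3 <= 0)
    stopf("headspace volume must be positive")
  if (!is_finite_num(height_m) || height_m <= 0)
    stopf("anchor height must be positive")
  structure(list(diameter_m = diameter_m, height_m = height_m,
                 volume_m3 = volume_m3,
                 area_m2 = pi * (diameter_m / 2)^2),
            class = "chamber_geometry")
}

#' Fit the concentration ramp of one chamber deployment
#'
#' Ordinary least-squares regression of headspace mole fraction on elapsed
#' time, over all points (no deadband removal); the slope is the
#' concentration accumulation rate and r-squared its linearity diagnostic.
#'
#' @param elapsed_s elapsed time since chamber closure (s), strictly
#'   increasing, at least 3 points.
#' @param ppm mole fraction (umol mol^-1), positive.
#' @return list with `slope_ppm_s`, `intercept_ppm`, `r2`, `n`.
#' @export
fit_concentration_slope <- function(elapsed_s, ppm) {
  if (length(elapsed_s) < 3L)
    stopf("need at least 3 concentration points, got %d", length(elapsed_s))
  if (length(ppm) != length(elapsed_s))
    stopf("elapsed_s and ppm lengths differ")
  if (!all(is.finite(elapsed_s)) || !all(is.finite(ppm)))
    stopf("non-finite values in concentration series")
  if (any(diff(elapsed_s) <= 0))
    stopf("elapsed times must be strictly increasing")
  if (any(ppm <= 0)) stopf("mole fractions must be positive")
  fit <- stats::lm(ppm ~ elapsed_s)
  sst <- sum((ppm - mean(ppm))^2)
  # a flat or exactly linear series is perfectly explained by the line
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope_ppm_s = unname(stats::coef(fit)[2L]),
       intercept_ppm = unname(stats::coef(fit)[1L]),
       r2 = r2, n = length(ppm))
}

#' Convert a concentration slope to a soil gas flux
#'
#' Applies the ideal gas law to the chamber headspace: the molar inventory
#' is `P V / (R T)`, so a mole-fraction accumulation rate of `slope` ppm/s
#' corresponds to a molar flux of `slope * 1e-6 * P V / (R T) / A`
#' (mol m^-2 s^-1), then expressed as element mass (CO2-C or N2O-N) per day.
#'
#' @param slope_ppm_s concentration slope (ppm s^-1); may be negative
#'   (uptake).
#' @param geom a [chamber_geometry()].
#' @param temp_k chamber air temperature (K).
#' @param pressure_pa air pressure (Pa).
#' @param gas `"CO2"` or `"N2O"`.
#' @return list with `molar_flux_mol_m2_s` and `mass_flux_g_m2_d`
#'   (g CO2-C or g N2O-N per m^2 per day).
#' @export
slope_to_mass_flux <- function(slope_ppm_s, geom, temp_k, pressure_pa, gas) {
  stopifnot(inherits(geom, "chamber_geometry"))
  gas <- match.arg(gas, names(ELEMENT_MASS))
  if (!is_finite_num(temp_k) || temp_k <= 0)
    stopf("temperature must be positive (K)")
  if (!is_finite_num(pressure_pa) || pressure_pa <= 0)
    stopf("pressure must be positive (Pa)")
  headspace_mol <- pressure_pa * geom$volume_m3 / (GAS_CONSTANT * temp_k)
  molar <- slope_ppm_s * 1e-6 * headspace_mol / geom$area_m2
  list(molar_flux_mol_m2_s = molar,
       mass_flux_g_m2_d = molar * ELEMENT_MASS[[gas]] * 86400)
}

#' Estimate fluxes for a table of chamber deployments
#'
#' Groups a long concentration table by deployment (plot, chamber, date,
#' gas), fits each ramp and converts it to an element-mass flux. Quality
#' control follows the retain-and-flag convention: a deployment with
#' r^2 < `r2_min` and |slope| above `slope_min` is flagged `low_r2` but kept
#' (near-zero fluxes legitimately regress poorly); nothing is discarded.
#'
#' @param chambers data frame with columns `plot_id`, `chamber_id`, `date`,
#'   `gas`, `elapsed_s`, `ppm`, `air_temp_c`, `pressure_kpa`.
#' @param geom a [chamber_geometry()].
#' @param r2_min r-squared below which a non-trivial slope is flagged.
#' @param slope_min |slope| (ppm/s) under which low r2 is not flagged.
#' @return data frame, one row per deployment: ids, `slope_ppm_s`, `r2`,
#'   `molar_flux_mol_m2_s`, `mass_flux_g_m2_d`, `qc_flag`.
#' @export
estimate_fluxes <- function(chambers, geom, r2_min = 0.7, slope_min = 0.002) {
  need_cols(chambers, c("plot_id", "chamber_id", "date", "gas", "elapsed_s",
                        "ppm", "air_temp_c", "pressure_kpa"), "chamber table")
  key <- interaction(chambers$plot_id, chambers$chamber_id,
                     chambers$date, chambers$gas, drop = TRUE)
  out <- lapply(split(chambers, key), function(d) {
    fit <- fit_concentration_slope(d$elapsed_s, d$ppm)
    fx <- slope_to_mass_flux(fit$slope_ppm_s, geom,
                             temp_k = mean(d$air_temp_c) + 273.15,
                             pressure_pa = mean(d$pressure_kpa) * 1000,
                             gas = as.character(d$gas[1L]))
    data.frame(plot_id = d$plot_id[1L], chamber_id = d$chamber_id[1L],
               date = as.Date(d$date[1L]), gas = as.character(d$gas[1L]),
               slope_ppm_s = fit$slope_ppm_s, r2 = fit$r2, n_points = fit$n,
               molar_flux_mol_m2_s = fx$molar_flux_mol_m2_s,
               mass_flux_g_m2_d = fx$mass_flux_g_m2_d,
               qc_flag = if (fit$r2 < r2_min &&
                             abs(fit$slope_ppm_s) > slope_min) "low_r2"
                         else "ok")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$plot_id, res$gas, res$date, res$chamber_id), ]
}

#' Interpolate chamber observations to a daily flux series
#'
#' Same-day replicate chambers within a plot are first averaged
#' (arithmetic mean), then daily values are linearly interpolated between
#' consecutive sampling dates. No extrapolation occurs before the first or
#' after the last observation; a single observation yields a one-day
#' series.
#'
#' @param fluxes data frame with `plot_id`, `gas`, `date`,
#'   `mass_flux_g_m2_d` (e.g. from [estimate_fluxes()]).
#' @return data frame `plot_id`, `gas`, `date`, `flux_g_m2_d`, `source`
#'   (`"observed"` on sampling days, `"interpolated"` between them).
#' @export
interpolate_daily_flux <- function(fluxes) {
  need_cols(fluxes, c("plot_id", "gas", "date", "mass_flux_g_m2_d"),
            "flux table")
  if (nrow(fluxes) == 0L) stopf("no flux observations to interpolate")
  key <- interaction(fluxes$plot_id, fluxes$gas, drop = TRUE)
  out <- lapply(split(fluxes, key), function(d) {
    d$date <- as.Date(d$date)
    daily_obs <- stats::aggregate(mass_flux_g_m2_d ~ date, data = d, FUN = mean)
    daily_obs <- daily_obs[order(daily_obs$date), ]
    days <- seq(min(daily_obs$date), max(daily_obs$date), by = "day")
    vals <- if (nrow(daily_obs) == 1L) daily_obs$mass_flux_g_m2_d else
      stats::approx(as.numeric(daily_obs$date), daily_obs$mass_flux_g_m2_d,
                    xout = as.numeric(days), method = "linear")$y
    data.frame(plot_id = d$plot_id[1L], gas = d$gas[1L], date = days,
               flux_g_m2_d = vals,
               source = ifelse(days %in% daily_obs$date,
                               "observed", "interpolated"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative seasonal emission
#'
#' Sums a daily element-mass flux series over the intersection of a window
#' with the observed span and converts to kg element per hectare
#' (1 g m^-2 = 10 kg ha^-1). The series is never extrapolated: if the
#' window extends beyond the observed span the cumulation is clipped and
#' the clipped span reported.
#'
#' @param daily data frame from [interpolate_daily_flux()] (or any table
#'   with `plot_id`, `gas`, `date`, `flux_g_m2_d`).
#' @param window a [season_window()].
#' @return data frame per plot and gas: `cum_g_m2`, `cum_kg_ha`,
#'   `span_start`, `span_end`, `n_days`, `clipped` (logical).
#' @export
cumulate_emissions <- function(daily, window) {
  stopifnot(inherits(window, "season_window"))
  need_cols(daily, c("plot_id", "gas", "date", "flux_g_m2_d"), "daily fluxes")
  key <- interaction(daily$plot_id, daily$gas, drop = TRUE)
  out <- lapply(split(daily, key), function(d) {
    d$date <- as.Date(d$date)
    keep <- d$date >= window$start & d$date <= window$end
    if (!any(keep))
      stopf("window %s does not intersect the observed span (%s..%s) for plot %s %s",
            window$label, min(d$date), max(d$date), d$plot_id[1L], d$gas[1L])
    dd <- d[keep, ]
    cum <- sum(dd$flux_g_m2_d)
    data.frame(plot_id = d$plot_id[1L], gas = d$gas[1L],
               window = window$label,
               cum_g_m2 = cum, cum_kg_ha = cum * 10,
               span_start = min(dd$date), span_end = max(dd$date),
               n_days = nrow(dd),
               clipped = min(dd$date) > window$start |
                         max(dd$date) < window$end)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
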