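# Soil-water-balance evapotranspiration from profile moisture sensors:
# trapezoidal profile integration -> field capacity -> nightly drainage ->
# day screening -> daily ET -> ET:PET gap-filling -> seasonal ET and WUE.

#' Depth-integrate a volumetric water content profile
#'
#' Converts point VWC readings at ordered sensor depths into total soil
#' moisture (TSM, mm) over the profile from the surface down to the deepest
#' sensor. The surface-to-first-sensor layer takes the shallowest sensor's
#' VWC (no shallower information exists); between sensors the trapezoidal
#' rule for nonuniform increments applies:
#' `sum((theta_i + theta_{i+1})/2 * (d_{i+1} - d_i))`.
#'
#' @param depth_cm sensor depths (cm), positive, unique; need not be sorted.
#' @param vwc volumetric water content (cm^3 cm^-3) at those depths, in
#'   \[0, 1\].
#' @return total soil moisture in mm.
#' @examples
#' profile_tsm(c(30, 60, 90), c(0.30, 0.35, 0.40))  # 300 mm
#' @export
profile_tsm <- function(depth_cm, vwc) {
  if (length(depth_cm) < 1L) stopf("need at least one sensor depth")
  if (length(depth_cm) != length(vwc)) stopf("depth and vwc lengths differ")
  if (anyDuplicated(depth_cm)) stopf("duplicate sensor depths")
  if (any(depth_cm <= 0)) stopf("sensor depths must be positive")
  if (any(!is.finite(vwc)) || any(vwc < 0 | vwc > 1))
    stopf("vwc outside [0, 1]")
  ord <- order(depth_cm)
  d <- depth_cm[ord]; th <- vwc[ord]
  cm <- d[1L] * th[1L]
  if (length(d) > 1L)
    cm <- cm + sum((th[-length(th)] + th[-1L]) / 2 * diff(d))
  cm * 10  # cm of water -> mm
}

#' Profile-integrate a sensor log into a TSM series
#'
#' Applies [profile_tsm()] at every plot and timestamp of a long VWC table.
#'
#' @param vwc data frame with columns `timestamp` (POSIXct or parseable),
#'   `plot_id`, `depth_cm`, `vwc`.
#' @return data frame `plot_id`, `timestamp`, `tsm_mm`, sorted by plot and
#'   time.
#' @export
tsm_series <- function(vwc) {
  need_cols(vwc, c("timestamp", "plot_id", "depth_cm", "vwc"), "vwc table")
  ts <- as.POSIXct(vwc$timestamp, tz = "UTC")
  key <- interaction(vwc$plot_id, as.numeric(ts), drop = TRUE)
  # split-free path: assume a complete depth grid per plot-timestamp
  ord <- order(vwc$plot_id, ts, vwc$depth_cm)
  v <- vwc[ord, ]; tso <- ts[ord]
  depths <- sort(unique(v$depth_cm))
  k <- length(depths)
  if (nrow(v) %% k != 0L ||
      !all(v$depth_cm == rep(depths, times = nrow(v) / k))) {
    # irregular grid: fall back to per-group computation
    out <- lapply(split(seq_len(nrow(vwc)), key), function(i) {
      data.frame(plot_id = vwc$plot_id[i[1L]], timestamp = ts[i[1L]],
                 tsm_mm = profile_tsm(vwc$depth_cm[i], vwc$vwc[i]))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res[order(res$plot_id, res$timestamp), ])
  }
  # trapezoid weights for the common grid (surface layer -> first sensor)
  w <- numeric(k)
  w[1L] <- depths[1L]
  if (k > 1L) {
    gaps <- diff(depths)
    w[-k] <- w[-k] + gaps / 2
    w[-1L] <- w[-1L] + gaps / 2
  }
  if (any(!is.finite(v$vwc)) || any(v$vwc < 0 | v$vwc > 1))
    stopf("vwc outside [0, 1]")
  m <- matrix(v$vwc, ncol = k, byrow = TRUE)
  data.frame(plot_id = v$plot_id[seq(1L, nrow(v), by = k)],
             timestamp = tso[seq(1L, nrow(v), by = k)],
             tsm_mm = as.numeric(m %*% w) * 10)
}

#' Estimate field capacity from pre-emergence soil moisture
#'
#' Field capacity (FC) is taken as the mean TSM over the 30 days preceding
#' crop emergence, on the premise that the profile fully recharges over
#' winter so pre-season storage sits at FC. Site-level by default (one FC
#' across plots); per-plot estimates are available where sensors differ
#' systematically.
#'
#' @param tsm TSM series from [tsm_series()].
#' @param emergence emergence date (`Date` or parseable).
#' @param window_days length of the averaging window ending at emergence.
#' @param by_plot if `TRUE`, estimate one FC per plot.
#' @return data frame `plot_id` (`"(site)"` for the pooled estimate),
#'   `fc_mm`, `n_readings`, `window_start`, `window_end`.
#' @export
estimate_field_capacity <- function(tsm, emergence, window_days = 30,
                                    by_plot = FALSE) {
  need_cols(tsm, c("plot_id", "timestamp", "tsm_mm"), "tsm series")
  emergence <- as.Date(emergence)
  t0 <- as.POSIXct(paste(emergence - window_days, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(emergence, "00:00:00"), tz = "UTC")
  ts <- as.POSIXct(tsm$timestamp, tz = "UTC")
  keep <- ts >= t0 & ts < t1
  if (!any(keep))
    stopf("no TSM readings in the %d days before emergence (%s)",
          window_days, emergence)
  sub <- tsm[keep, ]
  if (by_plot) {
    agg <- stats::aggregate(tsm_mm ~ plot_id, data = sub,
                            FUN = function(x) c(mean(x), length(x)))
    data.frame(plot_id = agg$plot_id, fc_mm = agg$tsm_mm[, 1L],
               n_readings = agg$tsm_mm[, 2L],
               window_start = emergence - window_days,
               window_end = emergence - 1)
  } else {
    data.frame(plot_id = "(site)", fc_mm = mean(sub$tsm_mm),
               n_readings = nrow(sub),
               window_start = emergence - window_days,
               window_end = emergence - 1)
  }
}

#' Nightly subsurface drainage rate
#'
#' Between 0000 h and 0400 h no evapotranspiration is expected, so any TSM
#' decline over that interval is attributed to gravitational drainage. The
#' hourly rate `(tsm_0000 - tsm_0400) / 4` is clamped at zero (an overnight
#' gain is not negative drainage) and scaled to a daily loss.
#'
#' @param tsm_0000,tsm_0400 TSM (mm) at midnight and 0400 h of the same
#'   day; vectorised. `NA` in either yields `NA` (day q-unavailable).
#' @return daily drainage `q` in mm day^-1.
#' @export
nightly_drainage <- function(tsm_0000, tsm_0400) {
  hourly <- pmax((tsm_0000 - tsm_0400) / 4, 0)
  24 * hourly
}

#' Screen days for water-balance validity
#'
#' A day enters the ET calculation only when its TSM decline can be read as
#' evapotranspiration. Day `j` is excluded when (first matching reason
#' recorded): the profile gained water overnight-to-overnight
#' (`TSM_{j+1} > TSM_j`, reason `net-gain`); precipitation fell on day `j`
#' or any of the preceding `precip_lag` days (reason `precip-window`); or
#' storage stands above field capacity (`TSM_j > fc`, reason `above-fc`).
#'
#' @param daily data frame with `date`, `tsm_j` (midnight TSM of day j,
#'   mm), `tsm_j1` (next midnight), `precip_mm`; one row per consecutive
#'   day.
#' @param fc field capacity (mm, scalar).
#' @param precip_lag days excluded after a precipitation event (default 3,
#'   i.e. event day plus the 3 following days).
#' @return the input with a `status` column:
#'   `included` / `net-gain` / `precip-window` / `above-fc`.
#' @export
screen_days <- function(daily, fc, precip_lag = 3) {
  need_cols(daily, c("date", "tsm_j", "tsm_j1", "precip_mm"), "daily table")
  d <- as.Date(daily$date)
  if (nrow(daily) > 1L && any(diff(d) != 1))
    stopf("daily table must cover consecutive days; gap after %s",
          d[which(diff(d) != 1)[1L]])
  n <- nrow(daily)
  rain <- daily$precip_mm > 0
  rain_window <- rain
  if (precip_lag > 0 && n > 1L) {
    for (l in seq_len(precip_lag)) {
      lagged <- c(rep(FALSE, l), rain[seq_len(n - l)])
      rain_window <- rain_window | lagged
    }
  }
  status <- rep("included", n)
  status[!is.na(daily$tsm_j) & daily$tsm_j > fc] <- "above-fc"
  status[rain_window] <- "precip-window"
  gain <- !is.na(daily$tsm_j1) & !is.na(daily$tsm_j) &
    daily$tsm_j1 > daily$tsm_j
  status[gain] <- "net-gain"
  daily$status <- status
  daily
}

#' Daily evapotranspiration from the midnight water balance
#'
#' For an included day, ET is the midnight-to-midnight storage depletion
#' adjusted for drainage. The physical balance subtracts the drainage loss
#' from the depletion (`et = (tsm_j - tsm_j1) - q`): water that left by
#' gravity did not evapotranspire. The `eq1_literal` convention instead
#' adds it (`et = tsm_j - tsm_j1 + q`); on retained days storage sits at or
#' below field capacity so q is near zero and the two conventions nearly
#' coincide. Negative results are not reported as negative ET; the day is
#' marked excluded (`negative-et`).
#'
#' @param tsm_j,tsm_j1 midnight TSM of day j and day j+1 (mm); vectorised.
#' @param q daily drainage (mm day^-1) from [nightly_drainage()]; `NA`
#'   marks the day q-unavailable.
#' @param convention `"physical"` (default) or `"eq1_literal"`.
#' @return numeric vector of ET (mm day^-1); `NA` where q is unavailable or
#'   the balance goes negative.
#' @export
daily_et <- function(tsm_j, tsm_j1, q,
                     convention = c("physical", "eq1_literal")) {
  convention <- match.arg(convention)
  et <- if (convention == "physical") (tsm_j - tsm_j1) - q
        else (tsm_j - tsm_j1) + q
  et[!is.na(et) & et < 0] <- NA_real_
  et
}

#' Gap-fill an ET series with ET:PET ratios
#'
#' Excluded days are approximated by scaling that day's reference
#' evapotranspiration with the latest measured ET:PET ratios: the mean of
#' the `ratio_window` most recent prior measured days' ratios (fewer if
#' fewer exist yet). `ratio_window = 1` uses the single most recent ratio;
#' the default of 3 makes the carried ratio robust to a single corrupted
#' reading, whose error would otherwise propagate across an entire
#' excluded run. Days before the first valid ratio are back-filled with
#' the earliest carried value. The ratio applied and the fill source are
#' recorded per day.
#'
#' @param et data frame with `date`, `et_mm` (`NA` on excluded days) and
#'   optionally `status`.
#' @param pet data frame with `date`, `et0_mm` (e.g. from
#'   [compute_et0()]).
#' @param ratio_window number of most recent measured days whose ratios
#'   are averaged for the carry value.
#' @return the input with columns `et_mm` (complete), `source`
#'   (`"measured"` / `"gap-filled"`), `ratio_used` (`NA` on measured days).
#' @export
gap_fill_et <- function(et, pet, ratio_window = 1) {
  if (ratio_window < 1) stopf("ratio_window must be >= 1")
  need_cols(et, c("date", "et_mm"), "et series")
  need_cols(pet, c("date", "et0_mm"), "pet series")
  et$date <- as.Date(et$date)
  idx <- match(et$date, as.Date(pet$date))
  if (anyNA(idx))
    stopf("PET series does not cover %s",
          paste(et$date[is.na(idx)][1L], "(and possibly later days)"))
  pet_day <- pet$et0_mm[idx]
  measured <- !is.na(et$et_mm) & pet_day > 0
  if (!any(measured))
    stopf("no measured ET day with positive PET; cannot form an ET:PET ratio")
  ratio <- rep(NA_real_, nrow(et))
  ratio[measured] <- et$et_mm[measured] / pet_day[measured]
  # carry the mean of the last `ratio_window` ratios forward; back-fill
  # the leading run with the earliest carry value
  filled_ratio <- rep(NA_real_, nrow(et))
  recent <- numeric(0)
  for (i in seq_along(filled_ratio)) {
    if (!is.na(ratio[i])) {
      recent <- c(recent, ratio[i])
      if (length(recent) > ratio_window)
        recent <- recent[(length(recent) - ratio_window + 1L):length(recent)]
    }
    filled_ratio[i] <- if (length(recent) > 0L) mean(recent) else NA_real_
  }
  first_valid <- filled_ratio[which(!is.na(filled_ratio))[1L]]
  filled_ratio[is.na(filled_ratio)] <- first_valid
  fill <- is.na(et$et_mm)
  et$source <- ifelse(fill, "gap-filled", "measured")
  et$ratio_used <- ifelse(fill, filled_ratio, NA_real_)
  et$et_mm[fill] <- filled_ratio[fill] * pet_day[fill]
  et
}

#' Water-balance ET for a season
#'
#' End-to-end daily ET per plot: profile integration, (optional) field
#' capacity estimation, midnight/0400 extraction, nightly drainage, day
#' screening, the midnight water balance and ET:PET gap-filling.
#'
#' @param vwc long VWC sensor log (`timestamp`, `plot_id`, `depth_cm`,
#'   `vwc`).
#' @param weather daily weather with `date` and `precip_mm`.
#' @param pet daily reference ET with `date`, `et0_mm`.
#' @param emergence crop emergence date; drives FC estimation.
#' @param window a [season_window()] over which daily ET is produced.
#' @param fc optional field capacity (mm) overriding estimation.
#' @param fc_by_plot estimate FC per plot instead of site-level.
#' @param convention drainage sign convention, see [daily_et()].
#' @param midnight_tol_min tolerance (minutes) when matching sensor records
#'   to the nominal 0000/0400 readings.
#' @param precip_lag see [screen_days()].
#' @param ratio_window see [gap_fill_et()].
#' @return list with `daily` (per plot-day: `et_mm`, `source`, `reason`,
#'   `ratio_used`, plus the water-day audit columns), `fc` (the FC table
#'   used), and `water_days` (the screened per-day water balance table).
#' @export
water_balance_et <- function(vwc, weather, pet, emergence, window,
                             fc = NULL, fc_by_plot = FALSE,
                             convention = c("physical", "eq1_literal"),
                             midnight_tol_min = 15, precip_lag = 3,
                             ratio_window = 1) {
  convention <- match.arg(convention)
  stopifnot(inherits(window, "season_window"))
  need_cols(weather, c("date", "precip_mm"), "weather")
  tsm <- tsm_series(vwc)
  fc_tab <- if (!is.null(fc)) {
    data.frame(plot_id = "(site)", fc_mm = fc, n_readings = NA_integer_,
               window_start = as.Date(NA), window_end = as.Date(NA))
  } else {
    estimate_field_capacity(tsm, emergence, by_plot = fc_by_plot)
  }
  fc_for <- function(plot) {
    if (nrow(fc_tab) == 1L && fc_tab$plot_id[1L] == "(site)")
      return(fc_tab$fc_mm[1L])
    v <- fc_tab$fc_mm[fc_tab$plot_id == plot]
    if (length(v) != 1L) stopf("no field capacity estimate for plot %s", plot)
    v
  }
  days <- seq(window$start, window$end, by = "day")
  wx_idx <- match(days, as.Date(weather$date))
  if (anyNA(wx_idx))
    stopf("weather does not cover the window; first missing day %s",
          days[is.na(wx_idx)][1L])
  precip <- weather$precip_mm[wx_idx]
  tol <- midnight_tol_min * 60

  per_plot <- lapply(split(tsm, tsm$plot_id), function(pt) {
    ts_num <- as.numeric(pt$timestamp)
    # nearest reading within tolerance of a nominal clock time
    at <- function(dates, hour) {
      nominal <- as.numeric(as.POSIXct(paste(dates, sprintf("%02d:00:00", hour)),
                                       tz = "UTC"))
      vapply(nominal, function(tn) {
        i <- which.min(abs(ts_num - tn))
        if (length(i) == 0L || abs(ts_num[i] - tn) > tol) NA_real_
        else pt$tsm_mm[i]
      }, numeric(1))
    }
    tsm0000 <- at(days, 0L)
    tsm0400 <- at(days, 4L)
    tsm_next <- at(days + 1, 0L)
    wd <- data.frame(plot_id = pt$plot_id[1L], date = days,
                     tsm_j = tsm0000, tsm_0400 = tsm0400, tsm_j1 = tsm_next,
                     precip_mm = precip)
    wd$q_mm <- nightly_drainage(wd$tsm_j, wd$tsm_0400)
    wd <- screen_days(wd, fc = fc_for(pt$plot_id[1L]), precip_lag = precip_lag)
    wd$reason <- wd$status
    usable <- wd$status == "included" & !is.na(wd$q_mm) &
      !is.na(wd$tsm_j) & !is.na(wd$tsm_j1)
    wd$reason[wd$status == "included" & !usable] <- "q-unavailable"
    et <- rep(NA_real_, nrow(wd))
    et[usable] <- daily_et(wd$tsm_j[usable], wd$tsm_j1[usable],
                           wd$q_mm[usable], convention = convention)
    wd$reason[usable & is.na(et)] <- "negative-et"
    wd$reason[usable & !is.na(et)] <- "included"
    filled <- gap_fill_et(data.frame(date = wd$date, et_mm = et), pet,
                          ratio_window = ratio_window)
    wd$et_mm <- filled$et_mm
    wd$source <- filled$source
    wd$ratio_used <- filled$ratio_used
    wd
  })
  daily <- do.call(rbind, per_plot)
  rownames(daily) <- NULL
  list(daily = daily[, c("plot_id", "date", "et_mm", "source", "reason",
                         "ratio_used", "tsm_j", "tsm_0400", "tsm_j1",
                         "q_mm", "precip_mm")],
       fc = fc_tab,
       water_days = daily)
}

#' Seasonal water use and water-use efficiency
#'
#' Sums a complete daily ET series over a window and divides aboveground
#' biomass by the cumulative ET to give water-use efficiency
#' (kg ha^-1 mm^-1).
#'
#' @param et complete daily ET for one plot (`date`, `et_mm`, optionally
#'   `source`).
#' @param agb aboveground dry biomass (kg ha^-1), `>= 0`.
#' @param window a [season_window()].
#' @return one-row data frame: `et_mm` (cumulative), `agb_kg_ha`,
#'   `wue_kg_ha_mm` (`NA` with `wue_note` when cumulative ET is zero and
#'   AGB positive), `n_measured`, `n_gap_filled`.
#' @export
season_water_summary <- function(et, agb, window) {
  stopifnot(inherits(window, "season_window"))
  need_cols(et, c("date", "et_mm"), "et series")
  if (!is_finite_num(agb) || agb < 0) stopf("agb must be >= 0")
  d <- as.Date(et$date)
  keep <- d >= window$start & d <= window$end
  if (!any(keep)) stopf("et series does not cover window %s", window$label)
  sub <- et[keep, ]
  if (anyNA(sub$et_mm))
    stopf("et series has unfilled gaps inside the window")
  cum <- sum(sub$et_mm)
  src <- if ("source" %in% names(sub)) sub$source else rep("measured", nrow(sub))
  wue <- if (agb == 0) 0
         else if (cum > 0) agb / cum
         else NA_real_
  data.frame(window = window$label, et_mm = cum, agb_kg_ha = agb,
             wue_kg_ha_mm = wue,
             wue_note = if (is.na(wue)) "undefined: cumulative ET is zero"
                        else "",
             n_measured = sum(src == "measured"),
             n_gap_filled = sum(src == "gap-filled"))
}
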