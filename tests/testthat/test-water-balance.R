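# water-balance ET: profile integration, field capacity, drainage,
# screening, daily ET, gap-filling, seasonal summaries

test_that("trapezoidal profile integration matches direct arithmetic", {
  # uniform profile: theta * profile depth
  expect_equal(profile_tsm(c(30, 60, 90), rep(0.38, 3)), 0.38 * 900,
               tolerance = 1e-12)
  # hand-worked nonuniform case: 90 + 97.5 + 112.5 mm
  expect_equal(profile_tsm(c(30, 60, 90), c(0.30, 0.35, 0.40)), 300,
               tolerance = 1e-12)
  expect_equal(profile_tsm(c(30, 60, 90), rep(0, 3)), 0)
  # order of the inputs must not matter
  expect_equal(profile_tsm(c(90, 30, 60), c(0.40, 0.30, 0.35)), 300,
               tolerance = 1e-12)
  expect_error(profile_tsm(c(30, 30, 90), c(0.3, 0.3, 0.3)), "duplicate")
  expect_error(profile_tsm(c(30, 60, 90), c(0.3, 1.2, 0.3)), "\\[0, 1\\]")
})

test_that("profile TSM stays within the bounds set by the extreme thetas", {
  withr::with_seed(5, {
    for (i in 1:100) {
      th <- runif(3, 0, 0.55)
      tsm <- profile_tsm(c(30, 60, 90), th)
      expect_gte(tsm, min(th) * 900 - 1e-9)
      expect_lte(tsm, max(th) * 900 + 1e-9)
    }
  })
})

test_that("tsm_series reproduces profile_tsm row by row", {
  vwc <- data.frame(
    timestamp = rep(as.POSIXct("2021-05-01 00:00:00", tz = "UTC"), 3),
    plot_id = "P1", depth_cm = c(30, 60, 90), vwc = c(0.30, 0.35, 0.40))
  expect_equal(tsm_series(vwc)$tsm_mm, 300, tolerance = 1e-12)
  # the fast matrix path and the generic path agree on a two-stamp table
  vwc2 <- rbind(vwc, within(vwc, timestamp <- timestamp + 3600))
  ts2 <- tsm_series(vwc2)
  expect_equal(ts2$tsm_mm, c(300, 300), tolerance = 1e-12)
})

test_that("field capacity is the pre-emergence window mean", {
  days <- seq(as.Date("2021-03-20"), as.Date("2021-04-30"), by = "day")
  tsm <- data.frame(
    plot_id = "P1",
    timestamp = as.POSIXct(paste(days, "12:00:00"), tz = "UTC"),
    tsm_mm = 339)
  fc <- estimate_field_capacity(tsm, emergence = "2021-04-25")
  expect_equal(fc$fc_mm, 339)
  # linearly declining storage: mean equals the explicit summation
  window_days <- seq(as.Date("2021-03-26"), as.Date("2021-04-24"), by = "day")
  vals <- seq(350, 330, length.out = length(window_days))
  tsm2 <- data.frame(
    plot_id = "P1",
    timestamp = as.POSIXct(paste(window_days, "12:00:00"), tz = "UTC"),
    tsm_mm = vals)
  fc2 <- estimate_field_capacity(tsm2, emergence = "2021-04-25")
  expect_equal(fc2$fc_mm, sum(vals) / length(vals), tolerance = 1e-12)
  # a single reading is its own mean; an empty window is rejected
  fc3 <- estimate_field_capacity(tsm2[1, ], emergence = "2021-04-25")
  expect_equal(fc3$fc_mm, 350)
  expect_error(estimate_field_capacity(tsm2, emergence = "2022-04-25"),
               "no TSM readings")
})

test_that("nightly drainage scales the clamped overnight decline", {
  expect_equal(nightly_drainage(340, 340), 0)
  expect_equal(nightly_drainage(340, 338), 12)  # 0.5 mm/h * 24
  expect_equal(nightly_drainage(338, 340), 0)   # overnight gain clamps
  expect_true(is.na(nightly_drainage(NA, 338)))
})

test_that("screening replays the three exclusion rules day by day", {
  # rain on day 5 of a flat dry sequence: days 5-8 are precip-window
  flat <- data.frame(date = as.Date("2021-06-01") + 0:9,
                     tsm_j = seq(330, 321, by = -1),
                     tsm_j1 = seq(329, 320, by = -1),
                     precip_mm = c(0, 0, 0, 0, 6, 0, 0, 0, 0, 0))
  st <- screen_days(flat, fc = 340)$status
  expect_equal(which(st == "precip-window"), 5:8)
  expect_equal(st[c(1:4, 9:10)], rep("included", 6))
  # storage a millimetre above FC is excluded as above-fc
  one <- data.frame(date = as.Date("2021-06-01"), tsm_j = 341,
                    tsm_j1 = 340, precip_mm = 0)
  expect_equal(screen_days(one, fc = 340)$status, "above-fc")
  # ten-day mixed sequence against a manual replay of the rules
  mixed <- data.frame(
    date = as.Date("2021-06-01") + 0:9,
    tsm_j  = c(345, 341, 339, 337, 336, 335, 336, 333, 331, 330),
    tsm_j1 = c(341, 339, 337, 336, 335, 336, 333, 331, 330, 329),
    precip_mm = c(0, 0, 0, 0, 6, 0, 0, 0, 0, 0))
  expect_equal(screen_days(mixed, fc = 340)$status,
               c("above-fc", "above-fc", "included", "included",
                 "precip-window", "net-gain", "precip-window",
                 "precip-window", "included", "included"))
  gappy <- mixed[c(1, 3:10), ]
  expect_error(screen_days(gappy, fc = 340), "consecutive")
})

test_that("daily ET follows the documented drainage conventions", {
  expect_equal(daily_et(330, 325, 0), 5)
  expect_equal(daily_et(330, 330, 0), 0)
  expect_equal(daily_et(330, 325, 1.2), 3.8)  # physical: depletion - q
  expect_equal(daily_et(330, 325, 1.2, convention = "eq1_literal"), 6.2)
  expect_true(is.na(daily_et(330, 331, 0)))   # negative -> excluded
  expect_true(is.na(daily_et(330, 325, NA)))
})

test_that("gap-filling carries the latest ratio and back-fills the lead", {
  days <- as.Date("2021-06-01") + 0:6
  pet <- data.frame(date = days, et0_mm = c(4, 4, 4, 4, 4, 4, 4))
  et <- data.frame(date = days,
                   et_mm = c(NA, NA, NA, 2.4, NA, 2.0, NA))
  filled <- gap_fill_et(et, pet)
  # first valid ratio 0.6 back-fills the three leading days
  expect_equal(filled$et_mm[1:3], rep(0.6 * 4, 3), tolerance = 1e-12)
  expect_equal(filled$et_mm[5], 0.6 * 4, tolerance = 1e-12)
  # after the second measured day the carried ratio is 0.5
  expect_equal(filled$et_mm[7], 0.5 * 4, tolerance = 1e-12)
  expect_equal(filled$source,
               c(rep("gap-filled", 3), "measured", "gap-filled",
                 "measured", "gap-filled"))
  # an all-measured series is returned unchanged
  full <- data.frame(date = days, et_mm = rep(2, 7))
  expect_equal(gap_fill_et(full, pet)$et_mm, full$et_mm)
  # no measured day with positive PET -> rejection
  none <- data.frame(date = days, et_mm = NA_real_)
  expect_error(gap_fill_et(none, pet), "ratio")
})

test_that("gap-filled values scale linearly with PET", {
  days <- as.Date("2021-06-01") + 0:2
  et <- data.frame(date = days, et_mm = c(2, NA, NA))
  pet1 <- data.frame(date = days, et0_mm = c(4, 3, 5))
  pet2 <- pet1; pet2$et0_mm[2:3] <- pet1$et0_mm[2:3] * 2
  f1 <- gap_fill_et(et, pet1); f2 <- gap_fill_et(et, pet2)
  expect_equal(f2$et_mm[2:3], 2 * f1$et_mm[2:3], tolerance = 1e-12)
})

test_that("seasonal summary divides biomass by cumulative ET", {
  days <- seq(as.Date("2021-04-01"), by = "day", length.out = 100)
  et <- data.frame(date = days, et_mm = 2, source = "measured")
  win <- season_window(days[1], days[100])
  sw <- season_water_summary(et, agb = 10000, win)
  expect_equal(sw$et_mm, 200)
  expect_equal(sw$wue_kg_ha_mm, 50)
  expect_equal(season_water_summary(et, 0, win)$wue_kg_ha_mm, 0)
  zero <- et; zero$et_mm <- 0
  sw0 <- season_water_summary(zero, 100, win)
  expect_true(is.na(sw0$wue_kg_ha_mm))
  expect_match(sw0$wue_note, "undefined")
})

test_that("mean of per-plot WUE differs from the ratio of means", {
  # three plots with different AGB and ET: the two reporting conventions
  # disagree, which is why both are emitted by the pipeline summaries
  agb <- c(8000, 12000, 10000)
  et <- c(150, 320, 240)
  mean_of_ratios <- mean(agb / et)
  ratio_of_means <- mean(agb) / mean(et)
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))
})

test_that("the end-to-end water balance recovers truth exactly without noise", {
  tr <- truth_params(seed = 7, years = 2021, precip_event_prob = 0,
                     sensor_offset_sd = 0, sensor_jitter_sd = 0,
                     sensor_resolution = 0, et_day_factor_sd = 0,
                     plots = data.frame(plot_id = c("C1", "S1"),
                                        crop = c("corn", "switchgrass"),
                                        block = 1:2))
  wx <- gen_weather(tr)
  soil <- gen_soil_moisture(tr, wx)
  site <- site_meta(tr$latitude, tr$elevation, wind_height = tr$wind_height_m)
  pet <- compute_et0(wx, site)
  win <- truth_window(tr, 2021)
  wb <- water_balance_et(soil$vwc, wx, pet, emergence = "2021-04-25",
                         window = win)
  d <- merge(wb$daily, soil$truth_daily[, c("plot_id", "date", "true_et_mm")],
             by = c("plot_id", "date"))
  measured <- d[d$reason == "included", ]
  expect_gt(nrow(measured), 100)
  expect_equal(measured$et_mm, measured$true_et_mm, tolerance = 1e-9)
  # every season day is classified exactly once as measured or gap-filled
  expect_true(all(d$source %in% c("measured", "gap-filled")))
  expect_equal(nrow(d), 2 * 183)
  plot_tot <- tapply(d$et_mm, d$plot_id, sum)
  by_class <- tapply(d$et_mm, list(d$plot_id, d$source), sum)
  expect_equal(as.numeric(plot_tot),
               as.numeric(rowSums(by_class, na.rm = TRUE)),
               tolerance = 1e-9)
})

test_that("all daily ET is nonnegative under the default noisy scenario", {
  tr <- truth_params(seed = 13, years = 2021,
                     plots = data.frame(plot_id = c("C1", "S1"),
                                        crop = c("corn", "switchgrass"),
                                        block = 1:2))
  wx <- gen_weather(tr)
  soil <- gen_soil_moisture(tr, wx)
  site <- site_meta(tr$latitude, tr$elevation, wind_height = tr$wind_height_m)
  pet <- compute_et0(wx, site)
  wb <- water_balance_et(soil$vwc, wx, pet, emergence = "2021-04-25",
                         window = truth_window(tr, 2021))
  expect_true(all(wb$daily$et_mm >= 0))
  expect_true(all(wb$daily$source %in% c("measured", "gap-filled")))
})
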