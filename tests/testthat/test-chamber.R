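# static-chamber flux estimation: slope fitting, ideal-gas conversion,
# daily interpolation, cumulation

test_that("slope fitting recovers exact lines and flat series", {
  t <- seq(0, 300, by = 20)
  fit <- fit_concentration_slope(t, 400 + 0.1 * t)
  expect_equal(fit$slope_ppm_s, 0.1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  flat <- fit_concentration_slope(t, rep(400, length(t)))
  expect_equal(flat$slope_ppm_s, 0, tolerance = 1e-12)
})

test_that("slope under noise equals the closed-form least-squares ratio", {
  t <- seq(0, 300, by = 20)
  y <- withr::with_seed(11, 400 + 0.1 * t + rnorm(length(t), 0, 1))
  fit <- fit_concentration_slope(t, y)
  # independent oracle: slope = cov(t, y) / var(t)
  oracle <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(fit$slope_ppm_s, oracle, tolerance = 1e-12)
})

test_that("degenerate concentration series are rejected", {
  expect_error(fit_concentration_slope(c(0, 20), c(400, 401)), "3")
  expect_error(fit_concentration_slope(c(0, 20, 20), c(400, 401, 402)),
               "increasing")
  expect_error(fit_concentration_slope(c(0, 20, 40), c(400, -1, 402)),
               "positive")
})

test_that("ideal-gas conversion matches the hand-calculated chain", {
  # oracle: headspace inventory n = P V / (R T)
  #       = 101325 * 0.005 / (8.314462618 * 298.15) = 0.2043702226 mol;
  # molar flux = 0.1e-6 * n / (pi * 0.1015^2) = 6.314451920896e-7;
  # CO2-C = molar * 12.011 * 86400 = 0.6552825007 g C m-2 d-1
  geom <- chamber_geometry(diameter_m = 0.203, volume_m3 = 0.005)
  expect_equal(geom$area_m2, pi * (0.203 / 2)^2, tolerance = 1e-12)
  fx <- slope_to_mass_flux(0.1, geom, temp_k = 298.15,
                           pressure_pa = 101325, gas = "CO2")
  expect_equal(fx$molar_flux_mol_m2_s, 6.314451920896e-7, tolerance = 1e-10)
  expect_equal(fx$mass_flux_g_m2_d, 0.6552825007, tolerance = 1e-8)
  # N2O carries two N per molecule
  fn <- slope_to_mass_flux(0.1, geom, 298.15, 101325, "N2O")
  expect_equal(fn$mass_flux_g_m2_d, 1.5283560048, tolerance = 1e-8)
})

test_that("flux is linear in slope and zero at zero", {
  geom <- chamber_geometry()
  f0 <- slope_to_mass_flux(0, geom, 298, 101325, "CO2")
  expect_equal(f0$mass_flux_g_m2_d, 0)
  f1 <- slope_to_mass_flux(0.05, geom, 298, 101325, "CO2")
  f2 <- slope_to_mass_flux(0.10, geom, 298, 101325, "CO2")
  expect_equal(f2$mass_flux_g_m2_d, 2 * f1$mass_flux_g_m2_d,
               tolerance = 1e-12)
  expect_error(slope_to_mass_flux(0.1, geom, -1, 101325, "CO2"),
               "temperature")
})

test_that("daily interpolation is linear between observations", {
  obs <- data.frame(plot_id = "P1", gas = "CO2",
                    date = as.Date("2021-06-01") + c(0, 4),
                    mass_flux_g_m2_d = c(1, 3))
  d <- interpolate_daily_flux(obs)
  expect_equal(d$flux_g_m2_d, c(1, 1.5, 2, 2.5, 3), tolerance = 1e-12)
  expect_equal(d$source, c("observed", rep("interpolated", 3), "observed"))
  # constant endpoints stay constant
  obs$mass_flux_g_m2_d <- c(2, 2)
  expect_equal(interpolate_daily_flux(obs)$flux_g_m2_d, rep(2, 5))
  # single observation gives a one-day series
  one <- interpolate_daily_flux(obs[1, ])
  expect_equal(nrow(one), 1L)
  expect_equal(one$flux_g_m2_d, 2)
  expect_error(interpolate_daily_flux(obs[0, ]), "no flux")
})

test_that("same-day replicate chambers are averaged before interpolation", {
  obs <- data.frame(plot_id = "P1", gas = "CO2",
                    date = as.Date("2021-06-01") + c(0, 0, 2),
                    mass_flux_g_m2_d = c(1, 3, 4))
  d <- interpolate_daily_flux(obs)
  expect_equal(d$flux_g_m2_d, c(2, 3, 4), tolerance = 1e-12)
})

test_that("cumulative emissions sum daily fluxes and convert units", {
  win <- season_window("2021-06-01", "2021-06-10")
  daily <- data.frame(plot_id = "P1", gas = "CO2",
                      date = seq(as.Date("2021-06-01"), by = "day",
                                 length.out = 10),
                      flux_g_m2_d = 1)
  cum <- cumulate_emissions(daily, win)
  expect_equal(cum$cum_g_m2, 10)
  expect_equal(cum$cum_kg_ha, 100)  # 1 g m-2 = 10 kg ha-1
  daily$flux_g_m2_d <- c(1, 1.5, 2, 2.5, 3, rep(0, 5))
  expect_equal(cumulate_emissions(daily, win)$cum_g_m2, 10)
  daily$flux_g_m2_d <- 0
  expect_equal(cumulate_emissions(daily, win)$cum_g_m2, 0)
  expect_error(cumulate_emissions(daily,
                                  season_window("2022-06-01", "2022-06-10")),
               "does not intersect")
})

test_that("cumulation is additive over disjoint windows and monotone", {
  daily <- data.frame(plot_id = "P1", gas = "CO2",
                      date = seq(as.Date("2021-06-01"), by = "day",
                                 length.out = 20),
                      flux_g_m2_d = withr::with_seed(3, runif(20, 0, 5)))
  whole <- cumulate_emissions(daily, season_window("2021-06-01", "2021-06-20"))
  a <- cumulate_emissions(daily, season_window("2021-06-01", "2021-06-07"))
  b <- cumulate_emissions(daily, season_window("2021-06-08", "2021-06-20"))
  expect_equal(whole$cum_g_m2, a$cum_g_m2 + b$cum_g_m2, tolerance = 1e-12)
  shorter <- cumulate_emissions(daily,
                                season_window("2021-06-01", "2021-06-15"))
  expect_lte(shorter$cum_g_m2, whole$cum_g_m2)
  # clipping beyond the observed span is reported
  wide <- cumulate_emissions(daily, season_window("2021-05-01", "2021-07-15"))
  expect_true(wide$clipped)
  expect_equal(wide$cum_g_m2, whole$cum_g_m2, tolerance = 1e-12)
})

test_that("zero-noise synthetic chambers return the generating flux", {
  geom <- chamber_geometry()
  tr <- truth_params(seed = 3, years = 2021,
                     plots = data.frame(plot_id = "P1", crop = "corn",
                                        block = 1),
                     chambers_per_plot = 2, flux_plot_sd = 0,
                     chamber_noise_ppm = c(CO2 = 0, N2O = 0))
  wx <- gen_weather(tr)
  ch <- gen_chamber_series(tr, geom, wx)
  est <- estimate_fluxes(ch$chambers, geom)
  m <- merge(ch$truth_flux, est, by = c("plot_id", "date", "gas"))
  expect_gt(nrow(m), 20)
  expect_equal(m$mass_flux_g_m2_d, m$true_flux_g_m2_d, tolerance = 1e-9)
})

test_that("a noisy 200-chamber ensemble is unbiased within 2 SE", {
  geom <- chamber_geometry()
  tr <- truth_params(seed = 9, years = 2021,
                     plots = data.frame(plot_id = "P1", crop = "corn",
                                        block = 1),
                     chambers_per_plot = 200, flux_plot_sd = 0,
                     sampling_interval_d = 400)  # a single sampling date
  wx <- gen_weather(tr)
  ch <- gen_chamber_series(tr, geom, wx)
  co2 <- ch$chambers[ch$chambers$gas == "CO2", ]
  est <- estimate_fluxes(co2, geom)
  expect_equal(nrow(est), 200L)
  truth <- ch$truth_flux$true_flux_g_m2_d[ch$truth_flux$gas == "CO2"]
  se <- sd(est$mass_flux_g_m2_d) / sqrt(nrow(est))
  expect_lt(abs(mean(est$mass_flux_g_m2_d) - truth), 2 * se)
})

test_that("low-r2 deployments with non-trivial slopes are flagged, not dropped", {
  t <- seq(0, 300, by = 20)
  # deterministic disturbance nearly orthogonal to time: r2 collapses but
  # the fitted slope stays well above the small-magnitude threshold
  wobble <- rep(c(1, -1), 8)
  ch <- data.frame(plot_id = "P1", chamber_id = "c1", date = "2021-06-01",
                   gas = "CO2", elapsed_s = t, ppm = 400 + 0.01 * t +
                     3 * wobble,
                   air_temp_c = 25, pressure_kpa = 101.3)
  est <- estimate_fluxes(ch, chamber_geometry())
  expect_equal(nrow(est), 1L)
  expect_lt(est$r2, 0.7)
  expect_gt(abs(est$slope_ppm_s), 0.002)
  expect_equal(est$qc_flag, "low_r2")
  # a near-zero slope with low r2 is legitimate and unflagged
  ch$ppm <- 400 + 0.5 * wobble
  est2 <- estimate_fluxes(ch, chamber_geometry())
  expect_lt(abs(est2$slope_ppm_s), 0.002)
  expect_equal(est2$qc_flag, "ok")
})
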