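#!/usr/bin/env Rscript
# Stage 3 — static-chamber fluxes.
# Fits every chamber deployment's concentration ramp, converts slopes to
# CO2-C and N2O-N mass fluxes via the ideal gas law, interpolates daily
# series per plot and cumulates growing-season emissions.

library(agrobalance)

ch <- read_chamber_csv("results/inputs/chamber.csv")
geom <- chamber_geometry()  # 20.3 cm anchors, 0.005 m3 dome headspace
fluxes <- estimate_fluxes(ch, geom)
write.csv(fluxes, "results/fluxes.csv", row.names = FALSE)
cat(sprintf("fitted %d deployments; %d flagged low_r2 (retained)\n",
            nrow(fluxes), sum(fluxes$qc_flag == "low_r2")))

years <- sort(unique(as.integer(format(fluxes$date, "%Y"))))
daily_all <- NULL; cum_all <- NULL
for (yr in years) {
  fy <- fluxes[format(fluxes$date, "%Y") == as.character(yr), ]
  daily <- interpolate_daily_flux(fy)
  win <- season_window(sprintf("%d-04-01", yr), sprintf("%d-09-30", yr),
                       label = sprintf("growing season %d", yr))
  cum <- cumulate_emissions(daily, win)
  cum$year <- yr; daily$year <- yr
  daily_all <- rbind(daily_all, daily); cum_all <- rbind(cum_all, cum)
}
write.csv(daily_all, "results/daily_flux.csv", row.names = FALSE)
write.csv(cum_all, "results/cumulative_emissions.csv", row.names = FALSE)

co2 <- cum_all[cum_all$gas == "CO2", ]
co2$crop <- ifelse(grepl("^C", co2$plot_id), "corn", "switchgrass")
by_crop <- aggregate(cum_kg_ha ~ crop + year, data = co2, FUN = mean)
cat("cumulative CO2-C (kg C/ha, crop means):\n")
print(by_crop, row.names = FALSE)
cat("switchgrass runs hotter on soil CO2 (larger belowground biomass in\n")
cat("the generating schedule), mirroring the perennial-system pattern.\n")
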