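# Readers for the pipeline's CSV interfaces and accessors for the packaged
# study tables.

read_checked <- function(path, cols, what) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, cols, sprintf("%s (%s)", what, path))
  df
}

#' Read pipeline input files
#'
#' Thin CSV readers that validate the documented column layout and fail
#' naming the file and the missing columns.
#'
#' @param path file path.
#' @return data frame with the validated columns.
#' @name readers
NULL

#' @rdname readers
#' @export
read_weather_csv <- function(path) {
  validate_weather(read_checked(
    path, c("date", "tmax_c", "tmin_c", "rhmax_pct", "rhmin_pct",
            "wind_ms", "sunshine_h", "precip_mm"), "weather"))
}

#' @rdname readers
#' @export
read_vwc_csv <- function(path) {
  read_checked(path, c("timestamp", "plot_id", "depth_cm", "vwc"), "vwc log")
}

#' @rdname readers
#' @export
read_chamber_csv <- function(path) {
  read_checked(path, c("plot_id", "chamber_id", "date", "gas", "elapsed_s",
                       "ppm", "air_temp_c", "pressure_kpa"), "chamber table")
}

#' @rdname readers
#' @export
read_leachate_csv <- function(path) {
  read_checked(path, c("date", "plot_id", "crop", "depth_cm", "no3n_mg_l"),
               "leachate table")
}

#' @rdname readers
#' @export
read_biomass_csv <- function(path) {
  read_checked(path, c("plot_id", "crop", "year", "component", "fresh_kg",
                       "moisture_pct", "area_m2"), "biomass table")
}

#' Packaged study tables (Urbana, IL field trial)
#'
#' Small reference tables from the Urbana, Illinois bioenergy field trial,
#' shipped as plain CSV: `urbana_monthly_weather()` gives monthly mean
#' temperature and precipitation for 2020-2022 plus the 30-year normal
#' (Champaign-Urbana Willard Airport station); `urbana_root_biomass()`
#' gives root biomass and soil total C by depth increment for corn and
#' switchgrass after three and a half seasons; `urbana_soil_baseline()`
#' gives pre-trial soil properties by depth.
#'
#' @return a data frame.
#' @name study_tables
NULL

#' @rdname study_tables
#' @export
urbana_monthly_weather <- function() {
  utils::read.csv(system.file("extdata", "urbana_monthly_weather.csv",
                              package = "agrobalance"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_tables
#' @export
urbana_root_biomass <- function() {
  utils::read.csv(system.file("extdata", "urbana_root_biomass.csv",
                              package = "agrobalance"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_tables
#' @export
urbana_soil_baseline <- function() {
  utils::read.csv(system.file("extdata", "urbana_soil_baseline.csv",
                              package = "agrobalance"),
                  stringsAsFactors = FALSE)
}
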