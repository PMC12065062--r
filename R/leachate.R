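# Pore-water nitrate summarisation by crop, depth and season.

#' Summarise pore-water NO3-N concentrations
#'
#' Groups leachate samples by crop, year and sampler depth and reports the
#' arithmetic mean, standard error (`sd / sqrt(n)`) and sample count per
#' group. Replicate samplers within a plot on the same date are averaged
#' first by default, so the plot-date is the statistical unit (mirroring
#' how chamber replicates are handled).
#'
#' @param samples data frame with `date`, `plot_id`, `crop`, `depth_cm`,
#'   `no3n_mg_l` (`>= 0`).
#' @param average_replicates average replicate samplers within a plot-date
#'   before summarising (default `TRUE`).
#' @return data frame per crop x year x depth: `mean_mg_l`, `se_mg_l`
#'   (`NA` for n = 1), `n`.
#' @export
summarize_no3 <- function(samples, average_replicates = TRUE) {
  need_cols(samples, c("date", "plot_id", "crop", "depth_cm", "no3n_mg_l"),
            "leachate table")
  if (any(samples$no3n_mg_l < 0)) stopf("negative NO3-N concentration")
  s <- samples
  s$year <- as.integer(format(as.Date(s$date), "%Y"))
  if (average_replicates) {
    s <- stats::aggregate(no3n_mg_l ~ date + plot_id + crop + depth_cm + year,
                          data = s, FUN = mean)
  }
  agg <- stats::aggregate(no3n_mg_l ~ crop + year + depth_cm, data = s,
                          FUN = function(x) {
                            c(mean(x),
                              if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                              else NA_real_,
                              length(x))
                          })
  out <- data.frame(crop = agg$crop, year = agg$year, depth_cm = agg$depth_cm,
                    mean_mg_l = agg$no3n_mg_l[, 1L],
                    se_mg_l = agg$no3n_mg_l[, 2L],
                    n = as.integer(agg$no3n_mg_l[, 3L]))
  out[order(out$crop, out$year, out$depth_cm), ]
}

#' Relative concentration reduction between two crops
#'
#' `(mean_ref - mean_alt) / mean_ref * 100`: the percentage by which the
#' alternative crop's mean concentration sits below the reference crop's.
#'
#' @param mean_ref reference-crop mean concentration (e.g. corn).
#' @param mean_alt alternative-crop mean (e.g. switchgrass).
#' @return reduction in percent; 0 when the means are equal, negative when
#'   the alternative exceeds the reference.
#' @export
relative_reduction <- function(mean_ref, mean_alt) {
  if (any(mean_ref <= 0)) stopf("reference mean must be positive")
  (mean_ref - mean_alt) / mean_ref * 100
}

#' Year-by-year reduction of one crop relative to another
#'
#' Convenience wrapper combining [summarize_no3()] group means (averaged
#' across depths within crop-year) with [relative_reduction()].
#'
#' @param samples leachate table as in [summarize_no3()].
#' @param ref_crop,alt_crop crop labels.
#' @return data frame `year`, `mean_ref`, `mean_alt`, `reduction_pct`.
#' @export
no3_reduction_by_year <- function(samples, ref_crop, alt_crop) {
  sm <- summarize_no3(samples)
  by_year <- stats::aggregate(mean_mg_l ~ crop + year, data = sm, FUN = mean)
  years <- sort(unique(by_year$year))
  out <- lapply(years, function(y) {
    mr <- by_year$mean_mg_l[by_year$crop == ref_crop & by_year$year == y]
    ma <- by_year$mean_mg_l[by_year$crop == alt_crop & by_year$year == y]
    if (length(mr) != 1L || length(ma) != 1L) return(NULL)
    data.frame(year = y, mean_ref = mr, mean_alt = ma,
               reduction_pct = relative_reduction(mr, ma))
  })
  do.call(rbind, out)
}
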