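# Yield and biomass derivations: moisture-adjusted dry yields, harvest-index
# AGB estimation, root-profile summaries and soil-C stock arithmetic.

#' Dry-matter yield from a fresh harvest record
#'
#' Removes harvest moisture (wet basis) and scales the sampled area to a
#' hectare: `dry = fresh * (1 - moisture/100) / area * 10000`.
#'
#' @param fresh_kg fresh mass harvested (kg).
#' @param moisture_pct moisture percentage, wet basis, in \[0, 100\].
#' @param area_m2 sampled area (m^2), positive. A combine-harvested plot
#'   passes its plot area; a quadrat passes 1.
#' @return dry yield in kg ha^-1. `moisture = 100` with positive fresh mass
#'   returns 0 with a warning (all water, no dry matter).
#' @export
dry_matter_yield <- function(fresh_kg, moisture_pct, area_m2) {
  if (any(moisture_pct < 0 | moisture_pct > 100))
    stopf("moisture must lie in [0, 100]")
  if (any(area_m2 <= 0)) stopf("sampled area must be positive")
  if (any(fresh_kg < 0)) stopf("fresh mass must be >= 0")
  if (any(moisture_pct == 100 & fresh_kg > 0))
    warning("moisture of 100% with positive fresh mass: dry yield is zero",
            call. = FALSE)
  fresh_kg * (1 - moisture_pct / 100) / area_m2 * 10000
}

#' Corn aboveground biomass from dry grain yield
#'
#' The harvest index is grain mass over total aboveground mass, so
#' `AGB = grain / HI`. The standard corn harvest index of 0.545 is the
#' default.
#'
#' @param grain_kg_ha dry grain yield (kg ha^-1), `>= 0`.
#' @param harvest_index grain/AGB ratio, in (0, 1\].
#' @return estimated AGB (kg ha^-1).
#' @examples
#' corn_agb_from_grain(5450)  # 10000
#' @export
corn_agb_from_grain <- function(grain_kg_ha, harvest_index = 0.545) {
  if (any(grain_kg_ha < 0)) stopf("grain yield must be >= 0")
  if (harvest_index <= 0 || harvest_index > 1)
    stopf("harvest index must lie in (0, 1]")
  grain_kg_ha / harvest_index
}

#' Summarise root biomass profiles
#'
#' For each crop: total root biomass over the profile (always recomputed
#' from the depth increments, never taken from a printed total), the
#' fraction of the total in each increment, and between-crop total ratios.
#'
#' @param roots data frame with `crop`, `depth_top_cm`, `depth_bottom_cm`,
#'   `root_kg_ha`; increments must be contiguous, non-overlapping and
#'   non-negative per crop.
#' @return list with `totals` (crop, `total_kg_ha`), `fractions` (per
#'   increment: `fraction` of crop total), and `ratio(crop_a, crop_b)`, a
#'   function returning the total-biomass ratio a/b.
#' @export
summarize_root_profile <- function(roots) {
  need_cols(roots, c("crop", "depth_top_cm", "depth_bottom_cm", "root_kg_ha"),
            "root table")
  if (any(roots$root_kg_ha < 0)) stopf("root biomass must be >= 0")
  parts <- split(roots, roots$crop)
  for (p in parts) {
    p <- p[order(p$depth_top_cm), ]
    if (any(p$depth_bottom_cm <= p$depth_top_cm))
      stopf("inverted depth interval for crop %s", p$crop[1L])
    if (nrow(p) > 1L &&
        any(abs(p$depth_top_cm[-1L] - p$depth_bottom_cm[-nrow(p)]) > 1e-9))
      stopf("root increments for crop %s are not contiguous", p$crop[1L])
  }
  totals <- do.call(rbind, lapply(parts, function(p) {
    data.frame(crop = p$crop[1L], total_kg_ha = sum(p$root_kg_ha))
  }))
  rownames(totals) <- NULL
  fractions <- do.call(rbind, lapply(parts, function(p) {
    tot <- sum(p$root_kg_ha)
    if (tot == 0) stopf("zero root total for crop %s: fractions undefined",
                        p$crop[1L])
    p$fraction <- p$root_kg_ha / tot
    p
  }))
  rownames(fractions) <- NULL
  ratio <- function(crop_a, crop_b) {
    ta <- totals$total_kg_ha[totals$crop == crop_a]
    tb <- totals$total_kg_ha[totals$crop == crop_b]
    if (length(ta) != 1L || length(tb) != 1L)
      stopf("unknown crop in ratio request")
    ta / tb
  }
  list(totals = totals, fractions = fractions, ratio = ratio)
}

#' Soil carbon stock of one layer
#'
#' `stock (Mg C ha^-1) = concentration (g kg^-1) x bulk density (g cm^-3)
#' x thickness (cm) x 0.1` — the 0.1 collects the unit conversions from
#' g C per cm^2 column to Mg per hectare.
#'
#' @param conc_g_kg total C concentration (g C per kg soil), `>= 0`.
#' @param bd_g_cm3 bulk density (g cm^-3), positive.
#' @param depth_top_cm,depth_bottom_cm layer bounds (cm), top < bottom.
#' @return stock in Mg C ha^-1.
#' @export
soil_c_stock <- function(conc_g_kg, bd_g_cm3, depth_top_cm, depth_bottom_cm) {
  if (any(depth_bottom_cm <= depth_top_cm))
    stopf("inverted depth interval")
  if (any(conc_g_kg < 0)) stopf("negative C concentration")
  if (any(bd_g_cm3 <= 0)) stopf("bulk density must be positive")
  conc_g_kg * bd_g_cm3 * (depth_bottom_cm - depth_top_cm) * 0.1
}
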