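# Gravimetric whole-plant transpiration: rates per VPD step from balance
# mass loss, normalized by leaf area, and the whole-plant transpiration
# reduction. Pot evaporation is taken as zero (the soil surface is covered),
# so all mass loss is transpiration.

#' Whole-plant transpiration rate per VPD step from balance mass
#'
#' For each design step, averages total mass over the first and last
#' `window_min` minutes of the step and differences the two window means:
#' `E_rate = (m_start - m_end) / (LA * dt)`, with `dt` the time between
#' window centres, converted from g m-2 s-1 to mmol m-2 s-1 via the molar
#' mass of water (18.015 g mol-1). Start-minus-end makes a transpiring
#' plant's rate positive.
#'
#' @param series One plant's balance `data.frame` from [read_balance()]
#'   (carries `leaf_area_m2` as attribute, or pass `leaf_area_m2`).
#' @param design Chamber step design ([validate_step_design()]); its
#'   `vpd_kpa` column provides the step's realized VPD.
#' @param window_min Averaging window in minutes (default 5).
#' @param leaf_area_m2 Leaf area override; defaults to the series attribute.
#' @param negative_tol Mass-gain tolerance in g before a watering-event
#'   warning is raised (default 0.5).
#' @return `data.frame`, one row per step: `plant`, `accession`, `level`,
#'   `vpd`, `e_rate` (mmol m-2 s-1), `m_start`, `m_end` (g), `dt_s`,
#'   `missing`.
#' @export
transpiration_from_weights <- function(series, design, window_min = 5,
                                       leaf_area_m2 = attr(series, "leaf_area_m2"),
                                       negative_tol = 0.5) {
  .stop_if_missing_cols(series, c("plant", "accession", "time_s", "mass_g"),
                        "balance series")
  if (is.null(leaf_area_m2) || !is.finite(leaf_area_m2) || leaf_area_m2 <= 0) {
    stop("leaf_area_m2 must be a positive number", call. = FALSE)
  }
  design <- if (is.null(design$vpd_kpa)) validate_step_design(design) else design
  ends <- cumsum(design$duration_min) * 60
  starts <- c(0, ends[-length(ends)])
  out <- lapply(seq_len(nrow(design)), function(k) {
    w1 <- series$time_s >= starts[k] & series$time_s < starts[k] + window_min * 60
    w2 <- series$time_s >= ends[k] - window_min * 60 & series$time_s < ends[k]
    base <- data.frame(plant = series$plant[1], accession = series$accession[1],
                       level = design$step[k], vpd = design$vpd_kpa[k],
                       e_rate = NA_real_, m_start = NA_real_, m_end = NA_real_,
                       dt_s = NA_real_, missing = TRUE, stringsAsFactors = FALSE)
    if (!any(w1) || !any(w2)) return(base)
    m1 <- mean(series$mass_g[w1]); m2 <- mean(series$mass_g[w2])
    t1 <- mean(series$time_s[w1]); t2 <- mean(series$time_s[w2])
    loss <- m1 - m2
    if (loss < -negative_tol) {
      warning(sprintf("plant '%s' step %s: mass increased by %.2f g (watering event?)",
                      series$plant[1], design$step[k], -loss), call. = FALSE)
    }
    base$m_start <- m1; base$m_end <- m2; base$dt_s <- t2 - t1
    base$e_rate <- loss / (leaf_area_m2 * (t2 - t1)) / MOLAR_MASS_WATER * 1000
    base$missing <- FALSE
    base
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Whole-plant rate table for a cohort
#'
#' @param collection Named list of balance series from [read_balance()].
#' @inheritParams transpiration_from_weights
#' @return Long `data.frame`, one row per plant x step.
#' @export
whole_plant_rate_table <- function(collection, design, window_min = 5) {
  do.call(rbind, c(lapply(collection, transpiration_from_weights,
                          design = design, window_min = window_min),
                   make.row.names = FALSE))
}

#' Whole-plant transpiration reduction
#'
#' Same contract as the leaf-level [phi_e()]: a line through the two lowest
#' chamber-VPD steps extrapolated to the highest step, `phi_E = 1 -
#' E_meas / E_pred`. Defaults compare the last step against steps 1-2.
#'
#' @param rates Whole-plant rate table ([whole_plant_rate_table()]).
#' @param baseline_levels Two step indices for the baseline line (default
#'   `c(1, 2)`, ~0.77 and 1.36 kPa).
#' @param target_levels Step index/indices to evaluate (default: the highest
#'   step present, ~2.64 kPa).
#' @return As [phi_e()].
#' @export
phi_e_whole_plant <- function(rates, baseline_levels = c(1, 2),
                              target_levels = max(rates$level)) {
  df <- rates[, c("plant", "accession", "level", "vpd")]
  df$E <- rates$e_rate
  .phi_e_core(df, baseline_levels, target_levels)
}
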