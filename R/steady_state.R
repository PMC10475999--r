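# Collapse gas-exchange time series to per-plant x per-level steady-state
# values. Records are assigned to VPD steps by elapsed-time intervals from
# the design (not by matching RH readings, which overshoot during
# transitions); the steady-state value is the mean over the final minutes of
# each step, by which time the step-change transient has decayed.

#' Steady-state values for one plant at each VPD level
#'
#' For each design step, averages `gs`, `E`, `A` and `vpd_leaf` over the
#' final `window_min` minutes of the step. Levels without records in that
#' window are flagged missing, never fabricated. `iwue` is recomputed as
#' `A/gs` of the steady-state row.
#'
#' @param series One plant's gas-exchange `data.frame` as returned by
#'   [read_gas_exchange()] (elements of the list).
#' @param design Step design table (see [validate_step_design()]); step
#'   boundaries are the cumulative `duration_min`.
#' @param window_min Width of the end-of-step averaging window in minutes
#'   (default 5). The protocol holds each level ~60 min, so the window sits
#'   well past the stomatal transient.
#' @return `data.frame` with one row per level: `plant`, `accession`,
#'   `level`, `vpd` (realized mean leaf VPD over the window), `gs`, `E`,
#'   `A`, `iwue`, `missing` (logical).
#' @export
extract_steady_state <- function(series, design, window_min = 5) {
  .stop_if_missing_cols(series, c("plant", "accession", "time_s", "gs", "E", "A",
                                  "vpd_leaf"), "gas-exchange series")
  design <- if (is.null(design$vpd_kpa)) validate_step_design(design) else design
  ends <- cumsum(design$duration_min) * 60
  starts <- c(0, ends[-length(ends)])
  out <- lapply(seq_len(nrow(design)), function(k) {
    win <- series$time_s >= (ends[k] - window_min * 60) & series$time_s < ends[k]
    if (!any(win)) {
      data.frame(plant = series$plant[1], accession = series$accession[1],
                 level = design$step[k], vpd = NA_real_, gs = NA_real_,
                 E = NA_real_, A = NA_real_, iwue = NA_real_, missing = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      w <- series[win, , drop = FALSE]
      gs <- mean(w$gs); A <- mean(w$A)
      data.frame(plant = series$plant[1], accession = series$accession[1],
                 level = design$step[k], vpd = mean(w$vpd_leaf), gs = gs,
                 E = mean(w$E), A = A,
                 iwue = if (gs > 0) A / gs else NA_real_,
                 missing = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (all(out$missing)) {
    stop(sprintf("plant '%s': no design step has records in its steady-state window",
                 series$plant[1]), call. = FALSE)
  }
  out
}

#' Steady-state table for a whole cohort
#'
#' Applies [extract_steady_state()] to every plant and binds the rows.
#'
#' @param collection Named list of per-plant series from [read_gas_exchange()].
#' @inheritParams extract_steady_state
#' @return Long `data.frame`, one row per plant x level.
#' @export
steady_state_table <- function(collection, design, window_min = 5) {
  do.call(rbind, c(lapply(collection, extract_steady_state, design = design,
                          window_min = window_min), make.row.names = FALSE))
}

#' Maximum observed stomatal conductance of one plant
#'
#' The highest steady-state `gs` across all VPD levels; missing levels are
#' ignored.
#'
#' @param rows Steady-state rows for a single plant.
#' @return Maximum gs, mol m-2 s-1.
#' @export
max_gs <- function(rows) {
  gs <- rows$gs[!is.na(rows$gs)]
  if (!length(gs)) stop("max_gs needs at least one non-missing level", call. = FALSE)
  max(gs)
}

#' Per-plant maximum gs for a steady-state table
#'
#' @param table Steady-state table from [steady_state_table()].
#' @return `data.frame` with columns `plant`, `accession`, `max_gs`.
#' @export
max_gs_table <- function(table) {
  sp <- split(table, table$plant)
  out <- data.frame(
    plant = vapply(sp, function(s) s$plant[1], character(1)),
    accession = vapply(sp, function(s) s$accession[1], character(1)),
    max_gs = vapply(sp, max_gs, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
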