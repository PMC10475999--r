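# Leaf-level response statistics derived from the steady-state table:
# transpiration reduction (phi_E), limitation of photosynthesis, and the
# stomatal reduction (slope of gs against log VPD).

# Shared phi_E core used at leaf and whole-plant level. A two-point line
# through the baseline levels (a linear regression through two points IS
# that line) is extrapolated to each target level's realized VPD.
.phi_e_core <- function(df, baseline_levels, target_levels) {
  stopifnot(length(baseline_levels) == 2)
  out <- list(); dropped <- character(0)
  for (s in split(df, df$plant)) {
    b <- s[match(baseline_levels, s$level), , drop = FALSE]
    if (any(is.na(b$E)) || any(is.na(b$vpd))) {
      dropped <- c(dropped, s$plant[1]); next
    }
    if (b$vpd[1] == b$vpd[2]) {
      stop(sprintf("plant '%s': baseline levels have identical VPD; baseline line is degenerate",
                   s$plant[1]), call. = FALSE)
    }
    slope <- (b$E[2] - b$E[1]) / (b$vpd[2] - b$vpd[1])
    inter <- b$E[1] - slope * b$vpd[1]
    tg <- s[s$level %in% target_levels & !is.na(s$E), , drop = FALSE]
    if (!nrow(tg)) next
    e_pred <- inter + slope * tg$vpd
    out[[length(out) + 1]] <- data.frame(
      plant = tg$plant, accession = tg$accession, level = tg$level,
      vpd = tg$vpd, e_pred = e_pred, e_meas = tg$E,
      phi_e = ifelse(e_pred > 0, 1 - tg$E / e_pred, NA_real_),
      valid = e_pred > 0, stringsAsFactors = FALSE
    )
  }
  if (length(dropped)) {
    message(sprintf("phi_E: excluded %d plant(s) with a missing baseline level: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (!length(out)) stop("phi_E: no plant has both baseline levels", call. = FALSE)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Transpiration reduction (phi_E) at leaf level
#'
#' For each plant, fits the exact line through the transpiration rate at the
#' two lowest VPD levels and extrapolates it to the high-VPD target levels.
#' `phi_E = 1 - E_meas / E_pred` measures the fractional shortfall of the
#' measured rate below this linear expectation: 0 means no stomatal
#' restriction of the VPD response, negative values a super-linear response.
#'
#' @param table Steady-state table ([steady_state_table()]).
#' @param baseline_levels Two level indices defining the baseline line
#'   (default `c(1, 2)`, i.e. ~0.91 and 1.50 kPa leaf VPD).
#' @param target_levels Level indices at which phi_E is evaluated (default
#'   `c(4, 5, 6)`, ~2.69 / 3.28 / 3.87 kPa).
#' @return `data.frame` with columns `plant`, `accession`, `level`, `vpd`,
#'   `e_pred`, `e_meas`, `phi_e`, `valid` (`FALSE` where the extrapolated
#'   `e_pred` is non-positive). Plants missing a baseline level are excluded
#'   with a message.
#' @export
phi_e <- function(table, baseline_levels = c(1, 2), target_levels = c(4, 5, 6)) {
  .phi_e_core(table, baseline_levels, target_levels)
}

#' Limitation of photosynthesis by stomatal closure
#'
#' Per accession and VPD level: `sum(A_max - A_meas) / sum(A_meas)`, with
#' `A_max` each plant's maximum steady-state A across levels and the sums
#' running over the accession's plants at the fixed level. Zero when every
#' plant sits at its own maximum; never negative.
#'
#' @param table Steady-state table.
#' @return `data.frame` with `accession`, `level`, `vpd` (mean realized VPD
#'   of the contributing plants), `limitation`, `n_plants`. Undefined rows
#'   (non-positive `sum(A_meas)`) carry `NA` with a warning.
#' @export
limitation_of_a <- function(table) {
  ok <- !is.na(table$A)
  a_max <- tapply(table$A[ok], table$plant[ok], max)
  out <- list()
  for (acc_df in split(table[ok, , drop = FALSE], table$accession[ok])) {
    for (lev_df in split(acc_df, acc_df$level)) {
      amax <- a_max[as.character(lev_df$plant)]
      denom <- sum(lev_df$A)
      lim <- if (denom > 0) sum(amax - lev_df$A) / denom else NA_real_
      if (is.na(lim)) {
        warning(sprintf("limitation_of_a undefined for accession '%s' level %s (sum A <= 0)",
                        lev_df$accession[1], lev_df$level[1]), call. = FALSE)
      }
      out[[length(out) + 1]] <- data.frame(
        accession = lev_df$accession[1], level = lev_df$level[1],
        vpd = mean(lev_df$vpd), limitation = lim, n_plants = nrow(lev_df),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Stomatal reduction: slope of gs against log VPD
#'
#' Fits, per plant, ordinary least squares of steady-state `gs` on
#' `log(VPD_leaf)`: `gs = a - phi_stom * log(VPD_leaf)`. `phi_stom` is
#' reported as the absolute slope; `a` is the fitted gs at VPD_leaf = 1 kPa
#' (the intercept, since log 1 = 0).
#'
#' @param table Steady-state table.
#' @param min_levels Minimum non-missing levels required per plant
#'   (default 3); plants below it are dropped with a warning.
#' @return `data.frame` with `plant`, `accession`, `a`, `phi_stom`,
#'   `slope` (signed), `r_squared`, `n_levels`.
#' @export
stomatal_reduction <- function(table, min_levels = 3) {
  out <- list(); dropped <- character(0)
  for (s in split(table, table$plant)) {
    s <- s[!is.na(s$gs) & !is.na(s$vpd), , drop = FALSE]
    if (nrow(s) < min_levels) { dropped <- c(dropped, s$plant[1]); next }
    lv <- log(s$vpd)
    if (stats::var(lv) == 0) {
      stop(sprintf("plant '%s': zero variance in log(VPD); stomatal fit undefined",
                   s$plant[1]), call. = FALSE)
    }
    fit <- stats::lm(gs ~ lv, data = data.frame(gs = s$gs, lv = lv))
    tss <- sum((s$gs - mean(s$gs))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
    out[[length(out) + 1]] <- data.frame(
      plant = s$plant[1], accession = s$accession[1],
      a = unname(stats::coef(fit)[1]),
      phi_stom = abs(unname(stats::coef(fit)[2])),
      slope = unname(stats::coef(fit)[2]),
      r_squared = r2, n_levels = nrow(s), stringsAsFactors = FALSE
    )
  }
  if (length(dropped)) {
    warning(sprintf("stomatal_reduction: dropped %d plant(s) with fewer than %d levels: %s",
                    length(dropped), min_levels, paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  if (!length(out)) stop("stomatal_reduction: no plant has enough levels", call. = FALSE)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Accession means with standard errors
#'
#' Aggregates a per-plant metric to accession level as mean +/- se, the
#' convention used for all figure-level summaries.
#'
#' @param df `data.frame` with an `accession` column.
#' @param value Name of the numeric column to aggregate.
#' @param by Extra grouping columns (e.g. `"level"`).
#' @return `data.frame` with `accession`, the `by` columns, `mean`, `se`, `n`.
#' @export
accession_means <- function(df, value, by = character(0)) {
  keys <- df[, c("accession", by), drop = FALSE]
  grp <- interaction(keys, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(seq_len(nrow(df)), grp), function(idx) {
    v <- df[[value]][idx]
    cbind(keys[idx[1], , drop = FALSE],
          data.frame(mean = mean(v, na.rm = TRUE), se = .se(v),
                     n = sum(!is.na(v))))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
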