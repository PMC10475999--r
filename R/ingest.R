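# Readers and writers for the instrument-style tabular inputs: gas-exchange
# CSV, balance logs, the VPD step design, plus lossless CSV output helpers.
# Dialect: comma-separated, '.' decimal, UTF-8, one header row. Instrument
# export variants are accommodated through a user-supplied column map.

#' Default logical-to-physical column map for gas-exchange files
#'
#' Maps the logical fields the pipeline needs (names) to the column headers
#' found in the file (values). Override any entry to read an instrument
#' export with different headers.
#'
#' @return Named character vector with entries `plant`, `accession`,
#'   `time_s`, `gs`, `E`, `A`, `t_leaf`, `rh_percent`, `vpd_leaf`.
#' @export
gas_exchange_columns <- function() {
  c(plant = "plant", accession = "accession", time_s = "time_s",
    gs = "gs", E = "E", A = "A", t_leaf = "t_leaf",
    rh_percent = "rh_percent", vpd_leaf = "vpd_leaf")
}

#' Read leaf gas-exchange time series
#'
#' Reads an instrument-style CSV holding one row per logged record (about
#' one per minute) for one or more plants, validates it, and returns one
#' ordered series per plant. Rows with any missing required field are
#' dropped with a reported count.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping logical fields to file
#'   headers; see [gas_exchange_columns()].
#' @return A named list of `data.frame`s, one per plant (names are plant
#'   ids), each with columns `plant`, `accession`, `time_s`, `gs`, `E`, `A`,
#'   `t_leaf`, `rh_percent`, `vpd_leaf`, ordered by time.
#' @export
read_gas_exchange <- function(path, column_map = gas_exchange_columns()) {
  needed <- gas_exchange_columns()
  if (!all(names(needed) %in% names(column_map))) {
    stop("column_map must name all logical fields: ",
         paste(names(needed), collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if_missing_cols(raw, unname(column_map[names(needed)]),
                        sprintf("gas-exchange file '%s'", path))
  df <- stats::setNames(raw[, unname(column_map[names(needed)])], names(needed))
  numeric_cols <- setdiff(names(needed), c("plant", "accession"))
  for (cc in numeric_cols) df[[cc]] <- as.numeric(df[[cc]])

  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    message(sprintf("read_gas_exchange: dropped %d row(s) with missing values",
                    sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  if (!nrow(df)) stop("gas-exchange file contains no complete records", call. = FALSE)
  if (any(df$gs < 0)) stop("negative stomatal conductance in gas-exchange file",
                           call. = FALSE)
  if (any(df$vpd_leaf <= 0)) stop("non-positive VPD_leaf in gas-exchange file",
                                  call. = FALSE)

  series <- split(df, df$plant)
  series <- lapply(series, function(s) {
    bad <- which(diff(s$time_s) <= 0)
    if (length(bad)) {
      stop(sprintf("non-monotone time for plant '%s' at record %d",
                   s$plant[1], bad[1] + 1), call. = FALSE)
    }
    rownames(s) <- NULL
    s
  })
  series[order(names(series))]
}

#' Read whole-plant balance logs and attach leaf areas
#'
#' Reads a balance CSV (one row per ~10 s weighing: `plant`, `accession`,
#' `time_s`, `mass_g`) and joins per-plant leaf areas. Every plant in the
#' log must have a leaf area; leaf-area entries for unknown plants are
#' ignored with a warning.
#'
#' @param path Path to the balance CSV.
#' @param leaf_areas `data.frame` with columns `plant` and `leaf_area_m2`.
#' @return Named list of per-plant `data.frame`s (`plant`, `accession`,
#'   `time_s`, `mass_g`), each carrying its leaf area (m2) as attribute
#'   `leaf_area_m2`.
#' @export
read_balance <- function(path, leaf_areas) {
  .stop_if_missing_cols(leaf_areas, c("plant", "leaf_area_m2"), "leaf-area table")
  if (any(!is.finite(leaf_areas$leaf_area_m2) | leaf_areas$leaf_area_m2 <= 0)) {
    stop("leaf areas must be positive and finite", call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if_missing_cols(raw, c("plant", "accession", "time_s", "mass_g"),
                        sprintf("balance file '%s'", path))
  raw$time_s <- as.numeric(raw$time_s)
  raw$mass_g <- as.numeric(raw$mass_g)
  complete <- stats::complete.cases(raw[, c("plant", "time_s", "mass_g")])
  if (any(!complete)) {
    message(sprintf("read_balance: dropped %d row(s) with missing values",
                    sum(!complete)))
    raw <- raw[complete, , drop = FALSE]
  }
  if (any(raw$mass_g <= 0)) stop("non-positive mass in balance file", call. = FALSE)

  extra <- setdiff(leaf_areas$plant, unique(raw$plant))
  if (length(extra)) {
    warning(sprintf("leaf-area table has %d plant id(s) absent from the balance log (ignored): %s",
                    length(extra), paste(extra, collapse = ", ")), call. = FALSE)
  }
  series <- split(raw, raw$plant)
  series <- lapply(series, function(s) {
    bad <- which(diff(s$time_s) <= 0)
    if (length(bad)) {
      stop(sprintf("non-monotone time for plant '%s' at record %d",
                   s$plant[1], bad[1] + 1), call. = FALSE)
    }
    idx <- match(s$plant[1], leaf_areas$plant)
    if (is.na(idx)) {
      stop(sprintf("no leaf area for plant '%s'", s$plant[1]), call. = FALSE)
    }
    rownames(s) <- NULL
    attr(s, "leaf_area_m2") <- leaf_areas$leaf_area_m2[idx]
    s
  })
  series[order(names(series))]
}

#' Read a VPD step design file
#'
#' The design describes the ordered RH step-down protocol: one row per step
#' with target RH (%), temperature set-point, duration, and optionally the
#' realized mean VPD of that step. Realized and set-point VPDs are kept as
#' distinct fields and never asserted equal: realized chamber means reflect
#' control overshoot and drying-capacity limits.
#'
#' @param path CSV with columns `step`, `rh_percent`, `temp_c`,
#'   `duration_min`, and optionally `vpd_kpa`.
#' @return Validated `data.frame`, one row per step in protocol order, with
#'   a `vpd_kpa` column (computed from set-points via [vpd()] when absent).
#' @export
read_step_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_step_design(df)
}

#' Validate (and complete) a step design table
#'
#' @param design `data.frame` with columns `step`, `rh_percent`, `temp_c`,
#'   `duration_min`, optional `vpd_kpa`.
#' @return The design, ordered by `step`, with `vpd_kpa` filled in from the
#'   set-points where missing.
#' @export
validate_step_design <- function(design) {
  .stop_if_missing_cols(design, c("step", "rh_percent", "temp_c", "duration_min"),
                        "step design")
  design <- design[order(design$step), , drop = FALSE]
  if (any(design$duration_min <= 0)) {
    stop("step durations must be positive", call. = FALSE)
  }
  if (any(diff(design$rh_percent) >= 0)) {
    stop("relative humidity must strictly decrease across steps (the protocol only dries the air)",
         call. = FALSE)
  }
  if (is.null(design$vpd_kpa)) design$vpd_kpa <- NA_real_
  fill <- is.na(design$vpd_kpa)
  design$vpd_kpa[fill] <- vpd(design$temp_c[fill], design$rh_percent[fill] / 100)
  rownames(design) <- NULL
  design
}

#' Write a pipeline output table as CSV
#'
#' Plain-CSV writer used for every tabular output. Numeric fields survive a
#' write/read round trip to at least 12 significant digits (full double
#' precision is written).
#'
#' @param df `data.frame` to write.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
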