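#' Saturation vapour pressure of air (Tetens formula)
#'
#' Computes the saturation vapour pressure `es(T)` over liquid water by the
#' Tetens formula, `es = 0.6108 * exp(17.27 * T / (T + 237.3))`. Tetens,
#' Magnus and Buck agree to within ~0.1% over the physiological range; the
#' Tetens constants are fixed here so every derived VPD is reproducible.
#'
#' @param temperature Air (or leaf) temperature in degrees Celsius. Must lie
#'   within `[0, 60]`; vectorised.
#' @return Saturation vapour pressure in kPa, same length as `temperature`.
#'   Strictly increasing in temperature.
#' @examples
#' saturation_vapour_pressure(36) # ~5.94 kPa
#' @export
saturation_vapour_pressure <- function(temperature) {
  if (!is.numeric(temperature)) {
    stop("`temperature` must be numeric (degrees Celsius)", call. = FALSE)
  }
  bad <- !is.na(temperature) & (temperature < 0 | temperature > 60)
  if (any(bad)) {
    stop(sprintf(
      "temperature out of supported range [0, 60] degC: %s",
      paste(format(temperature[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  0.6108 * exp(17.27 * temperature / (temperature + 237.3))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' VPD is the difference between saturation and actual vapour pressure,
#' `es(T) * (1 - RH)`. Applied with air temperature it gives the chamber VPD;
#' applied with leaf temperature it gives the leaf-to-air VPD that stomata
#' experience.
#'
#' @param temperature Temperature in degrees Celsius, in `[0, 60]`.
#' @param relative_humidity Relative humidity as a fraction in `[0, 1]`.
#'   Readers of instrument files convert percent to fraction at the boundary;
#'   internally everything is a fraction.
#' @return VPD in kPa. Zero for saturated air, strictly decreasing in RH at
#'   fixed temperature.
#' @examples
#' vpd(36, 0.87) # ~0.77 kPa
#' @export
vpd <- function(temperature, relative_humidity) {
  if (!is.numeric(relative_humidity)) {
    stop("`relative_humidity` must be numeric (fraction in [0, 1])", call. = FALSE)
  }
  bad <- !is.na(relative_humidity) &
    (relative_humidity < 0 | relative_humidity > 1)
  if (any(bad)) {
    stop(sprintf(
      "relative_humidity must be a fraction in [0, 1]; got %s",
      paste(format(relative_humidity[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  saturation_vapour_pressure(temperature) * (1 - relative_humidity)
}

#' Relative humidity implied by a temperature and a VPD
#'
#' Inverse of [vpd()] at fixed temperature; used by the synthetic generator
#' to emit the RH column consistent with a target VPD level.
#'
#' @param temperature Temperature in degrees Celsius.
#' @param vpd_kpa VPD in kPa; must not exceed the saturation vapour pressure.
#' @return Relative humidity as a fraction in `[0, 1]`.
#' @export
rh_from_vpd <- function(temperature, vpd_kpa) {
  es <- saturation_vapour_pressure(temperature)
  if (any(vpd_kpa < 0 | vpd_kpa > es)) {
    stop("`vpd_kpa` must lie in [0, es(temperature)]", call. = FALSE)
  }
  1 - vpd_kpa / es
}

#' Intrinsic water use efficiency
#'
#' `iWUE = A / gs`: micromoles of CO2 assimilated per mole of water vapour
#' the stomata conduct.
#'
#' @param A Net photosynthetic rate, umol CO2 m-2 s-1.
#' @param gs Stomatal conductance to water vapour, mol H2O m-2 s-1. Must be
#'   positive; non-positive conductances yield `NA` with a warning (the ratio
#'   is undefined for a closed stoma).
#' @return iWUE in umol CO2 mol-1 H2O.
#' @examples
#' intrinsic_wue(15, 0.3) # 50
#' @export
intrinsic_wue <- function(A, gs) {
  out <- A / gs
  bad <- !is.na(gs) & gs <= 0
  if (any(bad)) {
    warning(sprintf("iWUE undefined for %d observation(s) with gs <= 0; returning NA",
                    sum(bad)), call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}
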