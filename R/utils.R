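# Internal helpers shared across modules.

# Molar mass of water, g mol-1 (CODATA). Converts balance mass fluxes to
# molar transpiration rates.
MOLAR_MASS_WATER <- 18.015

# Deterministic 31-adic string hash into [0, 2^31 - 2]. Kept in plain double
# arithmetic (exact below 2^53) so it is platform independent.
.str_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

# Derive a child RNG seed from a master seed and a key path, so each plant's
# stream is a pure function of (master seed, accession, plant): adding a
# plant never perturbs the draws of any other.
.derive_seed <- function(master, ...) {
  key <- paste(..., sep = "/")
  as.integer((as.numeric(master) + .str_hash(key)) %% 2147483647)
}

# Standard error of the mean, NA-tolerant.
.se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

.stop_if_missing_cols <- function(df, cols, where) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}
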