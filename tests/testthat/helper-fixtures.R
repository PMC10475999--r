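# Shared fixtures and the independent grid-search oracle for segmented
# fits. Everything is built in code at test time.

# Exhaustive RSS-profiling oracle for the breakpoint: evaluates the
# fixed-psi least-squares RSS on a dense candidate grid and returns the
# discrete minimizer. Independent of the package's iterative fitter.
grid_search_psi <- function(x, y, plant = NULL, n_grid = 2000) {
  xs <- sort(unique(x))
  delta <- min(diff(xs))
  grid <- seq(min(x) + delta, max(x) - delta, length.out = n_grid)
  P <- if (is.null(plant)) matrix(1, length(x), 1) else
    stats::model.matrix(~ 0 + factor(plant))
  rss <- vapply(grid, function(psi) {
    sum(stats::lm.fit(cbind(P, x, pmax(x - psi, 0)), y)$residuals^2)
  }, numeric(1))
  list(psi = grid[which.min(rss)], rss = min(rss),
       resolution = grid[2] - grid[1])
}

# RSS of the fixed-psi model by the same independent route.
oracle_rss_at <- function(x, y, psi, plant = NULL) {
  P <- if (is.null(plant)) matrix(1, length(x), 1) else
    stats::model.matrix(~ 0 + factor(plant))
  sum(stats::lm.fit(cbind(P, x, pmax(x - psi, 0)), y)$residuals^2)
}

# Minimal single-plant steady-state table for metric tests.
make_ss_rows <- function(plant, vpd, E, gs = NULL, A = NULL,
                         accession = "accA") {
  n <- length(vpd)
  data.frame(plant = plant, accession = accession, level = seq_len(n),
             vpd = vpd, gs = if (is.null(gs)) rep(0.3, n) else gs,
             E = E, A = if (is.null(A)) rep(15, n) else A,
             iwue = NA_real_, missing = FALSE, stringsAsFactors = FALSE)
}

# Three-step design used by reader/steady-state tests.
tiny_design <- function(n_steps = 3, duration_min = 60) {
  data.frame(step = seq_len(n_steps),
             rh_percent = seq(85, by = -10, length.out = n_steps),
             temp_c = 36, duration_min = duration_min)
}

# Gas-exchange frame for one plant sampled every `dt_s` seconds with
# constant per-step values.
constant_step_series <- function(plant, design, values, dt_s = 60,
                                 accession = "accA") {
  ends <- cumsum(design$duration_min) * 60
  starts <- c(0, ends[-length(ends)])
  rows <- lapply(seq_len(nrow(design)), function(k) {
    tt <- seq(starts[k], ends[k] - dt_s, by = dt_s)
    data.frame(plant = plant, accession = accession, time_s = tt,
               gs = values$gs[k], E = values$E[k], A = values$A[k],
               t_leaf = 36, rh_percent = design$rh_percent[k],
               vpd_leaf = values$vpd[k], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Low-observation-noise cohort configuration used by end-to-end tests:
# default design and biological between-plant variation, instrument and
# balance noise scaled down.
low_noise_config <- function(seed = 1, noise_scale = 0.25) {
  cohort_config(
    noise = list(gs = 0.01 * noise_scale, E = 0.05 * noise_scale,
                 A = 0.3 * noise_scale, intercept_leaf = 0.15,
                 intercept_wp = 0.05, gs_plant = 0.02,
                 balance_g = 0.02 * noise_scale),
    seed = seed
  )
}
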