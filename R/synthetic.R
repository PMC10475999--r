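# Synthetic VPD-response cohorts with known ground truth. The generator
# emulates a step-change drying experiment on well-watered plants: leaf
# gas-exchange series at six leaf-VPD levels and balance logs at five
# chamber-VPD levels, for accessions drawn from three response archetypes
# (I conservative low-flux early limiter, II high-flux with strong high-VPD
# shutdown and a negative post-breakpoint slope, III risk-taking sustained
# transpiration). Every true parameter is recorded in a manifest so each
# pipeline stage can be checked against ground truth.

# Archetype parameter defaults. The slope change is always a reduction
# (slope2 < 0): I breaks early with a low slope before and near-flat
# transpiration after; II breaks around 2 kPa with a negative slope after
# (net transpiration decrease) at both measurement levels; III breaks late
# and keeps a high positive slope afterwards.
.archetype_defaults <- list(
  I = list(psi_leaf = 1.8, slope1_leaf = 1.2, slope2_leaf = -0.9, e0_leaf = 0.4,
           psi_wp = 1.7, slope1_wp = 0.55, slope2_wp = -0.65, e0_wp = 0.25,
           a_gs = 0.22, phi_stom = 0.06, a_max = 15, g50 = 0.05),
  II = list(psi_leaf = 2.0, slope1_leaf = 3.0, slope2_leaf = -3.4, e0_leaf = 0.6,
            psi_wp = 1.9, slope1_wp = 1.3, slope2_wp = -1.6, e0_wp = 0.35,
            a_gs = 0.50, phi_stom = 0.25, a_max = 22, g50 = 0.05),
  III = list(psi_leaf = 2.6, slope1_leaf = 2.8, slope2_leaf = -1.0, e0_leaf = 0.5,
             psi_wp = 2.2, slope1_wp = 1.1, slope2_wp = -0.45, e0_wp = 0.3,
             a_gs = 0.45, phi_stom = 0.15, a_max = 20, g50 = 0.05))

#' Configuration of a synthetic VPD-response cohort
#'
#' Defaults reproduce the study conditions the pipeline is built for: three
#' archetype groups of 1 / 2 / 6 accessions, 5 plants each, six leaf VPD
#' levels near 0.91/1.50/2.09/2.69/3.28/3.87 kPa and five chamber levels
#' near 0.77/1.36/1.93/2.34/2.64 kPa, a 90-min first step followed by
#' 60-min steps, leaf records every 60 s and balance records every 10 s.
#'
#' @param groups List of group specs; each needs `archetype` (`"I"`, `"II"`
#'   or `"III"`), `n_accessions`, `n_plants`, and may override any
#'   archetype parameter (`psi_leaf`, `slope1_leaf`, `slope2_leaf`,
#'   `e0_leaf`, `psi_wp`, `slope1_wp`, `slope2_wp`, `e0_wp`, `a_gs`,
#'   `phi_stom`, `a_max`, `g50`).
#' @param leaf_levels Leaf VPD levels (kPa).
#' @param chamber_levels Chamber VPD levels (kPa).
#' @param leaf_step_min,chamber_step_min Step durations (min); first step
#'   90 min, the rest 60.
#' @param sample_leaf_s,sample_balance_s Sampling intervals (s).
#' @param tau_min Time constant of the exponential within-step approach to
#'   steady state (min); 10 min leaves the end-of-step window effectively
#'   steady.
#' @param temp_c Leaf/air temperature set-point (degC).
#' @param noise Named list of noise SDs: `gs` (mol m-2 s-1), `E`
#'   (mmol m-2 s-1), `A` (umol m-2 s-1) observation noise; `intercept_leaf`,
#'   `intercept_wp` between-plant intercept SDs; `gs_plant` between-plant SD
#'   of the gs intercept `a`; `balance_g` balance reading noise (g).
#' @param leaf_area_m2 Mean leaf area (m2); per-plant areas vary +/-10%.
#' @param start_mass_g Initial pot + plant mass on the balance (g).
#' @param seed Master seed; per-plant streams are derived by stable hashing
#'   of (accession, plant), so adding a plant never perturbs others.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(groups = list(
                            list(archetype = "I", n_accessions = 1, n_plants = 5),
                            list(archetype = "II", n_accessions = 2, n_plants = 5),
                            list(archetype = "III", n_accessions = 6, n_plants = 5)),
                          leaf_levels = c(0.91, 1.50, 2.09, 2.69, 3.28, 3.87),
                          chamber_levels = c(0.77, 1.36, 1.93, 2.34, 2.64),
                          leaf_step_min = c(90, rep(60, length(leaf_levels) - 1)),
                          chamber_step_min = c(90, rep(60, length(chamber_levels) - 1)),
                          sample_leaf_s = 60, sample_balance_s = 10,
                          tau_min = 10, temp_c = 36,
                          noise = list(gs = 0.01, E = 0.05, A = 0.3,
                                       intercept_leaf = 0.15, intercept_wp = 0.05,
                                       gs_plant = 0.02, balance_g = 0.02),
                          leaf_area_m2 = 0.10, start_mass_g = 1500,
                          seed = 1) {
  stopifnot(length(leaf_step_min) == length(leaf_levels),
            length(chamber_step_min) == length(chamber_levels))
  if (any(unlist(noise) < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  groups <- lapply(groups, function(g) {
    if (!g$archetype %in% names(.archetype_defaults)) {
      stop("unknown archetype: ", g$archetype, call. = FALSE)
    }
    utils::modifyList(c(.archetype_defaults[[g$archetype]], list(n_accessions = 1L, n_plants = 5L)),
                      g)
  })
  cfg <- list(groups = groups, leaf_levels = leaf_levels,
              chamber_levels = chamber_levels, leaf_step_min = leaf_step_min,
              chamber_step_min = chamber_step_min, sample_leaf_s = sample_leaf_s,
              sample_balance_s = sample_balance_s, tau_min = tau_min,
              temp_c = temp_c, noise = noise, leaf_area_m2 = leaf_area_m2,
              start_mass_g = start_mass_g, seed = seed)
  # Reject parameter sets whose noiseless steady transpiration goes negative.
  for (g in groups) {
    e_leaf <- g$e0_leaf + g$slope1_leaf * leaf_levels +
      g$slope2_leaf * pmax(leaf_levels - g$psi_leaf, 0)
    e_wp <- g$e0_wp + g$slope1_wp * chamber_levels +
      g$slope2_wp * pmax(chamber_levels - g$psi_wp, 0)
    if (any(e_leaf <= 0) || any(e_wp <= 0)) {
      stop(sprintf("archetype %s parameters yield non-positive steady transpiration",
                   g$archetype), call. = FALSE)
    }
  }
  class(cfg) <- "cohort_config"
  cfg
}

# Piecewise-linear steady transpiration at level VPDs.
.steady_e <- function(v, e0, s1, s2, psi) e0 + s1 * v + s2 * pmax(v - psi, 0)

# Step-change trajectory: exponential approach from the previous steady
# value to each step's target, sampled on a regular grid.
.step_trajectory <- function(targets, step_min, dt_s, tau_s) {
  times <- list(); vals <- list()
  ends <- cumsum(step_min) * 60
  starts <- c(0, ends[-length(ends)])
  prev <- targets[1]
  for (k in seq_along(targets)) {
    tt <- seq(starts[k], ends[k] - dt_s, by = dt_s)
    v <- targets[k] + (prev - targets[k]) * exp(-(tt - starts[k]) / tau_s)
    prev <- v[length(v)]
    times[[k]] <- tt; vals[[k]] <- v
  }
  list(time_s = unlist(times), value = unlist(vals),
       step = rep(seq_along(targets), vapply(times, length, integer(1))))
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces, per plant: a leaf gas-exchange time series (gs declining
#' log-linearly in leaf VPD, transpiration piecewise-linear with the
#' plant's breakpoint and slopes, photosynthesis coupled to gs by a
#' rectangular hyperbola `A = A_max * gs / (gs + g50)`), and a balance mass
#' trace that integrates the whole-plant transpiration rate times leaf area
#' (molar-mass conversion) with additive reading noise. Within-step
#' dynamics converge exponentially to the steady value. Regeneration under
#' the same master seed is identical.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `gas_exchange` (long
#'   `data.frame`), `balance` (long `data.frame`), `leaf_areas`,
#'   `design_leaf`, `design_chamber`, and `truth` (list with `accessions`
#'   and `plants` parameter tables plus the config echo).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  es <- saturation_vapour_pressure(config$temp_c)
  design_leaf <- data.frame(step = seq_along(config$leaf_levels),
                            rh_percent = 100 * rh_from_vpd(config$temp_c, config$leaf_levels),
                            temp_c = config$temp_c,
                            duration_min = config$leaf_step_min,
                            vpd_kpa = config$leaf_levels)
  design_chamber <- data.frame(step = seq_along(config$chamber_levels),
                               rh_percent = 100 * rh_from_vpd(config$temp_c, config$chamber_levels),
                               temp_c = config$temp_c,
                               duration_min = config$chamber_step_min,
                               vpd_kpa = config$chamber_levels)
  tau_s <- config$tau_min * 60
  nz <- config$noise

  acc_rows <- list(); plant_rows <- list()
  ge <- list(); bal <- list(); la <- list()
  acc_counter <- 0L
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    for (ai in seq_len(g$n_accessions)) {
      acc_counter <- acc_counter + 1L
      acc <- sprintf("acc%02d_%s", acc_counter, g$archetype)
      acc_rows[[acc]] <- data.frame(
        accession = acc, group = gi, archetype = g$archetype,
        psi_leaf = g$psi_leaf, slope1_leaf = g$slope1_leaf,
        slope2_leaf = g$slope2_leaf, e0_leaf = g$e0_leaf,
        psi_wp = g$psi_wp, slope1_wp = g$slope1_wp, slope2_wp = g$slope2_wp,
        e0_wp = g$e0_wp, a_gs = g$a_gs, phi_stom = g$phi_stom,
        a_max = g$a_max, g50 = g$g50, stringsAsFactors = FALSE
      )
      for (pi in seq_len(g$n_plants)) {
        plant <- sprintf("%s_p%d", acc, pi)
        set.seed(.derive_seed(config$seed, acc, plant))
        off_leaf <- stats::rnorm(1, 0, nz$intercept_leaf)
        off_wp <- stats::rnorm(1, 0, nz$intercept_wp)
        off_gs <- stats::rnorm(1, 0, nz$gs_plant)
        area <- config$leaf_area_m2 * stats::runif(1, 0.9, 1.1)

        v_leaf <- config$leaf_levels
        gs_ss <- pmax(g$a_gs + off_gs - g$phi_stom * log(v_leaf), 0.02)
        e_ss <- .steady_e(v_leaf, g$e0_leaf + off_leaf, g$slope1_leaf,
                          g$slope2_leaf, g$psi_leaf)
        a_ss <- g$a_max * gs_ss / (gs_ss + g$g50)

        tr_gs <- .step_trajectory(gs_ss, config$leaf_step_min,
                                  config$sample_leaf_s, tau_s)
        tr_e <- .step_trajectory(e_ss, config$leaf_step_min,
                                 config$sample_leaf_s, tau_s)
        tr_a <- .step_trajectory(a_ss, config$leaf_step_min,
                                 config$sample_leaf_s, tau_s)
        nrec <- length(tr_gs$time_s)
        vpd_leaf <- v_leaf[tr_gs$step]
        ge[[plant]] <- data.frame(
          plant = plant, accession = acc, time_s = tr_gs$time_s,
          gs = pmax(tr_gs$value + stats::rnorm(nrec, 0, nz$gs), 1e-4),
          E = tr_e$value + stats::rnorm(nrec, 0, nz$E),
          A = tr_a$value + stats::rnorm(nrec, 0, nz$A),
          t_leaf = config$temp_c,
          rh_percent = 100 * (1 - vpd_leaf / es),
          vpd_leaf = vpd_leaf, stringsAsFactors = FALSE
        )

        e_wp_ss <- .steady_e(config$chamber_levels, g$e0_wp + off_wp,
                             g$slope1_wp, g$slope2_wp, g$psi_wp)
        tr_wp <- .step_trajectory(e_wp_ss, config$chamber_step_min,
                                  config$sample_balance_s, tau_s)
        # g lost per sample: E (mmol m-2 s-1) * area * dt * M / 1000
        dm <- tr_wp$value * area * config$sample_balance_s * MOLAR_MASS_WATER / 1000
        mass_true <- config$start_mass_g - cumsum(dm) + dm[1]
        bal[[plant]] <- data.frame(
          plant = plant, accession = acc, time_s = tr_wp$time_s,
          mass_g = mass_true + stats::rnorm(length(dm), 0, nz$balance_g),
          mass_true_g = mass_true, stringsAsFactors = FALSE
        )
        la[[plant]] <- data.frame(plant = plant, leaf_area_m2 = area,
                                  stringsAsFactors = FALSE)
        plant_rows[[plant]] <- data.frame(
          plant = plant, accession = acc, group = gi,
          intercept_leaf = off_leaf, intercept_wp = off_wp,
          intercept_gs = off_gs, leaf_area_m2 = area, stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(
    gas_exchange = do.call(rbind, c(ge, make.row.names = FALSE)),
    balance = do.call(rbind, c(bal, make.row.names = FALSE)),
    leaf_areas = do.call(rbind, c(la, make.row.names = FALSE)),
    design_leaf = design_leaf, design_chamber = design_chamber,
    truth = list(accessions = do.call(rbind, c(acc_rows, make.row.names = FALSE)),
                 plants = do.call(rbind, c(plant_rows, make.row.names = FALSE)),
                 config = config)
  ), class = "synthetic_cohort")
}

#' Write a synthetic cohort to the CSV dialects the readers consume
#'
#' Emits `gas_exchange.csv`, `balance.csv`, `leaf_areas.csv`,
#' `design_leaf.csv`, `design_chamber.csv` and `truth.json` under `dir`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bal <- cohort$balance[, c("plant", "accession", "time_s", "mass_g")]
  write_output_table(cohort$gas_exchange, file.path(dir, "gas_exchange.csv"))
  write_output_table(bal, file.path(dir, "balance.csv"))
  write_output_table(cohort$leaf_areas, file.path(dir, "leaf_areas.csv"))
  write_output_table(cohort$design_leaf, file.path(dir, "design_leaf.csv"))
  write_output_table(cohort$design_chamber, file.path(dir, "design_chamber.csv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  truth$config$groups <- lapply(truth$config$groups, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Steady-scale simulation of one accession's segmented response
#'
#' Direct simulation at the steady-state scale (no time series): `n_plants`
#' plants measured at `levels`, response piecewise-linear in VPD with a
#' common breakpoint and slopes, Gaussian per-plant intercepts and Gaussian
#' observation noise. This is the design used for estimator-recovery and
#' test-calibration simulations.
#'
#' @param n_plants Number of plants.
#' @param levels VPD levels (kPa).
#' @param psi True breakpoint (kPa).
#' @param slope_before,slope_after True slopes (response units per kPa).
#' @param intercept Mean intercept.
#' @param intercept_sd Between-plant intercept SD.
#' @param noise_sd Observation noise SD.
#' @param seed Optional seed.
#' @return `data.frame` with `plant`, `vpd`, `E`.
#' @export
simulate_accession_response <- function(n_plants = 5,
                                        levels = c(0.91, 1.50, 2.09, 2.69, 3.28, 3.87),
                                        psi = 2.0, slope_before = 2.5,
                                        slope_after = 0.5, intercept = 1.0,
                                        intercept_sd = 0.3, noise_sd = 0.15,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offs <- stats::rnorm(n_plants, 0, intercept_sd)
  plant <- rep(sprintf("p%d", seq_len(n_plants)), each = length(levels))
  v <- rep(levels, times = n_plants)
  mu <- intercept + rep(offs, each = length(levels)) + slope_before * v +
    (slope_after - slope_before) * pmax(v - psi, 0)
  data.frame(plant = plant, vpd = v,
             E = mu + stats::rnorm(length(v), 0, noise_sd),
             stringsAsFactors = FALSE)
}

#' Closed-form phi_E implied by an accession's true parameters
#'
#' Evaluates the transpiration-reduction statistic analytically from the
#' generative piecewise-linear response: the baseline line through the two
#' lowest levels extrapolated to a target level, compared with the true
#' response there.
#'
#' @param e0,slope1,slope2,psi Generative parameters (intercept, slope
#'   before, slope change after, breakpoint).
#' @param levels VPD levels; the first two define the baseline.
#' @param target Target VPD (default: the last level).
#' @return phi_E value.
#' @export
truth_phi_e <- function(e0, slope1, slope2, psi, levels, target = max(levels)) {
  e <- function(v) .steady_e(v, e0, slope1, slope2, psi)
  v1 <- levels[1]; v2 <- levels[2]
  sl <- (e(v2) - e(v1)) / (v2 - v1)
  e_pred <- e(v1) + sl * (target - v1)
  1 - e(target) / e_pred
}

#' Check pipeline outputs against a cohort's ground-truth manifest
#'
#' Compares estimated breakpoints, slopes, stomatal reduction and (label
#' invariantly, via the adjusted Rand index) the recovered clustering
#' against the generative truth.
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param seg_leaf,seg_wp Optional outputs of [segmented_by_accession()].
#' @param stom Optional output of [stomatal_reduction()].
#' @param clusters Optional [kmeans_cluster()] result.
#' @param tol Named list of absolute tolerances: `psi` (kPa), `slope`,
#'   `phi_stom`.
#' @return `data.frame` of checks (`check`, `id`, `true`, `estimate`,
#'   `tol`, `pass`); attribute `pass` is the conjunction.
#' @export
ground_truth_check <- function(truth, seg_leaf = NULL, seg_wp = NULL,
                               stom = NULL, clusters = NULL,
                               tol = list(psi = 0.15, slope = 0.3, phi_stom = 0.05)) {
  acc <- truth$accessions
  rows <- list()
  add <- function(check, id, true, est, tl) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, id = id, true = true, estimate = est, tol = tl,
      pass = is.finite(est) && abs(est - true) <= tl, stringsAsFactors = FALSE)
  }
  seg_block <- function(seg, psi_col, s1_col, s2_col, label) {
    if (!all(seg$accession %in% acc$accession)) {
      stop("ground_truth_check: segmented fits contain unknown accession ids",
           call. = FALSE)
    }
    for (i in seq_len(nrow(seg))) {
      j <- match(seg$accession[i], acc$accession)
      add(paste0("psi_", label), seg$accession[i], acc[[psi_col]][j],
          seg$psi[i], tol$psi)
      add(paste0("slope_before_", label), seg$accession[i], acc[[s1_col]][j],
          seg$slope_before[i], tol$slope)
      add(paste0("slope_after_", label), seg$accession[i],
          acc[[s1_col]][j] + acc[[s2_col]][j], seg$slope_after[i], tol$slope)
    }
  }
  if (!is.null(seg_leaf)) seg_block(seg_leaf, "psi_leaf", "slope1_leaf", "slope2_leaf", "leaf")
  if (!is.null(seg_wp)) seg_block(seg_wp, "psi_wp", "slope1_wp", "slope2_wp", "whole_plant")
  if (!is.null(stom)) {
    means <- tapply(stom$phi_stom, stom$accession, mean)
    if (!all(names(means) %in% acc$accession)) {
      stop("ground_truth_check: stomatal fits contain unknown accession ids",
           call. = FALSE)
    }
    for (id in names(means)) {
      j <- match(id, acc$accession)
      add("phi_stom", id, acc$phi_stom[j], unname(means[[id]]), tol$phi_stom)
    }
  }
  if (!is.null(clusters)) {
    ids <- names(clusters$cluster)
    if (!all(ids %in% acc$accession)) {
      stop("ground_truth_check: clustering contains unknown accession ids",
           call. = FALSE)
    }
    ari <- mclust::adjustedRandIndex(clusters$cluster,
                                     acc$group[match(ids, acc$accession)])
    rows[[length(rows) + 1]] <- data.frame(
      check = "cluster_ari", id = "all", true = 1, estimate = ari, tol = 0,
      pass = isTRUE(all.equal(ari, 1)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "pass") <- all(out$pass)
  out
}
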