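# Broken-stick (segmented) regression of a response on VPD with an
# estimated breakpoint psi, per-plant intercepts, delta-method breakpoint
# standard errors, and the Davies test of the linear null.
#
# Model: y = alpha_plant + beta1 * x + beta2 * (x - psi)_+ + eps.
# Fitted by iterative linearization: at a working psi, regress on
# U = (x - psi)_+ and V = -1{x > psi}; the coefficient gamma of V estimates
# beta2 * (psi_true - psi), so psi is updated by gamma / beta2 until the
# update is negligible. Per-plant intercepts enter as fixed dummy-coded
# offsets sharing slopes and psi: with 3-8 plants per accession a
# variance-component fit is fragile, and the estimands (psi, slopes) are
# unchanged under this fixed-effects approximation.

# Least-squares on an explicit design matrix with coefficient covariance.
.lin_fit <- function(X, y) {
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL) # rank deficient
  XtXinv <- chol2inv(ch)
  coef <- drop(XtXinv %*% crossprod(X, y))
  names(coef) <- colnames(X)
  res <- y - drop(X %*% coef)
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) rss / df else NA_real_
  list(coef = coef, rss = rss, df = df, sigma2 = sigma2,
       vcov = XtXinv * sigma2)
}

.plant_dummies <- function(plant, n) {
  if (is.null(plant)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    f <- factor(plant)
    stats::model.matrix(~ 0 + f)
  }
}

#' Profile residual sum of squares of the segmented model
#'
#' RSS of the least-squares fit of `y` on per-plant intercepts, `x` and
#' `(x - psi)_+` at each fixed candidate breakpoint. Diagnostic companion to
#' [fit_segmented()]: the fitted psi should sit at the profile minimum.
#'
#' @param x Numeric predictor (VPD, kPa).
#' @param y Numeric response (transpiration rate).
#' @param psi_grid Candidate breakpoints.
#' @param plant Optional plant ids for per-plant intercepts.
#' @return Numeric vector of RSS values, one per candidate.
#' @export
profile_rss <- function(x, y, psi_grid, plant = NULL) {
  P <- .plant_dummies(plant, length(x))
  vapply(psi_grid, function(psi) {
    fit <- .lin_fit(cbind(P, x = x, U = pmax(x - psi, 0)), y)
    if (is.null(fit)) Inf else fit$rss
  }, numeric(1))
}

.fit_from_start <- function(x, y, P, psi, lo, hi, tol, max_iter) {
  converged <- FALSE; n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    U <- pmax(x - psi, 0)
    V <- -as.numeric(x > psi)
    fit <- .lin_fit(cbind(P, x = x, U = U, V = V), y)
    if (is.null(fit)) break
    beta2 <- fit$coef[["U"]]; gamma <- fit$coef[["V"]]
    if (!is.finite(beta2) || abs(beta2) < 1e-12) break
    psi_new <- min(max(psi + gamma / beta2, lo), hi)
    moved <- abs(psi_new - psi)
    psi <- psi_new
    if (moved < tol) { converged <- TRUE; break }
  }
  # RSS of the model without the working regressor V, at the final psi
  final <- .lin_fit(cbind(P, x = x, U = pmax(x - psi, 0)), y)
  list(psi = psi, rss = if (is.null(final)) Inf else final$rss,
       converged = converged, n_iter = n_iter)
}

#' Fit a segmented (broken-stick) regression with an estimated breakpoint
#'
#' Estimates `y = alpha_plant + beta1 * x + beta2 * (x - psi)_+` by
#' iterative linearization (see file header), with the breakpoint
#' constrained to the interior of the observed `x` range. The fit is
#' attempted from the median, 25th and 75th percentile of `x` and the
#' best-RSS converged solution is kept. The breakpoint standard error is the
#' delta-method `SE(gamma) / |beta2|` at the solution.
#'
#' @param x Numeric predictor (VPD, kPa); needs >= 4 distinct values.
#' @param y Numeric response (transpiration rate, same length).
#' @param plant Optional plant ids; per-plant fixed intercepts are fitted.
#' @param psi0 Initial breakpoint, or `"auto"` (multi-start from the x
#'   quartiles, recommended).
#' @param tol Convergence tolerance on the psi update, kPa (default 1e-6).
#' @param max_iter Maximum linearization iterations per start (default 50).
#' @return Object of class `segmented_fit`: `psi`, `psi_se`, `slope_before`
#'   (+`_se`), `slope_after` (+`_se`), `beta2` (+`_se`), named per-plant
#'   `intercepts`, `rss`, `sigma2`, `df_residual`, `converged`, `n_iter`,
#'   `flags` (any of `"boundary"`, `"no_slope_change"`,
#'   `"interval_identified"`), `bounds`, and the data (`x`, `y`, `plant`)
#'   for prediction.
#' @seealso [davies_test()] for the significance of the slope change,
#'   [profile_rss()] for the RSS profile.
#' @export
fit_segmented <- function(x, y, plant = NULL, psi0 = "auto",
                          tol = 1e-6, max_iter = 50) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!is.null(plant)) plant <- plant[keep]
  xs <- sort(unique(x))
  if (length(xs) < 4) {
    stop("fit_segmented needs >= 4 distinct x values", call. = FALSE)
  }
  delta <- min(diff(xs))
  lo <- min(x) + delta; hi <- max(x) - delta
  if (lo >= hi) stop("x values too clustered to bracket a breakpoint", call. = FALSE)
  P <- .plant_dummies(plant, length(x))

  # The linearization is only locally convergent and the RSS profile can be
  # multimodal on noisy small samples. The profile's knots are the observed
  # x values, so "auto" starts one refinement in every interval between
  # consecutive interior distinct x values (its midpoint) and keeps the
  # best-RSS solution across starts.
  starts <- if (identical(psi0, "auto")) {
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    unique(pmin(pmax(mids, lo), hi))
  } else {
    min(max(as.numeric(psi0), lo), hi)
  }
  cands <- lapply(starts, .fit_from_start, x = x, y = y, P = P,
                  lo = lo, hi = hi, tol = tol, max_iter = max_iter)
  # The linearization update is not a descent step and can leave the basin
  # holding the global minimum, so each interior inter-knot interval is also
  # searched directly by bounded golden-section on the profile RSS.
  if (identical(psi0, "auto")) {
    prss <- function(psi) {
      fit <- .lin_fit(cbind(P, x = x, U = pmax(x - psi, 0)), y)
      if (is.null(fit)) Inf else fit$rss
    }
    br <- unique(pmin(pmax(xs, lo), hi))
    for (i in seq_len(length(br) - 1)) {
      if (br[i + 1] - br[i] < 1e-9) next
      op <- stats::optimize(prss, c(br[i], br[i + 1]), tol = 1e-8)
      cands[[length(cands) + 1]] <- list(psi = op$minimum, rss = op$objective,
                                         converged = TRUE, n_iter = NA_integer_)
    }
  }
  rsss <- vapply(cands, `[[`, numeric(1), "rss")
  sol <- cands[[which.min(rsss)]]
  psi <- sol$psi
  flags <- character(0)

  # Flat-RSS (interval-identified) check: with few discrete levels the RSS
  # can be constant between two adjacent observed x; report the interval
  # midpoint in that case.
  xl <- if (any(xs < psi)) max(xs[xs < psi]) else NA_real_
  xr <- if (any(xs > psi)) min(xs[xs > psi]) else NA_real_
  if (is.finite(xl) && is.finite(xr) && !any(xs == psi)) {
    probes <- seq(xl, xr, length.out = 7)[2:6]
    pr <- profile_rss(x, y, probes, plant = plant)
    if (max(pr) - min(pr) <= 1e-10 * (1 + max(pr))) {
      psi <- (xl + xr) / 2
      flags <- c(flags, "interval_identified")
    }
  }
  if (psi <= lo + tol || psi >= hi - tol) flags <- c(flags, "boundary")

  # Final models at the solution: with V for SE(psi), without V for slopes.
  U <- pmax(x - psi, 0); V <- -as.numeric(x > psi)
  with_v <- .lin_fit(cbind(P, x = x, U = U, V = V), y)
  final <- .lin_fit(cbind(P, x = x, U = U), y)
  if (is.null(final)) stop("segmented design matrix is rank deficient", call. = FALSE)
  k <- ncol(P)
  b1 <- final$coef[["x"]]; b2 <- final$coef[["U"]]
  v <- final$vcov
  slope_scale <- max(abs(b1), abs(b1 + b2), 1)
  no_change <- abs(b2) < 1e-8 * slope_scale
  if (no_change) flags <- c(flags, "no_slope_change")
  psi_se <- if (!no_change && !is.null(with_v) && is.finite(with_v$sigma2)) {
    sqrt(with_v$vcov[k + 3, k + 3]) / abs(with_v$coef[["U"]])
  } else NA_real_

  structure(list(
    psi = psi, psi_se = psi_se,
    slope_before = b1, slope_before_se = sqrt(v[k + 1, k + 1]),
    slope_after = b1 + b2,
    slope_after_se = sqrt(v[k + 1, k + 1] + v[k + 2, k + 2] + 2 * v[k + 1, k + 2]),
    beta2 = b2, beta2_se = sqrt(v[k + 2, k + 2]),
    intercepts = stats::setNames(final$coef[seq_len(k)],
                                 sub("^f", "", colnames(P))),
    rss = final$rss, sigma2 = final$sigma2, df_residual = final$df,
    converged = sol$converged, n_iter = sol$n_iter, flags = flags,
    bounds = c(lo, hi), n = length(x),
    x = x, y = y, plant = plant
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented regression fit\n")
  cat(sprintf("  breakpoint psi: %.4f kPa (SE %.4f)%s\n", x$psi, x$psi_se,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  cat(sprintf("  slope before:   %.4f (SE %.4f)\n", x$slope_before, x$slope_before_se))
  cat(sprintf("  slope after:    %.4f (SE %.4f)\n", x$slope_after, x$slope_after_se))
  cat(sprintf("  n = %d, plants = %d, RSS = %.6g, converged = %s (%d iter)\n",
              x$n, length(x$intercepts), x$rss, x$converged, x$n_iter))
  invisible(x)
}

#' Predicted mean response of a segmented fit
#'
#' @param object A `segmented_fit`.
#' @param x New predictor values.
#' @param plant Plant whose intercept to use (default: the first).
#' @param ... Unused.
#' @return Predicted response; continuous in `x` at the breakpoint.
#' @export
predict_segmented <- function(object, x, plant = NULL, ...) {
  a <- if (is.null(plant)) object$intercepts[1] else object$intercepts[[as.character(plant)]]
  unname(a + object$slope_before * x + object$beta2 * pmax(x - object$psi, 0))
}

#' Davies test for a breakpoint present only under the alternative
#'
#' Tests the linear null (`beta2 = 0`) against the segmented alternative.
#' Since psi is undefined under the null, the Wald t statistic for `beta2`
#' is computed at `K` fixed candidate breakpoints equally spaced between the
#' 2nd and (n-1)th ordered distinct `x`; with `M` the maximum of the
#' absolute statistics and `V` their total variation over the grid, the
#' two-sided Davies upper bound is
#' `p = min(1, 2 * (pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi)))`.
#' The bound is conservative (null rejection below the nominal level).
#'
#' @inheritParams fit_segmented
#' @param K Number of candidate breakpoints (default 10); reduced with a
#'   warning when fewer than `K + 2` distinct `x` values exist.
#' @return Object of class `davies_test`: `p_value`, `statistic` (M),
#'   `grid`, `stats` (signed t per candidate), `K`.
#' @export
davies_test <- function(x, y, plant = NULL, K = 10) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!is.null(plant)) plant <- plant[keep]
  xs <- sort(unique(x))
  if (length(xs) < 4) stop("davies_test needs >= 4 distinct x values", call. = FALSE)
  if (length(xs) < K + 2) {
    K <- length(xs) - 2L
    warning(sprintf("fewer than K + 2 distinct x values; K reduced to %d", K),
            call. = FALSE)
  }
  grid <- seq(xs[2], xs[length(xs) - 1], length.out = K)
  P <- .plant_dummies(plant, length(x))
  tt <- vapply(grid, function(psi) {
    fit <- .lin_fit(cbind(P, x = x, U = pmax(x - psi, 0)), y)
    if (is.null(fit) || fit$df <= 0) return(NA_real_)
    se <- sqrt(fit$vcov[ncol(P) + 2, ncol(P) + 2])
    b <- fit$coef[["U"]]
    # an (essentially) perfect fit makes the t ratio 0/0: no slope change
    # means no evidence, a real slope change means overwhelming evidence
    if (fit$rss <= 1e-12 * (1 + sum(y^2)) || !is.finite(se) || se == 0) {
      scale <- max(abs(fit$coef[["x"]]), 1)
      if (abs(b) < 1e-8 * scale) 0 else sign(b) * Inf
    } else b / se
  }, numeric(1))
  s <- abs(tt[is.finite(tt)])
  if (!length(s)) s <- Inf
  M <- max(abs(tt), na.rm = TRUE)
  Vt <- sum(abs(diff(abs(tt))), na.rm = TRUE)
  p <- if (!is.finite(M)) 0 else {
    min(max(2 * (stats::pnorm(-M) + Vt * exp(-M^2 / 2) / sqrt(8 * pi)), 0), 1)
  }
  structure(list(p_value = p, statistic = M, grid = grid, stats = tt, K = K),
            class = "davies_test")
}

#' @export
print.davies_test <- function(x, ...) {
  cat(sprintf("Davies test: max |t| = %.3f over %d candidate breakpoints, p = %.4g\n",
              x$statistic, x$K, x$p_value))
  invisible(x)
}

#' Segmented fits and Davies tests per accession
#'
#' Convenience driver: fits [fit_segmented()] and [davies_test()] per
#' accession on a steady-state (leaf) or rate (whole-plant) table and
#' returns one summary row per accession.
#'
#' @param table `data.frame` with `accession`, `plant`, `vpd` and the
#'   response in `response_col`.
#' @param response_col Name of the response column (`"E"` for leaf tables,
#'   `"e_rate"` for whole-plant tables).
#' @param measurement_level Label stored in the output (e.g. `"leaf"`).
#' @return `data.frame`: one row per accession with psi, slopes, their SEs,
#'   RSS, convergence flags and the Davies p-value.
#' @export
segmented_by_accession <- function(table, response_col = "E",
                                   measurement_level = "leaf") {
  out <- lapply(split(table, table$accession), function(df) {
    ok <- is.finite(df$vpd) & is.finite(df[[response_col]])
    df <- df[ok, , drop = FALSE]
    fit <- fit_segmented(df$vpd, df[[response_col]], plant = df$plant)
    dv <- davies_test(df$vpd, df[[response_col]], plant = df$plant)
    data.frame(accession = df$accession[1], measurement_level = measurement_level,
               psi = fit$psi, psi_se = fit$psi_se,
               slope_before = fit$slope_before, slope_before_se = fit$slope_before_se,
               slope_after = fit$slope_after, slope_after_se = fit$slope_after_se,
               rss = fit$rss, converged = fit$converged,
               flags = paste(fit$flags, collapse = ";"),
               davies_p = dv$p_value, n = fit$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
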