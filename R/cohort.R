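# Accession-level cohort analysis: the 16-variable trait matrix, k-means
# clustering with mass random restarts, PCA projection with an ordered
# loadings table, per-level one-way ANOVA with Benjamini-Hochberg
# correction, and trait-trait correlations.

#' Assemble the accession x trait matrix for clustering
#'
#' Builds the 16-variable trait set from accession means of the pipeline
#' outputs: limitation of A at leaf levels 2-6, transpiration reduction
#' (phi_E) at the three high leaf levels and the top whole-plant level,
#' breakpoint and both slopes at leaf and whole-plant level, and the
#' stomatal reduction. Columns are then z-scored (mean 0, SD 1).
#'
#' @param a_limitation Output of [limitation_of_a()] (leaf).
#' @param phi_e_leaf Output of [phi_e()] (leaf).
#' @param phi_e_wp Output of [phi_e_whole_plant()].
#' @param seg_leaf,seg_wp Outputs of [segmented_by_accession()] for leaf and
#'   whole-plant responses.
#' @param stom Output of [stomatal_reduction()].
#' @param lim_levels Leaf levels of the A-limitation traits (default 2:6).
#' @param phi_levels Leaf levels of the phi_E traits (default 4:6).
#' @param on_missing `"drop"` (default) removes accessions missing any
#'   trait with a message; `"impute"` replaces missing entries by the
#'   column mean before scaling.
#' @return Numeric matrix, accessions in rows, scaled to column mean 0 /
#'   SD 1, with attributes `center` and `scale`. Constant columns are an
#'   error.
#' @export
build_trait_matrix <- function(a_limitation, phi_e_leaf, phi_e_wp,
                               seg_leaf, seg_wp, stom,
                               lim_levels = 2:6, phi_levels = 4:6,
                               on_missing = c("drop", "impute")) {
  on_missing <- match.arg(on_missing)
  accs <- sort(unique(c(a_limitation$accession, seg_leaf$accession)))
  grab <- function(df, value, level = NULL) {
    if (!is.null(level)) df <- df[df$level == level, , drop = FALSE]
    if (!"plant" %in% names(df)) {
      out <- df[[value]][match(accs, df$accession)]
    } else {
      m <- tapply(df[[value]], df$accession, mean, na.rm = TRUE)
      out <- as.numeric(m[accs])
    }
    out
  }
  cols <- list()
  for (lv in lim_levels) {
    cols[[sprintf("a_limitation_L%d", lv)]] <- grab(a_limitation, "limitation", lv)
  }
  for (lv in phi_levels) {
    cols[[sprintf("phi_e_leaf_L%d", lv)]] <- grab(phi_e_leaf, "phi_e", lv)
  }
  cols[["phi_e_whole_plant"]] <- grab(phi_e_wp, "phi_e",
                                      max(phi_e_wp$level))
  cols[["breakpoint_leaf"]] <- grab(seg_leaf, "psi")
  cols[["breakpoint_whole_plant"]] <- grab(seg_wp, "psi")
  cols[["slope_before_leaf"]] <- grab(seg_leaf, "slope_before")
  cols[["slope_before_whole_plant"]] <- grab(seg_wp, "slope_before")
  cols[["slope_after_leaf"]] <- grab(seg_leaf, "slope_after")
  cols[["slope_after_whole_plant"]] <- grab(seg_wp, "slope_after")
  cols[["stomatal_reduction"]] <- grab(stom, "phi_stom")
  m <- do.call(cbind, cols)
  rownames(m) <- accs

  if (anyNA(m)) {
    if (on_missing == "drop") {
      bad <- rownames(m)[apply(m, 1, anyNA)]
      message(sprintf("build_trait_matrix: dropped accession(s) with missing traits: %s",
                      paste(bad, collapse = ", ")))
      m <- m[!rownames(m) %in% bad, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(m))) {
        nas <- is.na(m[, j])
        m[nas, j] <- mean(m[, j], na.rm = TRUE)
      }
    }
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("constant trait column(s): ", paste(colnames(m)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  scaled <- scale(m)
  out <- scaled[, , drop = FALSE]
  attr(out, "center") <- attr(scaled, "scaled:center")
  attr(out, "scale") <- attr(scaled, "scaled:scale")
  out
}

#' K-means clustering with mass random restarts
#'
#' Lloyd's algorithm started from `n_restarts` random sets of k distinct
#' rows; the solution with minimal total within-cluster sum of squares is
#' kept. Restarts that collapse to an empty cluster are discarded and
#' counted. Deterministic given `seed`.
#'
#' @param m Scaled trait matrix ([build_trait_matrix()]).
#' @param k Number of clusters (treated as a configured input; no automatic
#'   selection).
#' @param n_restarts Number of random centre sets (default 10000).
#' @param seed Integer RNG seed.
#' @return Object of class `kmeans_restarts`: `k`, named `cluster`
#'   assignments, `centers`, `tot_withinss`, `n_restarts`, `n_discarded`.
#' @export
kmeans_cluster <- function(m, k = 3, n_restarts = 10000, seed = 1) {
  if (k > nrow(m)) stop("k cannot exceed the number of accessions", call. = FALSE)
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  set.seed(seed)
  best <- NULL; discarded <- 0L
  for (i in seq_len(n_restarts)) {
    centers <- m[sample.int(nrow(m), k), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = centers, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(km) || any(km$size == 0)) { discarded <- discarded + 1L; next }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("all k-means restarts failed", call. = FALSE)
  structure(list(k = k,
                 cluster = stats::setNames(best$cluster, rownames(m)),
                 centers = best$centers, tot_withinss = best$tot.withinss,
                 n_restarts = n_restarts, n_discarded = discarded),
            class = "kmeans_restarts")
}

#' @export
print.kmeans_restarts <- function(x, ...) {
  cat(sprintf("k-means (k = %d, %d restarts, %d discarded): within-SS %.4f\n",
              x$k, x$n_restarts, x$n_discarded, x$tot_withinss))
  print(x$cluster)
  invisible(x)
}

#' Silhouette-vs-k diagnostic
#'
#' Mean silhouette width (Euclidean) for a range of k, emitted as a
#' diagnostic only; k itself stays a configured input.
#'
#' @param m Scaled trait matrix.
#' @param ks Candidate k values (default `2:5`).
#' @param n_restarts,seed Passed to [kmeans_cluster()].
#' @return `data.frame` with `k` and `mean_silhouette`.
#' @export
silhouette_by_k <- function(m, ks = 2:5, n_restarts = 100, seed = 1) {
  d <- as.matrix(stats::dist(m))
  sil_for <- function(assign) {
    mean(vapply(seq_len(nrow(m)), function(i) {
      own <- assign == assign[i]; own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(assign), assign[i]),
                      function(g) mean(d[i, assign == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
  }
  data.frame(k = ks, mean_silhouette = vapply(ks, function(k) {
    sil_for(kmeans_cluster(m, k, n_restarts, seed)$cluster)
  }, numeric(1)))
}

#' Principal-component projection with an ordered loadings table
#'
#' PCA of the already-scaled trait matrix. Loadings (unit-norm
#' eigenvectors) are reported for the first two components, ordered by the
#' absolute PC1 loading; the sign of each component is fixed by making its
#' largest-magnitude loading positive so tables are reproducible.
#'
#' @param m Scaled trait matrix.
#' @return List with `scores` (accessions x components), `loadings`
#'   (variables x components), `sdev`, `var_explained`, and
#'   `loadings_table` (`data.frame` with `variable`, `PC1`, `PC2` sorted by
#'   `|PC1|` descending).
#' @export
pca_project <- function(m) {
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(rownames(pc$rotation))) {
    rownames(pc$rotation) <- paste0("V", seq_len(nrow(pc$rotation)))
  }
  n_show <- min(2, ncol(pc$rotation))
  lt <- data.frame(variable = rownames(pc$rotation),
                   pc$rotation[, seq_len(n_show), drop = FALSE],
                   row.names = NULL)
  lt <- lt[order(-abs(lt$PC1)), , drop = FALSE]
  rownames(lt) <- NULL
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       var_explained = ve, loadings_table = lt)
}

#' Per-level one-way ANOVA with Benjamini-Hochberg correction
#'
#' Tests for accession differences separately at each VPD level by a
#' one-way ANOVA F-test, then adjusts the family of per-level p-values
#' (one measurement type = one family) by Benjamini-Hochberg.
#'
#' @param df `data.frame` with columns `accession`, `level`, and the value
#'   in `value_col`.
#' @param value_col Name of the response column.
#' @return `data.frame` with `level`, `df_between`, `df_within`,
#'   `f_statistic`, `p_value`, `p_adjusted`. Levels with fewer than 2
#'   accessions having >= 2 plants are skipped with a warning.
#' @export
anova_bh <- function(df, value_col = "value") {
  rows <- list()
  for (lev_df in split(df, df$level)) {
    lev_df <- lev_df[!is.na(lev_df[[value_col]]), , drop = FALSE]
    counts <- table(lev_df$accession)
    if (sum(counts >= 2) < 2) {
      warning(sprintf("anova_bh: level %s skipped (insufficient replication)",
                      lev_df$level[1]), call. = FALSE)
      next
    }
    fit <- stats::aov(v ~ accession,
                      data = data.frame(v = lev_df[[value_col]],
                                        accession = factor(lev_df$accession)))
    tab <- summary(fit)[[1]]
    rows[[length(rows) + 1]] <- data.frame(
      level = lev_df$level[1], df_between = tab$Df[1], df_within = tab$Df[2],
      f_statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("anova_bh: no level had enough replication", call. = FALSE)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Squared Pearson correlation between two accession-level traits
#'
#' @param x,y Numeric vectors over the same accessions (n >= 3).
#' @return List with `r_squared`, `p_value` (two-sided t-test), `n`. Zero
#'   variance in either trait yields `NA`s with a warning.
#' @export
correlation_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("correlation_r2 needs >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: zero variance", call. = FALSE)
    return(list(r_squared = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y)
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value, n = length(x))
}
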