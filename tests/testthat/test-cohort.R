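scaled_blob_matrix <- function(centers, n_per, sd = 0.05, seed = 4, p = 16) {
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_along(centers), function(g) {
    matrix(rnorm(n_per[g] * p, centers[g], sd), n_per[g], p)
  }))
  rownames(m) <- sprintf("acc%02d", seq_len(nrow(m)))
  scale(m)
}

test_that("trait matrix assembles 16 z-scored columns from pipeline outputs", {
  accs <- sprintf("acc%d", 1:4)
  lim <- expand.grid(accession = accs, level = 1:6, stringsAsFactors = FALSE)
  set.seed(2); lim$limitation <- runif(nrow(lim))
  pe <- expand.grid(plant = c("x", "y"), accession = accs, level = 4:6,
                    stringsAsFactors = FALSE)
  pe$phi_e <- runif(nrow(pe))
  pw <- expand.grid(plant = c("x", "y"), accession = accs, level = 5,
                    stringsAsFactors = FALSE)
  pw$phi_e <- runif(nrow(pw))
  seg <- data.frame(accession = accs, psi = runif(4, 1.6, 2.6),
                    slope_before = runif(4, 1, 3), slope_after = runif(4, -1, 1))
  stom <- data.frame(plant = rep(c("x", "y"), 4),
                     accession = rep(accs, each = 2), phi_stom = runif(8))
  tm <- build_trait_matrix(lim, pe, pw, seg, seg, stom)
  expect_equal(dim(tm), c(4, 16))
  expect_equal(unname(colMeans(tm)), rep(0, 16), tolerance = 1e-10)
  expect_equal(unname(apply(tm, 2, sd)), rep(1, 16), tolerance = 1e-10)

  lim$limitation <- 0.5 # constant trait
  expect_error(build_trait_matrix(lim, pe, pw, seg, seg, stom), "constant")
})

test_that("z-scoring matches a hand-computed 3x2 case", {
  m <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2)
  s <- scale(m)
  expect_equal(s[, 1], (c(1, 2, 3) - 2) / 1, ignore_attr = TRUE)
  expect_equal(s[, 2], (c(10, 20, 60) - 30) / sd(c(10, 20, 60)),
               ignore_attr = TRUE)
})

test_that("k-means recovers a planted partition and respects restart monotonicity", {
  m <- scaled_blob_matrix(centers = c(-5, 0, 5), n_per = c(1, 2, 6))
  truth <- rep(1:3, times = c(1, 2, 6))
  km <- kmeans_cluster(m, k = 3, n_restarts = 200, seed = 7)
  expect_equal(mclust::adjustedRandIndex(km$cluster, truth), 1)

  km1 <- kmeans_cluster(m, k = 3, n_restarts = 1, seed = 7)
  expect_lte(km$tot_withinss, km1$tot_withinss)

  # n = k distinct points: perfect fit
  mm <- scale(matrix(c(0, 5, 10, 0, 5, 10), 3, 2))
  expect_equal(kmeans_cluster(mm, k = 3, n_restarts = 5, seed = 1)$tot_withinss,
               0, tolerance = 1e-12)

  expect_error(kmeans_cluster(mm, k = 4), "exceed")
})

test_that("k-means is deterministic given the seed", {
  m <- scaled_blob_matrix(centers = c(-2, 0, 2), n_per = c(3, 3, 3), sd = 0.5)
  a <- kmeans_cluster(m, 3, n_restarts = 50, seed = 42)
  b <- kmeans_cluster(m, 3, n_restarts = 50, seed = 42)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$tot_withinss, b$tot_withinss)
})

test_that("PCA projection matches a brute-force eigendecomposition", {
  set.seed(6)
  m <- scale(matrix(rnorm(30), 10, 3))
  pc <- pca_project(m)
  ev <- eigen(crossprod(m) / (nrow(m) - 1))
  expect_equal(pc$sdev^2, ev$values, tolerance = 1e-10)
  for (j in 1:3) { # loadings match up to sign
    expect_equal(abs(sum(pc$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(unname(apply(pc$loadings, 2, function(v) sum(v^2))),
               rep(1, 3), tolerance = 1e-12)
})

test_that("PCA explains all variance for collinear data and preserves distances", {
  t_ <- seq(-2, 2, length.out = 8)
  m <- cbind(t_, 2 * t_, -t_) # exact line in trait space
  pc <- pca_project(m)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)

  set.seed(13)
  m2 <- scale(matrix(rnorm(50), 10, 5))
  pc2 <- pca_project(m2)
  expect_equal(as.matrix(dist(pc2$scores)), as.matrix(dist(m2)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("loadings table is ordered by absolute PC1 loading with fixed signs", {
  set.seed(17)
  m <- scale(matrix(rnorm(9 * 5), 9, 5,
                    dimnames = list(NULL, paste0("v", 1:5))))
  lt <- pca_project(m)$loadings_table
  expect_true(all(diff(abs(lt$PC1)) <= 1e-12))
  pc <- pca_project(m)
  for (j in 1:2) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("per-level ANOVA separates planted accession differences and BH adjusts", {
  set.seed(23)
  mk <- function(shift) {
    d <- expand.grid(plant = 1:5, accession = c("a", "b", "c"), level = 1:4,
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d), 0, 1) +
      shift * (d$accession == "c") * (d$level >= 3)
    d
  }
  null <- anova_bh(mk(0))
  expect_true(all(null$p_adjusted >= null$p_value - 1e-15))
  expect_true(all(diff(null$p_adjusted[order(null$p_value)]) >= -1e-15))

  strong <- anova_bh(mk(5))
  expect_lt(strong$p_adjusted[strong$level == 4], 0.01)
  expect_gt(null$p_value[1], 0.05) # typical null level (seeded)

  tiny <- data.frame(plant = 1:4, accession = c("a", "a", "b", "b"),
                     level = 1, value = rnorm(4))
  expect_equal(nrow(anova_bh(tiny)), 1)
  expect_equal(anova_bh(tiny)$p_adjusted, anova_bh(tiny)$p_value)
})

test_that("trait correlations are sign-blind with exact and null behaviour", {
  x <- 1:9
  expect_equal(correlation_r2(x, 2 * x + 1)$r_squared, 1)
  expect_equal(correlation_r2(x, -x)$r_squared, 1)
  expect_warning(out <- correlation_r2(x, rep(1, 9)), "zero variance")
  expect_true(is.na(out$r_squared))

  set.seed(41)
  r2s <- replicate(200, correlation_r2(rnorm(9), rnorm(9))$r_squared)
  expect_lt(mean(r2s), 0.25) # E[R2] = 1/(n-1) = 0.125 under independence
})
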