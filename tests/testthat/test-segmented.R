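test_that("noiseless piecewise-linear data is recovered exactly", {
  x <- c(1, 1.5, 2, 2.5, 3, 3.5)
  y <- c(3, 4, 5, 5.25, 5.5, 5.75) # psi 2, slopes 2 then 0.5
  fit <- fit_segmented(x, y)
  expect_equal(fit$psi, 2.0, tolerance = 1e-6)
  expect_equal(fit$slope_before, 2.0, tolerance = 1e-8)
  expect_equal(fit$slope_after, 0.5, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12)
})

test_that("fits are invariant to shifting the response", {
  x <- c(1, 1.5, 2, 2.5, 3, 3.5)
  y <- c(3, 4, 5, 5.25, 5.5, 5.75)
  f0 <- fit_segmented(x, y)
  f1 <- fit_segmented(x, y + 11.5)
  expect_equal(f1$psi, f0$psi, tolerance = 1e-8)
  expect_equal(f1$slope_before, f0$slope_before, tolerance = 1e-8)
  expect_equal(f1$slope_after, f0$slope_after, tolerance = 1e-8)
  expect_equal(unname(f1$intercepts), unname(f0$intercepts) + 11.5,
               tolerance = 1e-8)
})

test_that("the iterative fit matches the exhaustive grid oracle on a noisy instance", {
  set.seed(55)
  x <- rep(c(0.91, 1.5, 2.09, 2.69, 3.28, 3.87), each = 4)
  y <- 1 + 2.4 * x - 2.1 * pmax(x - 2.2, 0) + rnorm(length(x), 0, 0.1)
  fit <- fit_segmented(x, y)
  oracle <- grid_search_psi(x, y)
  expect_lt(abs(fit$psi - oracle$psi), 1e-3)
  expect_lte(fit$rss, oracle$rss + 1e-8)
})

test_that("per-plant intercept offsets are recovered", {
  set.seed(8)
  lev <- c(0.91, 1.5, 2.09, 2.69, 3.28, 3.87)
  offs <- c(p1 = -0.4, p2 = 0, p3 = 0.6)
  d <- expand.grid(plant = names(offs), vpd = lev, stringsAsFactors = FALSE)
  d$E <- 1 + offs[d$plant] + 2.5 * d$vpd - 2 * pmax(d$vpd - 2, 0)
  fit <- fit_segmented(d$vpd, d$E, plant = d$plant)
  expect_equal(diff(unname(fit$intercepts)), diff(unname(offs)) + c(0, 0),
               tolerance = 1e-6)
  expect_equal(fit$psi, 2, tolerance = 1e-6)
})

test_that("the fitted mean function is continuous at the breakpoint", {
  set.seed(21)
  x <- rep(c(0.91, 1.5, 2.09, 2.69, 3.28, 3.87), each = 5)
  y <- 1 + 2.5 * x - 2 * pmax(x - 2, 0) + rnorm(30, 0, 0.15)
  fit <- fit_segmented(x, y)
  eps <- 1e-12
  gap <- abs(predict_segmented(fit, fit$psi + eps) -
               predict_segmented(fit, fit$psi - eps))
  expect_lt(gap, 1e-10)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(fit_segmented(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  # exactly linear noiseless data has no slope change
  x <- c(1, 1.5, 2, 2.5, 3, 3.5)
  fit <- fit_segmented(x, 1 + 2 * x)
  expect_true("no_slope_change" %in% fit$flags)
  expect_true(is.na(fit$psi_se))
})

test_that("Davies test is exact-null safe and significant under a strong break", {
  x <- c(1, 1.5, 2, 2.5, 3, 3.5)
  dv_null <- suppressWarnings(davies_test(x, 1 + 2 * x))
  expect_equal(dv_null$p_value, 1)
  expect_equal(dv_null$statistic, 0)

  set.seed(3)
  xx <- rep(c(0.91, 1.5, 2.09, 2.69, 3.28, 3.87), each = 5)
  yy <- 1 + 2.5 * xx - 2 * pmax(xx - 2, 0) + rnorm(30, 0, 0.15)
  dv <- suppressWarnings(davies_test(xx, yy))
  expect_lt(dv$p_value, 0.05)
  expect_warning(davies_test(xx, yy), "K reduced")
})

test_that("Davies p-values stay in [0,1] across random small instances", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(10:30, 1)
    x <- sort(runif(n, 1, 4))
    y <- rnorm(n)
    p <- suppressWarnings(davies_test(x, y)$p_value)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("Davies rejection rate is monotone in the slope change", {
  set.seed(445)
  lev <- c(0.91, 1.5, 2.09, 2.69, 3.28, 3.87)
  rej <- vapply(c(0, 0.5, 1, 2), function(b2) {
    mean(replicate(500, {
      d <- simulate_accession_response(5, lev, psi = 2, slope_before = 2,
                                       slope_after = 2 - b2, intercept = 1,
                                       intercept_sd = 0, noise_sd = 0.2)
      suppressWarnings(davies_test(d$vpd, d$E, plant = d$plant)$p_value) < 0.05
    }))
  }, numeric(1))
  # allow one Monte-Carlo inversion between adjacent effect sizes
  expect_lte(sum(diff(rej) < 0), 1)
  expect_lt(rej[1], rej[4])
})
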