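test_that("phi_E reproduces the two-point extrapolation by hand", {
  ss <- make_ss_rows("p1", vpd = c(1, 2, 3), E = c(2, 4, 4.5))
  out <- phi_e(ss, baseline_levels = c(1, 2), target_levels = 3)
  expect_equal(out$e_pred, 6)
  expect_equal(out$phi_e, 0.25)
  expect_true(out$valid)
})

test_that("phi_E is zero on collinear data and signed for super-linear responses", {
  ss <- make_ss_rows("p1", vpd = c(1, 2, 3, 4), E = c(2, 4, 6, 8))
  out <- phi_e(ss, c(1, 2), c(3, 4))
  expect_equal(out$phi_e, c(0, 0))

  ss2 <- make_ss_rows("p1", vpd = c(1, 2, 3), E = c(2, 4, 7))
  expect_lt(phi_e(ss2, c(1, 2), 3)$phi_e, 0)
})

test_that("phi_E is invariant to rescaling all transpiration rates", {
  ss <- make_ss_rows("p1", vpd = c(1, 1.6, 2.4, 3.3), E = c(2, 3.1, 3.9, 4.2))
  base <- phi_e(ss, c(1, 2), c(3, 4))$phi_e
  ss$E <- ss$E * 7.3
  expect_equal(phi_e(ss, c(1, 2), c(3, 4))$phi_e, base)
})

test_that("phi_E guards degenerate baselines and negative predictions", {
  ss <- make_ss_rows("p1", vpd = c(1, 2, 3.5), E = c(4, 2, 1))
  out <- phi_e(ss, c(1, 2), 3)
  expect_false(out$valid) # e_pred = 4 - 2*2.5 < 0
  expect_true(is.na(out$phi_e))

  ss2 <- rbind(make_ss_rows("p1", vpd = c(1, 2, 3), E = c(2, 4, 4.5)),
               make_ss_rows("p2", vpd = c(1, 2, 3), E = c(NA, 4, 4.5)))
  expect_message(out2 <- phi_e(ss2, c(1, 2), 3), "excluded 1 plant")
  expect_equal(out2$plant, "p1")

  ss3 <- make_ss_rows("p1", vpd = c(2, 2, 3), E = c(2, 4, 4.5))
  expect_error(phi_e(ss3, c(1, 2), 3), "degenerate")
})

test_that("limitation of A matches hand-computed single- and multi-plant cases", {
  one <- make_ss_rows("p1", vpd = c(1, 2, 3), E = 1:3, A = c(20, 18, 16))
  lim <- limitation_of_a(one)
  expect_equal(lim$limitation[lim$level == 3], (20 - 16) / 16)
  expect_equal(lim$limitation[lim$level == 1], 0)

  two <- rbind(
    make_ss_rows("p1", vpd = c(1, 2), E = 1:2, A = c(20, 16)),
    make_ss_rows("p2", vpd = c(1, 2), E = 1:2, A = c(10, 8))
  )
  lim2 <- limitation_of_a(two)
  expect_equal(lim2$limitation[lim2$level == 2], (4 + 2) / (16 + 8))
})

test_that("limitation of A is non-negative and zero only at the per-plant maxima", {
  set.seed(31)
  for (i in 1:20) {
    ss <- rbind(
      make_ss_rows("p1", vpd = 1:4, E = 1:4, A = runif(4, 5, 20)),
      make_ss_rows("p2", vpd = 1:4, E = 1:4, A = runif(4, 5, 20))
    )
    lim <- limitation_of_a(ss)
    expect_true(all(lim$limitation >= 0))
  }
  flat <- rbind(make_ss_rows("p1", vpd = 1:3, E = 1:3, A = c(12, 12, 12)))
  expect_equal(limitation_of_a(flat)$limitation, c(0, 0, 0))
})

test_that("stomatal reduction recovers exact log-linear conductance", {
  ss <- make_ss_rows("p1", vpd = c(1, exp(1), exp(2)), E = 1:3,
                     gs = c(0.5, 0.4, 0.3))
  fit <- stomatal_reduction(ss)
  expect_equal(fit$a, 0.5)
  expect_equal(fit$phi_stom, 0.1)
  expect_equal(fit$r_squared, 1)

  flat <- make_ss_rows("p1", vpd = c(1, 2, 3), E = 1:3, gs = c(0.3, 0.3, 0.3))
  expect_equal(stomatal_reduction(flat)$phi_stom, 0)
})

test_that("stomatal reduction recovers a planted slope from noisy data", {
  set.seed(12)
  v <- c(0.91, 1.5, 2.09, 2.69, 3.28, 3.87)
  slopes <- replicate(40, {
    gs <- 0.6 - 0.15 * log(v) + rnorm(6, 0, 0.01)
    stomatal_reduction(make_ss_rows("p1", vpd = v, E = 1:6, gs = gs))$phi_stom
  })
  expect_equal(mean(slopes), 0.15, tolerance = 0.02)
  expect_error(stomatal_reduction(make_ss_rows("p1", vpd = c(1, 2), E = 1:2)),
               "no plant has enough levels") |> suppressWarnings()
})

test_that("phi_stom proportional to max gs yields R squared of 1 through the pipeline", {
  v <- c(0.91, 1.5, 2.09, 2.69, 3.28, 3.87)
  tabs <- lapply(1:5, function(j) {
    phi <- 0.05 * j
    a <- phi / 0.3
    make_ss_rows(sprintf("p%d", j), vpd = v, E = 1:6,
                 gs = a - phi * log(v), accession = sprintf("acc%d", j))
  })
  ss <- do.call(rbind, tabs)
  stom <- stomatal_reduction(ss)
  mg <- max_gs_table(ss)
  stopifnot(identical(stom$accession, mg$accession))
  r2 <- correlation_r2(stom$phi_stom, mg$max_gs)
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
})
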