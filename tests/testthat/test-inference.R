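test_that("classical GC has nonnegative Geweke measure and G = n F", {
  set.seed(5)
  for (i in 1:20) {
    pp <- independent_pair_panels(200 + 2 * i, n_time = 60, nsim = 1, b = 0.3)
    cl <- classical_gc(pp$x, pp$y, p = 1)
    expect_gte(cl$F, 0)   # residual variance cannot increase with regressors
    expect_equal(cl$statistic, cl$n_obs * cl$F, tolerance = 1e-10)
  }
})

test_that("classical GC detects a strong VAR cross-coefficient", {
  A <- matrix(c(0.5, 0, 0.5, 0.5), 2, 2)   # y -> x coefficient 0.5
  jm <- joint_arbekk_model(A = list(A), Bx = list(), By = list(),
                           Wx_chol = matrix(1), Wy_chol = matrix(1))
  hits <- 0L
  for (i in 1:20) {
    pan <- simulate(jm, nsim = 1, seed = 300 + i, n_time = 1000)
    cl <- classical_gc(panel_channels(pan, 1), panel_channels(pan, 2))
    if (cl$p_value < 0.05) hits <- hits + 1L
    expect_equal(cl$df, 1L)
  }
  expect_gte(hits, 19L)
})

test_that("classical GC type-I error is near nominal on white noise", {
  set.seed(17)
  pv <- vapply(1:200, function(i) {
    x <- trial_panel(matrix(rnorm(300), 1, 300))
    y <- trial_panel(matrix(rnorm(300), 1, 300))
    classical_gc(x, y)$p_value
  }, numeric(1))
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("sdn_gc detects variance-only coupling that classical GC misses", {
  # mean cross-coefficient 0, volatility cross-coefficient ~1
  A <- diag(c(0.5, 0.5))
  jm <- joint_arbekk_model(A = list(A),
                           Bx = list(matrix(c(0.4, 0.65), 1, 2)),
                           By = list(matrix(c(0, 0.4), 1, 2)),
                           Wx_chol = matrix(1), Wy_chol = matrix(1))
  expect_true(second_order_stable(jm)$stable)
  sdn_hits <- cl_hits <- 0L
  n_rep <- 15L
  for (i in seq_len(n_rep)) {
    pan <- simulate(jm, nsim = 2, seed = 400 + i, n_time = 1000)
    px <- panel_channels(pan, 1); py <- panel_channels(pan, 2)
    if (sdn_gc(px, py)$p_value < 0.01) sdn_hits <- sdn_hits + 1L
    if (classical_gc(px, py)$p_value < 0.01) cl_hits <- cl_hits + 1L
  }
  expect_gt(sdn_hits, n_rep / 2)    # majority detection
  expect_lt(cl_hits, n_rep / 2)     # classical stays near its nominal rate
})

test_that("sdn statistic has df = 2 for scalar pairs and is nonnegative", {
  pp <- independent_pair_panels(501, n_time = 300)
  tst <- sdn_gc(pp$x, pp$y)
  expect_equal(tst$df, 2L)
  expect_gte(tst$statistic, 0)
  expect_gte(tst$statistic_raw, -0.01)
  expect_true(tst$p_value >= 0 && tst$p_value <= 1)
})

test_that("difference distribution matches its closed forms and simulations", {
  expect_identical(difference_cdf(0, 1), 0.5)
  expect_identical(difference_cdf(0, 5), 0.5)
  # df = 2: difference of two Exp(1/2) variables is Laplace with scale 2
  d <- c(0.5, 1, 2, 4.61, 8)
  expect_equal(2 * (1 - difference_cdf(d, 2)), exp(-d / 2), tolerance = 1e-8)
  # density endpoint: finite limit for df >= 2 (Laplace value 1/4 at df = 2),
  # integrable logarithmic divergence at df = 1
  expect_equal(chisq_diff_density(0, 2), 0.25)
  expect_equal(chisq_diff_density(0, 4), chisq_diff_density(1e-9, 4),
               tolerance = 1e-6)
  expect_identical(chisq_diff_density(0, 1), Inf)
  # density integrates to one
  for (df in c(1, 2, 4)) {
    tot <- 2 * integrate(function(u) chisq_diff_density(u, df), 0, Inf,
                         rel.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  # Monte-Carlo check (smaller than the acceptance-scale run)
  set.seed(9)
  for (df in c(1, 4)) {
    sims <- rchisq(2e5, df) - rchisq(2e5, df)
    grid <- quantile(sims, seq(0.05, 0.95, by = 0.05))
    expect_lt(max(abs(difference_cdf(grid, df) - ecdf(sims)(grid))), 0.01)
  }
  expect_error(difference_cdf(1, 0), "positive integer")
  expect_error(difference_cdf(1, 2.5), "positive integer")
})

test_that("difference test is antisymmetric and monotone in |delta|", {
  t1 <- difference_test(5, 2, df = 2)
  t2 <- difference_test(2, 5, df = 2)
  expect_equal(t1$delta, -t2$delta)
  expect_equal(t1$p_value, t2$p_value)
  t0 <- difference_test(3, 3, df = 2)
  expect_equal(t0$delta, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$dominant, "none")
  ps <- vapply(c(0.5, 1, 2, 4, 8),
               function(d) difference_test(d, 0, df = 2)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("pair_table counts tests, applies Bonferroni, and relabels consistently", {
  st <- synth_fmri_panel(synth_fmri_config(n_subjects = 4, trials_per_subject = 5,
                                           n_time = 30), seed = 77)
  pan <- st$intensity
  pt <- pair_table(pan, method = "classical", alpha = 0.05)
  expect_equal(pt$n_tests, 12L)
  expect_equal(pt$threshold, 0.05 / 12)
  expect_true(all(is.na(diag(pt$statistic))))
  # region permutation permutes rows/columns consistently
  perm <- c(3, 1, 4, 2)
  pan2 <- panel_channels(pan, perm)
  pt2 <- pair_table(pan2, method = "classical", alpha = 0.05)
  expect_equal(pt2$statistic, pt$statistic[perm, perm], tolerance = 1e-10)
  # antisymmetry of the difference matrix
  off <- !is.na(pt$delta)
  expect_equal(pt$delta[off], -t(pt$delta)[off])
})

test_that("pair_table reports are written as CSV and JSON", {
  dir <- withr::local_tempdir()
  st <- synth_fmri_panel(synth_fmri_config(n_subjects = 3, trials_per_subject = 4,
                                           n_time = 25), seed = 78)
  pt <- pair_table(st$intensity, method = "classical")
  files <- write_pair_table(pt, file.path(dir, "tab"))
  expect_true(all(file.exists(files)))
  dir_df <- utils::read.csv(files[1])
  expect_equal(nrow(dir_df), 12L)
  js <- jsonlite::read_json(files[3], simplifyVector = TRUE)
  expect_equal(js$n_tests, 12L)
})
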