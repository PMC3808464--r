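test_that("design matrices have the documented shapes", {
  pan <- simulate(scalar_model(), nsim = 12, seed = 3, n_time = 30)
  d_lin <- build_design(pan, basis_spec("linear", 2))
  expect_equal(ncol(d_lin$X), 3L)                    # 2 lags + intercept
  d_poly <- build_design(pan, basis_spec("poly2", 1))
  expect_equal(ncol(d_poly$X), 3L)                   # x, x^2, intercept
  expect_equal(d_poly$X[, 3], d_poly$X[, 2]^2)
  d_f <- build_design(pan, basis_spec("fourier6", 1))
  expect_equal(ncol(d_f$X), 13L)                     # 6 sine + 6 cosine + intercept
  expect_true(all(abs(d_f$X[, -1]) <= 1 + 1e-12))
  short <- simulate(scalar_model(), nsim = 12, seed = 4, n_time = 3)
  expect_error(build_design(short, basis_spec("linear", 2)), "shorter")
})

test_that("a noiseless AR(1) panel is exactly representable in the linear basis", {
  v <- array(0, dim = c(12, 20, 1))
  set.seed(8)
  for (tr in 1:12) {
    x <- numeric(20); x[1] <- rnorm(1)
    for (t in 2:20) x[t] <- 0.8 * x[t - 1]
    v[tr, , 1] <- x
  }
  esn <- empirical_signal_noise(trial_panel(v), basis_spec("linear", 1))
  expect_lt(max(abs(esn$residual)), 1e-10)
  expect_gt(esn$r2[[1]], 1 - 1e-10)
})

test_that("sdn_correlation is exact under perfect proportionality and errors on constants", {
  pan <- simulate(scalar_model(), nsim = 15, seed = 5, n_time = 40)
  esn <- empirical_signal_noise(pan, basis_spec("linear", 1))
  ms2 <- apply(esn$signal_hat^2, 2, mean)
  esn$noise_var[, 1] <- 3 * ms2 + 1e-9   # exactly linear in the squared signal
  expect_equal(sdn_correlation(esn)$r, 1, tolerance = 1e-9)
  esn$noise_var[, 1] <- 2
  expect_error(sdn_correlation(esn), "constant")
  expect_error(empirical_signal_noise(panel_channels(pan, 1)[["values"]],
                                      basis_spec("linear", 1)))
  few <- simulate(scalar_model(), nsim = 5, seed = 5, n_time = 40)
  expect_error(empirical_signal_noise(few, basis_spec("linear", 1)), "10 trials")
})

test_that("signal-dependent noise is detected on AR-BEKK data but not homoskedastic data", {
  # trial-locked onset transients (no burn-in, zero initial state) give
  # the within-trial structure that the across-trial variance tracks
  hits_alt <- hits_null <- 0L
  for (i in 1:10) {
    alt <- simulate(scalar_model(0.5, 0.5), nsim = 60, seed = 600 + i,
                    n_time = 100, burn_in = 0)
    esn <- empirical_signal_noise(alt, basis_spec("linear", 1))
    sc <- sdn_correlation(esn)
    if (sc$r > 0 && sc$p_value < 0.05) hits_alt <- hits_alt + 1L
    nul <- simulate(scalar_model(0.5, NULL), nsim = 60, seed = 700 + i,
                    n_time = 100, burn_in = 0)
    scn <- sdn_correlation(empirical_signal_noise(nul, basis_spec("linear", 1)))
    if (scn$p_value < 0.05) hits_null <- hits_null + 1L
  }
  expect_gte(hits_alt, 8L)
  expect_lte(hits_null, 3L)
})

test_that("r2 never decreases with added lags on a common sample (nested projections)", {
  pan <- simulate(scalar_model(0.5, 0.5), nsim = 30, seed = 13, n_time = 40)
  Lmax <- 3L
  for (fam in c("linear", "poly2", "fourier6")) {
    r2s <- vapply(1:Lmax, function(L) {
      dsg <- build_design(pan, basis_spec(fam, L))
      keep <- dsg$time > Lmax          # identical rows across lag orders
      fit <- stats::lm.fit(dsg$X[keep, , drop = FALSE], dsg$y[keep])
      res <- fit$residuals
      1 - sum(res^2) / sum((dsg$y[keep] - mean(dsg$y[keep]))^2)
    }, numeric(1))
    expect_true(all(diff(r2s) > -1e-10))
  }
})

test_that("the signal-dependence verdict is stable across basis families", {
  pan <- simulate(scalar_model(0.5, 0.5), nsim = 60, seed = 13, n_time = 100,
                  burn_in = 0)
  for (fam in c("linear", "poly2", "fourier6")) {
    sc <- sdn_correlation(empirical_signal_noise(pan, basis_spec(fam, 1)))
    expect_gt(sc$r, 0)
    expect_lt(sc$p_value, 0.05)
  }
})

test_that("model concordance is high in-class, trial-exchangeable, and degenerate-safe", {
  # signal concordance is near perfect in-class; variance concordance is
  # attenuated by the chi-squared sampling noise of the across-trial
  # variance estimator, so a clearly positive value is the in-class bar
  pan <- simulate(scalar_model(0.5, 0.6), nsim = 100, seed = 14, n_time = 25)
  fit <- fit_arbekk(pan)
  esn <- empirical_signal_noise(pan, basis_spec("linear", 1))
  mc <- model_concordance(fit, esn, pan)
  expect_gt(mc$r_signal, 0.7)
  expect_gt(mc$r_variance, 0.15)
  rvs <- vapply(1:5, function(i) {
    pp <- simulate(scalar_model(0.5, 0.6), nsim = 100, seed = 20 + i, n_time = 25)
    ff <- fit_arbekk(pp)
    model_concordance(ff, empirical_signal_noise(pp, basis_spec("linear", 1)),
                      pp)$r_variance
  }, numeric(1))
  expect_true(all(rvs > 0))
  expect_gt(median(rvs), 0.25)
  # trial permutation leaves both correlations unchanged
  perm <- sample(n_trials(pan))
  pan2 <- trial_panel(pan$values[perm, , , drop = FALSE], dt = pan$dt)
  esn2 <- empirical_signal_noise(pan2, basis_spec("linear", 1))
  mc2 <- model_concordance(fit, esn2, pan2)
  expect_equal(mc2$r_signal, mc$r_signal, tolerance = 1e-9)
  expect_equal(mc2$r_variance, mc$r_variance, tolerance = 1e-9)
  # constant model variance: undefined, reported as such
  panv <- simulate(scalar_model(0.5, NULL), nsim = 30, seed = 15, n_time = 25)
  fv <- fit_arbekk(panv, q = 0)
  mcv <- model_concordance(fv, empirical_signal_noise(panv, basis_spec("linear", 1)),
                           panv)
  expect_true(is.na(mcv$r_variance))
  expect_match(mcv$note, "constant")
})
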