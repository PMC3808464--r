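test_that("Poisson spike trains have the right mean, Fano factor and edge cases", {
  expect_true(all(poisson_spikes(0, 1, 0.001, seed = 1)$counts == 0))
  expect_error(poisson_spikes(-1), "nonnegative")
  set.seed(2)
  totals <- vapply(1:2000, function(i) sum(rpois(1000, 40 * 0.001)), numeric(1))
  expect_equal(mean(totals), 40, tolerance = 0.1)
  expect_equal(var(totals) / mean(totals), 1, tolerance = 0.1)  # Fano ~ 1
  # thinning consistency: doubling dt keeps the expected total fixed
  s1 <- poisson_spikes(40, 1, 0.001, seed = 3)
  s2 <- poisson_spikes(40, 1, 0.002, seed = 3)
  expect_equal(length(s1$counts), 1000L)
  expect_equal(length(s2$counts), 500L)
  expect_equal(sum(s1$counts) / 40, 1, tolerance = 0.5)
})

test_that("the resting state is a fixed point with zero BOLD readout", {
  hf <- hemodynamic_forward(rep(0, 2000))
  expect_equal(max(abs(hf$s)), 0)
  expect_equal(range(hf$f), c(1, 1))
  expect_equal(range(hf$v), c(1, 1))
  expect_equal(range(hf$q), c(1, 1))
  expect_equal(max(abs(hf$bold)), 0)
})

test_that("BOLD response returns to baseline and scales with firing rate", {
  u <- c(poisson_spikes(40, 1, 0.001, seed = 4)$counts, rep(0, 24000))
  hf <- hemodynamic_forward(u)
  peak <- max(abs(hf$bold))
  expect_gt(peak, 0)
  expect_lt(abs(hf$bold[length(u), 1]), 0.01 * peak)  # back to baseline
  peaks <- vapply(c(5, 40, 80), function(r) {
    pb <- simulate_bold_trials(rate = r, n_trials = 30, seed = 6)
    max(colMeans(pb$values[, , 1]))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))  # 5 < 40 < 80 Hz
})

test_that("the integrator converges and is reproducible", {
  u1 <- poisson_spikes(40, 1, 0.001, seed = 7)$counts
  u <- c(u1, rep(0, 9000))
  b_euler <- hemodynamic_forward(u, dt = 0.001)$bold[, 1]
  # halved step, same input held over half-steps
  u_half <- rep(u, each = 2)
  b_half <- hemodynamic_forward(u_half, dt = 0.0005)$bold[, 1]
  b_half <- b_half[seq(2, length(b_half), by = 2)]
  expect_lt(max(abs(b_euler - b_half)) / max(abs(b_euler)), 0.001)
  # rk4 agrees with euler to within the Euler step error
  b_rk4 <- hemodynamic_forward(u, dt = 0.001, method = "rk4")$bold[, 1]
  expect_lt(max(abs(b_euler - b_rk4)) / max(abs(b_euler)), 0.005)
  # bit-reproducibility given the seed, with zero observation noise
  p1 <- simulate_bold_trials(rate = 40, n_trials = 5, seed = 8)
  p2 <- simulate_bold_trials(rate = 40, n_trials = 5, seed = 8)
  expect_identical(p1$values, p2$values)
  expect_error(hemodynamic_forward(u, dt = 0.05), "10 ms")
})

test_that("simulated BOLD trials show signal-dependent noise (default panel)", {
  pb <- simulate_bold_trials(seed = 9)   # 40 Hz, 100 trials, 25 s, 1 Hz
  expect_equal(dim(pb$values), c(100L, 25L, 1L))
  mean_tr <- colMeans(pb$values[, , 1])
  var_tr <- apply(pb$values[, , 1], 2, var)
  peak_t <- which.max(abs(mean_tr))
  expect_gt(var_tr[peak_t], var_tr[25])  # peak variance above baseline variance
  esn <- empirical_signal_noise(pb, basis_spec("poly2", 1))
  sc <- sdn_correlation(esn)
  expect_gt(sc$r, 0)
  expect_lt(sc$p_value, 0.01)
  # the variance-vs-squared-signal regression slope is positive
  ms2 <- apply(esn$signal_hat^2, 2, mean)
  slope <- coef(summary(lm(esn$noise_var[, 1] ~ ms2)))[2, ]
  expect_gt(slope["Estimate"], 0)
  expect_lt(slope["Pr(>|t|)"], 0.01)
})

test_that("hemodynamic parameter validation rejects unphysical values", {
  expect_error(hemodynamic_params(alpha = 1.2))
  expect_error(hemodynamic_params(E0 = 0))
  expect_error(hemodynamic_params(tau_s = -1))
})
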