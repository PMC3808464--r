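test_that("log-likelihood equals the standard-normal density in the trivial case", {
  # k = 1, one scored point, h = 1, residual 0
  m <- arbekk_model(A = matrix(1, 1, 1), B = list(), W_chol = matrix(1, 1, 1))
  pan <- trial_panel(array(c(2, 2), dim = c(1, 2, 1)))
  expect_equal(arbekk_loglik(m, pan), -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("log-likelihood matches a brute-force density oracle", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(1:2, 1)
    m <- random_stable_model(k)
    pan <- simulate(m, nsim = 1, seed = 100 + i, n_time = 20)
    expect_equal(arbekk_loglik(m, pan), brute_force_loglik(m, pan),
                 tolerance = 1e-10)
  }
})

test_that("panel log-likelihood is the sum of single-trial log-likelihoods", {
  m <- scalar_model(0.4, 0.5, 0.8)
  pan <- simulate(m, nsim = 3, seed = 21, n_time = 25)
  single <- vapply(1:3, function(tr)
    arbekk_loglik(m, trial_panel(pan$values[tr, , , drop = FALSE])),
    numeric(1))
  expect_equal(arbekk_loglik(m, pan), sum(single), tolerance = 1e-10)
})

test_that("initialization recovers VAR coefficients and yields a valid start", {
  mv <- arbekk_model(A = matrix(0.6, 1, 1), B = list(), W_chol = matrix(1, 1, 1))
  pan <- simulate(mv, nsim = 1, seed = 31, n_time = 1000)
  init <- arbekk_init(pan, p = 1, q = 1)
  expect_lt(abs(init$A[[1]][1, 1] - 0.6), 0.1)      # OLS consistency
  expect_true(all(diag(init$B[[1]]) >= 0))          # nonnegative diagonal start
  expect_true(second_order_stable(init)$stable)
  zero <- trial_panel(array(0, dim = c(2, 50, 1)))
  expect_error(arbekk_init(zero), "degenerate")
})

test_that("the univariate fit recovers generating parameters and ascends", {
  m <- scalar_model(0.5, 0.5, 1)
  pan <- simulate(m, nsim = 2, seed = 41, n_time = 1000)
  fit <- fit_arbekk(pan)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$A[[1]][1, 1] - 0.5), 0.1)
  expect_lt(abs(fit$model$B[[1]][1, 1] - 0.5), 0.1)
  expect_lt(abs(fit$model$W_chol[1, 1]^2 - 1), 0.15)
  expect_gte(fit$loglik, fit$init_loglik)           # ascent property
  expect_true(second_order_stable(fit$model)$stable)
  # local-maximum sanity: coordinate perturbations do not improve
  th <- c(fit$model$A[[1]][1, 1], fit$model$B[[1]][1, 1],
          fit$model$W_chol[1, 1]^2)
  for (j in 1:3) for (s in c(-1, 1)) {
    th2 <- th; th2[j] <- th2[j] + s * 1e-2
    m2 <- scalar_model(th2[1], th2[2], th2[3])
    expect_lt(arbekk_loglik(m2, pan), fit$loglik + 1e-6)
  }
})

test_that("with B = 0 the ML fit agrees with closed-form least squares", {
  mv <- arbekk_model(A = matrix(0.6, 1, 1), B = list(), W_chol = matrix(1, 1, 1))
  pan <- simulate(mv, nsim = 2, seed = 51, n_time = 500)
  fit <- fit_arbekk(pan, p = 1, q = 0)
  x <- pan$values
  y <- as.vector(x[, -1, 1]); xl <- as.vector(x[, -dim(x)[2], 1])
  a_ols <- sum(xl * y) / sum(xl^2)
  w_ml <- mean((y - a_ols * xl)^2)
  expect_equal(fit$model$A[[1]][1, 1], a_ols, tolerance = 1e-3)
  expect_equal(fit$model$W_chol[1, 1]^2, w_ml, tolerance = 1e-3)
})

test_that("joint fitting nests correctly and counts free parameters", {
  jm <- with_seed_local(61, random_coupled_pair())
  pan <- simulate(jm, nsim = 2, seed = 62, n_time = 400)
  px <- panel_channels(pan, 1); py <- panel_channels(pan, 2)
  full <- fit_joint_arbekk(px, py)
  restr <- fit_joint_arbekk(px, py, restriction = "y_to_x_zero")
  expect_equal(full$n_params, 10L)
  expect_equal(restr$n_params, 8L)
  expect_gte(full$loglik, restr$loglik - 1e-6)      # nested models
  expect_equal(restr$model$A[[1]][1, 2], 0)         # restriction held at zero
  expect_equal(restr$model$Bx[[1]][1, 2], 0)
  expect_true(first_order_stable(full$model)$stable)
  expect_error(fit_joint_arbekk(pan, py), "univariate blocks")
})

test_that("null-calibrated joint LR statistics sit near the chi-squared median", {
  set.seed(71)
  G <- numeric(40)
  for (i in 1:40) {
    pp <- independent_pair_panels(900 + 2 * i, n_time = 400)
    f <- fit_joint_arbekk(pp$x, pp$y)
    r <- fit_joint_arbekk(pp$x, pp$y, restriction = "y_to_x_zero")
    G[i] <- 2 * (f$loglik - r$loglik)
  }
  expect_true(all(G > -1e-6))
  # median of chi2(2) is 1.386; binomial band for 40 draws
  expect_gt(mean(G < qchisq(0.5, 2)), 0.25)
  expect_lt(mean(G < qchisq(0.5, 2)), 0.75)
})
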