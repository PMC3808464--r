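test_that("first-order stability matches the companion eigenvalues", {
  expect_equal(first_order_stable(matrix(0.5, 1, 1)),
               list(stable = TRUE, radius = 0.5))
  expect_equal(first_order_stable(matrix(1, 1, 1)),
               list(stable = FALSE, radius = 1))
  # p = 2 scalar: roots of lambda^2 - 0.5 lambda - 0.4
  r <- first_order_stable(list(matrix(0.5, 1, 1), matrix(0.4, 1, 1)))
  expect_equal(r$radius, max(Mod(polyroot(c(-0.4, -0.5, 1)))), tolerance = 1e-10)
  expect_true(r$stable)
  expect_error(first_order_stable(list(matrix(0, 1, 1), matrix(0, 2, 2))),
               "square")
})

test_that("second-order stability is the Kronecker operator radius", {
  expect_equal(second_order_stable(scalar_model(0.5, 0.5))$radius, 0.5)
  s <- second_order_stable(scalar_model(0.8, 0.7))
  expect_equal(s$radius, 1.13)
  expect_false(s$stable)  # despite first-order stability
  expect_true(first_order_stable(scalar_model(0.8, 0.7))$stable)
  expect_equal(second_order_stable(scalar_model(0.9, NULL))$radius, 0.81)
  m2 <- arbekk_model(A = list(matrix(0.2, 1, 1), matrix(0.1, 1, 1)),
                     B = list(), W_chol = matrix(1, 1, 1))
  expect_error(second_order_stable(m2), "first-order models")
})

test_that("conditional covariance follows the quadratic recursion", {
  # B = 0 reduces to the constant baseline covariance
  m0 <- arbekk_model(A = matrix(0.4, 1, 1), B = list(), W_chol = matrix(2, 1, 1))
  expect_equal(conditional_covariance(m0, 3), matrix(4, 1, 1))
  # forced arithmetic: w=1, b=0.5, x=2 -> 1 + (0.5*2)^2 = 2
  m1 <- scalar_model(0.5, 0.5, 1)
  expect_equal(conditional_covariance(m1, 2)[1, 1], 2)
  # rank-1 B with history on its null space -> H = W
  B <- matrix(c(1, 2, 0.5, 1), 2, 2)  # rows prop. to (1, 0.5): null space (1, -2)
  mk <- arbekk_model(A = diag(0.1, 2), B = B, W_chol = diag(2))
  expect_equal(conditional_covariance(mk, c(1, -2)), diag(2), tolerance = 1e-12)
  expect_error(conditional_covariance(m1, matrix(numeric(0), 0, 1)),
               "insufficient history")
})

test_that("conditional covariance is positive definite over random models", {
  set.seed(42)
  for (i in 1:1000) {
    k <- sample(1:2, 1)
    m <- random_stable_model(k)
    H <- conditional_covariance(m, matrix(rnorm(k, sd = 3), 1, k))
    expect_true(all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("stationary second moment solves the vectorized fixed point", {
  expect_equal(stationary_second_moment(scalar_model(0.5, 0.5, 1))[1, 1], 2)
  # b = 0 -> classical AR(1) variance w / (1 - a^2)
  expect_equal(stationary_second_moment(scalar_model(0.6, NULL, 2))[1, 1],
               2 / (1 - 0.36), tolerance = 1e-12)
  # diagonal bivariate model decouples componentwise
  md <- arbekk_model(A = diag(c(0.5, 0.3)), B = diag(c(0.5, 0.4)),
                     W_chol = diag(c(1, 2)))
  S <- stationary_second_moment(md)
  expect_equal(diag(S), c(1 / (1 - 0.25 - 0.25), 4 / (1 - 0.09 - 0.16)),
               tolerance = 1e-12)
  expect_equal(S[1, 2], 0)
  expect_error(stationary_second_moment(scalar_model(0.8, 0.7)), "unstable")
})

test_that("simulation respects the stability gate and is seed-reproducible", {
  expect_error(simulate(scalar_model(0.8, 0.7), nsim = 1, n_time = 10),
               "unstable")
  p0 <- simulate(scalar_model(0.8, 0.7), nsim = 1, n_time = 10, seed = 1,
                 override_unstable = TRUE)
  expect_equal(dim(p0$values), c(1L, 10L, 1L))
  p1 <- simulate(scalar_model(), nsim = 2, seed = 9, n_time = 50)
  p2 <- simulate(scalar_model(), nsim = 2, seed = 9, n_time = 50)
  expect_identical(p1$values, p2$values)
})

test_that("simulated second moments converge to the stationary solution", {
  m <- scalar_model(0.5, 0.5, 1)
  x <- simulate(m, nsim = 1, seed = 11, n_time = 20000)$values[1, , 1]
  # batch-means standard error (robust to autocorrelation)
  bm <- colMeans(matrix(x^2, nrow = 200))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(x^2) - 2), 3 * se)
  # bivariate model against the matrix fixed point (diagonal entries)
  md <- arbekk_model(A = matrix(c(0.4, 0.1, 0.2, 0.3), 2, 2),
                     B = matrix(c(0.4, 0, 0.2, 0.3), 2, 2),
                     W_chol = diag(2))
  S <- stationary_second_moment(md)
  pv <- simulate(md, nsim = 1, seed = 12, n_time = 20000)$values[1, , ]
  Shat <- crossprod(pv) / nrow(pv)
  expect_lt(max(abs(Shat - S) / diag(S)), 0.1)
})

test_that("with B = 0 the process is the Gaussian VAR", {
  # one-step prediction residuals of a simulated VAR recover W
  m <- arbekk_model(A = matrix(0.6, 1, 1), B = list(), W_chol = matrix(sqrt(2), 1, 1))
  x <- simulate(m, nsim = 1, seed = 3, n_time = 50000)$values[1, , 1]
  r <- x[-1] - 0.6 * x[-length(x)]
  expect_equal(var(r), 2, tolerance = 0.05)
  # likelihood reduces to the VAR conditional likelihood
  pan <- simulate(m, nsim = 1, seed = 4, n_time = 30)
  xx <- pan$values[1, , 1]
  ll_var <- sum(dnorm(xx[-1], 0.6 * xx[-30], sqrt(2), log = TRUE))
  expect_equal(arbekk_loglik(m, pan), ll_var, tolerance = 1e-10)
})

test_that("joint model enforces its restriction invariants", {
  A <- matrix(c(0.5, 0.2, 0.3, 0.5), 2, 2)
  expect_error(
    joint_arbekk_model(A = list(A), Bx = list(matrix(c(0.5, 0), 1, 2)),
                       By = list(matrix(c(0, 0.5), 1, 2)),
                       Wx_chol = matrix(1), Wy_chol = matrix(1),
                       restriction = "y_to_x_zero"),
    "y_to_x_zero")
  Ar <- matrix(c(0.5, 0.2, 0, 0.5), 2, 2)
  jm <- joint_arbekk_model(A = list(Ar), Bx = list(matrix(c(0.5, 0), 1, 2)),
                           By = list(matrix(c(0.1, 0.5), 1, 2)),
                           Wx_chol = matrix(1), Wy_chol = matrix(1),
                           restriction = "y_to_x_zero")
  # conditional covariance is block-diagonal (independent innovations)
  H <- conditional_covariance(jm, c(1.5, -2))
  expect_equal(H[1, 2], 0)
  expect_equal(H[2, 1], 0)
  expect_equal(H[1, 1], 1 + (0.5 * 1.5)^2)
})
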