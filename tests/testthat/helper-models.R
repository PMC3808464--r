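# Shared model builders and small simulation helpers.

with_seed_local <- function(seed, code) {
  set.seed(seed)
  code
}

scalar_model <- function(a = 0.5, b = 0.5, w = 1) {
  arbekk_model(A = matrix(a, 1, 1),
               B = if (is.null(b)) list() else matrix(b, 1, 1),
               W_chol = matrix(sqrt(w), 1, 1))
}

# Random stable univariate-or-bivariate AR-BEKK model (p = q = 1).
random_stable_model <- function(k = 1) {
  repeat {
    A <- matrix(stats::runif(k * k, -0.6, 0.6), k, k)
    B <- matrix(stats::runif(k * k, -0.5, 0.5), k, k)
    L <- diag(stats::runif(k, 0.5, 1.2), k)
    if (k > 1) L[lower.tri(L)] <- stats::runif(k * (k - 1) / 2, -0.3, 0.3)
    m <- arbekk_model(A = A, B = B, W_chol = L)
    if (first_order_stable(m)$stable && second_order_stable(m)$stable) return(m)
  }
}

# Joint scalar-pair model with both cross-links planted (for recovery).
random_coupled_pair <- function() {
  repeat {
    A <- matrix(c(stats::runif(1, 0.3, 0.7), stats::runif(1, 0.1, 0.5),
                  stats::runif(1, 0.1, 0.5), stats::runif(1, 0.3, 0.7)), 2, 2)
    bx <- c(stats::runif(1, 0.3, 0.6), 0.3)
    by <- c(0.3, stats::runif(1, 0.3, 0.6))
    jm <- joint_arbekk_model(A = list(A),
                             Bx = list(matrix(bx, 1, 2)),
                             By = list(matrix(by, 1, 2)),
                             Wx_chol = matrix(1, 1, 1), Wy_chol = matrix(1, 1, 1))
    if (first_order_stable(jm)$stable && second_order_stable(jm)$stable)
      return(jm)
  }
}

# Uncoupled joint pair: two independent scalar AR-BEKK series.
independent_pair_panels <- function(seed, n_time = 1000, nsim = 2,
                                    a = 0.5, b = 0.5, w = 1) {
  m <- scalar_model(a, b, w)
  list(x = simulate(m, nsim = nsim, seed = seed, n_time = n_time),
       y = simulate(m, nsim = nsim, seed = seed + 1L, n_time = n_time))
}

# Independent brute-force conditional-density likelihood oracle
# (dnorm / explicit multivariate normal density, no shared code with
# block_loglik_core).
brute_force_loglik <- function(model, panel) {
  k <- model$k; p <- model$p; q <- model$q
  m <- max(p, q)
  W <- model$W_chol %*% t(model$W_chol)
  ll <- 0
  for (tr in seq_len(n_trials(panel))) {
    x <- matrix(panel$values[tr, , ], ncol = k)
    for (t in (m + 1L):nrow(x)) {
      mu <- rep(0, k)
      for (i in seq_len(p)) mu <- mu + model$A[[i]] %*% x[t - i, ]
      H <- W
      for (j in seq_len(q)) {
        v <- model$B[[j]] %*% x[t - j, ]
        H <- H + v %*% t(v)
      }
      if (k == 1L) {
        ll <- ll + stats::dnorm(x[t, 1], mu[1], sqrt(H[1, 1]), log = TRUE)
      } else {
        r <- x[t, ] - as.vector(mu)
        ll <- ll - 0.5 * (k * log(2 * pi) + log(det(H)) +
                          as.numeric(t(r) %*% solve(H) %*% r))
      }
    }
  }
  ll
}
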