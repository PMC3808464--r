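# Maximum-likelihood machinery for AR-BEKK models.
#
# The conditional log-likelihood conditions on the first max(p, q)
# observations of every trial (identically in full and restricted fits,
# so likelihoods are nesting-comparable).  Optimization is penalized
# quasi-Newton: W is parameterized through its (log-diagonal) Cholesky
# factor so positive definiteness is free of constraints, and the two
# spectral-radius stability conditions enter as smooth quadratic
# penalties with margin 1e-6.  A Nelder-Mead simplex restart serves as
# fallback when the quasi-Newton pass fails to converge.

# Build pooled lagged design data from a (trial, time, channel) array.
lag_design <- function(values, m) {
  n <- dim(values)[1L]; tt <- dim(values)[2L]; k <- dim(values)[3L]
  if (tt <= m) stop("panel length must exceed max(p, q)")
  idx <- (m + 1L):tt
  y <- matrix(values[, idx, , drop = FALSE], ncol = k)
  lags <- lapply(seq_len(m), function(j)
    matrix(values[, idx - j, , drop = FALSE], ncol = k))
  list(y = y, lags = lags, n_obs = n * length(idx), k = k)
}

# Gaussian conditional log-likelihood of one block (rows `A_rows` of the
# mean recursion, volatility rows `B_rows`, baseline factor W_chol),
# given current values `y` (N x kb) and lagged joint states `lags`.
block_loglik_core <- function(y, lags, A_rows, B_rows, W_chol) {
  kb <- ncol(y)
  R <- y
  for (i in seq_along(A_rows)) R <- R - lags[[i]] %*% t(A_rows[[i]])
  if (kb == 1L) {
    h <- rep(W_chol[1L, 1L]^2, nrow(y))
    for (j in seq_along(B_rows)) h <- h + (lags[[j]] %*% t(B_rows[[j]]))^2
    return(-0.5 * sum(log(2 * pi) + log(h) + R^2 / h))
  }
  W <- W_chol %*% t(W_chol)
  ll <- 0
  const <- kb * log(2 * pi)
  for (r in seq_len(nrow(y))) {
    H <- W
    for (j in seq_along(B_rows)) {
      v <- B_rows[[j]] %*% lags[[j]][r, ]
      H <- H + tcrossprod(v)
    }
    U <- tryCatch(chol(H), error = function(e)
      stop("conditional covariance is numerically non-positive-definite at row ", r))
    z <- backsolve(U, R[r, ], transpose = TRUE)
    ll <- ll - 0.5 * (const + 2 * sum(log(diag(U))) + sum(z^2))
  }
  ll
}

#' Conditional log-likelihood of an AR-BEKK model
#'
#' Sums, over trials and over the time points beyond `max(p, q)`, the
#' Gaussian conditional log-density
#' \eqn{-\tfrac12 [k \ln(2\pi) + \ln\det H_t + r_t^\top H_t^{-1} r_t]}
#' with residual \eqn{r_t = x_t - \sum_i A_i x_{t-i}} and conditional
#' covariance \eqn{H_t} from [conditional_covariance()].  The first
#' `max(p, q)` observations of each trial are conditioned on.  Trials
#' are independent, so the panel log-likelihood is the sum of the
#' per-trial values.
#'
#' @param model an [arbekk_model()] or [joint_arbekk_model()].
#' @param panel a [trial_panel()] whose channel count matches the model.
#' @return The log-likelihood (scalar).
#' @export
arbekk_loglik <- function(model, panel) UseMethod("arbekk_loglik")

#' @export
arbekk_loglik.arbekk_model <- function(model, panel) {
  stopifnot(inherits(panel, "trial_panel"))
  if (n_channels(panel) != model$k) stop("panel channel count does not match model dimension")
  d <- lag_design(panel$values, max(model$p, model$q))
  block_loglik_core(d$y, d$lags, model$A, model$B, model$W_chol)
}

#' @export
arbekk_loglik.joint_arbekk_model <- function(model, panel) {
  stopifnot(inherits(panel, "trial_panel"))
  if (n_channels(panel) != model$k) stop("panel channel count does not match model dimension")
  d <- lag_design(panel$values, max(model$p, model$q))
  xi <- seq_len(model$kx); yi <- model$kx + seq_len(model$ky)
  Ax <- lapply(model$A, function(M) M[xi, , drop = FALSE])
  Ay <- lapply(model$A, function(M) M[yi, , drop = FALSE])
  block_loglik_core(d$y[, xi, drop = FALSE], d$lags, Ax, model$Bx, model$Wx_chol) +
    block_loglik_core(d$y[, yi, drop = FALSE], d$lags, Ay, model$By, model$Wy_chol)
}

#' Least-squares initialization of an AR-BEKK fit
#'
#' Mean coefficients come from per-equation ordinary least squares of
#' the VAR; then, per channel, the squared AR residuals are regressed on
#' the squared lagged values (with intercept) to initialize the
#' diagonal volatility entries \eqn{B_j} (square root of the
#' nonnegative-clipped slope) and the baseline variance (the intercept,
#' floored at 1e-6).  Off-diagonal volatility entries start at zero.
#' The starting model is projected into the stable region if necessary.
#'
#' @param panel a [trial_panel()].
#' @param p,q model orders.
#' @return A stable [arbekk_model()] usable as an optimizer start.
#' @export
arbekk_init <- function(panel, p = 1, q = 1) {
  stopifnot(inherits(panel, "trial_panel"))
  values <- panel$values
  if (stats::sd(values) == 0) stop("degenerate (constant) input panel")
  k <- dim(values)[3L]
  m <- max(p, q, 1L)
  d <- lag_design(values, m)
  X <- do.call(cbind, d$lags[seq_len(p)])
  fit <- stats::lm.fit(X, d$y)
  C <- as.matrix(fit$coefficients)
  C[is.na(C)] <- 0
  A <- lapply(seq_len(p), function(i) t(C[(i - 1L) * k + seq_len(k), , drop = FALSE]))
  E <- d$y - X %*% C
  w <- numeric(k)
  Bdiag <- matrix(0, k, max(q, 1L))
  for (i in seq_len(k)) {
    if (q >= 1L) {
      Z <- cbind(1, vapply(seq_len(q), function(j) d$lags[[j]][, i]^2,
                           numeric(nrow(E))))
      cf <- stats::lm.fit(Z, E[, i]^2)$coefficients
      cf[is.na(cf)] <- 0
      w[i] <- max(cf[1L], 1e-6)
      Bdiag[i, seq_len(q)] <- sqrt(pmax(cf[-1L], 0))
    } else {
      w[i] <- max(mean(E[, i]^2), 1e-6)
    }
  }
  B <- if (q >= 1L) lapply(seq_len(q), function(j) diag(Bdiag[, j], k, k)) else list()
  model <- arbekk_model(A = A, B = B, W_chol = diag(sqrt(w), k, k))
  stabilize_start(model)
}

# Scale a starting model into the stable region (comfortably inside, so
# the penalty is inactive at the optimizer start).
stabilize_start <- function(model) {
  f <- first_order_stable(model)
  if (f$radius > 0.95) {
    sc <- 0.95 / f$radius
    if (inherits(model, "arbekk_model")) model$A <- lapply(model$A, function(M) M * sc)
    else model$A <- lapply(model$A, function(M) M * sc)
  }
  if (model$p <= 1L && model$q == 1L) {
    for (it in seq_len(100L)) {
      s <- second_order_stable(model)
      if (s$radius <= 0.98) break
      if (inherits(model, "arbekk_model")) {
        model$B <- lapply(model$B, function(M) M * 0.9)
      } else {
        model$Bx <- lapply(model$Bx, function(M) M * 0.9)
        model$By <- lapply(model$By, function(M) M * 0.9)
      }
    }
  }
  model
}

# Keep the log-variance parameter inside a range where exp() neither
# underflows to an exact zero (which would break the Cholesky factor)
# nor overflows.
clamp_logvar <- function(th) min(max(th, -40), 50)

fit_control <- function(control = list()) {
  ctl <- list(maxit = 500L, reltol = 1e-12, ndeps = 1e-6,
              penalty_weight = 1e6, margin = 1e-6, fallback_maxit = 2000L)
  ctl[names(control)] <- control
  ctl
}

# Penalized negative log-likelihood optimizer with simplex fallback.
# `negll` maps a parameter vector to a finite value (Inf on failure).
optimize_negll <- function(theta0, negll, ctl) {
  safe <- function(th) {
    v <- tryCatch(negll(th), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  res1 <- tryCatch(
    stats::optim(theta0, safe, method = "BFGS",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol,
                                ndeps = rep(ctl$ndeps, length(theta0)))),
    error = function(e) list(par = theta0, value = safe(theta0),
                             convergence = 99L, message = conditionMessage(e)))
  best <- res1; algorithm <- "bfgs"
  if (res1$convergence != 0L || !is.finite(res1$value)) {
    res2 <- tryCatch(
      stats::optim(best$par, safe, method = "Nelder-Mead",
                   control = list(maxit = ctl$fallback_maxit, reltol = ctl$reltol)),
      error = function(e) NULL)
    if (!is.null(res2) && is.finite(res2$value) && res2$value <= best$value) {
      best <- res2; algorithm <- "bfgs+nelder-mead"
    }
  }
  if (safe(theta0) < best$value) {  # never leave the ascent property behind
    best <- list(par = theta0, value = safe(theta0), convergence = 1L,
                 message = "optimizer failed to improve on the initial point")
    algorithm <- paste0(algorithm, "(init)")
  }
  list(par = best$par, value = best$value,
       converged = identical(best$convergence, 0L),
       algorithm = algorithm,
       message = if (!is.null(best$message)) best$message else NULL)
}

new_sdngc_fit <- function(model, loglik, n_params, n_obs, converged,
                          algorithm, trace, init_loglik) {
  structure(list(model = model, loglik = loglik, n_params = n_params,
                 n_obs = n_obs, converged = converged, algorithm = algorithm,
                 optimizer_trace = trace, init_loglik = init_loglik),
            class = "sdngc_fit")
}

#' @export
print.sdngc_fit <- function(x, ...) {
  cat(sprintf("<sdngc_fit> loglik = %.4f, %d free parameter(s), n_obs = %d, converged = %s (%s)\n",
              x$loglik, x$n_params, x$n_obs, x$converged, x$algorithm))
  invisible(x)
}

#' Constrained maximum-likelihood fit of a univariate AR-BEKK model
#'
#' Maximizes the conditional log-likelihood over the mean coefficients,
#' volatility coefficients and baseline variance, subject to the first-
#' and second-order stability conditions (spectral radii at most
#' `1 - margin`, imposed through a smooth penalty) with the baseline
#' variance parameterized on the log scale.  The fit starts from
#' [arbekk_init()].
#'
#' @param panel a single-channel [trial_panel()].
#' @param p,q model orders; the constrained second-order condition
#'   requires `p = q = 1` (`q = 0` fits the nested Gaussian AR model).
#' @param control optional list overriding `maxit`, `reltol`,
#'   `penalty_weight`, `margin`.
#' @return An object of class `sdngc_fit` with the fitted model, the
#'   maximized log-likelihood, parameter and observation counts, and a
#'   convergence record.
#' @export
fit_arbekk <- function(panel, p = 1, q = 1, control = list()) {
  stopifnot(inherits(panel, "trial_panel"))
  if (n_channels(panel) != 1L)
    stop("fit_arbekk handles univariate panels; use fit_joint_arbekk for paired series")
  if (q > 1L || (p > 1L && q >= 1L))
    stop("the constrained second-order condition is derived for p = q = 1")
  ctl <- fit_control(control)
  init <- arbekk_init(panel, p = p, q = q)
  m <- max(p, q)
  d <- lag_design(panel$values, m)
  a0 <- vapply(init$A, function(M) M[1L, 1L], numeric(1L))
  b0 <- if (q) vapply(init$B, function(M) M[1L, 1L], numeric(1L)) else numeric(0)
  theta0 <- c(a0, b0, log(init$W_chol[1L, 1L]^2))
  unpack <- function(th) {
    a <- th[seq_len(p)]
    b <- if (q) th[p + seq_len(q)] else numeric(0)
    w <- exp(clamp_logvar(th[p + q + 1L]))
    list(a = a, b = b, w = w)
  }
  negll <- function(th) {
    pp <- unpack(th)
    # companion spectral radius of a scalar AR(p): reciprocal root of the
    # characteristic polynomial 1 - a_1 z - ... - a_p z^p
    r1 <- 1 / min(Mod(polyroot(c(1, -pp$a))))
    pen <- ctl$penalty_weight * max(0, r1 - (1 - ctl$margin))^2
    if (p == 1L && q == 1L) {
      r2 <- pp$a[1L]^2 + pp$b[1L]^2
      pen <- pen + ctl$penalty_weight * max(0, r2 - (1 - ctl$margin))^2
    }
    A_rows <- lapply(pp$a, function(v) matrix(v, 1L, 1L))
    B_rows <- lapply(pp$b, function(v) matrix(v, 1L, 1L))
    -block_loglik_core(d$y, d$lags, A_rows, B_rows, matrix(sqrt(pp$w), 1L, 1L)) + pen
  }
  opt <- optimize_negll(theta0, negll, ctl)
  pp <- unpack(opt$par)
  b_final <- if (q) abs(pp$b) else numeric(0)  # scalar volatility sign convention
  model <- arbekk_model(A = lapply(pp$a, function(v) matrix(v, 1L, 1L)),
                        B = lapply(b_final, function(v) matrix(v, 1L, 1L)),
                        W_chol = matrix(sqrt(pp$w), 1L, 1L))
  model <- enforce_stability(model)
  ll <- arbekk_loglik(model, panel)
  new_sdngc_fit(model, ll, n_params = p + q + 1L, n_obs = d$n_obs,
                converged = opt$converged, algorithm = opt$algorithm,
                trace = opt["message"], init_loglik = arbekk_loglik(init, panel))
}

# Final guard: shrink volatility (then mean) coefficients just inside
# the stable region when a penalized optimum sits on the boundary.
enforce_stability <- function(model) {
  f <- first_order_stable(model)
  if (f$radius >= 1) {
    sc <- (1 - 1e-6) / f$radius
    model$A <- lapply(model$A, function(M) M * sc)
  }
  if (model$p <= 1L && model$q == 1L) {
    for (it in seq_len(200L)) {
      s <- second_order_stable(model)
      if (s$radius < 1) break
      shrink <- function(M) M * 0.995
      if (inherits(model, "arbekk_model")) model$B <- lapply(model$B, shrink)
      else { model$Bx <- lapply(model$Bx, shrink); model$By <- lapply(model$By, shrink) }
    }
  }
  model
}

# ---- joint (two-block) fitting -------------------------------------------

# Fit one univariate block of the joint model: target channel `target`,
# regressors all k channels with `free_cols` marking unrestricted
# columns (restricted cross-columns are held at zero).  The volatility
# surface is multimodal in the cross-coefficients (only the linear
# combination entering the squared term is observed), so unrestricted
# fits run from several starts — the least-squares start, cross-
# volatility perturbations of either sign, and any caller-supplied
# warm starts — and keep the best optimum.
fit_scalar_block <- function(d, target, free_cols, p, q, ctl,
                             extra_starts = list()) {
  k <- d$k
  y <- d$y[, target, drop = FALSE]
  nf <- sum(free_cols)
  Xm <- do.call(cbind, lapply(d$lags[seq_len(p)],
                              function(L) L[, free_cols, drop = FALSE]))
  cf <- stats::lm.fit(Xm, y[, 1L])$coefficients
  cf[is.na(cf)] <- 0
  e <- y[, 1L] - Xm %*% cf
  if (q >= 1L) {
    Z <- cbind(1, vapply(seq_len(q), function(j) d$lags[[j]][, target]^2,
                         numeric(length(e))))
    vc <- stats::lm.fit(Z, as.vector(e)^2)$coefficients
    vc[is.na(vc)] <- 0
    w0 <- max(vc[1L], 1e-6)
    bdiag0 <- sqrt(pmax(vc[-1L], 0))
  } else {
    w0 <- max(mean(e^2), 1e-6)
    bdiag0 <- numeric(0)
  }
  a0 <- numeric(p * nf)
  a0[seq_along(cf)] <- cf
  b0 <- numeric(q * nf)
  own <- which(which(free_cols) == target)
  if (q >= 1L && length(own)) {
    for (j in seq_len(q)) b0[(j - 1L) * nf + own] <- min(bdiag0[j], 0.9)
  }
  theta0 <- c(a0, b0, log(w0))
  unpack <- function(th) {
    A_rows <- vector("list", p); B_rows <- vector("list", q)
    for (i in seq_len(p)) {
      row <- numeric(k); row[free_cols] <- th[(i - 1L) * nf + seq_len(nf)]
      A_rows[[i]] <- matrix(row, 1L, k)
    }
    for (j in seq_len(q)) {
      row <- numeric(k); row[free_cols] <- th[p * nf + (j - 1L) * nf + seq_len(nf)]
      B_rows[[j]] <- matrix(row, 1L, k)
    }
    w <- exp(clamp_logvar(th[(p + q) * nf + 1L]))
    list(A_rows = A_rows, B_rows = B_rows, w = w)
  }
  negll <- function(th) {
    pp <- unpack(th)
    -block_loglik_core(y, d$lags, pp$A_rows, pp$B_rows, matrix(sqrt(pp$w), 1L, 1L))
  }
  starts <- c(list(theta0), extra_starts)
  if (q >= 1L && nf > 1L) {
    cross <- setdiff(seq_len(nf), own)
    for (s in c(0.4, -0.4)) {
      th <- theta0
      for (j in seq_len(q)) th[p * nf + (j - 1L) * nf + cross] <- s
      starts <- c(starts, list(th))
    }
  }
  opt <- NULL
  for (th0 in starts) {
    cand <- optimize_negll(th0, negll, ctl)
    if (is.null(opt) || cand$value < opt$value) opt <- cand
  }
  pp <- unpack(opt$par)
  if (q >= 1L) {  # row sign convention: own-channel volatility entry nonnegative
    for (j in seq_len(q)) {
      if (pp$B_rows[[j]][1L, target] < 0) pp$B_rows[[j]] <- -pp$B_rows[[j]]
    }
  }
  list(A_rows = pp$A_rows, B_rows = pp$B_rows, w = pp$w,
       loglik = -negll(opt$par), converged = opt$converged,
       algorithm = opt$algorithm, message = opt$message,
       n_free = (p + q) * nf + 1L)
}

#' Constrained maximum-likelihood fit of the joint two-block AR-BEKK model
#'
#' Fits the partitioned model over the pair `(x, y)`, optionally with
#' the cross-coefficients of one direction held at zero (the nested
#' null model of the causality test).  Because the joint conditional
#' covariance is block-diagonal with independent innovations, the
#' likelihood separates over the two blocks; each block is maximized by
#' penalized quasi-Newton and the assembled model is refit jointly with
#' the stability penalty active only if it lands outside the stable
#' region.  For the scalar pair with `p = q = 1` the full model has 10
#' free parameters and either restricted model has 8.
#'
#' @param panel_x,panel_y aligned single-channel [trial_panel()]s (the
#'   blocks; multivariate blocks are not supported by the optimizer).
#' @param p,q model orders (`p = 1`; `q` in `{0, 1}`).
#' @param restriction `"none"`, `"y_to_x_zero"` or `"x_to_y_zero"`.
#' @param control optimizer control, see [fit_arbekk()].
#' @param warm_model optional [joint_arbekk_model()] (e.g. a nested
#'   fit) supplying an additional optimizer start for each block.
#' @return An object of class `sdngc_fit` holding a
#'   [joint_arbekk_model()].
#' @export
fit_joint_arbekk <- function(panel_x, panel_y, p = 1, q = 1,
                             restriction = c("none", "y_to_x_zero", "x_to_y_zero"),
                             control = list(), warm_model = NULL) {
  restriction <- match.arg(restriction)
  joint <- bind_channels(panel_x, panel_y)
  kx <- n_channels(panel_x); ky <- n_channels(panel_y)
  if (kx != 1L || ky != 1L)
    stop("joint fitting is implemented for univariate blocks (kx = ky = 1)")
  if (p != 1L || q > 1L)
    stop("joint fitting requires p = 1 and q in {0, 1}")
  ctl <- fit_control(control)
  if (stats::sd(joint$values) == 0) stop("degenerate (constant) input panel")
  d <- lag_design(joint$values, max(p, q))
  k <- kx + ky
  free_x <- rep(TRUE, k); free_y <- rep(TRUE, k)
  if (restriction == "y_to_x_zero") free_x[kx + seq_len(ky)] <- FALSE
  if (restriction == "x_to_y_zero") free_y[seq_len(kx)] <- FALSE
  warm_x <- warm_y <- list()
  if (!is.null(warm_model)) {
    pack_block <- function(A_row, B_row, w, free) {
      c(unlist(lapply(seq_len(p), function(i) A_row[[i]][free])),
        if (q) unlist(lapply(seq_len(q), function(j) B_row[[j]][free])),
        log(max(w, 1e-8)))
    }
    warm_x <- list(pack_block(lapply(warm_model$A, function(M) M[1L, ]),
                              lapply(warm_model$Bx, function(M) M[1L, ]),
                              warm_model$Wx_chol[1L, 1L]^2, free_x))
    warm_y <- list(pack_block(lapply(warm_model$A, function(M) M[2L, ]),
                              lapply(warm_model$By, function(M) M[1L, ]),
                              warm_model$Wy_chol[1L, 1L]^2, free_y))
  }
  bx <- fit_scalar_block(d, target = 1L, free_cols = free_x, p = p, q = q,
                         ctl = ctl, extra_starts = warm_x)
  by <- fit_scalar_block(d, target = 2L, free_cols = free_y, p = p, q = q,
                         ctl = ctl, extra_starts = warm_y)
  A <- lapply(seq_len(p), function(i) rbind(bx$A_rows[[i]], by$A_rows[[i]]))
  Bx <- if (q) lapply(seq_len(q), function(j) bx$B_rows[[j]]) else list()
  By <- if (q) lapply(seq_len(q), function(j) by$B_rows[[j]]) else list()
  model <- joint_arbekk_model(A = A, Bx = Bx, By = By,
                              Wx_chol = matrix(sqrt(bx$w), 1L, 1L),
                              Wy_chol = matrix(sqrt(by$w), 1L, 1L),
                              kx = kx, ky = ky, restriction = restriction)
  refit <- FALSE
  if (!joint_is_stable(model, p, q)) {
    model <- refit_joint_penalized(model, d, free_x, free_y, p, q, ctl)
    refit <- TRUE
  }
  ll <- arbekk_loglik(model, joint)
  converged <- bx$converged && by$converged
  new_sdngc_fit(model, ll, n_params = bx$n_free + by$n_free,
                n_obs = d$n_obs, converged = converged,
                algorithm = paste0("blockwise ", bx$algorithm,
                                   if (refit) " + joint-penalized refit" else ""),
                trace = list(x_block = bx$message, y_block = by$message),
                init_loglik = NA_real_)
}

joint_is_stable <- function(model, p, q) {
  f <- first_order_stable(model)
  if (!f$stable) return(FALSE)
  if (p <= 1L && q <= 1L) second_order_stable(model)$stable else TRUE
}

# Joint penalized refit over all free parameters of both blocks; only
# invoked when the separable optima assemble to an unstable model.
refit_joint_penalized <- function(model, d, free_x, free_y, p, q, ctl) {
  k <- model$k
  pack <- function(m) {
    c(as.vector(m$A[[1L]][1L, free_x]), as.vector(m$A[[1L]][2L, free_y]),
      if (q) c(as.vector(m$Bx[[1L]][1L, free_x]), as.vector(m$By[[1L]][1L, free_y])),
      log(m$Wx_chol[1L, 1L]^2), log(m$Wy_chol[1L, 1L]^2))
  }
  nx <- sum(free_x); ny <- sum(free_y)
  unpack <- function(th) {
    ax <- numeric(k); ax[free_x] <- th[seq_len(nx)]
    ay <- numeric(k); ay[free_y] <- th[nx + seq_len(ny)]
    at <- nx + ny
    if (q) {
      bxv <- numeric(k); bxv[free_x] <- th[at + seq_len(nx)]
      byv <- numeric(k); byv[free_y] <- th[at + nx + seq_len(ny)]
      at <- at + nx + ny
    } else bxv <- byv <- NULL
    wx <- exp(clamp_logvar(th[at + 1L])); wy <- exp(clamp_logvar(th[at + 2L]))
    joint_arbekk_model(A = list(rbind(ax, ay, deparse.level = 0)),
                       Bx = if (q) list(matrix(bxv, 1L, k)) else list(),
                       By = if (q) list(matrix(byv, 1L, k)) else list(),
                       Wx_chol = matrix(sqrt(wx), 1L, 1L),
                       Wy_chol = matrix(sqrt(wy), 1L, 1L),
                       kx = 1L, ky = 1L, restriction = model$restriction)
  }
  negll <- function(th) {
    m <- unpack(th)
    r1 <- first_order_stable(m)$radius
    pen <- ctl$penalty_weight * max(0, r1 - (1 - ctl$margin))^2
    if (p <= 1L && q == 1L) {
      r2 <- second_order_stable(m)$radius
      pen <- pen + ctl$penalty_weight * max(0, r2 - (1 - ctl$margin))^2
    }
    xi <- 1L; yi <- 2L
    llx <- block_loglik_core(d$y[, xi, drop = FALSE], d$lags,
                             list(m$A[[1L]][xi, , drop = FALSE]),
                             m$Bx, m$Wx_chol)
    lly <- block_loglik_core(d$y[, yi, drop = FALSE], d$lags,
                             list(m$A[[1L]][yi, , drop = FALSE]),
                             m$By, m$Wy_chol)
    -(llx + lly) + pen
  }
  opt <- optimize_negll(pack(model), negll, ctl)
  out <- unpack(opt$par)
  if (q) {  # sign convention, then final boundary guard
    if (out$Bx[[1L]][1L, 1L] < 0) out$Bx[[1L]] <- -out$Bx[[1L]]
    if (out$By[[1L]][1L, 2L] < 0) out$By[[1L]] <- -out$By[[1L]]
  }
  enforce_stability(out)
}
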