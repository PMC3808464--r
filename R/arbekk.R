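#' AR-BEKK model objects
#'
#' An AR-BEKK process combines a vector autoregression in the mean with
#' a BEKK-form conditional covariance driven by the lagged *process*
#' (not the residuals):
#' \deqn{x_t = \sum_{i=1}^p A_i x_{t-i} + H_t^{1/2} \epsilon_t, \qquad
#'       H_t = W + \sum_{j=1}^q B_j x_{t-j} x_{t-j}^\top B_j^\top,}
#' with \eqn{\epsilon_t} i.i.d. standard Gaussian.  The noise variance is
#' therefore a quadratic function of the signal ("signal-dependent
#' noise"); with all \eqn{B_j = 0} the model reduces to a Gaussian VAR.
#'
#' @param A mean coefficient matrices: a `k x k` matrix or a list of `p`
#'   such matrices.
#' @param B volatility coefficient matrices: a `k x k` matrix, a list of
#'   `q` such matrices, or an empty list for a pure VAR (`q = 0`).
#' @param W_chol lower-triangular Cholesky factor of the baseline
#'   conditional covariance `W = W_chol %*% t(W_chol)` (positive
#'   diagonal), guaranteeing positive definiteness.
#'
#' @return An object of class `arbekk_model` with fields `k`, `p`, `q`,
#'   `A`, `B`, `W_chol`.
#' @seealso [joint_arbekk_model()], [simulate.arbekk_model()],
#'   [first_order_stable()], [second_order_stable()]
#' @export
arbekk_model <- function(A, B = list(), W_chol) {
  A <- as_mat_list(A, "A")
  B <- as_mat_list(B, "B", allow_empty = TRUE)
  k <- nrow(A[[1L]])
  for (M in c(A, B)) {
    if (!is.matrix(M) || nrow(M) != k || ncol(M) != k)
      stop("all coefficient matrices must be square with matching dimension")
  }
  W_chol <- check_chol(W_chol, k)
  structure(list(k = k, p = length(A), q = length(B),
                 A = A, B = B, W_chol = W_chol),
            class = "arbekk_model")
}

#' Partitioned two-block AR-BEKK model for causal testing
#'
#' The joint model over blocks `x` (dimension `kx`) and `y` (dimension
#' `ky`) has a full mean recursion over the stacked state, but each
#' block's conditional covariance is driven by its own volatility rows
#' and innovations are independent across blocks, so the joint
#' conditional covariance is block-diagonal.  The block `y` does not
#' Granger-cause block `x` exactly when the `y`-columns of the `x`-rows
#' of every `A` and the `y`-columns of every `Bx` are zero.
#'
#' @param A list of `p` mean matrices of size `(kx+ky) x (kx+ky)`
#'   (block `x` rows first).
#' @param Bx list of `q` volatility matrices of size `kx x (kx+ky)`
#'   feeding block `x` (may be empty for `q = 0`).
#' @param By list of `q` volatility matrices of size `ky x (kx+ky)`.
#' @param Wx_chol,Wy_chol lower-triangular baseline covariance factors
#'   of the two blocks.
#' @param kx,ky block dimensions.
#' @param restriction `"none"`, `"y_to_x_zero"` or `"x_to_y_zero"`; when
#'   set, the corresponding cross-coefficient blocks must be zero.
#'
#' @return An object of class `joint_arbekk_model`.
#' @export
joint_arbekk_model <- function(A, Bx = list(), By = list(), Wx_chol, Wy_chol,
                               kx = NULL, ky = NULL,
                               restriction = c("none", "y_to_x_zero", "x_to_y_zero")) {
  restriction <- match.arg(restriction)
  A <- as_mat_list(A, "A")
  Bx <- as_mat_list(Bx, "Bx", allow_empty = TRUE)
  By <- as_mat_list(By, "By", allow_empty = TRUE)
  k <- nrow(A[[1L]])
  if (is.null(kx)) kx <- if (length(Bx)) nrow(Bx[[1L]]) else nrow(check_chol(Wx_chol, NULL))
  if (is.null(ky)) ky <- k - kx
  if (kx + ky != k) stop("kx + ky must equal the joint dimension")
  for (M in A) if (nrow(M) != k || ncol(M) != k) stop("A matrices must be (kx+ky) square")
  for (M in Bx) if (nrow(M) != kx || ncol(M) != k) stop("Bx matrices must be kx x (kx+ky)")
  for (M in By) if (nrow(M) != ky || ncol(M) != k) stop("By matrices must be ky x (kx+ky)")
  if (length(Bx) != length(By)) stop("Bx and By must have the same order q")
  Wx_chol <- check_chol(Wx_chol, kx)
  Wy_chol <- check_chol(Wy_chol, ky)
  xi <- seq_len(kx); yi <- kx + seq_len(ky)
  if (restriction == "y_to_x_zero") {
    for (M in A) if (any(M[xi, yi, drop = FALSE] != 0))
      stop("restriction y_to_x_zero requires zero y-columns in the x-rows of A")
    for (M in Bx) if (any(M[, yi, drop = FALSE] != 0))
      stop("restriction y_to_x_zero requires zero y-columns in Bx")
  }
  if (restriction == "x_to_y_zero") {
    for (M in A) if (any(M[yi, xi, drop = FALSE] != 0))
      stop("restriction x_to_y_zero requires zero x-columns in the y-rows of A")
    for (M in By) if (any(M[, xi, drop = FALSE] != 0))
      stop("restriction x_to_y_zero requires zero x-columns in By")
  }
  structure(list(kx = kx, ky = ky, k = k, p = length(A), q = length(Bx),
                 A = A, Bx = Bx, By = By,
                 Wx_chol = Wx_chol, Wy_chol = Wy_chol,
                 restriction = restriction),
            class = "joint_arbekk_model")
}

as_mat_list <- function(M, name, allow_empty = FALSE) {
  if (is.matrix(M)) return(list(M))
  if (is.numeric(M) && length(M) == 1L) return(list(matrix(M, 1L, 1L)))
  if (is.list(M)) {
    if (!length(M)) {
      if (allow_empty) return(list())
      stop("`", name, "` must contain at least one matrix")
    }
    return(lapply(M, function(m) {
      if (is.numeric(m) && length(m) == 1L) matrix(m, 1L, 1L)
      else if (is.matrix(m)) m
      else stop("`", name, "` must be a matrix or list of matrices")
    }))
  }
  stop("`", name, "` must be a matrix or list of matrices")
}

check_chol <- function(L, k) {
  if (is.numeric(L) && length(L) == 1L) L <- matrix(L, 1L, 1L)
  if (!is.matrix(L) || nrow(L) != ncol(L)) stop("Cholesky factor must be square")
  if (!is.null(k) && nrow(L) != k) stop("Cholesky factor has wrong dimension")
  if (any(L[upper.tri(L)] != 0)) stop("Cholesky factor must be lower triangular")
  if (any(diag(L) <= 0)) stop("Cholesky factor must have positive diagonal")
  L
}

#' @export
print.arbekk_model <- function(x, ...) {
  cat(sprintf("<arbekk_model> k = %d, p = %d, q = %d\n", x$k, x$p, x$q))
  invisible(x)
}

#' @export
print.joint_arbekk_model <- function(x, ...) {
  cat(sprintf("<joint_arbekk_model> kx = %d, ky = %d, p = %d, q = %d, restriction = %s\n",
              x$kx, x$ky, x$p, x$q, x$restriction))
  invisible(x)
}

#' First-order (mean-recursion) stability
#'
#' Checks that all eigenvalues of the mean recursion have modulus less
#' than one; for order `p > 1` the usual companion embedding of the VAR
#' is used.
#'
#' @param A a mean coefficient matrix, a list of `p` such matrices, or a
#'   model object (its `A` is used).
#' @return A list with `stable` (logical) and `radius` (spectral radius
#'   of the companion mean operator).
#' @export
first_order_stable <- function(A) {
  if (inherits(A, "arbekk_model") || inherits(A, "joint_arbekk_model")) A <- A$A
  A <- as_mat_list(A, "A")
  k <- nrow(A[[1L]])
  for (M in A) if (!is.matrix(M) || nrow(M) != k || ncol(M) != k)
    stop("mean matrices must be square with a common dimension")
  C <- companion_matrix(A)
  radius <- max(Mod(eigen(C, only.values = TRUE)$values))
  list(stable = radius < 1, radius = radius)
}

companion_matrix <- function(A) {
  p <- length(A); k <- nrow(A[[1L]])
  if (p == 1L) return(A[[1L]])
  C <- matrix(0, k * p, k * p)
  C[seq_len(k), ] <- do.call(cbind, A)
  C[k + seq_len(k * (p - 1L)), seq_len(k * (p - 1L))] <- diag(k * (p - 1L))
  C
}

#' Second-order (covariance-recursion) stability
#'
#' For the first-order model (`p = q = 1`) the stationary second moment
#' obeys a linear fixed point whose operator is
#' \eqn{M = A_1 \otimes A_1 + B_1 \otimes B_1}; the unconditional
#' covariance exists exactly when the spectral radius of `M` is below
#' one.  For the joint two-block model the cross-block rows of the
#' volatility term are projected out, because the joint conditional
#' covariance is block-diagonal.
#'
#' @param model an [arbekk_model()] or [joint_arbekk_model()].
#' @param ... unused.
#' @return A list with `stable` (logical) and `radius` (spectral radius
#'   of the second-moment operator).
#' @export
second_order_stable <- function(model, ...) UseMethod("second_order_stable")

#' @rdname second_order_stable
#' @export
second_order_stable.arbekk_model <- function(model, ...) {
  M <- second_moment_operator(model)
  radius <- max(Mod(eigen(M, only.values = TRUE)$values))
  list(stable = radius < 1, radius = radius)
}

#' @rdname second_order_stable
#' @export
second_order_stable.joint_arbekk_model <- function(model, ...) {
  M <- second_moment_operator(model)
  radius <- max(Mod(eigen(M, only.values = TRUE)$values))
  list(stable = radius < 1, radius = radius)
}

second_moment_operator <- function(model) {
  if (model$p > 1L || model$q > 1L)
    stop("second-order stability is only derived for first-order models (p = q = 1)")
  if (inherits(model, "arbekk_model")) {
    A1 <- model$A[[1L]]
    B1 <- if (model$q >= 1L) model$B[[1L]] else matrix(0, model$k, model$k)
    return(kronecker(A1, A1) + kronecker(B1, B1))
  }
  k <- model$k
  A1 <- model$A[[1L]]
  Bt <- if (model$q >= 1L) rbind(model$Bx[[1L]], model$By[[1L]]) else matrix(0, k, k)
  mask <- matrix(0, k, k)
  xi <- seq_len(model$kx); yi <- model$kx + seq_len(model$ky)
  mask[xi, xi] <- 1; mask[yi, yi] <- 1
  D <- diag(as.vector(mask))
  kronecker(A1, A1) + D %*% kronecker(Bt, Bt)
}

#' Conditional covariance given a history
#'
#' Evaluates \eqn{H_t = W + \sum_j B_j x_{t-j} x_{t-j}^\top B_j^\top}
#' for a supplied history.  With all `B = 0` this reduces to the
#' constant baseline covariance `W` (the Gaussian VAR case).
#'
#' @param model an [arbekk_model()] or [joint_arbekk_model()].
#' @param history the last `q` state vectors: a `q x k` matrix whose row
#'   `j` is the state at lag `j` (row 1 = most recent), or a vector for
#'   `k = 1` / `q = 1`.
#' @return The `k x k` conditional covariance matrix (block-diagonal for
#'   joint models).
#' @export
conditional_covariance <- function(model, history) {
  k <- model$k; q <- model$q
  history <- as_history(history, k, q)
  if (inherits(model, "arbekk_model")) {
    H <- model$W_chol %*% t(model$W_chol)
    for (j in seq_len(q)) {
      v <- model$B[[j]] %*% history[j, ]
      H <- H + tcrossprod(v)
    }
    return((H + t(H)) / 2)
  }
  Hx <- model$Wx_chol %*% t(model$Wx_chol)
  Hy <- model$Wy_chol %*% t(model$Wy_chol)
  for (j in seq_len(q)) {
    vx <- model$Bx[[j]] %*% history[j, ]
    vy <- model$By[[j]] %*% history[j, ]
    Hx <- Hx + tcrossprod(vx)
    Hy <- Hy + tcrossprod(vy)
  }
  H <- matrix(0, k, k)
  H[seq_len(model$kx), seq_len(model$kx)] <- (Hx + t(Hx)) / 2
  H[model$kx + seq_len(model$ky), model$kx + seq_len(model$ky)] <- (Hy + t(Hy)) / 2
  H
}

as_history <- function(history, k, q) {
  if (is.null(dim(history))) {
    if (k == 1L) history <- matrix(history, ncol = 1L)
    else if (length(history) == k) history <- matrix(history, nrow = 1L)
    else stop("history must be a q x k matrix")
  }
  if (ncol(history) != k) stop("history must have k columns")
  if (nrow(history) < q) stop("insufficient history: need at least q = ", q, " rows")
  history[seq_len(max(q, 1L)), , drop = FALSE]
}

#' Stationary second moment of a first-order AR-BEKK model
#'
#' Solves the vectorized fixed point
#' \eqn{\mathrm{vec}(S) = (A \otimes A + B \otimes B)\,\mathrm{vec}(S) +
#' \mathrm{vec}(W)} of the second-moment recursion.  For a scalar model
#' this is \eqn{S = w / (1 - a^2 - b^2)}; with `B = 0` it is the
#' classical VAR stationary covariance.
#'
#' @param model an [arbekk_model()] or [joint_arbekk_model()] with
#'   `p = q = 1` that passes [second_order_stable()].
#' @return The symmetric positive definite `k x k` stationary second
#'   moment `S`.
#' @export
stationary_second_moment <- function(model) {
  chk <- second_order_stable(model)
  if (!chk$stable)
    stop(sprintf("model is second-order unstable (radius %.3f >= 1): no stationary moment", chk$radius))
  M <- second_moment_operator(model)
  k <- model$k
  if (inherits(model, "arbekk_model")) {
    W <- model$W_chol %*% t(model$W_chol)
  } else {
    W <- matrix(0, k, k)
    W[seq_len(model$kx), seq_len(model$kx)] <- model$Wx_chol %*% t(model$Wx_chol)
    W[model$kx + seq_len(model$ky), model$kx + seq_len(model$ky)] <-
      model$Wy_chol %*% t(model$Wy_chol)
  }
  s <- solve(diag(k * k) - M, as.vector(W))
  S <- matrix(s, k, k)
  (S + t(S)) / 2
}

#' Simulate an AR-BEKK process
#'
#' Generates independent trial realizations of the model recursion,
#' starting from a zero initial state and discarding a burn-in segment.
#' The conditional covariance square root is taken as its Cholesky
#' factor (any factor `L` with `L L' = H` yields the same Gaussian
#' distribution).
#'
#' @param object an [arbekk_model()] or [joint_arbekk_model()].
#' @param nsim number of independent trials.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param n_time number of retained time points per trial.
#' @param burn_in number of initial samples discarded per trial.
#' @param dt sampling interval recorded in the output panel.
#' @param override_unstable simulate even if the stability checks fail.
#' @param ... unused.
#' @return A [trial_panel()] of dimension `nsim x n_time x k`.
#' @export
simulate.arbekk_model <- function(object, nsim = 1, seed = NULL, n_time = 100,
                                  burn_in = 500, dt = 1,
                                  override_unstable = FALSE, ...) {
  check_simulation_stability(object, override_unstable)
  with_seed(seed, simulate_arbekk_core(object, nsim, n_time, burn_in, dt))
}

#' @rdname simulate.arbekk_model
#' @export
simulate.joint_arbekk_model <- function(object, nsim = 1, seed = NULL, n_time = 100,
                                        burn_in = 500, dt = 1,
                                        override_unstable = FALSE, ...) {
  check_simulation_stability(object, override_unstable)
  with_seed(seed, simulate_arbekk_core(object, nsim, n_time, burn_in, dt))
}

check_simulation_stability <- function(model, override) {
  if (override) return(invisible(TRUE))
  f <- first_order_stable(model)
  if (!f$stable)
    stop(sprintf("model is first-order unstable (radius %.3f >= 1); pass override_unstable = TRUE to force", f$radius))
  if (model$p <= 1L && model$q <= 1L) {
    s <- second_order_stable(model)
    if (!s$stable)
      stop(sprintf("model is second-order unstable (radius %.3f >= 1); pass override_unstable = TRUE to force", s$radius))
  }
  invisible(TRUE)
}

simulate_arbekk_core <- function(model, nsim, n_time, burn_in, dt) {
  k <- model$k; p <- model$p; q <- model$q
  m <- max(p, q)
  total <- n_time + burn_in
  joint <- inherits(model, "joint_arbekk_model")
  scalar <- (k == 1L && !joint)
  vals <- array(0, dim = c(nsim, n_time, k))
  if (scalar) {
    a <- vapply(model$A, function(M) M[1L, 1L], numeric(1L))
    b <- if (q) vapply(model$B, function(M) M[1L, 1L], numeric(1L)) else numeric(0)
    w <- model$W_chol[1L, 1L]^2
    for (tr in seq_len(nsim)) {
      x <- numeric(m + total)
      eps <- stats::rnorm(total)
      for (t in (m + 1L):(m + total)) {
        mu <- 0; h <- w
        for (i in seq_len(p)) mu <- mu + a[i] * x[t - i]
        for (j in seq_len(q)) h <- h + (b[j] * x[t - j])^2
        x[t] <- mu + sqrt(h) * eps[t - m]
      }
      vals[tr, , 1L] <- x[m + burn_in + seq_len(n_time)]
    }
  } else {
    for (tr in seq_len(nsim)) {
      x <- matrix(0, m + total, k)
      eps <- matrix(stats::rnorm(total * k), total, k)
      for (t in (m + 1L):(m + total)) {
        mu <- numeric(k)
        for (i in seq_len(p)) mu <- mu + model$A[[i]] %*% x[t - i, ]
        hist <- x[t - seq_len(max(q, 1L)), , drop = FALSE]
        H <- conditional_covariance(model, hist)
        L <- t(chol(H))
        x[t, ] <- mu + L %*% eps[t - m, ]
      }
      vals[tr, , ] <- x[m + burn_in + seq_len(n_time), ]
    }
  }
  nm <- if (joint) c(paste0("x", seq_len(model$kx)), paste0("y", seq_len(model$ky)))
        else paste0("ch", seq_len(k))
  trial_panel(vals, dt = dt, channel_names = nm)
}
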