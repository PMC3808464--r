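# Projection-based diagnostics for signal-dependent noise.  The
# "signal" at time t is the projection of x_t onto a subspace spanned
# by functions of its own past; the "noise" is the projection residual,
# whose variance across trials at a fixed within-trial time point is
# compared with the squared signal.

#' Projection basis specification
#'
#' Three families of basis functions of the lagged values are
#' supported: `"linear"` (the lagged values themselves), `"poly2"`
#' (lagged values and their squares) and `"fourier6"` (order 1..6
#' sine/cosine pairs of each lagged value rescaled to `[-1, 1]` by the
#' panel-wide range).  Regressor counts are `n_lags`, `2 * n_lags` and
#' `12 * n_lags` respectively, plus an intercept when requested.
#'
#' @param family basis family.
#' @param n_lags number of time lags (`>= 1`).
#' @param include_intercept include an intercept column.
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(family = c("linear", "poly2", "fourier6"),
                       n_lags = 1L, include_intercept = TRUE) {
  family <- match.arg(family)
  n_lags <- as.integer(n_lags)
  if (n_lags < 1L) stop("`n_lags` must be >= 1")
  n_reg <- switch(family, linear = n_lags, poly2 = 2L * n_lags,
                  fourier6 = 12L * n_lags)
  structure(list(family = family, n_lags = n_lags,
                 include_intercept = include_intercept,
                 n_regressors = n_reg),
            class = "basis_spec")
}

#' Build the pooled projection design for one channel of a panel
#'
#' Rows are `(trial, t)` pairs with `t > n_lags`, pooled over all
#' trials; columns are the basis functions of the channel's lagged
#' values.
#'
#' @param panel a [trial_panel()].
#' @param spec a [basis_spec()].
#' @param channel channel index or name (single channel).
#' @return A list with design matrix `X`, response `y`, and the
#'   `trial` / `time` index of every row.
#' @export
build_design <- function(panel, spec, channel = 1L) {
  stopifnot(inherits(panel, "trial_panel"), inherits(spec, "basis_spec"))
  if (is.character(channel)) channel <- match(channel, panel$channel_names)
  L <- spec$n_lags
  if (n_times(panel) < L + 2L) stop("trial shorter than n_lags + 2")
  v <- panel$values[, , channel, drop = FALSE]
  dim(v) <- dim(v)[1:2]
  ntr <- nrow(v); tt <- ncol(v)
  idx <- (L + 1L):tt
  y <- as.vector(v[, idx])
  lagmat <- vapply(seq_len(L), function(j) as.vector(v[, idx - j]),
                   numeric(ntr * length(idx)))
  X <- switch(spec$family,
    linear = lagmat,
    poly2 = cbind(lagmat, lagmat^2),
    fourier6 = {
      rng <- range(v)
      u <- if (diff(rng) > 0) 2 * (lagmat - rng[1L]) / diff(rng) - 1 else lagmat * 0
      do.call(cbind, lapply(1:6, function(j) cbind(sin(j * pi * u), cos(j * pi * u))))
    })
  X <- as.matrix(X)
  if (spec$include_intercept) X <- cbind(`(intercept)` = 1, X)
  list(X = X, y = y,
       trial = rep(seq_len(ntr), times = length(idx)),
       time = rep(idx, each = ntr))
}

#' Empirical signal and noise by projection onto the past
#'
#' Projects the current state of each channel onto the span of the
#' chosen basis functions of its past (one pooled least-squares fit per
#' channel across all trials).  The fitted values are the empirical
#' signal, the residuals the empirical noise, and the noise variance at
#' each within-trial time point is the variance of the residuals across
#' trials.  Collinear design columns are dropped and recorded.
#'
#' @param panel a [trial_panel()] with at least 10 trials (the
#'   across-trial variance must be estimable).
#' @param spec a [basis_spec()].
#' @return An object of class `empirical_sn` with arrays `signal_hat`
#'   and `residual` of dimension `(trial, time, channel)` (time points
#'   `n_lags + 1 .. T`), the `noise_var` matrix (time x channel), per
#'   channel `r2`, the basis used, and any dropped columns.
#' @export
empirical_signal_noise <- function(panel, spec) {
  stopifnot(inherits(panel, "trial_panel"), inherits(spec, "basis_spec"))
  if (n_trials(panel) < 10L)
    stop("at least 10 trials are required to estimate the across-trial noise variance")
  k <- n_channels(panel)
  L <- spec$n_lags
  ntr <- n_trials(panel)
  nt <- n_times(panel) - L
  signal <- resid <- array(NA_real_, dim = c(ntr, nt, k))
  noise_var <- matrix(NA_real_, nt, k,
                      dimnames = list(NULL, panel$channel_names))
  r2 <- numeric(k)
  dropped <- vector("list", k)
  for (c_ in seq_len(k)) {
    dsg <- build_design(panel, spec, channel = c_)
    fit <- stats::lm.fit(dsg$X, dsg$y)
    cf <- fit$coefficients
    drop_idx <- which(is.na(cf))
    dropped[[c_]] <- colnames(dsg$X)[drop_idx]
    cf[is.na(cf)] <- 0
    fitted <- as.vector(dsg$X %*% cf)
    res <- dsg$y - fitted
    sig_m <- matrix(fitted, ntr, nt)
    res_m <- matrix(res, ntr, nt)
    signal[, , c_] <- sig_m
    resid[, , c_] <- res_m
    noise_var[, c_] <- apply(res_m, 2L, stats::var)
    tss <- sum((dsg$y - mean(dsg$y))^2)
    r2[c_] <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  }
  structure(list(signal_hat = signal, residual = resid,
                 noise_var = noise_var, basis = spec,
                 time_index = (L + 1L):n_times(panel),
                 r2 = stats::setNames(r2, panel$channel_names),
                 dropped = dropped, dt = panel$dt),
            class = "empirical_sn")
}

#' @export
print.empirical_sn <- function(x, ...) {
  d <- dim(x$signal_hat)
  cat(sprintf("<empirical_sn> basis %s (%d lag(s)), %d trial(s) x %d time point(s) x %d channel(s)\n",
              x$basis$family, x$basis$n_lags, d[1L], d[2L], d[3L]))
  cat("r2:", paste(sprintf("%s = %.3f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' Correlation between squared signal and across-trial noise variance
#'
#' The headline diagnostic: the per-time-point mean of the squared
#' empirical signal is correlated with the across-trial noise variance
#' over within-trial time points, pooling channels.  A significantly
#' positive correlation indicates signal-dependent noise; an
#' approximately linear relation is the signature of a variance that is
#' quadratic in the signal.
#'
#' @param esn an [empirical_signal_noise()] result.
#' @param method `"pearson"` (default; the relation of interest is
#'   linear) or `"spearman"`.
#' @return A list with the correlation `r`, its two-sided `p_value`,
#'   and the number of points `n`.
#' @export
sdn_correlation <- function(esn, method = c("pearson", "spearman")) {
  stopifnot(inherits(esn, "empirical_sn"))
  method <- match.arg(method)
  ms2 <- apply(esn$signal_hat^2, c(2L, 3L), mean)
  x <- as.vector(ms2)
  y <- as.vector(esn$noise_var)
  if (dim(esn$signal_hat)[2L] < 5L)
    stop("at least 5 within-trial time points are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant squared signal or noise variance")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Concordance between model-based and empirical signal/noise
#'
#' Correlates the empirically estimated (projection-based) signal with
#' the fitted model's one-step mean prediction, and the empirical
#' across-trial noise variance with the per-time average of the model's
#' conditional variance.  High correlations indicate that the
#' parametric model captures the signal and noise structure found
#' non-parametrically.
#'
#' @param fit an [fit_arbekk()] result (univariate model) computed on
#'   `panel`.
#' @param esn an [empirical_signal_noise()] result computed on `panel`.
#' @param panel the common [trial_panel()] (single channel).
#' @return A list with `r_signal`, `r_variance` (NA with an explanatory
#'   `note` when the model variance is constant), and the number of
#'   common time points.
#' @export
model_concordance <- function(fit, esn, panel) {
  stopifnot(inherits(fit, "sdngc_fit"), inherits(esn, "empirical_sn"),
            inherits(panel, "trial_panel"))
  model <- fit$model
  if (!inherits(model, "arbekk_model") || model$k != 1L)
    stop("model_concordance expects a univariate arbekk_model fit")
  if (dim(esn$signal_hat)[1L] != n_trials(panel))
    stop("mismatched panels: trial counts differ")
  m <- max(model$p, model$q)
  v <- panel$values[, , 1L]
  ntr <- nrow(v); tt <- ncol(v)
  a <- vapply(model$A, function(M) M[1L, 1L], numeric(1L))
  b <- if (model$q) vapply(model$B, function(M) M[1L, 1L], numeric(1L)) else numeric(0)
  w <- model$W_chol[1L, 1L]^2
  t_model <- (m + 1L):tt
  mu <- matrix(0, ntr, length(t_model))
  hv <- matrix(w, ntr, length(t_model))
  for (i in seq_along(a)) mu <- mu + a[i] * v[, t_model - i]
  for (j in seq_along(b)) hv <- hv + (b[j] * v[, t_model - j])^2
  t_common <- intersect(esn$time_index, t_model)
  if (length(t_common) < 3L) stop("mismatched panels: too few overlapping time points")
  ei <- match(t_common, esn$time_index)
  mi <- match(t_common, t_model)
  r_signal <- stats::cor(as.vector(esn$signal_hat[, ei, 1L]),
                         as.vector(mu[, mi]))
  hbar <- colMeans(hv)[mi]
  if (stats::sd(hbar) < 1e-12) {
    r_variance <- NA_real_
    note <- "model conditional variance is constant (B = 0); variance concordance undefined"
  } else {
    r_variance <- stats::cor(esn$noise_var[ei, 1L], hbar)
    note <- NULL
  }
  list(r_signal = r_signal, r_variance = r_variance,
       n_time = length(t_common), note = note)
}

#' Sweep the diagnostic across basis families and lags
#'
#' Convenience wrapper running [empirical_signal_noise()] +
#' [sdn_correlation()] over a grid of projection spaces (defaults:
#' linear bases up to 9 lags, second-order polynomial bases up to 6
#' lags, sixth-order Fourier bases up to 2 lags).
#'
#' @param panel a [trial_panel()].
#' @param families named list mapping family to maximum lag.
#' @param method correlation method.
#' @return A data frame with one row per (family, n_lags): `r`,
#'   `p_value`, pooled `r2`.
#' @export
sdn_diagnostic_sweep <- function(panel,
                                 families = list(linear = 9L, poly2 = 6L,
                                                 fourier6 = 2L),
                                 method = "pearson") {
  out <- list()
  for (fam in names(families)) {
    for (L in seq_len(families[[fam]])) {
      if (n_times(panel) < L + 5L) next
      esn <- empirical_signal_noise(panel, basis_spec(fam, n_lags = L))
      sc <- sdn_correlation(esn, method = method)
      out[[length(out) + 1L]] <- data.frame(
        family = fam, n_lags = L, r = sc$r, p_value = sc$p_value,
        r2 = mean(esn$r2, na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}
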