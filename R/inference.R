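# Causal inference: the classical Granger likelihood-ratio test, its
# signal-dependent-noise analogue, and the two-sided test on the
# difference of causalities in opposite directions.

new_causality_test <- function(direction, statistic, df, p_value, method,
                               full_fit, restricted_fit, extra = list()) {
  structure(c(list(direction = direction, statistic = statistic, df = df,
                   p_value = p_value, method = method,
                   full_fit = full_fit, restricted_fit = restricted_fit),
              extra),
            class = "causality_test")
}

#' @export
print.causality_test <- function(x, ...) {
  cat(sprintf("<causality_test> %s [%s]: G = %.4f, df = %d, p = %.4g\n",
              x$direction, x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Classical Granger causality (Gaussian VAR likelihood-ratio test)
#'
#' Tests whether the past of `panel_y` improves the least-squares
#' prediction of `panel_x` beyond `panel_x`'s own past (the direction
#' `y -> x`).  The restricted model regresses the target block on its
#' own `p` lags; the full model adds the source block's lags; both are
#' pooled over trials.  The statistic is the Gaussian likelihood ratio
#' \eqn{G = 2(\ln L_f - \ln L_r) = n \ln(\det\Sigma_r / \det\Sigma_f)},
#' referred to a chi-squared null with `p * kx * ky` degrees of freedom.
#' Geweke's measure \eqn{F = \ln(\det\Sigma_r / \det\Sigma_f)} is
#' reported alongside (so `G = n F` exactly).
#'
#' @param panel_x target [trial_panel()] (the block being predicted).
#' @param panel_y source [trial_panel()] whose influence is tested.
#' @param p VAR order (`>= 1`).
#' @return A `causality_test` with fields `statistic`, `df`, `p_value`,
#'   `F` (Geweke's measure), `n_obs`, and both fits.
#' @export
classical_gc <- function(panel_x, panel_y, p = 1) {
  stopifnot(p >= 1L)
  joint <- bind_channels(panel_x, panel_y)
  if (n_times(joint) < p + 2L) stop("series shorter than p + 2")
  kx <- n_channels(panel_x); ky <- n_channels(panel_y)
  d <- lag_design(joint$values, p)
  xi <- seq_len(kx)
  Y <- d$y[, xi, drop = FALSE]
  X_own <- do.call(cbind, lapply(d$lags[seq_len(p)],
                                 function(L) L[, xi, drop = FALSE]))
  X_all <- do.call(cbind, d$lags[seq_len(p)])
  n <- nrow(Y)
  res_r <- stats::lm.fit(X_own, Y)$residuals
  res_f <- stats::lm.fit(X_all, Y)$residuals
  Sr <- crossprod(as.matrix(res_r)) / n
  Sf <- crossprod(as.matrix(res_f)) / n
  F_gew <- as.numeric(determinant(as.matrix(Sr), logarithm = TRUE)$modulus -
                      determinant(as.matrix(Sf), logarithm = TRUE)$modulus)
  G <- n * F_gew
  df <- p * kx * ky
  pval <- stats::pchisq(max(G, 0), df = df, lower.tail = FALSE)
  new_causality_test(
    direction = paste0(paste(panel_y$channel_names, collapse = "+"), " -> ",
                       paste(panel_x$channel_names, collapse = "+")),
    statistic = G, df = df, p_value = pval, method = "classical",
    full_fit = list(sigma = Sf, n_params = p * kx * (kx + ky)),
    restricted_fit = list(sigma = Sr, n_params = p * kx * kx),
    extra = list(F = F_gew, n_obs = n))
}

#' Granger causality with signal-dependent noise (AR-BEKK LR test)
#'
#' Fits the joint AR-BEKK model with and without the tested direction's
#' cross-coefficients (both the mean column and the volatility column
#' feeding the target block) and forms the likelihood-ratio statistic
#' \eqn{G = 2(\ln L_f - \ln L_r)}, referred to a chi-squared null whose
#' degrees of freedom equal the number of zeroed coefficients,
#' `(p + q) * kx * ky` (2 for a scalar pair at `p = q = 1`).  The test
#' is sensitive to influences on the target's mean *and* on its noise
#' variance.  Non-convergence of either fit is propagated through the
#' `reliable` flag, never silently dropped.
#'
#' @param panel_x target [trial_panel()].
#' @param panel_y source [trial_panel()] whose influence `y -> x` is tested.
#' @param p,q model orders (`p = 1`, `q` in `{0, 1}`; `q = 0` reduces to
#'   the classical Gaussian test fitted by maximum likelihood).
#' @param control optimizer control, see [fit_arbekk()].
#' @return A `causality_test`; tiny negative statistics (optimizer
#'   round-off on nested fits) are clamped to zero.
#' @export
sdn_gc <- function(panel_x, panel_y, p = 1, q = 1, control = list()) {
  restr <- fit_joint_arbekk(panel_x, panel_y, p = p, q = q,
                            restriction = "y_to_x_zero", control = control)
  # warm-starting the full fit from the nested optimum guarantees the
  # likelihood-ratio nesting inequality up to optimizer round-off
  full <- fit_joint_arbekk(panel_x, panel_y, p = p, q = q,
                           restriction = "none", control = control,
                           warm_model = restr$model)
  G_raw <- 2 * (full$loglik - restr$loglik)
  reliable <- full$converged && restr$converged && G_raw > -0.01
  G <- max(G_raw, 0)
  kx <- n_channels(panel_x); ky <- n_channels(panel_y)
  df <- (p + q) * kx * ky
  pval <- stats::pchisq(G, df = df, lower.tail = FALSE)
  new_causality_test(
    direction = paste0(paste(panel_y$channel_names, collapse = "+"), " -> ",
                       paste(panel_x$channel_names, collapse = "+")),
    statistic = G, df = df, p_value = pval, method = "sdn",
    full_fit = full, restricted_fit = restr,
    extra = list(statistic_raw = G_raw, reliable = reliable, n_obs = full$n_obs))
}

#' Distribution of the difference of two chi-squared variables
#'
#' CDF of `D = X - Y` with `X, Y` independent chi-squared on `df`
#' degrees of freedom, the null of the difference-of-causalities test.
#' The density is the variance-gamma form
#' \deqn{f(d) = \frac{(1/2)^{df}}{\sqrt{\pi}\,\Gamma(df/2)}
#'   |d|^{(df-1)/2} K_{(df-1)/2}(|d|/2),}
#' with `K` the modified Bessel function of the second kind; the CDF is
#' obtained by numerical quadrature and is exactly 0.5 at zero by
#' symmetry.  For `df = 2` the distribution is Laplace with scale 2, so
#' \eqn{P(|D| > d) = e^{-d/2}} serves as a closed-form cross-check.
#'
#' @param d quantile(s).
#' @param df common degrees of freedom (positive integer).
#' @return `P(D <= d)`, vectorized over `d`.
#' @export
difference_cdf <- function(d, df) {
  if (length(df) != 1L || !is.finite(df) || df < 1 || df != round(df))
    stop("`df` must be a positive integer")
  dens <- function(u) chisq_diff_density(u, df)
  vapply(d, function(di) {
    if (di == 0) return(0.5)
    half <- stats::integrate(dens, 0, abs(di), rel.tol = 1e-10,
                             abs.tol = 1e-12)$value
    half <- min(half, 0.5)
    if (di > 0) 0.5 + half else 0.5 - half
  }, numeric(1L))
}

#' @rdname difference_cdf
#' @export
chisq_diff_density <- function(d, df) {
  nu <- (df - 1) / 2
  const <- 0.5^df / (sqrt(pi) * gamma(df / 2))
  out <- numeric(length(d))
  ad <- abs(d)
  pos <- ad > 0
  out[pos] <- const * ad[pos]^nu * besselK(ad[pos] / 2, nu)
  # small-argument limit: d^nu K_nu(d/2) -> Gamma(nu) 4^nu / 2 for nu > 0,
  # so the density is finite at zero for df >= 2 and diverges
  # (integrably, like -log|d|) only for df = 1
  if (any(!pos))
    out[!pos] <- if (df == 1) Inf else const * gamma(nu) * 4^nu / 2
  out
}

#' Two-sided test on the difference of causalities in opposite directions
#'
#' Given the likelihood-ratio statistics for `forward` (x -> y style)
#' and `backward` directions of the same pair — each approximately
#' chi-squared on `df` degrees of freedom under its null — tests whether
#' one direction dominates, using the symmetric difference distribution
#' of [difference_cdf()].
#'
#' @param G_forward,G_backward the two directed statistics.
#' @param df their common degrees of freedom.
#' @param alpha significance level used to call a dominant direction.
#' @param labels optional length-2 character vector naming the
#'   directions.
#' @return A list of class `difference_test` with `delta`
#'   (`G_forward - G_backward`), `p_value` (two-sided), and `dominant`.
#' @export
difference_test <- function(G_forward, G_backward, df, alpha = 0.01,
                            labels = c("forward", "backward")) {
  stopifnot(length(G_forward) == 1L, length(G_backward) == 1L)
  delta <- G_forward - G_backward
  p <- 2 * (1 - difference_cdf(abs(delta), df))
  p <- min(max(p, 0), 1)
  dominant <- if (p < alpha) labels[if (delta > 0) 1L else 2L] else "none"
  structure(list(delta = delta, df = df, p_value = p, dominant = dominant,
                 alpha = alpha, labels = labels),
            class = "difference_test")
}

#' @export
print.difference_test <- function(x, ...) {
  cat(sprintf("<difference_test> delta = %.4f (df = %d), p = %.4g, dominant: %s\n",
              x$delta, x$df, x$p_value, x$dominant))
  invisible(x)
}

#' Pairwise directed causality table over a set of regions
#'
#' Runs the chosen directed test for every ordered pair of regions
#' (channels), applies a Bonferroni family-wise correction over the
#' number of directed tests actually run, and reports the
#' difference-of-causalities test for every unordered pair.  Follows
#' the row-to-column convention: entry `(i, j)` is the influence of
#' region `i` on region `j`.
#'
#' @param panel a multi-channel [trial_panel()] whose channels are the
#'   regions, or a named list of single-channel panels.
#' @param method `"sdn"` or `"classical"`.
#' @param alpha family-wise significance level.
#' @param correction `"bonferroni"` (divide `alpha` by the number of
#'   directed tests) or `"none"`.
#' @param p,q model orders passed to the tests.
#' @param diff_alpha significance level of the difference test.
#' @param control optimizer control for the SDN fits.
#' @return A `pair_table` object with matrices `statistic`, `p_value`,
#'   `significant`, `reliable`, the antisymmetric `delta` matrix with
#'   `delta_p` and `delta_significant`, and the correction metadata.
#' @export
pair_table <- function(panel, method = c("sdn", "classical"), alpha = 0.05,
                       correction = c("bonferroni", "none"), p = 1, q = 1,
                       diff_alpha = 0.01, control = list()) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  if (is.list(panel) && !inherits(panel, "trial_panel")) {
    nm <- names(panel)
    if (is.null(nm)) stop("a list of panels must be named by region")
    stopifnot(length(panel) >= 2L)
    merged <- panel[[1L]]
    merged$channel_names <- nm[1L]
    dimnames(merged$values)[[3L]] <- nm[1L]
    for (i in 2L:length(panel)) {
      pi_ <- panel[[i]]
      pi_$channel_names <- nm[i]
      dimnames(pi_$values)[[3L]] <- nm[i]
      merged <- bind_channels(merged, pi_)
    }
    panel <- merged
  }
  k <- n_channels(panel)
  if (k < 2L) stop("pair_table needs at least 2 regions")
  regions <- panel$channel_names
  n_tests <- k * (k - 1L)
  thr <- if (correction == "bonferroni") alpha / n_tests else alpha
  stat <- pmat <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  reliable <- matrix(NA, k, k, dimnames = list(regions, regions))
  df_used <- NA_integer_
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    src <- panel_channels(panel, i)
    tgt <- panel_channels(panel, j)
    tst <- tryCatch(
      if (method == "sdn") sdn_gc(tgt, src, p = p, q = q, control = control)
      else classical_gc(tgt, src, p = p),
      error = function(e) e)
    if (inherits(tst, "error")) {
      reliable[i, j] <- FALSE
    } else {
      stat[i, j] <- tst$statistic
      pmat[i, j] <- tst$p_value
      reliable[i, j] <- if (method == "sdn") isTRUE(tst$reliable) else TRUE
      df_used <- tst$df
    }
  }
  significant <- !is.na(pmat) & pmat < thr
  delta <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  delta_p <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j || is.na(stat[i, j]) || is.na(stat[j, i])) next
    dt <- difference_test(stat[i, j], stat[j, i], df = df_used,
                          alpha = diff_alpha,
                          labels = c(paste0(regions[i], "->", regions[j]),
                                     paste0(regions[j], "->", regions[i])))
    delta[i, j] <- dt$delta; delta[j, i] <- -dt$delta
    delta_p[i, j] <- delta_p[j, i] <- dt$p_value
  }
  delta_significant <- !is.na(delta_p) & delta_p < diff_alpha
  structure(list(regions = regions, method = method,
                 statistic = stat, p_value = pmat,
                 significant = significant, reliable = reliable,
                 delta = delta, delta_p = delta_p,
                 delta_significant = delta_significant,
                 alpha = alpha, correction = correction,
                 n_tests = n_tests, threshold = thr,
                 df = df_used, diff_alpha = diff_alpha),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> method = %s, %d directed tests, %s threshold = %.4g\n",
              x$method, x$n_tests, x$correction, x$threshold))
  cat("statistics (row -> column):\n")
  print(round(x$statistic, 3))
  cat("significant after correction:\n")
  print(x$significant)
  invisible(x)
}

#' Write a pairwise causality table to CSV and JSON reports
#'
#' Emits `<prefix>_causality.csv` (directed statistic, p-value and
#' significance flag per ordered pair), `<prefix>_differences.csv`
#' (signed difference, its p-value and flag per unordered pair), and a
#' JSON summary `<prefix>.json`.
#'
#' @param x a [pair_table()] result.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_pair_table <- function(x, prefix) {
  stopifnot(inherits(x, "pair_table"))
  k <- length(x$regions)
  rows <- expand.grid(source = x$regions, target = x$regions,
                      stringsAsFactors = FALSE)
  rows <- rows[rows$source != rows$target, ]
  idx <- cbind(match(rows$source, x$regions), match(rows$target, x$regions))
  dir_df <- data.frame(rows,
                       statistic = x$statistic[idx],
                       p_value = x$p_value[idx],
                       significant = x$significant[idx],
                       reliable = x$reliable[idx])
  f1 <- paste0(prefix, "_causality.csv")
  utils::write.csv(dir_df, f1, row.names = FALSE)
  up <- which(upper.tri(x$delta), arr.ind = TRUE)
  diff_df <- data.frame(forward = paste0(x$regions[up[, 1L]], "->", x$regions[up[, 2L]]),
                        backward = paste0(x$regions[up[, 2L]], "->", x$regions[up[, 1L]]),
                        delta = x$delta[up],
                        p_value = x$delta_p[up],
                        significant = x$delta_significant[up])
  f2 <- paste0(prefix, "_differences.csv")
  utils::write.csv(diff_df, f2, row.names = FALSE)
  f3 <- paste0(prefix, ".json")
  jsonlite::write_json(list(method = x$method, regions = x$regions,
                            alpha = x$alpha, correction = x$correction,
                            n_tests = x$n_tests, threshold = x$threshold,
                            df = x$df, diff_alpha = x$diff_alpha,
                            causality = dir_df, differences = diff_df),
                       f3, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(f1, f2, f3))
}
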