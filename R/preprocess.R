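# Per-trial denoising and normalization applied before causal analysis.
#
# Denoising uses the maximal-overlap discrete wavelet transform (MODWT)
# with the Daubechies-2 (four-tap) filters, circular boundary handling
# and exact reconstruction; detail coefficients are soft-thresholded at
# the universal threshold with the noise scale estimated once from the
# first-level details.

# Daubechies-2 (D4) orthonormal scaling filter and its quadrature
# mirror wavelet filter.
db2_filters <- function() {
  h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)  # g_l = (-1)^l h_{L-1-l}
  list(h = h, g = g)
}

circ_shift_sum <- function(x, filt, stride, reverse = FALSE) {
  n <- length(x)
  out <- numeric(n)
  for (l in seq_along(filt)) {
    s <- (l - 1L) * stride
    idx <- if (reverse) ((seq_len(n) - 1L + s) %% n) + 1L
           else ((seq_len(n) - 1L - s) %% n) + 1L
    out <- out + filt[l] * x[idx]
  }
  out
}

#' Maximal-overlap discrete wavelet transform (db2, circular)
#'
#' Shift-invariant multilevel wavelet decomposition with the
#' Daubechies-2 filters, defined for any series length, with exact
#' inverse [imodwt()].
#'
#' @param x numeric series (length `>= 4`).
#' @param levels decomposition depth (default `floor(log2(N)) - 1`,
#'   at least 1).
#' @return A list with detail coefficient vectors `W` (one per level)
#'   and the final smooth `V`.
#' @export
modwt_db2 <- function(x, levels = NULL) {
  n <- length(x)
  if (n < 4L) stop("series too short for one decomposition level (need >= 4)")
  if (is.null(levels)) levels <- max(1L, floor(log2(n)) - 1L)
  if (levels < 1L || levels > floor(log2(n)))
    stop("`levels` must be between 1 and floor(log2(N))")
  flt <- db2_filters()
  ht <- flt$h / sqrt(2); gt <- flt$g / sqrt(2)
  W <- vector("list", levels)
  V <- x
  for (j in seq_len(levels)) {
    stride <- 2L^(j - 1L)
    W[[j]] <- circ_shift_sum(V, gt, stride)
    V <- circ_shift_sum(V, ht, stride)
  }
  list(W = W, V = V, levels = levels, n = n)
}

#' @rdname modwt_db2
#' @param decomp a decomposition returned by [modwt_db2()].
#' @export
imodwt_db2 <- function(decomp) {
  flt <- db2_filters()
  ht <- flt$h / sqrt(2); gt <- flt$g / sqrt(2)
  V <- decomp$V
  for (j in rev(seq_len(decomp$levels))) {
    stride <- 2L^(j - 1L)
    V <- circ_shift_sum(V, ht, stride, reverse = TRUE) +
         circ_shift_sum(decomp$W[[j]], gt, stride, reverse = TRUE)
  }
  V
}

#' Universal wavelet threshold
#'
#' The noise scale is estimated once from the first-level detail
#' coefficients as `sigma_hat = median(|W1|) / 0.6745` and the
#' universal threshold is `lambda = sigma_hat * sqrt(2 ln N)`.
#'
#' @param x numeric series.
#' @return A list with `sigma_hat` and `lambda`.
#' @export
universal_threshold <- function(x) {
  W1 <- modwt_db2(x, levels = 1L)$W[[1L]]
  sigma_hat <- stats::median(abs(W1)) / 0.6745
  list(sigma_hat = sigma_hat, lambda = sigma_hat * sqrt(2 * log(length(x))))
}

#' Wavelet denoising of one trial
#'
#' Multilevel db2 MODWT, thresholding of all detail coefficients at the
#' universal threshold (noise scale from the first-level details only),
#' reconstruction.  Output length equals input length; a constant
#' series is returned unchanged (all detail coefficients vanish).
#'
#' @param series numeric vector (length `>= 4`).
#' @param rule `"soft"` (shrink toward zero) or `"hard"` (keep or kill).
#' @param levels decomposition depth, see [modwt_db2()].
#' @return The denoised series.
#' @export
wavelet_denoise <- function(series, rule = c("soft", "hard"), levels = NULL) {
  rule <- match.arg(rule)
  dec <- modwt_db2(series, levels = levels)
  thr <- universal_threshold(series)
  lam <- thr$lambda
  for (j in seq_along(dec$W)) {
    w <- dec$W[[j]]
    dec$W[[j]] <- if (rule == "soft") sign(w) * pmax(abs(w) - lam, 0)
                  else w * (abs(w) > lam)
  }
  imodwt_db2(dec)
}

#' Detrend and center a series
#'
#' Subtracts the least-squares line, then the mean; the output has zero
#' mean and zero OLS slope, and the operation is idempotent.
#'
#' @param series numeric vector (length `>= 3`).
#' @return The detrended, centered series.
#' @export
detrend_center <- function(series) {
  n <- length(series)
  if (n < 3L) stop("series must have length >= 3")
  t_ <- seq_len(n)
  cf <- stats::lm.fit(cbind(1, t_), series)$coefficients
  out <- series - cf[1L] - cf[2L] * t_
  out - mean(out)
}

#' Preprocess every trial of a panel
#'
#' Applies, per trial and channel: wavelet denoising (optional), linear
#' detrending and mean-centering — the normalization chain used before
#' causal analysis of pooled BOLD trials.
#'
#' @param panel a [trial_panel()].
#' @param denoise apply [wavelet_denoise()].
#' @param detrend `"linear"` or `"none"`.
#' @param center subtract the trial mean.
#' @param rule thresholding rule for the denoiser.
#' @return A new [trial_panel()] with identical shape and metadata.
#' @export
preprocess_panel <- function(panel, denoise = TRUE, detrend = c("linear", "none"),
                             center = TRUE, rule = "soft") {
  stopifnot(inherits(panel, "trial_panel"))
  detrend <- match.arg(detrend)
  vals <- panel$values
  for (tr in seq_len(dim(vals)[1L])) {
    for (c_ in seq_len(dim(vals)[3L])) {
      x <- vals[tr, , c_]
      if (denoise) x <- wavelet_denoise(x, rule = rule)
      if (detrend == "linear") x <- detrend_center(x)
      else if (center) x <- x - mean(x)
      vals[tr, , c_] <- x
    }
  }
  trial_panel(vals, dt = panel$dt, channel_names = panel$channel_names,
              meta = panel$meta)
}
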