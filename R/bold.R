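# Poisson-spiking -> hemodynamic (balloon model) BOLD simulator.  The
# purpose is illustrative: near-Poisson cortical firing (count variance
# equal to the count mean) propagated through the hemodynamic state
# equations yields BOLD trials whose across-trial noise variance grows
# with the squared mean response — signal-dependent noise.

#' Poisson spike train
#'
#' Bins of width `dt` receive independent Poisson(rate * dt) counts, so
#' the count variance in any window equals the count mean (Fano factor
#' one).
#'
#' @param rate mean firing rate in Hz (`>= 0`).
#' @param duration train duration in seconds.
#' @param dt bin width in seconds.
#' @param seed optional integer seed.
#' @return An object of class `spike_train` with fields `counts`, `dt`,
#'   `rate`, `duration`.
#' @export
poisson_spikes <- function(rate, duration = 1, dt = 0.001, seed = NULL) {
  if (!is.numeric(rate) || rate < 0) stop("`rate` must be nonnegative")
  if (dt <= 0) stop("`dt` must be positive")
  n <- round(duration / dt)
  counts <- with_seed(seed, stats::rpois(n, rate * dt))
  structure(list(counts = counts, dt = dt, rate = rate, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %g Hz for %g s at dt = %g s: %d spikes\n",
              x$rate, x$duration, x$dt, sum(x$counts)))
  invisible(x)
}

#' Hemodynamic (balloon model) parameters
#'
#' Biophysical constants of the hemodynamic state equations and the
#' BOLD observation equation.  Defaults are canonical values from the
#' hemodynamic-modelling literature with 1.5-T observation constants
#' `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2`.
#'
#' @param tau_s signal-decay time constant (s).
#' @param tau_f autoregulatory feedback time constant (s).
#' @param tau_0 mean transit time of the venous compartment (s).
#' @param alpha Grubb's exponent (0 < alpha < 1).
#' @param E0 resting oxygen extraction fraction (0 < E0 < 1).
#' @param V0 resting blood volume fraction.
#' @param k1,k2,k3 BOLD observation constants.
#' @param efficacy neuronal efficacy: input gain per spike per bin.
#' @param obs_noise_sd standard deviation of additive observation noise.
#' @return A list of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(tau_s = 0.8, tau_f = 0.4, tau_0 = 1.0,
                               alpha = 0.32, E0 = 0.34, V0 = 0.02,
                               k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2,
                               efficacy = 0.5, obs_noise_sd = 0) {
  stopifnot(tau_s > 0, tau_f > 0, tau_0 > 0,
            alpha > 0, alpha < 1, E0 > 0, E0 < 1, V0 > 0, obs_noise_sd >= 0)
  structure(list(tau_s = tau_s, tau_f = tau_f, tau_0 = tau_0, alpha = alpha,
                 E0 = E0, V0 = V0, k1 = k1, k2 = k2, k3 = k3,
                 efficacy = efficacy, obs_noise_sd = obs_noise_sd),
            class = "hemodynamic_params")
}

#' Integrate the hemodynamic state equations
#'
#' Integrates, per input column, the balloon-model ODE system
#' \deqn{\dot s = \varepsilon u - s/\tau_s - (f - 1)/\tau_f,\quad
#'       \dot f = s,\quad
#'       \dot v = (f - v^{1/\alpha})/\tau_0,}
#' \deqn{\dot q = \big(f\,E(f, E_0)/E_0 - v^{1/\alpha} q / v\big)/\tau_0,
#'       \qquad E(f, E_0) = 1 - (1 - E_0)^{1/f},}
#' from the resting state `(s, f, v, q) = (0, 1, 1, 1)`, and forms the
#' BOLD readout
#' \deqn{y = V_0 \{k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v)\} + e_t.}
#' The default integrator is explicit Euler at the input resolution
#' (1 ms is the intended step); a classical fourth-order Runge-Kutta
#' option (`method = "rk4"`, input held constant within a step) is
#' provided for convergence checks.
#'
#' @param u input series: numeric vector (one trial) or matrix with one
#'   column per trial, in spikes per bin.
#' @param params a [hemodynamic_params()].
#' @param dt integration step in seconds (at most 0.01 for accuracy).
#' @param method `"euler"` or `"rk4"`.
#' @param seed optional seed for the observation noise.
#' @return A list with state matrices `s`, `f`, `v`, `q` and the `bold`
#'   matrix (time x trial).
#' @export
hemodynamic_forward <- function(u, params = hemodynamic_params(), dt = 0.001,
                                method = c("euler", "rk4"), seed = NULL) {
  method <- match.arg(method)
  if (dt > 0.01) stop("`dt` must be at most 10 ms for integration accuracy")
  if (is.null(dim(u))) u <- matrix(u, ncol = 1L)
  nt <- nrow(u); ntr <- ncol(u)
  s <- f <- v <- q <- matrix(NA_real_, nt, ntr)
  st <- list(s = rep(0, ntr), f = rep(1, ntr), v = rep(1, ntr), q = rep(1, ntr))
  deriv <- function(st, uu) {
    E <- 1 - (1 - params$E0)^(1 / st$f)
    fv <- st$v^(1 / params$alpha)
    list(s = params$efficacy * uu - st$s / params$tau_s - (st$f - 1) / params$tau_f,
         f = st$s,
         v = (st$f - fv) / params$tau_0,
         q = (st$f * E / params$E0 - fv * st$q / st$v) / params$tau_0)
  }
  step_add <- function(st, dd, h) list(s = st$s + h * dd$s, f = st$f + h * dd$f,
                                       v = st$v + h * dd$v, q = st$q + h * dd$q)
  for (t in seq_len(nt)) {
    uu <- u[t, ]
    if (method == "euler") {
      st <- step_add(st, deriv(st, uu), dt)
    } else {
      d1 <- deriv(st, uu)
      d2 <- deriv(step_add(st, d1, dt / 2), uu)
      d3 <- deriv(step_add(st, d2, dt / 2), uu)
      d4 <- deriv(step_add(st, d3, dt), uu)
      st <- list(s = st$s + dt / 6 * (d1$s + 2 * d2$s + 2 * d3$s + d4$s),
                 f = st$f + dt / 6 * (d1$f + 2 * d2$f + 2 * d3$f + d4$f),
                 v = st$v + dt / 6 * (d1$v + 2 * d2$v + 2 * d3$v + d4$v),
                 q = st$q + dt / 6 * (d1$q + 2 * d2$q + 2 * d3$q + d4$q))
    }
    if (any(!is.finite(st$f)) || any(!is.finite(st$v)) || any(!is.finite(st$q)) ||
        any(st$f <= 0) || any(st$v <= 0) || any(st$q <= 0))
      stop("integration failure: hemodynamic state left the physical domain (f, v, q > 0)")
    s[t, ] <- st$s; f[t, ] <- st$f; v[t, ] <- st$v; q[t, ] <- st$q
  }
  bold <- params$V0 * (params$k1 * (1 - q) + params$k2 * (1 - q / v) +
                       params$k3 * (1 - v))
  if (params$obs_noise_sd > 0)
    bold <- bold + with_seed(seed,
      matrix(stats::rnorm(nt * ntr, sd = params$obs_noise_sd), nt, ntr))
  list(s = s, f = f, v = v, q = q, bold = bold)
}

#' Simulate BOLD trials from Poisson spike trains
#'
#' Generates `n_trials` independent Poisson spike trains (stimulus
#' window at the start of the trial), feeds each through
#' [hemodynamic_forward()] at millisecond resolution, and decimates the
#' BOLD readout to `out_hz` (every `1/(out_hz * dt)`-th sample).  The
#' defaults reproduce the illustrative setting: 100 trials of 25 s at
#' 1 Hz output driven by a 1-s spike burst.
#'
#' @param rate mean firing rate in Hz.
#' @param n_trials number of trials.
#' @param total_seconds trial duration.
#' @param out_hz output sampling rate (`out_hz * total_seconds` must be
#'   integral).
#' @param seed optional integer seed.
#' @param params a [hemodynamic_params()].
#' @param dt integration step (s).
#' @param stim_seconds duration of the spiking stimulus.
#' @param method integrator passed to [hemodynamic_forward()].
#' @return A single-channel [trial_panel()] (`n_trials x
#'   total_seconds * out_hz x 1`, `dt = 1/out_hz`).
#' @export
simulate_bold_trials <- function(rate = 40, n_trials = 100, total_seconds = 25,
                                 out_hz = 1, seed = NULL,
                                 params = hemodynamic_params(), dt = 0.001,
                                 stim_seconds = 1, method = "euler") {
  n_out <- out_hz * total_seconds
  if (abs(n_out - round(n_out)) > 1e-9)
    stop("`out_hz * total_seconds` must be an integer")
  n_out <- round(n_out)
  nt <- round(total_seconds / dt)
  n_stim <- round(stim_seconds / dt)
  u <- with_seed(seed, {
    uu <- matrix(0, nt, n_trials)
    uu[seq_len(n_stim), ] <- stats::rpois(n_stim * n_trials, rate * dt)
    uu
  })
  hw <- hemodynamic_forward(u, params = params, dt = dt, method = method,
                            seed = if (!is.null(seed)) seed + 1L else NULL)
  stride <- round(1 / (out_hz * dt))
  keep <- seq(stride, nt, by = stride)[seq_len(n_out)]
  vals <- array(t(hw$bold[keep, , drop = FALSE]), dim = c(n_trials, n_out, 1L))
  trial_panel(vals, dt = 1 / out_hz, channel_names = "BOLD",
              meta = data.frame(trial = seq_len(n_trials), rate = rate))
}
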