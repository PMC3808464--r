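# Seeded synthetic benchmark studies: (i) a ROC comparison of the
# classical and signal-dependent-noise causality tests over random
# scalar-pair AR-BEKK models, and (ii) a four-region, two-condition
# multi-subject panel generator standing in for non-deposited fMRI
# recordings.

#' Configuration of the ROC simulation study
#'
#' For each of `n_models` random scalar-pair models, each direction
#' independently carries a causal link with probability
#' `link_probability`; a present link sets the volatility
#' cross-coefficient to `var_coupling_value` and (unless
#' `mode = "variance_only"`) draws the mean cross-coefficient uniformly
#' from `mean_coupling_range`.  Diagonal coefficients are drawn
#' uniformly and models failing either stability condition are
#' rejection-resampled, then the volatility cross-coefficients are
#' scaled down if needed.
#'
#' @param n_models number of random models.
#' @param series_length simulated points per replicate.
#' @param n_replicates trials per model.
#' @param link_probability probability that a directed link is present.
#' @param mean_coupling_range uniform range of nonzero mean
#'   cross-coefficients.
#' @param var_coupling_value volatility cross-coefficient of a present
#'   link (before any stability rescaling).
#' @param diag_mean_range,diag_var_range uniform ranges of the diagonal
#'   mean / volatility coefficients.
#' @param w baseline innovation variance of both series.
#' @param mode `"both"` (links act on mean and variance),
#'   `"variance_only"`, or `"mean_only"`.
#' @param p_grid p-value thresholds for the ROC sweep.
#' @param seed integer seed.
#' @return A list of class `roc_config`.
#' @export
roc_config <- function(n_models = 100L, series_length = 1000L,
                       n_replicates = 2L, link_probability = 0.4,
                       mean_coupling_range = c(0.1, 0.5),
                       var_coupling_value = 1,
                       diag_mean_range = c(0.3, 0.7),
                       diag_var_range = c(0.3, 0.7),
                       w = 1,
                       mode = c("both", "variance_only", "mean_only"),
                       p_grid = seq(0, 1, by = 0.01),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(link_probability >= 0, link_probability <= 1,
            n_models >= 1L, series_length > 10L, n_replicates >= 1L)
  structure(list(n_models = as.integer(n_models),
                 series_length = as.integer(series_length),
                 n_replicates = as.integer(n_replicates),
                 link_probability = link_probability,
                 mean_coupling_range = mean_coupling_range,
                 var_coupling_value = var_coupling_value,
                 diag_mean_range = diag_mean_range,
                 diag_var_range = diag_var_range,
                 w = w, mode = mode, p_grid = p_grid,
                 seed = as.integer(seed)),
            class = "roc_config")
}

# Draw one random stable scalar-pair model plus its ground-truth links.
draw_roc_model <- function(config) {
  link_yx <- stats::runif(1) < config$link_probability  # y -> x (channel 2 -> 1)
  link_xy <- stats::runif(1) < config$link_probability
  cross <- function(present) {
    if (!present) return(c(mean = 0, var = 0))
    mv <- if (config$mode == "variance_only") 0
          else stats::runif(1, config$mean_coupling_range[1L],
                            config$mean_coupling_range[2L])
    vv <- if (config$mode == "mean_only") 0 else config$var_coupling_value
    c(mean = mv, var = vv)
  }
  for (attempt in seq_len(400L)) {
    c_yx <- cross(link_yx); c_xy <- cross(link_xy)
    # progressively relax the volatility cross value if stability keeps failing
    relax <- 0.9^((attempt - 1L) %/% 20L)
    a11 <- stats::runif(1, config$diag_mean_range[1L], config$diag_mean_range[2L])
    a22 <- stats::runif(1, config$diag_mean_range[1L], config$diag_mean_range[2L])
    b11 <- stats::runif(1, config$diag_var_range[1L], config$diag_var_range[2L])
    b22 <- stats::runif(1, config$diag_var_range[1L], config$diag_var_range[2L])
    A <- matrix(c(a11, c_xy["mean"], c_yx["mean"], a22), 2L, 2L)
    Bx <- matrix(c(b11, c_yx["var"] * relax), 1L, 2L)
    By <- matrix(c(c_xy["var"] * relax, b22), 1L, 2L)
    model <- joint_arbekk_model(A = list(A), Bx = list(Bx), By = list(By),
                                Wx_chol = matrix(sqrt(config$w), 1L, 1L),
                                Wy_chol = matrix(sqrt(config$w), 1L, 1L),
                                kx = 1L, ky = 1L)
    if (first_order_stable(model)$stable && second_order_stable(model)$stable)
      return(list(model = model,
                  truth = c(y_to_x = link_yx, x_to_y = link_xy)))
  }
  stop("stability rejection sampling exceeded the retry cap")
}

#' Generate the random models of the ROC study
#'
#' @param config a [roc_config()].
#' @return A list of `n_models` elements, each with a stable
#'   [joint_arbekk_model()] `model` and a logical `truth` vector naming
#'   the directed links present.
#' @export
generate_roc_models <- function(config) {
  stopifnot(inherits(config, "roc_config"))
  with_seed(config$seed,
            lapply(seq_len(config$n_models), function(i) draw_roc_model(config)))
}

#' Run the ROC comparison of classical and SDN Granger causality
#'
#' Simulates every generated model (`series_length` points,
#' `n_replicates` trials), applies both directed tests to both
#' directions of every pair, and summarizes performance as ROC curves
#' over the p-value threshold grid and as the area under the curve
#' (computed from the continuous p-values).  Individual fit failures
#' are logged and counted, not fatal.
#'
#' @param config a [roc_config()].
#' @param control optimizer control for the SDN fits.
#' @return A list with the per-direction `results` data frame, the
#'   `auc` of each method, threshold-sweep `curves`, and the failure
#'   count.
#' @export
run_roc_study <- function(config, control = list()) {
  models <- generate_roc_models(config)
  rows <- vector("list", 2L * length(models))
  n_failed <- 0L
  for (i in seq_along(models)) {
    mi <- models[[i]]
    panel <- simulate(mi$model, nsim = config$n_replicates,
                      seed = config$seed + 1000L + i,
                      n_time = config$series_length)
    px <- panel_channels(panel, 1L)
    py <- panel_channels(panel, 2L)
    one <- function(target, source, truth_key) {
      cl <- tryCatch(classical_gc(target, source, p = 1L), error = function(e) NULL)
      sd_ <- tryCatch(sdn_gc(target, source, p = 1L, q = 1L, control = control),
                      error = function(e) NULL)
      if (is.null(cl) || is.null(sd_)) n_failed <<- n_failed + 1L
      data.frame(model = i, direction = truth_key,
                 truth = unname(mi$truth[truth_key]),
                 p_classical = if (is.null(cl)) NA_real_ else cl$p_value,
                 p_sdn = if (is.null(sd_)) NA_real_ else sd_$p_value)
    }
    rows[[2L * i - 1L]] <- one(px, py, "y_to_x")
    rows[[2L * i]] <- one(py, px, "x_to_y")
  }
  results <- do.call(rbind, rows)
  auc_of <- function(pvals) {
    ok <- !is.na(pvals)
    if (length(unique(results$truth[ok])) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = results$truth[ok],
                                   predictor = 1 - pvals[ok],
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }
  curve_of <- function(pvals) {
    ok <- !is.na(pvals)
    t(vapply(config$p_grid, function(thr) {
      called <- pvals[ok] < thr
      c(threshold = thr,
        sensitivity = mean(called[results$truth[ok]]),
        one_minus_specificity = mean(called[!results$truth[ok]]))
    }, numeric(3L)))
  }
  curves <- rbind(data.frame(method = "classical", curve_of(results$p_classical)),
                  data.frame(method = "sdn", curve_of(results$p_sdn)))
  list(results = results,
       auc = c(classical = auc_of(results$p_classical),
               sdn = auc_of(results$p_sdn)),
       curves = curves,
       n_failed = n_failed,
       config = config)
}

#' Configuration of the synthetic four-region fMRI-style study
#'
#' Emulates the dimensions of a pooled two-condition taste-attention
#' experiment: 12 subjects contributing 9 trials each (108 pooled
#' trials per condition) over four regions (OFC, AntINS, AntLPFC,
#' PostLPFC), with a different planted directed-link pattern per
#' condition: `PostLPFC -> AntINS` under attention to intensity;
#' `AntLPFC -> OFC`, `PostLPFC -> OFC` and `AntINS -> OFC` under
#' attention to pleasantness.  The generating process is a four-node
#' AR-BEKK network; planted links act on both the mean and the
#' volatility.
#'
#' @param n_subjects,trials_per_subject,n_time,dt panel dimensions.
#' @param mean_coupling,var_coupling strength of a planted link (set
#'   both to 0 for the null setting).
#' @param diag_mean,diag_var diagonal (self) coefficients.
#' @param w baseline innovation variance.
#' @param burn_in simulation burn-in per trial.
#' @return A list of class `synth_fmri_config`.
#' @export
synth_fmri_config <- function(n_subjects = 12L, trials_per_subject = 9L,
                              n_time = 16L, dt = 2,
                              mean_coupling = 0.3, var_coupling = 0.5,
                              diag_mean = 0.5, diag_var = 0.4, w = 1,
                              burn_in = 500L) {
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 n_time = as.integer(n_time), dt = dt,
                 mean_coupling = mean_coupling, var_coupling = var_coupling,
                 diag_mean = diag_mean, diag_var = diag_var, w = w,
                 burn_in = as.integer(burn_in),
                 regions = c("OFC", "AntINS", "AntLPFC", "PostLPFC")),
            class = "synth_fmri_config")
}

synth_fmri_links <- function(regions) {
  list(intensity = rbind(c(source = "PostLPFC", target = "AntINS")),
       pleasantness = rbind(c(source = "AntLPFC", target = "OFC"),
                            c(source = "PostLPFC", target = "OFC"),
                            c(source = "AntINS", target = "OFC")))
}

#' Generate the synthetic two-condition four-region panel
#'
#' @param config a [synth_fmri_config()].
#' @param seed integer seed.
#' @return A list with pooled [trial_panel()]s `intensity` and
#'   `pleasantness` (108 trials each under the defaults, with subject
#'   and condition metadata) and `truth`, the planted directed
#'   adjacency matrix (source row, target column) per condition.
#' @export
synth_fmri_panel <- function(config = synth_fmri_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_fmri_config"))
  regions <- config$regions
  k <- length(regions)
  links <- synth_fmri_links(regions)
  out <- list()
  truth <- list()
  for (ci in seq_along(links)) {
    cond <- names(links)[ci]
    A1 <- diag(config$diag_mean, k)
    B1 <- diag(config$diag_var, k)
    adj <- matrix(FALSE, k, k, dimnames = list(regions, regions))
    for (r in seq_len(nrow(links[[cond]]))) {
      si <- match(links[[cond]][r, "source"], regions)
      ti <- match(links[[cond]][r, "target"], regions)
      A1[ti, si] <- config$mean_coupling
      B1[ti, si] <- config$var_coupling
      adj[si, ti] <- config$mean_coupling != 0 || config$var_coupling != 0
    }
    model <- arbekk_model(A = list(A1), B = list(B1),
                          W_chol = diag(sqrt(config$w), k))
    if (!second_order_stable(model)$stable)
      stop("planted network is second-order unstable; reduce the couplings")
    n_pool <- config$n_subjects * config$trials_per_subject
    panel <- simulate(model, nsim = n_pool, seed = seed + 13L * ci,
                      n_time = config$n_time, burn_in = config$burn_in,
                      dt = config$dt)
    panel$channel_names <- regions
    dimnames(panel$values)[[3L]] <- regions
    panel$meta <- data.frame(
      trial = seq_len(n_pool),
      subject = rep(seq_len(config$n_subjects), each = config$trials_per_subject),
      condition = cond)
    out[[cond]] <- panel
    truth[[cond]] <- adj
  }
  c(out, list(truth = truth, config = config))
}
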