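#' Multi-trial time-series panel
#'
#' The universal data carrier of the package: repeated realizations
#' (trials) of a multi-channel series sampled on a uniform grid.  Used
#' both for simulated AR-BEKK / BOLD data and for pooled region-wise
#' fMRI trials, which are treated as repeated realizations from a
#' common underlying model.
#'
#' @param values numeric array indexed `(trial, time, channel)`; a
#'   `trials x time` matrix is promoted to a single-channel array.
#' @param dt sampling interval in seconds (must be positive).
#' @param channel_names optional character vector of channel labels.
#' @param meta optional data frame with one row per trial carrying
#'   provenance (e.g. `subject`, `condition`).
#'
#' @return An object of class `trial_panel`.
#' @export
trial_panel <- function(values, dt = 1, channel_names = NULL, meta = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a (trial, time, channel) array or a trials x time matrix")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("`values` must be numeric with no missing or non-finite entries")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("`dt` must be a positive scalar")
  k <- dim(values)[3L]
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(dimnames(values)[[3L]])) dimnames(values)[[3L]]
                     else paste0("ch", seq_len(k))
  }
  if (length(channel_names) != k) stop("`channel_names` length must match channel count")
  if (is.null(meta)) meta <- data.frame(trial = seq_len(dim(values)[1L]))
  if (!is.data.frame(meta) || nrow(meta) != dim(values)[1L])
    stop("`meta` must be a data frame with one row per trial")
  dimnames(values) <- list(NULL, NULL, channel_names)
  structure(list(values = values, dt = dt, channel_names = channel_names,
                 meta = meta),
            class = "trial_panel")
}

#' @export
print.trial_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_panel> %d trial(s) x %d time point(s) x %d channel(s), dt = %g s\n",
              d[1L], d[2L], d[3L], x$dt))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  extra <- setdiff(names(x$meta), "trial")
  if (length(extra)) cat("meta:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Panel dimensions
#'
#' @param panel a [trial_panel()].
#' @return Integer count of trials, time points or channels.
#' @export
n_trials <- function(panel) dim(panel$values)[1L]

#' @rdname n_trials
#' @export
n_times <- function(panel) dim(panel$values)[2L]

#' @rdname n_trials
#' @export
n_channels <- function(panel) dim(panel$values)[3L]

#' Select a subset of channels from a panel
#'
#' @param panel a [trial_panel()].
#' @param channels integer indices or channel names.
#' @return A new `trial_panel` with the requested channels.
#' @export
panel_channels <- function(panel, channels) {
  if (is.character(channels)) {
    idx <- match(channels, panel$channel_names)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(channels[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(channels)
  vals <- panel$values[, , idx, drop = FALSE]
  trial_panel(vals, dt = panel$dt, channel_names = panel$channel_names[idx],
              meta = panel$meta)
}

#' Bind two aligned panels channel-wise
#'
#' Used to form the joint (x, y) system from two panels sharing the same
#' trial structure and sampling grid.
#'
#' @param x,y [trial_panel()] objects with equal trial count, length and `dt`.
#' @return A `trial_panel` whose channels are those of `x` followed by `y`.
#' @export
bind_channels <- function(x, y) {
  stopifnot(inherits(x, "trial_panel"), inherits(y, "trial_panel"))
  if (n_trials(x) != n_trials(y) || n_times(x) != n_times(y))
    stop("panels are misaligned: trial counts and lengths must match")
  if (abs(x$dt - y$dt) > 1e-12) stop("panels are misaligned: `dt` differs")
  nm <- make.unique(c(x$channel_names, y$channel_names))
  vals <- array(0, dim = c(n_trials(x), n_times(x), n_channels(x) + n_channels(y)))
  vals[, , seq_len(n_channels(x))] <- x$values
  vals[, , n_channels(x) + seq_len(n_channels(y))] <- y$values
  trial_panel(vals, dt = x$dt, channel_names = nm, meta = x$meta)
}

#' Pool trials across subjects
#'
#' Concatenates the trial axes of several aligned panels (e.g. one per
#' subject) into one panel, so that all trials are treated as repeated
#' realizations from a common underlying model.  Provenance is retained:
#' a `subject` column is added to the pooled metadata when absent.
#'
#' @param panels a list of [trial_panel()] objects with identical trial
#'   length, sampling interval and channels.
#' @return A single pooled `trial_panel`.
#' @export
pool_trials <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1L)
  ref <- panels[[1L]]
  for (p in panels) {
    if (!inherits(p, "trial_panel")) stop("all elements must be trial_panel objects")
    if (n_times(p) != n_times(ref) || n_channels(p) != n_channels(ref))
      stop("mismatched trial lengths or channels across panels")
    if (abs(p$dt - ref$dt) > 1e-12) stop("mismatched `dt` across panels")
    if (!identical(p$channel_names, ref$channel_names))
      stop("mismatched channel names across panels")
  }
  ntr <- vapply(panels, n_trials, integer(1L))
  vals <- array(0, dim = c(sum(ntr), n_times(ref), n_channels(ref)))
  metas <- vector("list", length(panels))
  at <- 0L
  for (i in seq_along(panels)) {
    vals[at + seq_len(ntr[i]), , ] <- panels[[i]]$values
    m <- panels[[i]]$meta
    if (!"subject" %in% names(m)) m$subject <- i
    metas[[i]] <- m
    at <- at + ntr[i]
  }
  meta <- do.call(rbind, metas)
  meta$trial <- seq_len(nrow(meta))
  rownames(meta) <- NULL
  trial_panel(vals, dt = ref$dt, channel_names = ref$channel_names, meta = meta)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# RNG state afterwards.  seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
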