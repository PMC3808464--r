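#' Read and write trial panels as long-format CSV
#'
#' Panels are serialized as plain-text CSV in long format with header
#' `subject,condition,region,trial,t,value`, plus a JSON sidecar
#' (`<path>.json`) holding the sampling interval and channel order so
#' that a write/read round trip is lossless.
#'
#' @param panel a [trial_panel()].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   [trial_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "trial_panel"))
  ntr <- n_trials(panel); nt <- n_times(panel); k <- n_channels(panel)
  subj <- if ("subject" %in% names(panel$meta)) panel$meta$subject else rep(NA, ntr)
  cond <- if ("condition" %in% names(panel$meta)) panel$meta$condition else rep(NA, ntr)
  df <- data.frame(
    subject   = rep(subj, times = nt * k),
    condition = rep(cond, times = nt * k),
    region    = rep(panel$channel_names, each = ntr * nt),
    trial     = rep(seq_len(ntr), times = nt * k),
    t         = rep(rep(seq_len(nt), each = ntr), times = k),
    value     = as.vector(panel$values))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(dt = panel$dt, channels = as.list(panel$channel_names)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input file: ", path)
  need <- c("subject", "condition", "region", "trial", "t", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$value)) stop("non-numeric values in `value` column")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dt <- as.numeric(meta$dt)
    channels <- as.character(meta$channels)
  } else {
    dt <- 1
    channels <- sort(unique(df$region))
  }
  trials <- sort(unique(df$trial))
  times <- sort(unique(df$t))
  ntr <- length(trials); nt <- length(times); k <- length(channels)
  if (nrow(df) != ntr * nt * k)
    stop("ragged input: every trial must cover every time point and region")
  vals <- array(NA_real_, dim = c(ntr, nt, k))
  ti <- match(df$trial, trials); si <- match(df$t, times); ci <- match(df$region, channels)
  if (anyNA(ci)) stop("region(s) in CSV not listed in sidecar: ",
                      paste(unique(df$region[is.na(ci)]), collapse = ", "))
  vals[cbind(ti, si, ci)] <- df$value
  if (anyNA(vals)) stop("ragged input: every trial must cover every time point and region")
  first <- !duplicated(df$trial)
  meta <- data.frame(trial = seq_len(ntr),
                     subject = df$subject[first][order(df$trial[first])],
                     condition = df$condition[first][order(df$trial[first])])
  trial_panel(vals, dt = dt, channel_names = channels, meta = meta)
}
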