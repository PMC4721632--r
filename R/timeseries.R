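#' Multichannel time series
#'
#' Canonical container for recordings: rows are time samples, columns are
#' channels. Rows containing non-finite values are rejected at construction
#' with a message saying how many were dropped.
#'
#' @param data T x N numeric matrix, rows = time.
#' @param sampling_rate samples per second (Hz).
#' @param labels optional channel names; default `ch1..chN`.
#' @return An object of class `"time_series"`.
#' @export
time_series <- function(data, sampling_rate = 1, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  bad <- !apply(is.finite(data), 1, all)
  if (any(bad)) {
    message(sprintf("dropping %d row(s) containing non-finite values (first at row %d)",
                    sum(bad), which(bad)[1]))
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) < 2) stop("a time series needs at least 2 finite samples",
                           call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (is.null(labels)) {
    labels <- colnames(data)
    if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  }
  if (length(labels) != ncol(data)) stop("labels must match channel count",
                                         call. = FALSE)
  colnames(data) <- labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 labels = as.character(labels)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series: %d samples x %d channel(s) at %g Hz\n",
              nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

detect_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a multichannel recording from delimited text
#'
#' Accepts CSV (by extension) or tab-delimited text, with an optional header
#' row of channel names. Non-numeric cells are reported with their line and
#' column.
#'
#' @param path file path.
#' @param layout `"rows_time"` (default) if rows are time samples,
#'   `"rows_channels"` if the file stores one channel per row (it is then
#'   transposed into canonical form).
#' @param sampling_rate samples per second attached to the result.
#' @param delim field delimiter; default by extension (`,` for `.csv`,
#'   otherwise tab).
#' @return A [time_series()].
#' @export
read_timeseries <- function(path, layout = c("rows_time", "rows_channels"),
                            sampling_rate = 1, delim = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           blank.lines.skip = TRUE)
  header <- NULL
  first <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  data_start <- 1L
  if (anyNA(first)) {
    header <- as.character(unlist(raw[1, ]))
    data_start <- 2L
  }
  body <- raw[seq(data_start, nrow(raw)), , drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  bad <- which(is.na(num) & !is.nan(num) & !is.na(as.matrix(body)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at line %d, column %d of %s",
                 as.matrix(body)[bad[1, 1], bad[1, 2]],
                 bad[1, 1] + data_start - 1L, bad[1, 2], path), call. = FALSE)
  }
  if (layout == "rows_channels") num <- t(num)
  # a header names the file's columns, which are channels only in rows_time
  labels <- if (layout == "rows_time" && !is.null(header)) header else NULL
  time_series(num, sampling_rate = sampling_rate, labels = labels)
}

#' Write a time series as delimited text
#'
#' Rows are time samples, columns channels, with a header row of labels.
#'
#' @param ts a [time_series()].
#' @param path file path; `.csv` extension selects commas, otherwise tabs.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  utils::write.table(ts$data, path, sep = detect_delim(path),
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Bipolar re-referencing of neighboring channels
#'
#' Produces one output channel per electrode pair as the difference
#' `channel i - channel j`, suppressing signal components common to both
#' electrodes (line noise, reference drift). Output labels are `"i-j"` using
#' the input channel labels.
#'
#' @param ts a [time_series()].
#' @param pairs two-column integer matrix (or list of length-2 vectors) of
#'   1-based channel indices; one row per output channel.
#' @return A [time_series()] with `nrow(pairs)` channels.
#' @export
bipolar_rereference <- function(ts, pairs) {
  stopifnot(inherits(ts, "time_series"))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns (i, j)", call. = FALSE)
  n <- ncol(ts$data)
  if (any(pairs < 1 | pairs > n) || anyNA(pairs)) {
    stop("pair indices must lie in 1..", n, call. = FALSE)
  }
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("a pair references the same channel twice", call. = FALSE)
  }
  out <- ts$data[, pairs[, 1], drop = FALSE] - ts$data[, pairs[, 2], drop = FALSE]
  labels <- paste0(ts$labels[pairs[, 1]], "-", ts$labels[pairs[, 2]])
  time_series(out, sampling_rate = ts$sampling_rate, labels = labels)
}

#' Read an electrode-pair list from two-column delimited text
#'
#' @param path file path; two integer columns, 0-based indices as in the
#'   other text interfaces (converted to 1-based internally).
#' @return two-column integer matrix of 1-based indices.
#' @export
read_electrode_pairs <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 2) stop("pair file must have exactly two columns", call. = FALSE)
  storage.mode(m) <- "integer"
  m + 1L
}

#' Estimate lagged covariances from a recording by windowed averaging
#'
#' Splits the recording into windows, forms within-window lagged sample
#' pairs \eqn{(X^{t-\tau}, X^t)}, computes per-window mean-subtracted sample
#' covariances (maximum-likelihood 1/n denominator), and averages the three
#' matrices across windows. Pairs never straddle a window boundary, so the
#' window must be at least `2 * lag` samples long.
#'
#' @param ts a [time_series()].
#' @param lag lag \eqn{\tau} in samples (see [ms_to_samples()] to convert
#'   from milliseconds).
#' @param window window length in seconds; default the whole recording.
#' @param step step between window starts in seconds; default `window`
#'   (non-overlapping).
#' @param total total duration analyzed, in seconds from the start; default
#'   the whole recording.
#' @return A [lagged_gaussian()] triple (past and present marginals
#'   estimated separately, not forced equal).
#' @export
estimate_lagged_covariance <- function(ts, lag = 1L, window = NULL,
                                       step = NULL, total = NULL) {
  stopifnot(inherits(ts, "time_series"))
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1 sample", call. = FALSE)
  T_all <- nrow(ts$data)
  fs <- ts$sampling_rate
  total_s <- if (is.null(total)) T_all / fs else total
  if (total_s * fs > T_all + 1e-9) {
    stop("total exceeds the recording length", call. = FALSE)
  }
  win_n <- if (is.null(window)) floor(total_s * fs) else round(window * fs)
  step_n <- if (is.null(step)) win_n else round(step * fs)
  if (win_n < 2 * lag) {
    stop(sprintf("window of %d samples is too short for lag %d (need >= %d)",
                 win_n, lag, 2 * lag), call. = FALSE)
  }
  if (step_n < 1) stop("step must be at least one sample", call. = FALSE)
  starts <- seq(1L, floor(total_s * fs) - win_n + 1L, by = step_n)
  if (length(starts) == 0) stop("no complete window fits in 'total'", call. = FALSE)
  n <- ncol(ts$data)
  Sp <- Spr <- Sc <- matrix(0, n, n)
  for (s0 in starts) {
    idx <- s0:(s0 + win_n - 1L)
    past <- ts$data[idx[seq_len(win_n - lag)], , drop = FALSE]
    pres <- ts$data[idx[(lag + 1L):win_n], , drop = FALSE]
    past <- sweep(past, 2, colMeans(past))
    pres <- sweep(pres, 2, colMeans(pres))
    m <- nrow(past)
    Sp <- Sp + crossprod(past) / m
    Spr <- Spr + crossprod(pres) / m
    Sc <- Sc + crossprod(past, pres) / m
  }
  k <- length(starts)
  g <- tryCatch(
    lagged_gaussian(Sp / k, Spr / k, Sc / k, lag = lag, labels = ts$labels),
    error = function(e) {
      stop(paste0("estimated covariances are not a valid Gaussian triple (",
                  conditionMessage(e),
                  "); try longer windows or fewer channels"), call. = FALSE)
    })
  g
}

#' Convert a lag in milliseconds to samples
#'
#' @param ms lag in milliseconds.
#' @param sampling_rate samples per second.
#' @return integer number of samples (rounded, at least 1).
#' @export
ms_to_samples <- function(ms, sampling_rate) {
  max(1L, as.integer(round(ms * sampling_rate / 1000)))
}
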