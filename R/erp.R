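#' An epoched multichannel EEG container
#'
#' @param data numeric array, channels x samples x epochs, microvolts.
#' @param time_ms numeric vector of sample times, ms relative to event
#'   onset (e.g. -200 .. 596 at 250 Hz).
#' @param sample_rate Hz.
#' @param labels data frame with one row per epoch (e.g. subject,
#'   condition, segment, presentation); NULL allowed.
#' @param channels channel ids; defaults to dimnames or E1..En.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, sample_rate, labels = NULL,
                      channels = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (length(time_ms) != dim(data)[2L])
    stop_input("time_ms length must match the sample dimension")
  if (!is.null(labels) && nrow(labels) != dim(data)[3L])
    stop_input("labels must have one row per epoch")
  channels <- channels %||% dimnames(data)[[1L]] %||%
    paste0("E", seq_len(dim(data)[1L]))
  dimnames(data)[[1L]] <- channels
  structure(list(data = data, time_ms = time_ms, sample_rate = sample_rate,
                 labels = labels, channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d channels x %d samples x %d epochs @ %g Hz, %g..%g ms\n",
              d[1], d[2], d[3], x$sample_rate,
              min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Re-reference to the average voltage
#'
#' Subtracts, at every sample, the mean across channels, so the average
#' reference is exactly zero.  Idempotent.
#'
#' @param data channels x samples matrix, or an `epoch_set`.
#' @return same shape/class as the input.
#' @export
average_reference <- function(data) {
  if (inherits(data, "epoch_set")) {
    data$data <- array(apply(data$data, 3L, function(m)
      sweep(m, 2L, colMeans(m))), dim = dim(data$data),
      dimnames = dimnames(data$data))
    return(data)
  }
  if (nrow(data) < 2L) stop_input("average reference needs >= 2 channels")
  sweep(data, 2L, colMeans(data))
}

#' Zero-phase Butterworth bandpass
#'
#' Applies a 4th-order Butterworth band (default 0.25-75 Hz) with zero
#' phase shift.  The filter is realized in the frequency domain as the
#' squared Butterworth magnitude response, which is exactly the transfer
#' function of a forward-backward (filtfilt) application and introduces
#' no phase distortion; the signal is reflection-padded to suppress
#' wrap-around edge effects.
#'
#' @param data channels x samples matrix.
#' @param low,high band edges, Hz; `0 < low < high < sample_rate / 2`.
#' @param sample_rate Hz.
#' @param order Butterworth order of each one-pass half (default 4).
#' @return filtered matrix, same shape.
#' @export
bandpass <- function(data, low = 0.25, high = 75, sample_rate, order = 4L) {
  if (!(low > 0 && low < high)) stop_input("need 0 < low < high")
  if (high >= sample_rate / 2) stop_input("high edge must be below Nyquist")
  one_d <- is.null(dim(data))
  x <- if (one_d) matrix(data, nrow = 1L) else as.matrix(data)
  n <- ncol(x)
  # reflection padding on both sides (mirror, excluding edge samples)
  np <- n - 1L
  left  <- x[, (np + 1L):2, drop = FALSE]
  right <- x[, (n - 1L):(n - np), drop = FALSE]
  xp <- cbind(left, x, right)
  m <- ncol(xp)
  f <- (seq_len(m) - 1L) / m * sample_rate
  f <- pmin(f, sample_rate - f)           # two-sided spectrum frequencies
  hp <- 1 / (1 + (low / pmax(f, 1e-12))^(2 * order))
  hp[f == 0] <- 0
  lp <- 1 / (1 + (f / high)^(2 * order))
  gain <- hp * lp                          # |H|^2: forward-backward
  ft <- stats::mvfft(t(xp))
  filt <- Re(stats::mvfft(ft * gain, inverse = TRUE)) / m
  out <- t(filt)[, np + seq_len(n), drop = FALSE]
  dimnames(out) <- dimnames(if (one_d) NULL else data)
  if (one_d) drop(out) else out
}

#' Extract fixed-window epochs around events
#'
#' Cuts one epoch per event from a continuous channels x samples array.
#' The window is half-open, `[-200, 600)` ms by default, so at 250 Hz an
#' epoch spans 200 samples: 50 before the onset and 150 from the onset
#' on.  Events too close to the recording edges are dropped (the count
#' is kept in the `n_dropped` attribute and messaged).
#'
#' @param data channels x samples matrix of continuous EEG, microvolts.
#' @param event_samples 1-based sample indices of event onsets.
#' @param window_ms `c(start, end)` of the half-open epoch window, ms.
#' @param sample_rate Hz.
#' @param labels optional data frame, one row per event, subset along
#'   with the admissible events.
#' @return an [epoch_set()] with attribute `n_dropped`.
#' @export
extract_epochs <- function(data, event_samples, window_ms = c(-200, 600),
                           sample_rate, labels = NULL) {
  data <- as.matrix(data)
  pre <- round(-window_ms[1] / 1000 * sample_rate)
  post <- round(window_ms[2] / 1000 * sample_rate)
  n <- ncol(data)
  ok <- event_samples - pre >= 1L & event_samples + post - 1L <= n
  n_drop <- sum(!ok)
  if (!any(ok)) stop_input("no admissible events inside the recording")
  if (n_drop > 0)
    message(n_drop, " event(s) too close to the recording edge; dropped")
  ev <- event_samples[ok]
  arr <- array(NA_real_, c(nrow(data), pre + post, length(ev)))
  for (k in seq_along(ev))
    arr[, , k] <- data[, (ev[k] - pre):(ev[k] + post - 1L), drop = FALSE]
  out <- epoch_set(arr,
                   time_ms = (seq_len(pre + post) - pre - 1L) / sample_rate * 1000,
                   sample_rate = sample_rate,
                   labels = if (is.null(labels)) NULL else labels[ok, , drop = FALSE],
                   channels = rownames(data))
  attr(out, "n_dropped") <- n_drop
  out
}

#' Reject epochs on a peak-to-peak amplitude threshold
#'
#' A deterministic surrogate for manual artifact inspection: any epoch
#' whose peak-to-peak amplitude on any channel exceeds the threshold is
#' removed.  The per-epoch log (max peak-to-peak, rejected flag) is kept
#' in the `rejection_log` attribute.
#'
#' @param epochs an `epoch_set`.
#' @param peak_to_peak_max threshold, microvolts (> 0).
#' @return the `epoch_set` with offending epochs removed.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_max) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (peak_to_peak_max <= 0) stop_input("threshold must be > 0")
  ptp <- apply(epochs$data, 3L, function(m)
    max(apply(m, 1L, function(ch) diff(range(ch)))))
  keep <- ptp <= peak_to_peak_max
  if (!any(keep))
    stop_input("all epochs exceed the peak-to-peak threshold (",
               peak_to_peak_max, " uV); review the threshold")
  out <- epoch_set(epochs$data[, , keep, drop = FALSE], epochs$time_ms,
                   epochs$sample_rate,
                   labels = if (is.null(epochs$labels)) NULL
                            else epochs$labels[keep, , drop = FALSE],
                   channels = epochs$channels)
  attr(out, "rejection_log") <- data.frame(epoch = seq_along(ptp),
                                           peak_to_peak = ptp,
                                           rejected = !keep)
  out
}

#' Average epochs into an ERP
#'
#' `condition_average()` takes the pointwise mean over the epochs whose
#' labels match the requested cell; `grand_average()` averages subject
#' ERPs with equal weight per subject, regardless of epoch counts.
#'
#' @param epochs an `epoch_set` with labels.
#' @param ... named label filters, e.g. `condition = "Flip"`,
#'   `presentation = 4`; an epoch matches when all named columns equal
#'   the given values.
#' @param baseline if TRUE, subtract the mean of the pre-onset interval
#'   (time < 0) per channel.  Off by default.
#' @return an object of class `erp`: list with `data` (channels x
#'   samples), `time_ms`, `sample_rate`, `n_epochs`, `cell`.
#' @export
condition_average <- function(epochs, ..., baseline = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  cell <- list(...)
  keep <- rep(TRUE, dim(epochs$data)[3L])
  for (nm in names(cell)) {
    if (is.null(epochs$labels[[nm]]))
      stop_input("no label column '", nm, "'")
    keep <- keep & epochs$labels[[nm]] %in% cell[[nm]]
  }
  if (!any(keep))
    stop_input("no epochs match cell: ",
               paste(names(cell), unlist(cell), sep = "=", collapse = ", "))
  m <- apply(epochs$data[, , keep, drop = FALSE], c(1L, 2L), mean)
  if (baseline) m <- m - rowMeans(m[, epochs$time_ms < 0, drop = FALSE])
  structure(list(data = m, time_ms = epochs$time_ms,
                 sample_rate = epochs$sample_rate,
                 n_epochs = sum(keep), cell = cell,
                 channels = epochs$channels),
            class = "erp")
}

#' @rdname condition_average
#' @param erps list of `erp` objects with identical axes (one per
#'   subject).
#' @export
grand_average <- function(erps) {
  if (length(erps) < 1L) stop_input("grand_average needs >= 1 ERP")
  stopifnot(all(vapply(erps, inherits, logical(1), "erp")))
  dims <- vapply(erps, function(e) dim(e$data), numeric(2))
  if (any(dims != dims[, 1])) stop_input("ERPs differ in shape")
  m <- Reduce(`+`, lapply(erps, `[[`, "data")) / length(erps)
  structure(list(data = m, time_ms = erps[[1]]$time_ms,
                 sample_rate = erps[[1]]$sample_rate,
                 n_epochs = sum(vapply(erps, `[[`, numeric(1), "n_epochs")),
                 cell = erps[[1]]$cell, channels = erps[[1]]$channels,
                 n_subjects = length(erps)),
            class = "erp")
}
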