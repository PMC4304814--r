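#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), per channel (and per trial for epoched input), so
#' component latencies are not displaced by filter group delay. The default
#' band is 0.02-30 Hz.
#'
#' @param x an [eeg_recording] or [eeg_epochs] object.
#' @param low,high band edges in Hz; `0 <= low < high < fs/2`.
#' @return an object of the same class with filtered amplitudes.
#' @export
bandpass_filter <- function(x, low = 0.02, high = 30) {
  fs <- x$fs
  if (!(low >= 0 && low < high))
    stop("band edges must satisfy 0 <= low < high", call. = FALSE)
  if (high >= fs / 2)
    stop("`high` (", high, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)", call. = FALSE)
  bf <- if (low > 0)
    signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  else
    signal::butter(2, high / (fs / 2), type = "low")
  apply_ch <- function(v) signal::filtfilt(bf, v)
  if (inherits(x, "eeg_recording")) {
    x$samples <- t(apply(x$samples, 1, apply_ch))
    return(x)
  }
  if (inherits(x, "eeg_epochs")) {
    for (i in seq_len(dim(x$data)[1]))
      x$data[i, , ] <- t(apply(x$data[i, , , drop = TRUE], 1, apply_ch))
    return(x)
  }
  stop("`x` must be an eeg_recording or eeg_epochs object", call. = FALSE)
}

#' Re-reference to the average of the two mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel at every
#' time point. After re-referencing, the mean of the mastoid pair is
#' identically zero.
#'
#' @param x an [eeg_epochs] or [eeg_recording] object.
#' @param mastoids pair of mastoid channel labels.
#' @return same class as `x`, re-referenced.
#' @export
rereference <- function(x, mastoids = c("M1", "M2")) {
  if (length(mastoids) != 2L)
    stop("`mastoids` must name exactly two channels", call. = FALSE)
  if (inherits(x, "eeg_recording")) {
    idx <- channel_index(mastoids, x$channel_labels)
    ref <- colMeans(x$samples[idx, , drop = FALSE])
    x$samples <- sweep(x$samples, 2, ref)
    return(x)
  }
  if (inherits(x, "eeg_epochs")) {
    idx <- channel_index(mastoids, x$montage)
    ref <- apply(x$data[, idx, , drop = FALSE], c(1, 3), mean)  # trial x time
    nt <- dim(x$data)[1]; nc <- dim(x$data)[2]; ns <- dim(x$data)[3]
    x$data <- x$data - aperm(array(ref, c(nt, ns, nc)), c(1, 3, 2))
    return(x)
  }
  stop("`x` must be an eeg_recording or eeg_epochs object", call. = FALSE)
}

#' Cut epochs around stimulus events and baseline-correct
#'
#' Cuts one epoch per event from a continuous recording and subtracts the
#' per-trial, per-channel mean over the baseline window. Events too close to
#' the record edge for the full window are skipped (and counted in the
#' `skipped` attribute).
#'
#' @param r an [eeg_recording] with an events table.
#' @param window epoch window in ms relative to onset; the epoch covers
#'   `[window[1], window[2])` at the sample level (default -200..1000 ms,
#'   i.e. 1200 ms).
#' @param baseline baseline window in ms (`[start, 0)` by default); `NULL`
#'   to skip baseline correction.
#' @param subject_id subject identifier stored in the result.
#' @return an [eeg_epochs]; attribute `skipped` holds the indices of skipped
#'   events.
#' @export
epoch_recording <- function(r, window = c(-200, 1000), baseline = c(-200, 0),
                            subject_id = "S01") {
  stopifnot(inherits(r, "eeg_recording"))
  fs <- r$fs
  s0 <- ms_to_samples(window[1], fs)               # offset of first sample
  n_samp <- ms_to_samples(window[2] - window[1], fs)  # half-open on the right
  times <- samples_to_ms(s0 + seq_len(n_samp) - 1L, fs)
  n_rec <- ncol(r$samples)
  keep <- logical(nrow(r$events)); skipped <- integer()
  for (i in seq_len(nrow(r$events))) {
    a <- r$events$sample_index[i] + s0
    if (a >= 1L && a + n_samp - 1L <= n_rec) keep[i] <- TRUE
    else skipped <- c(skipped, i)
  }
  if (length(skipped))
    message(length(skipped), " event(s) skipped: epoch window outside record")
  ev <- r$events[keep, , drop = FALSE]
  if (!nrow(ev)) stop("no events leave room for the epoch window", call. = FALSE)
  data <- array(0, c(nrow(ev), nrow(r$samples), n_samp))
  for (i in seq_len(nrow(ev))) {
    a <- ev$sample_index[i] + s0
    data[i, , ] <- r$samples[, a:(a + n_samp - 1L)]
  }
  x <- eeg_epochs(data, times, ev$condition, fs, subject_id, r$channel_labels)
  if (!is.null(baseline)) x <- baseline_correct(x, baseline)
  attr(x, "skipped") <- skipped
  x
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial, per-channel mean over the baseline window
#' (`[start, 0)` relative to onset by default). Idempotent.
#'
#' @param x an [eeg_epochs] object.
#' @param baseline ms pair; samples with `baseline[1] <= t < baseline[2]`.
#' @return baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(x, baseline = c(-200, 0)) {
  stopifnot(inherits(x, "eeg_epochs"))
  idx <- which(x$times >= baseline[1] - 1e-9 & x$times < baseline[2] - 1e-9)
  if (!length(idx))
    stop("baseline window contains no samples", call. = FALSE)
  bl <- apply(x$data[, , idx, drop = FALSE], c(1, 2), mean)
  x$data <- x$data - array(bl, dim(x$data))
  x
}

#' Reject trials with amplitude artifacts
#'
#' Removes every trial in which any scalp channel at any sample exceeds the
#' threshold in absolute value (+/-80 muV by default). EOG channels are
#' excluded from the screen.
#'
#' @param x an [eeg_epochs] object.
#' @param threshold rejection threshold in muV (> 0).
#' @param exclude channel labels ignored by the screen (ocular channels).
#' @return list with `epochs` (surviving trials) and `rejected` (logical mask
#'   over the original trials, `TRUE` = rejected).
#' @export
reject_artifacts <- function(x, threshold = 80,
                             exclude = c("VEOG", "HEOG", "EOG")) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  chans <- which(!(x$montage %in% exclude))
  peak <- apply(abs(x$data[, chans, , drop = FALSE]), 1, max)
  rejected <- peak > threshold
  if (all(rejected))
    stop("all trials rejected at threshold ", threshold,
         " muV; downstream averaging undefined", call. = FALSE)
  list(epochs = subset_trials(x, !rejected), rejected = rejected)
}
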