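#' @useDynLib erpride, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov coef cor fitted median pf pt qt quantile rnorm
#'   sd setNames t.test var
#' @importFrom utils read.delim write.csv packageVersion
NULL

CONDITIONS <- c("CON", "SEM", "SEM+SYN")

#' Continuous EEG recording
#'
#' Container for a continuous multi-channel recording with stimulus events.
#' Amplitudes are in microvolts, time is indexed in samples at rate `fs`.
#'
#' @param samples numeric matrix, channel x time (muV).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names
#'   (10-20 system labels for scalp channels).
#' @param events data.frame with columns `sample_index` (1-based sample of
#'   stimulus onset) and `condition` (one of `CON`, `SEM`, `SEM+SYN`).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels, events) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique", call. = FALSE)
  if (length(channel_labels) != nrow(samples))
    stop("length(channel_labels) must equal nrow(samples)", call. = FALSE)
  events <- as.data.frame(events)
  if (!all(c("sample_index", "condition") %in% names(events)))
    stop("`events` needs columns sample_index and condition", call. = FALSE)
  if (nrow(events) && (min(events$sample_index) < 1L ||
                       max(events$sample_index) > ncol(samples)))
    stop("event sample_index outside record length", call. = FALSE)
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels), events = events),
    class = "eeg_recording")
}

#' Epoched single-trial EEG
#'
#' The common currency of all analysis stages: a trial x channel x time
#' tensor of single-trial EEG cut around stimulus onset, with a millisecond
#' time axis (onset = 0 ms) and one condition label per trial.
#'
#' @param data numeric array, trial x channel x time (muV).
#' @param times numeric vector of sample times in ms relative to stimulus
#'   onset; strictly increasing with uniform step `1000/fs`.
#' @param conditions character vector, one condition label per trial.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier (scalar).
#' @param montage character vector of channel labels, one per channel.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, conditions, fs, subject_id = "S01",
                       montage = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trial x channel x time)", call. = FALSE)
  if (is.null(montage)) montage <- dimnames(data)[[2]]
  if (is.null(montage))
    stop("`montage` (channel labels) is required", call. = FALSE)
  if (length(montage) != dim(data)[2])
    stop("montage length (", length(montage), ") != channel dimension (",
         dim(data)[2], ")", call. = FALSE)
  if (anyDuplicated(montage))
    stop("montage labels must be unique", call. = FALSE)
  if (length(times) != dim(data)[3])
    stop("times length (", length(times), ") != time dimension (",
         dim(data)[3], ")", call. = FALSE)
  step <- 1000 / fs
  if (length(times) > 1L) {
    d <- diff(times)
    if (any(d <= 0) || max(abs(d - step)) > 1e-6)
      stop("`times` must be strictly increasing with uniform step 1000/fs ms",
           call. = FALSE)
  }
  conditions <- as.character(conditions)
  if (length(conditions) != dim(data)[1])
    stop("conditions length (", length(conditions),
         ") != trial count (", dim(data)[1], ")", call. = FALSE)
  dimnames(data) <- list(NULL, montage, NULL)
  structure(
    list(data = data, times = as.numeric(times), conditions = conditions,
         fs = fs, subject_id = subject_id, montage = as.character(montage)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> subject", x$subject_id, "\n")
  cat(sprintf("  %d trials x %d channels x %d samples (%.0f Hz, %g..%g ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              min(x$times), max(x$times)))
  tb <- table(x$conditions)
  cat("  trials per condition:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

#' Subset epochs by trial
#'
#' @param x an [eeg_epochs] object.
#' @param trials logical or integer index over trials.
#' @return an `eeg_epochs` with the selected trials.
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "eeg_epochs"))
  eeg_epochs(x$data[trials, , , drop = FALSE], x$times,
             x$conditions[trials], x$fs, x$subject_id, x$montage)
}

#' Subset epochs by channel
#'
#' Restricting a RIDE fit to the latency channels gives the identical latency
#' trajectory at a fraction of the cost (the decomposition is channel-wise
#' independent given the latency sets), which is convenient when only
#' latencies are needed.
#'
#' @param x an [eeg_epochs] object.
#' @param labels channel labels to keep, in the requested order.
#' @return an `eeg_epochs` with the selected channels.
#' @export
subset_channels <- function(x, labels) {
  idx <- channel_index(labels, x$montage)
  eeg_epochs(x$data[, idx, , drop = FALSE], x$times, x$conditions, x$fs,
             x$subject_id, x$montage[idx])
}

#' Per-condition or averaged evoked response
#'
#' A channel x time average, either a conventional stimulus-locked average
#' or a RIDE reconstruction.
#'
#' @param data numeric matrix, channel x time (muV).
#' @param times ms axis.
#' @param condition condition label.
#' @param n_trials number of trials averaged (>= 1).
#' @param montage channel labels.
#' @param subject_id subject identifier (NA for grand averages).
#' @return an object of class `eeg_evoked`.
#' @export
eeg_evoked <- function(data, times, condition, n_trials, montage,
                       subject_id = NA_character_) {
  data <- as.matrix(data)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (nrow(data) != length(montage) || ncol(data) != length(times))
    stop("evoked dimensions must match montage and times", call. = FALSE)
  rownames(data) <- montage
  structure(
    list(data = data, times = as.numeric(times), condition = condition,
         n_trials = as.integer(n_trials), montage = as.character(montage),
         subject_id = subject_id),
    class = "eeg_evoked")
}

#' @export
print.eeg_evoked <- function(x, ...) {
  cat(sprintf("<eeg_evoked> condition %s, %d trials, %d channels x %d samples\n",
              x$condition, x$n_trials, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Default 38-channel 10-20 montage
#'
#' The 38 scalp sites used throughout: frontal-polar through occipital rows of
#' the international 10-20/10-10 system.
#'
#' @return character vector of 38 channel labels.
#' @export
default_montage <- function() {
  c("FP1", "FPz", "FP2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "PO7", "PO5", "POz", "PO6", "PO8", "Oz")
}

#' Midline / lateral-ROI electrode layout
#'
#' Analysis layout: 8 midline electrodes and six lateral regions of interest
#' (anterior/central/posterior crossed with hemisphere), four electrodes each,
#' plus the mastoid reference pair. Loaded from a YAML definition.
#'
#' @param path YAML file with fields `midline`, `rois` (name -> 4 labels) and
#'   `mastoids`; defaults to the layout shipped with the package.
#' @return an object of class `roi_layout`: list with `midline`, `rois`,
#'   `mastoids`.
#' @export
roi_layout <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "montage_1020_38.yaml", package = "erpride")
  y <- yaml::read_yaml(path)
  lay <- structure(list(midline = as.character(y$midline),
                        rois = lapply(y$rois, as.character),
                        mastoids = as.character(y$mastoids)),
                   class = "roi_layout")
  validate_roi_layout(lay)
  lay
}

validate_roi_layout <- function(lay, montage = default_montage()) {
  if (length(lay$midline) != 8L)
    stop("midline must have 8 electrodes", call. = FALSE)
  all_roi <- unlist(lay$rois, use.names = FALSE)
  if (anyDuplicated(all_roi))
    stop("lateral ROIs must be disjoint", call. = FALSE)
  missing <- setdiff(c(lay$midline, all_roi), montage)
  if (length(missing))
    stop("layout members not in montage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(lay)
}

channel_index <- function(labels, montage) {
  idx <- match(labels, montage)
  if (anyNA(idx))
    stop("channel(s) not found: ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

time_index <- function(times, window) {
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (!length(idx))
    stop("window [", window[1], ", ", window[2],
         "] ms contains no samples", call. = FALSE)
  idx
}

ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))
samples_to_ms <- function(s, fs) s * 1000 / fs
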