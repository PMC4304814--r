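#' Conventional stimulus-locked average
#'
#' Pointwise mean across the trials of one condition.
#'
#' @param x an [eeg_epochs] object.
#' @param condition condition label to average (default: all trials).
#' @return an [eeg_evoked].
#' @export
average_evoked <- function(x, condition = NULL) {
  stopifnot(inherits(x, "eeg_epochs"))
  sel <- if (is.null(condition)) rep(TRUE, n_trials(x))
         else x$conditions == condition
  if (!any(sel))
    stop("no trials for condition ", condition, call. = FALSE)
  d <- x$data[sel, , , drop = FALSE]
  m <- apply(d, c(2, 3), mean)
  eeg_evoked(m, x$times, condition %||% "all", sum(sel), x$montage,
             x$subject_id)
}

#' Grand average across subjects
#'
#' @param evokeds list of [eeg_evoked] with identical channel/time axes.
#' @param weighting `"equal_subject"` (default, standard ERP practice) or
#'   `"by_trials"` (weights each evoked by its trial count).
#' @return an [eeg_evoked]; `n_trials` is the summed trial count.
#' @export
grand_average <- function(evokeds, weighting = c("equal_subject", "by_trials")) {
  weighting <- match.arg(weighting)
  stopifnot(length(evokeds) >= 1)
  e1 <- evokeds[[1]]
  for (e in evokeds) {
    if (!identical(dim(e$data), dim(e1$data)) ||
        max(abs(e$times - e1$times)) > 1e-9 ||
        !identical(e$montage, e1$montage))
      stop("evokeds have mismatching channel/time axes", call. = FALSE)
  }
  w <- if (weighting == "equal_subject") rep(1, length(evokeds))
       else vapply(evokeds, `[[`, 0L, "n_trials")
  w <- w / sum(w)
  acc <- 0
  for (i in seq_along(evokeds)) acc <- acc + w[i] * evokeds[[i]]$data
  eeg_evoked(acc, e1$times, e1$condition,
             sum(vapply(evokeds, `[[`, 0L, "n_trials")), e1$montage)
}

#' Mean amplitude in a time window, per electrode or ROI
#'
#' Averages over the samples whose times fall in `[window[1], window[2]]`
#' (both boundary samples included), then over each unit's electrodes.
#'
#' @param e an [eeg_evoked].
#' @param window ms pair inside the epoch.
#' @param units either a character vector of electrode labels (each its own
#'   unit) or a named list mapping ROI name -> electrode labels.
#' @return data.frame: subject_id, condition, unit, win_lo, win_hi,
#'   mean_amplitude (muV).
#' @export
window_mean <- function(e, window, units) {
  stopifnot(inherits(e, "eeg_evoked"))
  idx <- time_index(e$times, window)
  if (!is.list(units)) units <- setNames(as.list(units), units)
  rows <- lapply(names(units), function(u) {
    ch <- channel_index(units[[u]], e$montage)
    data.frame(subject_id = e$subject_id, condition = e$condition, unit = u,
               win_lo = window[1], win_hi = window[2],
               mean_amplitude = mean(e$data[ch, idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-channel difference topography in a time window
#'
#' Window mean of `a - b` per channel, the quantity shown in difference
#' scalp maps.
#'
#' @param a,b [eeg_evoked] objects on identical axes.
#' @param window ms pair.
#' @return data.frame: channel, value (muV).
#' @export
difference_topography <- function(a, b, window) {
  stopifnot(inherits(a, "eeg_evoked"), inherits(b, "eeg_evoked"))
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$times - b$times)) > 1e-9 || !identical(a$montage, b$montage))
    stop("evokeds have mismatching channel/time axes", call. = FALSE)
  idx <- time_index(a$times, window)
  d <- a$data[, idx, drop = FALSE] - b$data[, idx, drop = FALSE]
  data.frame(channel = a$montage, value = rowMeans(d),
             stringsAsFactors = FALSE)
}
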