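#' RIDE configuration
#'
#' Settings for residue iteration decomposition: the three component clusters
#' (S locked to stimulus onset; C1 and C2 latency-variable inside their search
#' windows), the channels whose mean drives latency estimation, and the
#' iteration controls.
#'
#' @param c1_window,c2_window latency search windows in ms (defaults
#'   200-600 ms for the N400-complex cluster and 400-800 ms for the
#'   P600-complex cluster).
#' @param latency_channels labels of the channels averaged into the latency
#'   estimation signal (default centro-parietal Cz, CPz, Pz).
#' @param max_outer maximum outer (decompose + latency update) iterations.
#' @param max_inner maximum inner decomposition sweeps.
#' @param tol relative waveform-change tolerance for convergence (> 0).
#' @param taper_ms cosine roll-off width (ms) applied at cluster window edges
#'   and at edges vacated by shifting.
#' @param s_window optional ms window restricting the stimulus-locked cluster
#'   (default: the full epoch).
#' @return an object of class `ride_config`.
#' @export
ride_config <- function(c1_window = c(200, 600), c2_window = c(400, 800),
                        latency_channels = c("Cz", "CPz", "Pz"),
                        max_outer = 10, max_inner = 100, tol = 1e-3,
                        taper_ms = 50, s_window = NULL) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (c1_window[1] >= c1_window[2] || c2_window[1] >= c2_window[2])
    stop("search windows must be increasing ms pairs", call. = FALSE)
  structure(list(windows = list(C1 = c1_window, C2 = c2_window),
                 latency_channels = latency_channels,
                 max_outer = max_outer, max_inner = max_inner, tol = tol,
                 taper_ms = taper_ms, s_window = s_window),
            class = "ride_config")
}

#' Shift a waveform along time
#'
#' Non-circular shift: samples moved past the epoch edge are dropped, vacated
#' samples are zero-filled, and a half-cosine taper of width `taper_ms` is
#' applied at the junction so subtraction of shifted waveforms does not
#' introduce hard discontinuities. A shift of 0 is the identity.
#'
#' @param w channel x time numeric matrix.
#' @param delta_ms shift in ms (positive = later).
#' @param fs sampling rate Hz (shift is rounded to whole samples).
#' @param taper_ms taper width in ms.
#' @return shifted channel x time matrix.
#' @export
shift_waveform <- function(w, delta_ms, fs, taper_ms = 50) {
  if (!is.finite(delta_ms)) stop("shift must be finite", call. = FALSE)
  s <- ms_to_samples(delta_ms, fs)
  shift_samples(w, s, ms_to_samples(taper_ms, fs))
}

shift_samples <- function(w, s, taper_n = 0L) {
  ns <- ncol(w)
  if (abs(s) >= ns) stop("shift exceeds the epoch span", call. = FALSE)
  if (s == 0) return(w)
  out <- matrix(0, nrow(w), ns)
  if (s > 0) out[, (s + 1L):ns] <- w[, 1L:(ns - s)]
  else out[, 1L:(ns + s)] <- w[, (1L - s):ns]
  if (taper_n > 0L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(taper_n) - 0.5) / taper_n))
    if (s > 0) {
      j <- (s + 1L):min(ns, s + taper_n)
      out[, j] <- sweep(out[, j, drop = FALSE], 2, ramp[seq_along(j)], `*`)
    } else {
      j <- (ns + s):max(1L, ns + s - taper_n + 1L)
      out[, j] <- sweep(out[, j, drop = FALSE], 2, ramp[seq_along(j)], `*`)
    }
  }
  out
}

# Raised-cosine window weights over the epoch: 1 inside [lo, hi], cosine
# roll-off over taper_ms outside, 0 beyond.
window_taper <- function(times, window, taper_ms) {
  if (is.null(window)) return(rep(1, length(times)))
  w <- numeric(length(times))
  lo <- window[1]; hi <- window[2]
  w[times >= lo & times <= hi] <- 1
  if (taper_ms > 0) {
    left <- times >= lo - taper_ms & times < lo
    w[left] <- 0.5 * (1 + cos(pi * (lo - times[left]) / taper_ms))
    right <- times > hi & times <= hi + taper_ms
    w[right] <- 0.5 * (1 + cos(pi * (times[right] - hi) / taper_ms))
  }
  w
}

latency_signal <- function(x, latency_channels) {
  idx <- channel_index(latency_channels, x$montage)
  # trial x time mean over the latency channels
  apply(x$data[, idx, , drop = FALSE], c(1, 3), mean)
}

# Normalized cross-correlation (cosine) lag scores, the classical Woody
# matching criterion: sig (trial x time), template over window indices
# win_idx; returns trial x lag score matrix for integer sample lags `lags`.
lag_scores <- function(sig, template, win_idx, lags) {
  ns <- ncol(sig)
  scores <- matrix(-Inf, nrow(sig), length(lags))
  for (j in seq_along(lags)) {
    idx <- win_idx + lags[j]
    ok <- idx >= 1L & idx <= ns
    seg <- sig[, idx[ok], drop = FALSE]
    en <- sqrt(rowSums(seg^2) * sum(template[ok]^2))
    scores[, j] <- (seg %*% template[ok]) / pmax(en, 1e-12)
  }
  scores
}

# Arg-max lag per trial with ties broken toward the smaller |lag|.
best_lags <- function(scores, lags) {
  ord <- order(abs(lags), lags)
  apply(scores, 1, function(sc) {
    if (all(abs(sc) < 1e-12)) return(0L)
    m <- max(sc)
    cand <- which(sc >= m - 1e-9 * max(abs(m), 1))
    lags[ord[match(TRUE, ord %in% cand)]]
  })
}

recentre <- function(lags) as.integer(lags - round(median(lags)))

#' Woody adaptive-filter latency estimation
#'
#' Iterative template matching: the template starts as the trial average of
#' the latency-channel signal restricted to the search window; each trial's
#' latency is the arg-max of the cross-correlation between template and trial
#' within the admissible shift range; the template is re-averaged at the
#' aligned latencies; repeated until the latency assignments stabilize.
#' Returned latencies are median-centered (ms).
#'
#' @param x an [eeg_epochs] (>= 2 trials).
#' @param window ms search window inside the epoch.
#' @param latency_channels channel labels averaged into the estimation signal.
#' @param max_iter maximum template iterations.
#' @return numeric vector of per-trial latencies in ms (median 0).
#' @export
woody_latency <- function(x, window, latency_channels = c("Cz", "CPz", "Pz"),
                          max_iter = 20) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (n_trials(x) < 2) stop("need at least 2 trials", call. = FALSE)
  sig <- latency_signal(x, latency_channels)
  win_idx <- time_index(x$times, window)
  step <- 1000 / x$fs
  max_lag <- floor((window[2] - window[1]) / 2 / step)
  lags_grid <- seq.int(-max_lag, max_lag)
  flat <- apply(sig, 1, function(v) var(v) < 1e-24)
  if (any(flat))
    warning(sum(flat), " flat (zero-variance) trial(s); latency set to 0")
  lags <- integer(nrow(sig))
  for (it in seq_len(max_iter)) {
    template <- colMeans(align_rows(sig, win_idx, lags))
    scores <- lag_scores(sig, template, win_idx, lags_grid)
    new_lags <- best_lags(scores, lags_grid)
    new_lags[flat] <- 0L
    new_lags <- recentre(new_lags)
    if (identical(new_lags, lags)) break
    lags <- new_lags
  }
  lags * step
}

# Gather sig[i, win_idx + lag_i] rows (zero padded outside the epoch).
align_rows <- function(sig, win_idx, lags) {
  out <- matrix(0, nrow(sig), length(win_idx))
  ns <- ncol(sig)
  for (i in seq_len(nrow(sig))) {
    idx <- win_idx + lags[i]
    ok <- idx >= 1L & idx <= ns
    out[i, ok] <- sig[i, idx[ok]]
  }
  out
}

#' RIDE decomposition at fixed latencies
#'
#' Iterative-subtraction estimation of the S, C1 and C2 cluster waveforms
#' given per-trial latency sets: for each cluster in turn, the current
#' estimates of the other clusters (shifted to their own trial latencies) are
#' subtracted from every trial, the residual trials are aligned to the target
#' cluster's latencies, and the cluster waveform is the pointwise median
#' across aligned trials, restricted to the cluster's window with a cosine
#' roll-off. Sweeps repeat until the waveforms stop changing.
#'
#' @param x an [eeg_epochs].
#' @param latencies named list of per-trial latencies in ms:
#'   `S` (all zero), `C1`, `C2`.
#' @param cfg a [ride_config].
#' @param init optional named list of waveforms to warm-start from (used by
#'   the outer RIDE loop).
#' @return list with `waves` (named list of channel x time matrices),
#'   `n_inner`, `converged`.
#' @export
decompose_components <- function(x, latencies, cfg = ride_config(),
                                 init = NULL) {
  step <- 1000 / x$fs
  nc <- dim(x$data)[2]; ns <- dim(x$data)[3]
  names_c <- c("S", "C1", "C2")
  for (nm in c("C1", "C2"))
    if (length(latencies[[nm]]) != n_trials(x))
      stop("latency set for ", nm, " incomplete", call. = FALSE)
  latencies$S <- latencies$S %||% rep(0, n_trials(x))
  shifts <- lapply(latencies[names_c], function(l) as.integer(round(l / step)))
  tapers <- list(
    S = window_taper(x$times, cfg$s_window, cfg$taper_ms),
    C1 = window_taper(x$times, cfg$windows$C1, cfg$taper_ms),
    C2 = window_taper(x$times, cfg$windows$C2, cfg$taper_ms))
  waves <- if (is.null(init)) setNames(rep(list(matrix(0, nc, ns)), 3), names_c)
           else lapply(init[names_c], unname)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_inner)) {
    delta <- 0
    for (nm in names_c) {
      others <- setdiff(names_c, nm)
      new_w <- cpp_cluster_median(
        x$data, waves[others],
        do.call(cbind, shifts[others]), shifts[[nm]], tapers[[nm]])
      # relative RMS change; the pointwise median makes max-abs change noisy
      scale <- sqrt(mean(new_w^2))
      delta <- max(delta, sqrt(mean((new_w - waves[[nm]])^2)) /
                     max(scale, 1e-12))
      waves[[nm]] <- new_w
    }
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  for (nm in names_c) rownames(waves[[nm]]) <- x$montage
  list(waves = waves, n_inner = it, converged = converged)
}

#' Update cluster latencies by cross-correlation with the template
#'
#' For each trial, the other two clusters (shifted to that trial's current
#' latencies) are subtracted, the residual signal (mean over the latency
#' channels) is cross-correlated with the target cluster's template inside
#' the admissible shift range, and the arg-max lag is returned (ties toward
#' the smaller |lag|). Results are median-centered.
#'
#' @param x an [eeg_epochs].
#' @param waves named list of current cluster waveforms (channel x time).
#' @param latencies named list of current per-trial latencies (ms).
#' @param target `"C1"` or `"C2"`.
#' @param cfg a [ride_config].
#' @return per-trial latencies in ms (median 0).
#' @export
update_latencies <- function(x, waves, latencies, target, cfg = ride_config()) {
  stopifnot(target %in% c("C1", "C2"))
  step <- 1000 / x$fs
  ch <- channel_index(cfg$latency_channels, x$montage)
  tmpl_full <- colMeans(waves[[target]][ch, , drop = FALSE])
  if (max(abs(tmpl_full)) < 1e-12) {
    warning("all-zero template for ", target, "; latencies unchanged")
    return(latencies[[target]])
  }
  others <- setdiff(c("S", "C1", "C2"), target)
  shifts <- vapply(others, function(nm)
    as.integer(round((latencies[[nm]] %||% rep(0, n_trials(x))) / step)),
    integer(n_trials(x)))
  resid <- cpp_residuals(x$data, waves[others], cbind(shifts))
  sig <- apply(resid[, ch, , drop = FALSE], c(1, 3), mean)
  window <- cfg$windows[[target]]
  win_idx <- time_index(x$times, window)
  max_lag <- floor((window[2] - window[1]) / 2 / step)
  lags_grid <- seq.int(-max_lag, max_lag)
  scores <- lag_scores(sig, tmpl_full[win_idx], win_idx, lags_grid)
  lags <- best_lags(scores, lags_grid)
  # hysteresis: near the peak the correlation is flat, so the arg-max flips
  # between neighbouring samples from iteration to iteration; keep a trial's
  # current latency whenever its score is within a small tolerance of the
  # maximum, so the outer loop can settle
  cur <- as.integer(round(latencies[[target]] / step))
  for (i in seq_len(nrow(scores))) {
    j <- match(cur[i], lags_grid)
    if (!is.na(j) && scores[i, j] >= max(scores[i, ]) - 2e-3)
      lags[i] <- cur[i]
  }
  recentre(lags) * step
}

#' Fit a residue iteration decomposition (RIDE) model
#'
#' Decomposes one subject-and-condition set of single-trial epochs into a
#' stimulus-locked cluster (S) and two latency-variable clusters (C1,
#' N400-complex; C2, P600-complex). Per-trial C1/C2 latencies are initialized
#' by Woody's method inside the configured search windows; the outer loop then
#' alternates waveform decomposition ([decompose_components()]) and
#' cross-correlation latency updating ([update_latencies()]) until the median
#' latency change falls below one sample and the waveforms stabilize.
#'
#' @param x an [eeg_epochs]; typically the trials of a single condition
#'   (use `condition` to subset).
#' @param cfg a [ride_config].
#' @param condition optional condition label to subset before fitting.
#' @return an object of class `ride_fit`: cluster waveforms and per-trial
#'   latencies, the latency-compensated reconstructed ERP
#'   ([reconstruct_erp()]), iteration diagnostics (`n_iterations`,
#'   `converged`, `residual_rms` trace), and the epochs the model was fit to.
#' @seealso [reconstruct_erp()], [woody_latency()]
#' @examples
#' cfg <- sim_config(n_subjects = 1, trials_per_condition = 20, seed = 7,
#'                   noise_sd = 1, include_mastoids = FALSE)
#' sim <- simulate_subject(cfg)
#' fit <- ride(sim$epochs, condition = "SEM")
#' fit
#' @export
ride <- function(x, cfg = ride_config(), condition = NULL) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (!is.null(condition)) x <- subset_trials(x, x$conditions == condition)
  if (n_trials(x) < 10)
    warning("RIDE fitted to fewer than 10 trials; estimates may be unstable")
  step <- 1000 / x$fs
  lat <- list(S = rep(0, n_trials(x)),
              C1 = woody_latency(x, cfg$windows$C1, cfg$latency_channels),
              C2 = woody_latency(x, cfg$windows$C2, cfg$latency_channels))
  # The decomposition is channel-wise independent given the latency sets, and
  # the latency updates read only the latency channels, so the outer loop is
  # run on the latency channels alone (identical latency trajectory at a
  # fraction of the cost); the remaining channels are decomposed once at the
  # final latencies below. The residual-RMS trace is over latency channels.
  xl <- subset_channels(x, cfg$latency_channels)
  rms_trace <- numeric(0)
  converged <- FALSE
  waves <- NULL
  n_outer <- 0L
  stall <- 0L
  for (n_outer in seq_len(cfg$max_outer)) {
    dec <- decompose_components(xl, lat, cfg, init = waves)
    waves <- dec$waves
    new_c1 <- suppressWarnings(update_latencies(xl, waves, lat, "C1", cfg))
    new_c2 <- suppressWarnings(update_latencies(xl, waves, lat, "C2", cfg))
    dlat <- c(abs(new_c1 - lat$C1), abs(new_c2 - lat$C2)) / step
    lat$C1 <- new_c1; lat$C2 <- new_c2
    rms_trace <- c(rms_trace, residual_rms(xl, waves, lat, step))
    # converged when the latency assignments have settled (median change
    # below one sample) and the decomposition's own sweep-to-sweep waveform
    # change fell below tol
    if (median(dlat) < 1 && dec$converged) { converged <- TRUE; break }
    # plateau guard: when a condition carries no sizeable latency-variable
    # component the arg-max chases noise and never settles; once the residual
    # stops improving for two consecutive iterations while latencies are
    # still jumping, further alternation cannot help - stop (flagged
    # unconverged)
    k <- length(rms_trace)
    if (k >= 2 && rms_trace[k] > min(rms_trace[1:(k - 1)]) * (1 - 1e-4) &&
        median(dlat) >= 2) stall <- stall + 1L else stall <- 0L
    if (stall >= 2L) break
  }
  # final decomposition of all channels at the converged latencies
  waves <- decompose_components(x, lat, cfg)$waves
  clusters <- list(
    S = list(name = "S", waveform = waves$S, latencies = lat$S,
             window = cfg$s_window),
    C1 = list(name = "C1", waveform = waves$C1, latencies = lat$C1,
              window = cfg$windows$C1),
    C2 = list(name = "C2", waveform = waves$C2, latencies = lat$C2,
              window = cfg$windows$C2))
  fit <- structure(
    list(clusters = clusters, config = cfg, epochs = x,
         condition = if (is.null(condition)) "all" else condition,
         n_iterations = n_outer, converged = converged,
         residual_rms = rms_trace),
    class = "ride_fit")
  fit$reconstructed <- reconstruct_erp(fit)
  fit
}

residual_rms <- function(x, waves, lat, step) {
  shifts <- vapply(c("S", "C1", "C2"), function(nm)
    as.integer(round(lat[[nm]] / step)), integer(n_trials(x)))
  r <- cpp_residuals(x$data, waves[c("S", "C1", "C2")], cbind(shifts))
  sqrt(mean(r^2))
}

#' Latency-compensated (reconstructed) ERP
#'
#' The reconstructed ERP places every cluster at its most probable latency:
#' S plus C1 and C2 each shifted to the median of its per-trial latencies
#' (zero by construction, since latencies are median-centered).
#'
#' @param fit a [ride()] fit.
#' @return an [eeg_evoked] on the same channel/time axes as the input epochs.
#' @export
reconstruct_erp <- function(fit) {
  stopifnot(inherits(fit, "ride_fit"))
  x <- fit$epochs
  step <- 1000 / x$fs
  acc <- matrix(0, dim(x$data)[2], dim(x$data)[3])
  for (cl in fit$clusters) {
    s <- as.integer(round(median(cl$latencies) / step))
    acc <- acc + shift_samples(cl$waveform, s,
                               ms_to_samples(fit$config$taper_ms, x$fs))
  }
  eeg_evoked(acc, x$times, fit$condition, n_trials(x), x$montage,
             x$subject_id)
}

#' @export
print.ride_fit <- function(x, ...) {
  cat("<ride_fit>", x$condition, "-", n_trials(x$epochs), "trials,",
      x$n_iterations, "outer iteration(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  for (nm in c("C1", "C2"))
    cat(sprintf("  %s latencies (ms): sd %.1f, range [%g, %g]\n", nm,
                sd(x$clusters[[nm]]$latencies),
                min(x$clusters[[nm]]$latencies),
                max(x$clusters[[nm]]$latencies)))
  invisible(x)
}

#' @export
summary.ride_fit <- function(object, ...) {
  out <- list(
    condition = object$condition,
    n_trials = n_trials(object$epochs),
    n_iterations = object$n_iterations,
    converged = object$converged,
    residual_rms = object$residual_rms,
    latency_sd = vapply(object$clusters, function(cl) sd(cl$latencies), 0),
    peak = vapply(object$clusters, function(cl) {
      i <- which.max(abs(cl$waveform))
      cl$waveform[i]
    }, 0))
  class(out) <- "summary.ride_fit"
  out
}

#' @export
print.summary.ride_fit <- function(x, ...) {
  cat("RIDE fit:", x$condition, "-", x$n_trials, "trials\n")
  cat(sprintf("  %d outer iteration(s); converged: %s\n", x$n_iterations,
              x$converged))
  cat("  residual RMS trace:",
      paste(sprintf("%.3f", x$residual_rms), collapse = " -> "), "\n")
  cat("  cluster latency SD (ms):",
      paste(sprintf("%s=%.1f", names(x$latency_sd), x$latency_sd),
            collapse = ", "), "\n")
  cat("  cluster peak amplitude (muV):",
      paste(sprintf("%s=%.2f", names(x$peak), x$peak), collapse = ", "), "\n")
  invisible(x)
}

#' Per-trial latencies of a RIDE fit
#'
#' @param object a [ride()] fit.
#' @param ... unused.
#' @return data.frame: trial, cluster, latency_ms.
#' @export
coef.ride_fit <- function(object, ...) {
  nt <- n_trials(object$epochs)
  do.call(rbind, lapply(object$clusters, function(cl)
    data.frame(trial = seq_len(nt), cluster = cl$name,
               latency_ms = cl$latencies, stringsAsFactors = FALSE)))
}

#' Per-trial model prediction of a RIDE fit
#'
#' @param object a [ride()] fit.
#' @param average if `TRUE`, return the trial-average of the summed shifted
#'   clusters (the model's prediction of the conventional average) as a
#'   channel x time matrix; otherwise the full trial x channel x time array.
#' @param ... unused.
#' @export
fitted.ride_fit <- function(object, average = FALSE, ...) {
  x <- object$epochs
  step <- 1000 / x$fs
  shifts <- vapply(object$clusters, function(cl)
    as.integer(round(cl$latencies / step)), integer(n_trials(x)))
  waves <- lapply(object$clusters, `[[`, "waveform")
  if (average) {
    m <- cpp_model_average(waves, cbind(shifts), dim(x$data)[2], dim(x$data)[3])
    rownames(m) <- x$montage
    return(m)
  }
  x$data - cpp_residuals(x$data, waves, cbind(shifts))
}

#' Residuals of a RIDE fit
#'
#' @param object a [ride()] fit.
#' @param ... unused.
#' @return trial x channel x time array of `data - fitted`.
#' @export
residuals.ride_fit <- function(object, ...) {
  x <- object$epochs
  step <- 1000 / x$fs
  shifts <- vapply(object$clusters, function(cl)
    as.integer(round(cl$latencies / step)), integer(n_trials(x)))
  cpp_residuals(x$data, lapply(object$clusters, `[[`, "waveform"),
                cbind(shifts))
}

#' Plot a RIDE fit
#'
#' Conventional average, reconstructed ERP, and the three cluster waveforms
#' at one channel.
#'
#' @param x a [ride()] fit.
#' @param channel channel label (default: first latency channel).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ride_fit <- function(x, channel = x$config$latency_channels[1], ...) {
  ep <- x$epochs
  ch <- channel_index(channel, ep$montage)
  conv <- apply(ep$data[, ch, , drop = FALSE], 3, mean)
  mat <- cbind(conventional = conv,
               reconstructed = x$reconstructed$data[ch, ],
               S = x$clusters$S$waveform[ch, ],
               C1 = x$clusters$C1$waveform[ch, ],
               C2 = x$clusters$C2$waveform[ch, ])
  graphics::matplot(ep$times, mat, type = "l", lty = c(1, 1, 2, 2, 2),
                    col = c("grey40", "red", "blue", "darkgreen", "purple"),
                    xlab = "time (ms)", ylab = "amplitude (muV)",
                    main = paste("RIDE fit at", channel), ...)
  graphics::legend("topleft", colnames(mat), lty = c(1, 1, 2, 2, 2),
                   col = c("grey40", "red", "blue", "darkgreen", "purple"),
                   bty = "n", cex = 0.8)
  invisible(x)
}
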