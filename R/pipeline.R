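#' End-to-end pipeline configuration
#'
#' @param seed integer seed (mandatory when simulating).
#' @param source `"simulate"` (default) or `"files"`.
#' @param sim a [sim_config] (for `source = "simulate"`); its seed is
#'   overridden by `seed`.
#' @param files character vector of epochs-container paths (for
#'   `source = "files"`), one per subject.
#' @param ride a [ride_config].
#' @param windows per-track analysis windows (ms): conventional N400/P600
#'   default 300-500 and 570-810; reconstructed P600 window 500-800.
#' @param reject_threshold artifact rejection threshold in muV.
#' @param layout an [roi_layout].
#' @param out_dir output directory (`NULL` = return results only).
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, source = c("simulate", "files"),
                            sim = NULL, files = NULL,
                            ride = ride_config(),
                            windows = list(
                              conventional = list(N400 = c(300, 500),
                                                  P600 = c(570, 810)),
                              reconstructed = list(N400 = c(300, 500),
                                                   P600 = c(500, 800))),
                            reject_threshold = 80,
                            layout = roi_layout(), out_dir = NULL,
                            log_level = c("info", "quiet")) {
  source <- match.arg(source)
  log_level <- match.arg(log_level)
  if (source == "simulate") {
    if (missing(seed)) stop("`seed` is required when simulating", call. = FALSE)
    if (is.null(sim)) sim <- sim_config(seed = seed)
    sim$seed <- as.integer(seed)
  } else {
    if (is.null(files) || !all(file.exists(files)))
      stop("`files` must list existing epochs files", call. = FALSE)
    if (missing(seed)) seed <- 0L
  }
  structure(list(seed = as.integer(seed), source = source, sim = sim,
                 files = files, ride = ride, windows = windows,
                 reject_threshold = reject_threshold, layout = layout,
                 out_dir = out_dir, log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(cfg, ...) {
  if (cfg$log_level != "quiet") message(sprintf(...))
}

roi_region <- function(roi) sub("^(left|right) ", "", roi)
roi_hemisphere <- function(roi) sub(" .*$", "", roi)

#' Run the full two-track ERP analysis
#'
#' Simulates (or loads) epoched EEG per subject, preprocesses
#' (re-referencing to the mastoid mean where mastoid channels are present,
#' baseline correction, +/- threshold artifact rejection), computes the
#' conventional per-condition averages and the RIDE-reconstructed ERPs, then
#' extracts window amplitudes (midline electrodes and lateral ROIs) for each
#' track's N400 and P600 windows, fits the two repeated-measures ANOVA
#' designs per track and window, and runs planned pairwise comparisons.
#' Writes tidy CSV tables plus a machine-readable manifest when `out_dir`
#' is set. Identical config and seed give identical outputs.
#'
#' @param cfg a [pipeline_config].
#' @return an object of class `erp_pipeline`: list with `evokeds` (per
#'   subject/track/condition), `grand` (grand averages), `amplitudes`
#'   (long table), `anova` (per track/window/design), `pairwise`,
#'   `topographies`, `ride_diagnostics`, `log` and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "setup"
  out <- tryCatch(
    run_pipeline_stages(cfg, function(s) stage <<- s),
    error = function(e) {
      if (!is.null(cfg$out_dir)) {
        fdir <- file.path(cfg$out_dir, "failed")
        dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
        existing <- list.files(cfg$out_dir, full.names = TRUE,
                               pattern = "\\.(csv|json)$")
        file.rename(existing, file.path(fdir, basename(existing)))
      }
      stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
           call. = FALSE)
    })
  out
}

run_pipeline_stages <- function(cfg, set_stage) {
  lay <- cfg$layout
  midline <- lay$midline
  rois <- lay$rois
  tracks <- names(cfg$windows)
  n_sub <- if (cfg$source == "simulate") cfg$sim$n_subjects
           else length(cfg$files)
  ids <- sprintf("S%02d", seq_len(n_sub))
  evokeds <- list(); diag <- list(); log <- list()
  amp_rows <- list()
  for (si in seq_len(n_sub)) {
    set_stage("load")
    id <- ids[si]
    if (cfg$source == "simulate") {
      x <- simulate_subject(cfg$sim, id, subject_seed(cfg$seed, si))$epochs
    } else {
      x <- read_epochs(cfg$files[si], "tsv")
      x$subject_id <- id
    }
    set_stage("preprocess")
    if (all(lay$mastoids %in% x$montage)) x <- rereference(x, lay$mastoids)
    x <- baseline_correct(x, c(min(x$times), 0))
    rej <- reject_artifacts(x, cfg$reject_threshold)
    x <- rej$epochs
    log[[id]] <- list(
      n_rejected = sum(rej$rejected),
      trials_per_condition = as.list(table(x$conditions)))
    pipe_log(cfg, "%s: %d trial(s) rejected; %s", id, sum(rej$rejected),
             paste(sprintf("%s=%d", names(table(x$conditions)),
                           table(x$conditions)), collapse = " "))
    for (cond in intersect(CONDITIONS, unique(x$conditions))) {
      set_stage("erp")
      conv <- average_evoked(x, cond)
      set_stage("ride")
      fit <- ride(x, cfg$ride, condition = cond)
      rec <- fit$reconstructed
      evokeds[[id]][["conventional"]][[cond]] <- conv
      evokeds[[id]][["reconstructed"]][[cond]] <- rec
      diag[[length(diag) + 1L]] <- data.frame(
        subject = id, condition = cond, n_trials = conv$n_trials,
        n_iterations = fit$n_iterations, converged = fit$converged,
        residual_rms = utils::tail(fit$residual_rms, 1),
        stringsAsFactors = FALSE)
      set_stage("window_amplitudes")
      for (track in tracks) {
        e <- if (track == "conventional") conv else rec
        for (wname in names(cfg$windows[[track]])) {
          win <- cfg$windows[[track]][[wname]]
          wm_mid <- window_mean(e, win, midline)
          wm_mid$design <- "midline"
          wm_roi <- window_mean(e, win, rois)
          wm_roi$design <- "lateral"
          wm <- rbind(wm_mid, wm_roi)
          wm$track <- track; wm$window <- wname
          amp_rows[[length(amp_rows) + 1L]] <- wm
        }
      }
    }
  }
  amplitudes <- do.call(rbind, amp_rows)
  names(amplitudes)[names(amplitudes) == "subject_id"] <- "subject"
  set_stage("grand_average")
  grand <- list()
  for (track in tracks) for (cond in CONDITIONS) {
    es <- lapply(evokeds, function(s) s[[track]][[cond]])
    es <- es[!vapply(es, is.null, TRUE)]
    if (length(es)) grand[[track]][[cond]] <- grand_average(es)
  }
  set_stage("topography")
  topo <- list()
  pair_defs <- list(c("SEM", "CON"), c("SEM+SYN", "CON"), c("SEM+SYN", "SEM"))
  for (track in tracks) for (wname in names(cfg$windows[[track]])) {
    win <- cfg$windows[[track]][[wname]]
    for (p in pair_defs) {
      key <- paste0(track, ".", wname, ".", p[1], "-", p[2])
      topo[[key]] <- difference_topography(grand[[track]][[p[1]]],
                                           grand[[track]][[p[2]]], win)
    }
  }
  set_stage("stats")
  anova_tabs <- list(); pairwise_tabs <- list()
  if (n_sub < 2) {
    pipe_log(cfg, "fewer than 2 subjects: ANOVA/pairwise stages skipped")
    tracks_stats <- character(0)
  } else tracks_stats <- tracks
  for (track in tracks_stats) for (wname in names(cfg$windows[[track]])) {
    sel <- amplitudes$track == track & amplitudes$window == wname
    mid <- amplitudes[sel & amplitudes$design == "midline", ]
    lat <- amplitudes[sel & amplitudes$design == "lateral", ]
    lat$region <- roi_region(lat$unit)
    lat$hemisphere <- roi_hemisphere(lat$unit)
    key <- paste0(track, ".", wname)
    anova_tabs[[paste0(key, ".midline")]] <- rm_anova(
      mid, dv = "mean_amplitude", within = c("condition", "unit"))
    anova_tabs[[paste0(key, ".lateral")]] <- rm_anova(
      lat, dv = "mean_amplitude",
      within = c("condition", "region", "hemisphere"))
    pairwise_tabs[[key]] <- planned_pairwise(
      rbind(mid, lat[names(mid)]), dv = "mean_amplitude")
  }
  res <- structure(
    list(evokeds = evokeds, grand = grand, amplitudes = amplitudes,
         anova = anova_tabs, pairwise = pairwise_tabs, topographies = topo,
         ride_diagnostics = do.call(rbind, diag), log = log, config = cfg),
    class = "erp_pipeline")
  if (!is.null(cfg$out_dir)) {
    set_stage("export")
    write_pipeline_outputs(res, cfg$out_dir)
  }
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$amplitudes, file.path(dir, "window_amplitudes.csv"),
            row.names = FALSE)
  av <- do.call(rbind, lapply(names(res$anova), function(k) {
    d <- as.data.frame(res$anova[[k]])
    cbind(analysis = k, d)
  }))
  write.csv(av, file.path(dir, "anova_tables.csv"), row.names = FALSE)
  pw <- do.call(rbind, lapply(names(res$pairwise), function(k)
    cbind(analysis = k, res$pairwise[[k]])))
  write.csv(pw, file.path(dir, "pairwise_tables.csv"), row.names = FALSE)
  tp <- do.call(rbind, lapply(names(res$topographies), function(k)
    cbind(map = k, res$topographies[[k]])))
  write.csv(tp, file.path(dir, "difference_topographies.csv"),
            row.names = FALSE)
  write.csv(res$ride_diagnostics, file.path(dir, "ride_diagnostics.csv"),
            row.names = FALSE)
  for (id in names(res$evokeds)) {
    for (track in names(res$evokeds[[id]])) {
      rows <- list()
      for (cond in names(res$evokeds[[id]][[track]])) {
        e <- res$evokeds[[id]][[track]][[cond]]
        m <- as.data.frame(e$data)
        names(m) <- paste0("t", format(e$times, trim = TRUE,
                                       scientific = FALSE))
        rows[[cond]] <- cbind(condition = cond, channel = e$montage,
                              n_trials = e$n_trials, m)
      }
      write.csv(do.call(rbind, rows),
                file.path(dir, sprintf("evoked_%s_%s.csv", id, track)),
                row.names = FALSE)
    }
  }
  manifest <- list(
    package = "erpride",
    version = as.character(packageVersion("erpride")),
    seed = res$config$seed,
    source = res$config$source,
    windows = res$config$windows,
    reject_threshold = res$config$reject_threshold,
    n_subjects = length(res$evokeds),
    sim = if (!is.null(res$config$sim))
      res$config$sim[c("n_subjects", "trials_per_condition", "fs", "window",
                       "noise_sd", "noise_model", "ar_rho", "seed",
                       "contaminate")],
    log = res$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.erp_pipeline <- function(x, ...) {
  cat("<erp_pipeline>", length(x$evokeds), "subject(s), seed",
      x$config$seed, "\n")
  cat("ANOVA condition effects (midline):\n")
  for (k in grep("midline", names(x$anova), value = TRUE)) {
    tb <- x$anova[[k]]
    i <- tb$effect == "condition"
    cat(sprintf("  %-28s F(%g, %g) = %6.2f, p_gg = %.4g, pes = %.3f\n",
                k, tb$df_num[i], tb$df_den[i], tb$F[i], tb$p_gg[i],
                tb$partial_eta2[i]))
  }
  invisible(x)
}
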