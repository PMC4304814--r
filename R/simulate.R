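# Approximate schematic 2-D positions of the 38-site montage (x: left -1 ..
# right +1; y: posterior -1 .. anterior +1), used only to derive smooth scalp
# weight maps for simulated components. Mastoids/EOG sit outside the scalp
# grid and always get weight 0.
channel_positions <- function() {
  p <- rbind(
    FP1 = c(-0.30, 0.90), FPz = c(0.00, 0.95), FP2 = c(0.30, 0.90),
    AF7 = c(-0.55, 0.80), AF3 = c(-0.25, 0.78), AF4 = c(0.25, 0.78),
    AF8 = c(0.55, 0.80),
    F7 = c(-0.75, 0.55), F3 = c(-0.40, 0.55), Fz = c(0.00, 0.55),
    F4 = c(0.40, 0.55), F8 = c(0.75, 0.55),
    FT7 = c(-0.85, 0.30), FC3 = c(-0.42, 0.30), FCz = c(0.00, 0.30),
    FC4 = c(0.42, 0.30), FT8 = c(0.85, 0.30),
    T7 = c(-0.95, 0.00), C3 = c(-0.45, 0.00), Cz = c(0.00, 0.00),
    C4 = c(0.45, 0.00), T8 = c(0.95, 0.00),
    TP7 = c(-0.85, -0.30), CP3 = c(-0.42, -0.30), CPz = c(0.00, -0.30),
    CP4 = c(0.42, -0.30), TP8 = c(0.85, -0.30),
    P7 = c(-0.75, -0.55), P3 = c(-0.40, -0.55), Pz = c(0.00, -0.55),
    P4 = c(0.40, -0.55), P8 = c(0.75, -0.55),
    PO7 = c(-0.55, -0.80), PO5 = c(-0.35, -0.78), POz = c(0.00, -0.78),
    PO6 = c(0.35, -0.78), PO8 = c(0.55, -0.80),
    Oz = c(0.00, -0.95))
  colnames(p) <- c("x", "y")
  p
}

#' Smooth scalp weight map for a simulated component
#'
#' Gaussian fall-off of per-channel gain around a scalp center, on a schematic
#' 2-D layout of the 38-site montage. Channels not on the scalp grid
#' (mastoids, EOG) get weight 0.
#'
#' @param center c(x, y) on the schematic layout (x: left -1 .. right +1;
#'   y: posterior -1 .. anterior +1).
#' @param spread Gaussian spatial SD in layout units.
#' @param montage channel labels the map is evaluated for.
#' @return named numeric vector of weights in `[0, 1]`.
#' @export
scalp_weights <- function(center = c(0, -0.35), spread = 0.9,
                          montage = default_montage()) {
  pos <- channel_positions()
  w <- setNames(numeric(length(montage)), montage)
  on_grid <- montage %in% rownames(pos)
  d2 <- rowSums(sweep(pos[montage[on_grid], , drop = FALSE], 2, center)^2)
  w[on_grid] <- exp(-d2 / (2 * spread^2))
  w
}

#' Specification of one simulated ERP component cluster
#'
#' @param name cluster name: `"S"` (stimulus-locked), `"C1"` (N400-like) or
#'   `"C2"` (P600-like).
#' @param shape waveform family, `"gaussian"` or `"halfcosine"`.
#' @param center peak time mu in ms.
#' @param width temporal width w in ms (Gaussian SD, or half-cosine
#'   half-width); must be > 0.
#' @param scalp_weights named per-channel gain in `[-1, 1]` (see
#'   [scalp_weights()]).
#' @param amplitude named numeric: signed peak amplitude in muV per condition
#'   (sign carries polarity).
#' @param latency_sd trial-to-trial latency SD in ms (0 for S).
#' @param latency_shift named numeric: condition-specific mean latency shift
#'   in ms (default 0).
#' @param amplitude_subject_sd SD (muV) of a per-subject additive amplitude
#'   offset, shared across that subject's conditions and trials.
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(name, shape = c("gaussian", "halfcosine"),
                           center, width, scalp_weights, amplitude,
                           latency_sd = 0, latency_shift = NULL,
                           amplitude_subject_sd = 0) {
  shape <- match.arg(shape)
  if (width <= 0) stop("component width must be > 0", call. = FALSE)
  if (latency_sd < 0) stop("latency_sd must be >= 0", call. = FALSE)
  if (name == "S" && latency_sd != 0)
    stop("the stimulus-locked cluster S must have latency_sd = 0", call. = FALSE)
  if (is.null(latency_shift))
    latency_shift <- setNames(rep(0, length(amplitude)), names(amplitude))
  structure(list(name = name, shape = shape, center = center, width = width,
                 scalp_weights = scalp_weights, amplitude = amplitude,
                 latency_sd = latency_sd, latency_shift = latency_shift,
                 amplitude_subject_sd = amplitude_subject_sd),
            class = "component_spec")
}

component_shape <- function(spec, times, latency = 0) {
  t0 <- spec$center + latency
  switch(spec$shape,
    gaussian = exp(-(times - t0)^2 / (2 * spec$width^2)),
    halfcosine = {
      v <- cos(pi * (times - t0) / (2 * spec$width))
      v[abs(times - t0) > spec$width] <- 0
      v
    })
}

#' Channel x time waveform of a component at its nominal latency
#'
#' Deterministic single-trial waveform of one component: unit temporal shape
#' peaking at `center`, scaled by the per-channel scalp weights and the
#' condition's amplitude.
#'
#' @param spec a [component_spec].
#' @param times ms axis; `center` must lie inside it.
#' @param condition condition whose amplitude is used (default: first).
#' @return channel x time numeric matrix (muV).
#' @export
component_waveform <- function(spec, times,
                               condition = names(spec$amplitude)[1]) {
  if (spec$center < min(times) || spec$center > max(times))
    stop("component center must lie inside the epoch window", call. = FALSE)
  amp <- spec$amplitude[[condition]]
  outer(spec$scalp_weights * amp, component_shape(spec, times))
}

#' Expected peak attenuation of an averaged jittered Gaussian component
#'
#' A Gaussian bump of temporal width `w` whose single-trial latency varies
#' with SD `sigma` across trials averages to a wider, lower bump; the peak
#' retains the fraction `w / sqrt(w^2 + sigma^2)`. This is the smearing that
#' latency-compensated reconstruction is designed to undo.
#'
#' @param w Gaussian temporal SD in ms (> 0).
#' @param sigma latency SD in ms (>= 0).
#' @return attenuation fraction in (0, 1].
#' @export
smearing_factor <- function(w, sigma) {
  if (w <= 0) stop("`w` must be > 0", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  w / sqrt(w^2 + sigma^2)
}

#' Simulation configuration
#'
#' Describes a full synthetic study: subjects, trials, epoch geometry,
#' component clusters and the noise model. The default scenario mirrors a
#' three-condition sentence-violation design: a stimulus-locked early
#' cluster, an N400-like negative cluster (equal in `SEM` and `SEM+SYN`,
#' absent in `CON`) and a P600-like positive cluster ordered
#' `SEM+SYN > SEM > CON`, with centro-parietal topographies.
#'
#' @param n_subjects number of subjects (default 18).
#' @param trials_per_condition trials per condition per subject (default 40).
#' @param fs sampling rate Hz (default 500).
#' @param window epoch window ms, half-open on the right (default -200..1000).
#' @param components list of [component_spec]; default [default_components()].
#' @param noise_sd single-trial noise SD in muV.
#' @param noise_model `"ar1"` (temporally correlated, default) or `"white"`.
#' @param ar_rho AR(1) coefficient for `noise_model = "ar1"`.
#' @param seed integer seed; mandatory, echoed into all outputs.
#' @param include_mastoids add `M1`/`M2` channels (noise only) so mastoid
#'   re-referencing can be exercised.
#' @param contaminate number of trials per subject to contaminate with a
#'   large-amplitude spike (for artifact-rejection tests); 0 by default.
#' @param contaminate_amplitude spike amplitude in muV.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 18, trials_per_condition = 40, fs = 500,
                       window = c(-200, 1000),
                       components = default_components(),
                       noise_sd = 8, noise_model = c("ar1", "white"),
                       ar_rho = 0.95, seed, include_mastoids = TRUE,
                       contaminate = 0, contaminate_amplitude = 120) {
  noise_model <- match.arg(noise_model)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (trials_per_condition < 1) stop("trials_per_condition must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 trials_per_condition = trials_per_condition, fs = fs,
                 window = window, components = components,
                 noise_sd = noise_sd, noise_model = noise_model,
                 ar_rho = ar_rho, seed = as.integer(seed),
                 include_mastoids = include_mastoids,
                 contaminate = contaminate,
                 contaminate_amplitude = contaminate_amplitude),
            class = "sim_config")
}

#' Default three-cluster component scenario
#'
#' S: early fronto-central positive bump (stimulus-locked). C1: N400-like
#' centro-parietal negativity at ~400 ms, equal in the two violation
#' conditions and absent in the congruent one. C2: P600-like centro-parietal
#' positivity at ~650 ms, ordered `SEM+SYN > SEM > CON`. C1/C2 latencies
#' jitter from trial to trial with SD `latency_sd`.
#'
#' @param latency_sd trial-to-trial latency SD in ms for C1 and C2.
#' @param c1_amp,c2_amp named amplitude vectors (muV) overriding the defaults.
#' @param montage channel labels.
#' @return list of three [component_spec] objects.
#' @export
default_components <- function(latency_sd = 40,
                               c1_amp = c(CON = 0, SEM = -3, `SEM+SYN` = -3),
                               c2_amp = c(CON = 0.5, SEM = 2.5, `SEM+SYN` = 4),
                               montage = default_montage()) {
  list(
    component_spec("S", "gaussian", center = 170, width = 30,
                   scalp_weights = scalp_weights(c(0, 0.3), 0.8, montage),
                   amplitude = c(CON = 4, SEM = 4, `SEM+SYN` = 4),
                   latency_sd = 0, amplitude_subject_sd = 1),
    component_spec("C1", "gaussian", center = 400, width = 50,
                   scalp_weights = scalp_weights(c(0, -0.3), 0.9, montage),
                   amplitude = c1_amp, latency_sd = latency_sd,
                   amplitude_subject_sd = 1),
    component_spec("C2", "gaussian", center = 650, width = 80,
                   scalp_weights = scalp_weights(c(0, -0.45), 0.9, montage),
                   amplitude = c2_amp, latency_sd = latency_sd,
                   amplitude_subject_sd = 1))
}

# Truncated-Gaussian latency draw: redraw until within +/- 3 SD of the mean
# shift, so components stay inside the epoch.
draw_latency <- function(mean_shift, sd) {
  if (sd == 0) return(mean_shift)
  repeat {
    l <- rnorm(1, mean_shift, sd)
    if (abs(l - mean_shift) <= 3 * sd) return(l)
  }
}

ar1_noise <- function(n_series, n_samp, sd, rho) {
  if (sd == 0) return(matrix(0, n_series, n_samp))
  burn <- 100L
  innov <- matrix(rnorm(n_series * (n_samp + burn)), n_samp + burn, n_series)
  out <- stats::filter(innov, rho, method = "recursive")
  t(out[(burn + 1L):(burn + n_samp), , drop = FALSE]) * (sd * sqrt(1 - rho^2))
}

#' Simulate one subject's single-trial epochs
#'
#' Each trial is the sum of the configured component clusters — each scaled by
#' its condition amplitude (plus the subject's amplitude offset) and shifted
#' by a latency drawn from a truncated Gaussian — plus AR(1) or white noise.
#' Trial order is randomized across conditions.
#'
#' @param cfg a [sim_config].
#' @param subject_id subject label.
#' @param seed integer seed for this subject's draws.
#' @return list with `epochs` ([eeg_epochs]) and `ground_truth` (data.frame:
#'   trial, condition, component, latency_ms, amplitude; attribute
#'   `contaminated` lists contaminated trial indices).
#' @export
simulate_subject <- function(cfg, subject_id = "S01", seed = cfg$seed) {
  set.seed(seed)
  fs <- cfg$fs
  n_samp <- ms_to_samples(cfg$window[2] - cfg$window[1], fs)
  times <- cfg$window[1] + (seq_len(n_samp) - 1L) * 1000 / fs
  montage <- names(cfg$components[[1]]$scalp_weights)
  if (cfg$include_mastoids) montage_full <- c(montage, "M1", "M2")
  else montage_full <- montage
  conds <- rep(CONDITIONS, each = cfg$trials_per_condition)
  conds <- sample(conds)
  nt <- length(conds)
  nc <- length(montage_full)
  data <- array(0, c(nt, nc, n_samp))
  gt <- vector("list", nt)
  subj_offsets <- vapply(cfg$components,
                         function(cp) rnorm(1, 0, cp$amplitude_subject_sd), 0)
  for (i in seq_len(nt)) {
    cond <- conds[i]
    rows <- lapply(seq_along(cfg$components), function(k) {
      cp <- cfg$components[[k]]
      lat <- draw_latency(cp$latency_shift[[cond]] %||% 0, cp$latency_sd)
      amp <- cp$amplitude[[cond]]
      if (amp != 0) amp <- amp + subj_offsets[k]
      data.frame(trial = i, condition = cond, component = cp$name,
                 latency_ms = lat, amplitude = amp,
                 stringsAsFactors = FALSE)
    })
    gt[[i]] <- do.call(rbind, rows)
    for (k in seq_along(cfg$components)) {
      cp <- cfg$components[[k]]
      r <- gt[[i]][k, ]
      if (r$amplitude == 0) next
      wave <- outer(cp$scalp_weights * r$amplitude,
                    component_shape(cp, times, r$latency_ms))
      data[i, seq_along(montage), ] <- data[i, seq_along(montage), ] + wave
    }
  }
  noise <- ar1_noise(nt * nc, n_samp, cfg$noise_sd,
                     if (cfg$noise_model == "ar1") cfg$ar_rho else 0)
  data <- data + aperm(array(t(noise), c(n_samp, nt, nc)), c(2, 3, 1))
  contaminated <- integer()
  if (cfg$contaminate > 0) {
    contaminated <- sort(sample(nt, min(cfg$contaminate, nt)))
    post <- which(times >= 0)
    for (i in contaminated) {
      ch <- sample(seq_along(montage), 1)
      s <- sample(post, 1)
      data[i, ch, s] <- data[i, ch, s] +
        sign(rnorm(1)) * cfg$contaminate_amplitude
    }
  }
  gt <- do.call(rbind, gt)
  gt$subject <- subject_id
  attr(gt, "contaminated") <- contaminated
  attr(gt, "seed") <- seed
  x <- eeg_epochs(data, times, conds, fs, subject_id, montage_full)
  x <- baseline_correct(x, c(cfg$window[1], 0))
  list(epochs = x, ground_truth = gt)
}

#' Simulate a full multi-subject study
#'
#' Runs [simulate_subject()] once per subject with per-subject seeds derived
#' from `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return list with `epochs` (list of [eeg_epochs], one per subject) and
#'   `ground_truth` (row-bound per-trial draws; attributes `seed` and
#'   `contaminated` per subject are kept on the per-subject pieces).
#' @export
simulate_trials <- function(cfg) {
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  res <- lapply(seq_along(ids), function(i)
    simulate_subject(cfg, ids[i], seed = subject_seed(cfg$seed, i)))
  list(epochs = setNames(lapply(res, `[[`, "epochs"), ids),
       ground_truth = setNames(lapply(res, `[[`, "ground_truth"), ids),
       seed = cfg$seed)
}

# Per-subject substream seed, kept within 32-bit integer range.
subject_seed <- function(seed, i) as.integer((seed + 7919 * i) %% .Machine$integer.max)
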