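# Small synthetic builders shared across tests. All randomness is seeded at
# the call site.

tiny_epochs <- function(n_trials = 6, n_channels = 4, n_times = 50, fs = 500,
                        conditions = NULL, data = NULL,
                        montage = paste0("ch", seq_len(n_channels))) {
  times <- -20 + (seq_len(n_times) - 1L) * 1000 / fs
  if (is.null(conditions))
    conditions <- rep(c("CON", "SEM", "SEM+SYN"), length.out = n_trials)
  if (is.null(data)) data <- array(0, c(n_trials, n_channels, n_times))
  eeg_epochs(data, times, conditions, fs, "S01", montage)
}

# three-cluster scenario with controlled amplitudes and no subject-level
# amplitude variability, for recovery checks against exact ground truth
controlled_components <- function(latency_sd = 40,
                                  c1_amp = c(CON = 0, SEM = -3,
                                             `SEM+SYN` = -3),
                                  c2_amp = c(CON = 0.5, SEM = 2.5,
                                             `SEM+SYN` = 4),
                                  montage = default_montage()) {
  list(
    component_spec("S", "gaussian", 170, 30,
                   scalp_weights(c(0, 0.3), 0.8, montage),
                   c(CON = 4, SEM = 4, `SEM+SYN` = 4), 0),
    component_spec("C1", "gaussian", 400, 50,
                   scalp_weights(c(0, -0.3), 0.9, montage),
                   c1_amp, latency_sd),
    component_spec("C2", "gaussian", 650, 80,
                   scalp_weights(c(0, -0.45), 0.9, montage),
                   c2_amp, latency_sd))
}

# balanced long table with known structure for ANOVA tests
random_long_table <- function(n_subjects, levels_list, sd = 1) {
  g <- do.call(expand.grid, c(list(subject = sprintf("S%02d", seq_len(n_subjects))),
                              levels_list,
                              stringsAsFactors = FALSE))
  g$amplitude <- rnorm(nrow(g), 0, sd)
  g
}
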