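# Independent oracles, deliberately written by direct summation /
# enumeration so they share no code path with the package.

# Brute-force fully-within-subjects ANOVA: sums of squares by explicit
# inclusion-exclusion over cell means; every effect tested against its own
# effect-by-subject interaction.
oracle_rm_anova <- function(data, dv = "amplitude", within = "condition",
                            subject = "subject") {
  data <- as.data.frame(data)
  for (f in c(subject, within)) data[[f]] <- factor(data[[f]])
  y <- data[[dv]]
  grand <- mean(y)
  n_obs <- nrow(data)
  # inclusion-exclusion effect estimate for a subset of factors, evaluated
  # per observation
  subsets <- function(v) {
    out <- list()
    for (m in seq_along(v)) out <- c(out, combn(v, m, simplify = FALSE))
    out
  }
  # per-observation estimate of the pure |facs|-way effect by
  # inclusion-exclusion over marginal means
  cell_dev <- function(facs) {
    est <- rep(0, n_obs)
    for (k in 0:length(facs)) {
      sign <- (-1)^(length(facs) - k)
      if (k == 0) { est <- est + sign * grand; next }
      subs <- combn(facs, k, simplify = FALSE)
      for (sub in subs) {
        means <- tapply(y, data[sub], mean)
        idx <- do.call(cbind, lapply(sub, function(f) as.integer(data[[f]])))
        est <- est + sign * means[idx]
      }
    }
    est
  }
  effs <- subsets(within)
  rows <- lapply(effs, function(facs) {
    eff_name <- paste(facs, collapse = ":")
    dev_e <- cell_dev(facs)
    # dev is constant within each unique cell; summing per observation
    # multiplies each squared deviation by its replication count, which is
    # exactly the balanced-design SS
    ss_e <- sum(dev_e^2)
    dev_err <- cell_dev(c(facs, subject))   # effect x subject interaction
    ss_err <- sum(dev_err^2)
    df_num <- prod(vapply(facs, function(f) nlevels(data[[f]]) - 1L, 0L))
    df_den <- df_num * (nlevels(data[[subject]]) - 1L)
    F <- (ss_e / df_num) / (ss_err / df_den)
    data.frame(effect = eff_name, df_num = df_num, df_den = df_den,
               ss_effect = ss_e, ss_error = ss_err, F = F,
               p = pf(F, df_num, df_den, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# GG epsilon by explicit eigen-decomposition in an independently constructed
# (polynomial) orthonormal contrast basis; epsilon is basis-invariant.
oracle_gg_epsilon <- function(Y) {
  k <- ncol(Y)
  M <- stats::contr.poly(k)          # k x (k-1), orthonormal by construction
  S <- cov(Y %*% M)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  max(min(sum(lam)^2 / ((k - 1) * sum(lam^2)), 1), 1 / (k - 1))
}

# Peak attenuation of a jittered bump by direct numeric convolution of the
# bump with the latency density.
oracle_smearing <- function(w, sigma, span = 2000, dt = 0.1) {
  t <- seq(-span, span, by = dt)
  bump <- exp(-t^2 / (2 * w^2))
  if (sigma == 0) return(1)
  dens <- dnorm(t, 0, sigma)
  smeared <- convolve(bump, rev(dens), type = "open") * dt
  max(smeared)
}
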