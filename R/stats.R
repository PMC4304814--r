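orthonormal_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))  # k x (k-1), orthonormal, sum-to-zero
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor for a k-level within-subject
#' factor: `eps = (sum lambda)^2 / ((k - 1) * sum lambda^2)` over the
#' eigenvalues `lambda` of the covariance matrix of the orthonormal contrast
#' scores, clipped to `[1/(k-1), 1]`.
#'
#' @param cell_matrix numeric matrix, subject x level.
#' @return epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(cell_matrix) {
  cell_matrix <- as.matrix(cell_matrix)
  k <- ncol(cell_matrix)
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  gg_epsilon_contrast(cell_matrix, orthonormal_contrasts(k))
}

gg_epsilon_contrast <- function(Y, M) {
  # M: cells x d orthonormal contrast basis of the effect space
  S <- stats::cov(Y %*% M)
  d <- ncol(M)
  lambda <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  if (sum(lambda) <= 0) return(1)
  eps <- sum(lambda)^2 / (d * sum(lambda^2))
  min(max(eps, 1 / d), 1)
}

#' Partial eta squared
#'
#' Effect size for within-subject ANOVA effects:
#' `ss_effect / (ss_effect + ss_error)`.
#'
#' @param ss_effect,ss_error sums of squares (>= 0, not both 0).
#' @return fraction in `[0, 1]`.
#' @export
partial_eta2 <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0) || any(ss_error < 0))
    stop("sums of squares must be >= 0", call. = FALSE)
  if (all(ss_effect + ss_error == 0))
    stop("ss_effect and ss_error cannot both be 0", call. = FALSE)
  ss_effect / (ss_effect + ss_error)
}

check_balanced <- function(data, subject, factors) {
  counts <- table(data[c(subject, factors)])
  if (all(counts == 1L)) return(invisible(TRUE))
  bad <- which(counts != 1L, arr.ind = TRUE)
  dn <- dimnames(counts)
  cells <- apply(bad, 1, function(r)
    paste(mapply(function(d, i) dn[[d]][i], seq_along(r), r), collapse = "/"))
  stop("unbalanced table; cells not observed exactly once: ",
       paste(utils::head(cells, 10), collapse = ", "),
       if (length(cells) > 10) " ...", call. = FALSE)
}

#' Fully-within-subjects repeated-measures ANOVA
#'
#' Standard within-subject partition for 1-3 within factors on a balanced
#' long table: each effect is tested against its own effect-by-subject
#' interaction stratum (via `stats::aov` with an `Error(subject/...)`
#' design). For every effect, the Greenhouse-Geisser epsilon is estimated
#' from the covariance of the effect's orthonormal contrast scores and a
#' corrected p-value is reported alongside the uncorrected one, together
#' with partial eta squared.
#'
#' @param data long-format data.frame, one row per subject x cell.
#' @param dv name of the amplitude (dependent variable) column.
#' @param within character vector (length 1-3) of within-subject factor
#'   columns.
#' @param subject name of the subject identifier column.
#' @return an object of class `anova_rm`: data.frame with columns effect,
#'   df_num, df_den, ss_effect, ss_error, F, p_uncorrected, gg_epsilon,
#'   p_gg, partial_eta2. Attribute `ss_subject` carries the subject-stratum
#'   sum of squares (for the total-SS partition).
#' @export
rm_anova <- function(data, dv = "amplitude", within = "condition",
                     subject = "subject") {
  if (length(within) < 1 || length(within) > 3)
    stop("1 to 3 within-subject factors supported", call. = FALSE)
  data <- as.data.frame(data)
  for (f in c(subject, within)) data[[f]] <- factor(data[[f]])
  check_balanced(data, subject, within)
  fml <- stats::as.formula(paste(
    dv, "~", paste(within, collapse = "*"),
    "+ Error(", subject, "/(", paste(within, collapse = "*"), "))"))
  fit <- aov(fml, data = data)
  sm <- summary(fit)
  rows <- list()
  ss_subject <- NA_real_
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1]]
    effs <- trimws(rownames(tab))
    resid_i <- which(effs == "Residuals")
    if (grepl(paste0("^Error: ", subject, "$"), stratum)) {
      ss_subject <- tab[resid_i, "Sum Sq"]
      next
    }
    for (i in setdiff(seq_along(effs), resid_i)) {
      rows[[effs[i]]] <- data.frame(
        effect = effs[i],
        df_num = tab[i, "Df"], df_den = tab[resid_i, "Df"],
        ss_effect = tab[i, "Sum Sq"], ss_error = tab[resid_i, "Sum Sq"],
        F = tab[i, "F value"], p_uncorrected = tab[i, "Pr(>F)"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # order effects: main effects first, then interactions, in `within` order
  key <- vapply(strsplit(out$effect, ":"), function(p)
    length(p) * 100 + min(match(p, within)), 0)
  out <- out[order(key), , drop = FALSE]
  out$gg_epsilon <- NA_real_
  for (i in seq_len(nrow(out))) {
    facs <- strsplit(out$effect[i], ":")[[1]]
    out$gg_epsilon[i] <- effect_epsilon(data, dv, subject, within, facs)
  }
  out$p_gg <- pf(out$F, out$gg_epsilon * out$df_num,
                 out$gg_epsilon * out$df_den, lower.tail = FALSE)
  out$partial_eta2 <- partial_eta2(out$ss_effect, out$ss_error)
  rownames(out) <- NULL
  attr(out, "ss_subject") <- ss_subject
  class(out) <- c("anova_rm", "data.frame")
  out
}

# GG epsilon for one effect: average the dv over factors not in the effect,
# then apply the Kronecker product of the factors' orthonormal contrasts.
effect_epsilon <- function(data, dv, subject, within, facs) {
  ks <- vapply(facs, function(f) nlevels(data[[f]]), 0L)
  if (prod(ks - 1L) == 1L) return(1)  # 1 numerator df: no correction
  agg <- stats::aggregate(data[[dv]],
                          by = data[c(subject, facs)], FUN = mean)
  agg <- agg[do.call(order, agg[c(facs, subject)]), ]
  n <- nlevels(data[[subject]])
  Y <- matrix(agg$x, nrow = n)  # subject x cells, cells vary slowest on facs[last]
  # cells are ordered with the last factor varying fastest, matching the
  # row order of the Kronecker product taken in factor order
  M <- Reduce(`%x%`, lapply(facs,
                            function(f) orthonormal_contrasts(nlevels(data[[f]]))))
  gg_epsilon_contrast(Y, M)
}

#' @export
print.anova_rm <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subjects, Greenhouse-Geisser corrected)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$gg_epsilon <- round(df$gg_epsilon, 3)
  df$partial_eta2 <- round(df$partial_eta2, 3)
  df$p_uncorrected <- signif(df$p_uncorrected, 3)
  df$p_gg <- signif(df$p_gg, 3)
  print(df[c("effect", "df_num", "df_den", "F", "p_uncorrected",
             "gg_epsilon", "p_gg", "partial_eta2")], row.names = FALSE)
  invisible(x)
}

#' Planned pairwise comparisons
#'
#' Paired two-sided t-tests for every condition pair, separately per unit
#' (electrode or ROI). Uncorrected p-values by default; Holm adjustment
#' (across the pairs within each unit) optional. Pairs with zero
#' within-pair variance are flagged as degenerate.
#'
#' @param data long-format data.frame (subject x condition x unit rows).
#' @param dv,condition,unit,subject column names.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame: unit, a, b, mean_diff, t, df, p, degenerate.
#' @export
planned_pairwise <- function(data, dv = "amplitude", condition = "condition",
                             unit = "unit", subject = "subject",
                             adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  data <- as.data.frame(data)
  if (!unit %in% names(data)) { data[[unit]] <- "all"; }
  conds <- unique(as.character(data[[condition]]))
  if (length(conds) < 2) stop("need >= 2 conditions", call. = FALSE)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  rows <- list()
  for (u in unique(data[[unit]])) {
    du <- data[data[[unit]] == u, ]
    for (p in pairs) {
      a <- du[du[[condition]] == p[1], c(subject, dv)]
      b <- du[du[[condition]] == p[2], c(subject, dv)]
      m <- merge(a, b, by = subject)
      if (nrow(m) < 2) {
        warning("pair ", p[1], " vs ", p[2], " at ", u,
                " has < 2 subjects; skipped")
        next
      }
      d <- m[[paste0(dv, ".x")]] - m[[paste0(dv, ".y")]]
      degenerate <- FALSE
      if (sd(d) < 1e-12) {
        if (abs(mean(d)) < 1e-12) {       # identical columns: no difference
          tval <- 0; pval <- 1
        } else {                          # nonzero shift with zero variance
          degenerate <- TRUE
          tval <- NA_real_; pval <- NA_real_
        }
      } else {
        tt <- t.test(d)
        tval <- unname(tt$statistic); pval <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, a = p[1], b = p[2], mean_diff = mean(d),
        t = tval, df = nrow(m) - 1L, p = pval, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm")
    for (u in unique(out$unit)) {
      i <- out$unit == u
      out$p[i] <- stats::p.adjust(out$p[i], "holm")
    }
  rownames(out) <- NULL
  out
}

#' Simple main effects of condition within strata
#'
#' One-way repeated-measures ANOVA of condition run separately inside each
#' level of a stratifying factor (region, hemisphere or ROI), GG-corrected.
#'
#' @param data long-format data.frame.
#' @param dv,of,subject column names (`of` is the tested factor).
#' @param within_levels_of column whose levels define the strata.
#' @return named list of [rm_anova()] tables, one per stratum level.
#' @export
simple_effects <- function(data, dv = "amplitude", of = "condition",
                           within_levels_of = "unit", subject = "subject") {
  data <- as.data.frame(data)
  lv <- unique(as.character(data[[within_levels_of]]))
  setNames(lapply(lv, function(l)
    rm_anova(data[data[[within_levels_of]] == l, ], dv = dv,
             within = of, subject = subject)), lv)
}

#' Simulate null window-amplitude tables
#'
#' Generates balanced long tables (subject x condition x unit) with a random
#' subject intercept, fixed unit (electrode) effects, and independent
#' Gaussian noise, but no condition effect - the null model used to check
#' the type-I error calibration of the GG-corrected condition test.
#'
#' @param n_subjects subjects per table.
#' @param conditions condition labels.
#' @param n_units number of electrodes/ROIs.
#' @param sd_subject SD of the subject intercept (muV).
#' @param sd_noise residual SD (muV).
#' @return data.frame: subject, condition, unit, amplitude.
#' @export
simulate_null_table <- function(n_subjects = 18, conditions = CONDITIONS,
                                n_units = 8, sd_subject = 2, sd_noise = 1) {
  g <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   condition = conditions,
                   unit = sprintf("E%02d", seq_len(n_units)),
                   stringsAsFactors = FALSE)
  subj_int <- setNames(rnorm(n_subjects, 0, sd_subject),
                       sprintf("S%02d", seq_len(n_subjects)))
  unit_eff <- setNames(seq_len(n_units) * 0.3, sprintf("E%02d", seq_len(n_units)))
  g$amplitude <- subj_int[g$subject] + unit_eff[g$unit] +
    rnorm(nrow(g), 0, sd_noise)
  g
}
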