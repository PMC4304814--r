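test_that("gg_epsilon matches closed forms and the eigen oracle", {
  set.seed(1)
  n <- 40
  # compound symmetry (here: iid columns plus shared subject effect) -> eps 1
  # in expectation; use an exactly compound-symmetric population via large n
  # is stochastic, so instead construct data with exactly exchangeable
  # sample covariance: duplicate a column pattern
  z <- rnorm(n)
  Y <- cbind(z + rnorm(n), z + rnorm(n), z + rnorm(n))
  eps <- gg_epsilon(Y)
  expect_gte(eps, 0.5)
  expect_lte(eps, 1)
  expect_equal(eps, oracle_gg_epsilon(Y), tolerance = 1e-10)

  # exactly compound-symmetric sample covariance: contrast covariance is
  # proportional to identity when columns are an orthogonal rotation; build
  # Y whose sample covariance is I + c
  Y2 <- matrix(rnorm(n * 3), n, 3)
  Y2 <- scale(Y2, center = TRUE, scale = FALSE)
  # orthonormalize columns then equalize variances -> cov = s^2 I
  Q <- qr.Q(qr(Y2))
  expect_equal(gg_epsilon(Q), 1, tolerance = 1e-10)

  # rank-1 covariance, k = 3 -> lower bound 1/(k-1) = 0.5
  base <- rnorm(n)
  Y3 <- cbind(base, -base, base + 100)  # contrasts collapse to rank 1
  Y3 <- cbind(base, 2 * base, 3 * base)
  expect_equal(gg_epsilon(Y3), 0.5, tolerance = 1e-10)

  # fixed covariance fixture vs oracle in a different contrast basis
  set.seed(7)
  Y4 <- matrix(rnorm(25 * 4), 25, 4) %*% matrix(c(1, .8, .2, 0,
                                                  0, 1, .5, .1,
                                                  0, 0, 1, .7,
                                                  0, 0, 0, 1), 4, 4)
  expect_equal(gg_epsilon(Y4), oracle_gg_epsilon(Y4), tolerance = 1e-10)
  expect_error(gg_epsilon(Y4[, 1, drop = FALSE]), "2 levels")
})

test_that("partial_eta2 follows its definition and rejects bad input", {
  expect_equal(partial_eta2(3, 9), 0.25)
  expect_equal(partial_eta2(5, 0), 1)
  expect_equal(partial_eta2(0, 4), 0)
  expect_error(partial_eta2(-1, 2), ">= 0")
  expect_error(partial_eta2(0, 0), "both")
})

test_that("rm_anova matches the brute-force oracle on random designs", {
  set.seed(42)
  designs <- list(
    list(within = list(condition = c("CON", "SEM", "SEM+SYN"))),
    list(within = list(condition = c("CON", "SEM", "SEM+SYN"),
                       unit = sprintf("E%02d", 1:8))),
    list(within = list(condition = c("CON", "SEM", "SEM+SYN"),
                       region = c("anterior", "central", "posterior"),
                       hemisphere = c("left", "right"))))
  for (d in designs) {
    for (rep in 1:5) {
      tab <- random_long_table(18, d$within)
      got <- rm_anova(tab, within = names(d$within))
      exp <- oracle_rm_anova(tab, within = names(d$within))
      exp <- exp[match(got$effect, exp$effect), ]
      expect_equal(got$ss_effect, exp$ss_effect, tolerance = 1e-8)
      expect_equal(got$ss_error, exp$ss_error, tolerance = 1e-8)
      expect_equal(got$F, exp$F, tolerance = 1e-8)
      expect_equal(got$df_num, exp$df_num)
      expect_equal(got$df_den, exp$df_den)
      expect_equal(got$p_uncorrected, exp$p, tolerance = 1e-8)
      expect_true(all(got$gg_epsilon >= 1 / got$df_num - 1e-12))
      expect_true(all(got$gg_epsilon <= 1 + 1e-12))
    }
  }
})

test_that("two-level within factor reproduces the squared paired t", {
  set.seed(3)
  tab <- random_long_table(18, list(condition = c("A", "B")))
  got <- rm_anova(tab, within = "condition")
  a <- tab$amplitude[tab$condition == "A"][order(tab$subject[tab$condition == "A"])]
  b <- tab$amplitude[tab$condition == "B"][order(tab$subject[tab$condition == "B"])]
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p_uncorrected, tt$p.value, tolerance = 1e-10)
  expect_equal(got$gg_epsilon, 1)  # 1 numerator df
})

test_that("identical amplitudes give zero F and SS partition is conserved", {
  tab <- random_long_table(6, list(condition = c("CON", "SEM", "SEM+SYN"),
                                   unit = c("Fz", "Cz", "Pz")))
  tab$amplitude <- 5
  got <- rm_anova(tab, within = c("condition", "unit"))
  # every effect (and error) sum of squares vanishes; F is then a 0/0 form
  expect_lt(max(got$ss_effect), 1e-16)
  expect_lt(max(got$ss_error), 1e-16)

  set.seed(9)
  tab$amplitude <- rnorm(nrow(tab))
  got <- rm_anova(tab, within = c("condition", "unit"))
  total <- sum((tab$amplitude - mean(tab$amplitude))^2)
  parts <- sum(got$ss_effect) + sum(got$ss_error) + attr(got, "ss_subject")
  expect_equal(parts, total, tolerance = 1e-8)
})

test_that("permuting condition labels uniformly leaves other effects unchanged", {
  set.seed(11)
  tab <- random_long_table(10, list(condition = c("CON", "SEM", "SEM+SYN"),
                                    unit = c("Fz", "Cz", "Pz")))
  base <- rm_anova(tab, within = c("condition", "unit"))
  perm <- tab
  map <- c(CON = "SEM", SEM = "SEM+SYN", `SEM+SYN` = "CON")
  perm$condition <- map[perm$condition]
  per <- rm_anova(perm, within = c("condition", "unit"))
  expect_equal(per$F[per$effect == "unit"], base$F[base$effect == "unit"],
               tolerance = 1e-10)
  expect_equal(per$F[per$effect == "condition"],
               base$F[base$effect == "condition"], tolerance = 1e-10)
})

test_that("rm_anova rejects unbalanced tables, naming missing cells", {
  tab <- random_long_table(5, list(condition = c("A", "B")))
  tab <- tab[-1, ]
  expect_error(rm_anova(tab, within = "condition"), "unbalanced")
})

test_that("planned pairwise comparisons match the closed-form paired t", {
  set.seed(21)
  n <- 18
  subj <- sprintf("S%02d", 1:n)
  a <- rnorm(n, 0, 1)
  b <- a + 2 + rnorm(n, 0, 1)
  tab <- data.frame(subject = rep(subj, 2),
                    condition = rep(c("CON", "SEM"), each = n),
                    unit = "Pz", amplitude = c(a, b))
  got <- planned_pairwise(tab)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$df, n - 1L)
  expect_false(got$degenerate)

  # identical columns -> t = 0, p = 1
  tab2 <- tab; tab2$amplitude <- rep(a, 2)
  got2 <- planned_pairwise(tab2)
  expect_equal(got2$t, 0)
  expect_equal(got2$p, 1)

  # constant offset with zero within-pair variance -> degenerate flag
  tab3 <- tab; tab3$amplitude <- c(a, a + 1)
  got3 <- planned_pairwise(tab3)
  expect_true(got3$degenerate)
  expect_true(is.na(got3$t))
})

test_that("simple effects find a planted effect only where planted", {
  set.seed(31)
  units <- c("left posterior", "right posterior", "left anterior")
  tab <- random_long_table(18, list(condition = c("CON", "SEM", "SEM+SYN"),
                                    unit = units), sd = 1)
  sel <- tab$unit == "left posterior" & tab$condition == "SEM+SYN"
  tab$amplitude[sel] <- tab$amplitude[sel] + 3
  se <- simple_effects(tab)
  expect_named(se, units, ignore.order = TRUE)
  expect_lt(se[["left posterior"]]$p_gg, 0.05)
  expect_gt(se[["right posterior"]]$p_gg, 0.05)
  expect_gt(se[["left anterior"]]$p_gg, 0.05)
  # every simple-effect table passes the oracle
  for (u in units) {
    got <- se[[u]]
    exp <- oracle_rm_anova(tab[tab$unit == u, ])
    expect_equal(got$F, exp$F, tolerance = 1e-8)
  }
})
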