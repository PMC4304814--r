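test_that("waveform shifting is a zero-filled, non-circular shift", {
  w <- matrix(0, 2, 200)
  w[, 100] <- 1
  s <- shift_waveform(w, 10 * 2, fs = 500, taper_ms = 0)  # +10 samples
  expect_equal(which(s[1, ] == 1), 110)
  expect_equal(sum(s), 2)                     # nothing wrapped around
  expect_identical(shift_waveform(w, 0, 500), w)
  expect_error(shift_waveform(w, Inf, 500), "finite")
  expect_error(shift_waveform(w, 1000, 500), "epoch span")

  # shift(+d) then shift(-d) restores a bump away from the edges
  t <- seq_len(300)
  bump <- rbind(exp(-(t - 150)^2 / (2 * 10^2)))
  back <- shift_waveform(shift_waveform(bump, 40, 500), -40, 500)
  interior <- 60:240
  expect_equal(back[, interior], bump[, interior], tolerance = 1e-9)

  # vacated-edge taper ramps smoothly from zero
  s2 <- shift_waveform(matrix(1, 1, 100), 10 * 2, 500, taper_ms = 20)
  expect_equal(s2[1, 1:10], rep(0, 10))
  expect_lt(s2[1, 11], 0.1)
  expect_true(all(diff(s2[1, 11:20]) > 0))
})

test_that("Woody recovers constructed shifts exactly without noise", {
  fs <- 500
  times <- seq(-200, 998, by = 2)
  bump <- exp(-(times - 400)^2 / (2 * 50^2))
  shifts <- c(-40, 0, 40, -40, 0, 40)
  data <- array(0, c(6, 3, length(times)))
  for (i in seq_along(shifts)) {
    sh <- exp(-(times - 400 - shifts[i])^2 / (2 * 50^2))
    for (ch in 1:3) data[i, ch, ] <- sh
  }
  x <- eeg_epochs(data, times, rep("SEM", 6), fs, "S01",
                  c("Cz", "CPz", "Pz"))
  lat <- woody_latency(x, c(200, 600))
  expect_equal(lat, shifts, tolerance = 1e-9)
  expect_equal(median(lat), 0)

  # identical trials -> all latencies 0
  xid <- x
  for (i in 1:6) xid$data[i, , ] <- data[1, , ]
  expect_equal(woody_latency(xid, c(200, 600)), rep(0, 6))
  expect_error(woody_latency(subset_trials(x, 1), c(200, 600)), "2 trials")
  # flat trials warn and get latency 0
  xf <- x; xf$data[2, , ] <- 0
  expect_warning(latf <- woody_latency(xf, c(200, 600)), "flat")
  expect_equal(latf[2], 0)
})

test_that("decomposition attributes a pure stimulus-locked bump to S", {
  comps <- controlled_components(latency_sd = 0)
  cfg <- sim_config(n_subjects = 1, trials_per_condition = 10, seed = 31,
                    noise_sd = 0, include_mastoids = FALSE,
                    components = comps[1])        # S only
  x <- simulate_subject(cfg)$epochs
  n <- dim(x)[1]
  dec <- decompose_components(
    x, list(S = rep(0, n), C1 = rep(0, n), C2 = rep(0, n)))
  truth <- component_waveform(comps[[1]], x$times, "SEM")
  peak <- max(abs(truth))
  expect_lt(max(abs(dec$waves$S - truth)) / peak, 0.02)
  expect_lt(max(abs(dec$waves$C1)) / peak, 0.02)
  expect_lt(max(abs(dec$waves$C2)) / peak, 0.02)

  # all-zero data -> all-zero waveforms
  x0 <- x; x0$data[] <- 0
  dec0 <- decompose_components(
    x0, list(S = rep(0, n), C1 = rep(0, n), C2 = rep(0, n)))
  expect_equal(max(abs(unlist(dec0$waves))), 0)
})

test_that("decomposition recovers a jittered C1 against ground truth", {
  comps <- controlled_components(latency_sd = 50)[1:2]   # S + C1, no noise
  cfg <- sim_config(n_subjects = 1, trials_per_condition = 60, seed = 33,
                    noise_sd = 0, include_mastoids = FALSE,
                    components = comps)
  sim <- simulate_subject(cfg)
  x <- subset_trials(sim$epochs, sim$epochs$conditions == "SEM")
  gt <- sim$ground_truth
  lat_true <- gt$latency_ms[gt$condition == "SEM" & gt$component == "C1"]
  lat_true <- lat_true - median(lat_true)
  n <- dim(x)[1]
  dec <- decompose_components(
    x, list(S = rep(0, n), C1 = lat_true, C2 = rep(0, n)))
  truth <- component_waveform(comps[[2]], x$times, "SEM")
  win <- x$times >= 250 & x$times <= 550
  expect_gt(cor(dec$waves$C1["CPz", win], truth["CPz", win]), 0.99)
})

test_that("latency updates are a fixed point at the truth and find offsets", {
  fs <- 500
  times <- seq(-200, 998, by = 2)
  m <- c("Cz", "CPz", "Pz")
  s_wave <- outer(rep(1, 3), 4 * exp(-(times - 170)^2 / (2 * 30^2)))
  c1_wave <- outer(rep(1, 3), -3 * exp(-(times - 400)^2 / (2 * 50^2)))
  c2_wave <- outer(rep(1, 3), 2 * exp(-(times - 650)^2 / (2 * 80^2)))
  set.seed(71)
  truth <- as.numeric(sample(seq(-40, 40, 2), 12, replace = TRUE))
  truth <- truth - round(median(truth) / 2) * 2
  data <- array(0, c(12, 3, length(times)))
  for (i in 1:12)
    data[i, , ] <- s_wave +
      erpride:::shift_samples(c1_wave, as.integer(truth[i] / 2)) + c2_wave
  x <- eeg_epochs(data, times, rep("SEM", 12), fs, "S01", m)
  waves <- list(S = s_wave, C1 = c1_wave, C2 = c2_wave)
  lat <- list(S = rep(0, 12), C1 = truth, C2 = rep(0, 12))
  upd <- update_latencies(x, waves, lat, "C1")
  expect_equal(upd, truth, tolerance = 1e-9)

  # one trial offset by +30 ms is found when the others are exact
  lat2 <- lat; lat2$C1[5] <- lat2$C1[5] - 30
  x2 <- x
  x2$data[5, , ] <- s_wave +
    erpride:::shift_samples(c1_wave, as.integer((lat2$C1[5] + 30) / 2)) + c2_wave
  upd2 <- update_latencies(x2, waves, lat2, "C1")
  delta <- upd2 - lat2$C1
  expect_equal(delta[5] - median(delta), 30, tolerance = 1e-9)

  # all-zero template leaves latencies unchanged with a warning
  wz <- waves; wz$C1 <- 0 * wz$C1
  expect_warning(u3 <- update_latencies(x, wz, lat, "C1"), "all-zero")
  expect_equal(u3, lat$C1)
})

test_that("RIDE is deterministic and equals the conventional average at zero jitter", {
  comps <- controlled_components(latency_sd = 0)
  cfg <- sim_config(n_subjects = 1, trials_per_condition = 12, seed = 41,
                    noise_sd = 0.5, include_mastoids = FALSE,
                    components = comps)
  x <- simulate_subject(cfg)$epochs
  expect_warning(fit1 <- ride(x, condition = "SEM"), NA)
  fit2 <- ride(x, condition = "SEM")
  expect_identical(fit1$clusters$C1$latencies, fit2$clusters$C1$latencies)
  expect_identical(fit1$reconstructed$data, fit2$reconstructed$data)

  # noise-free zero-jitter input: reconstruction equals the conventional
  # average and the outer loop stops immediately
  cfg0 <- sim_config(n_subjects = 1, trials_per_condition = 12, seed = 41,
                     noise_sd = 0, include_mastoids = FALSE,
                     components = comps)
  x0 <- simulate_subject(cfg0)$epochs
  fit0 <- ride(x0, condition = "SEM")
  conv <- average_evoked(x0, "SEM")
  rel <- sqrt(mean((fit0$reconstructed$data - conv$data)^2)) /
    sqrt(mean(conv$data^2))
  expect_lt(rel, 0.01)
  expect_lte(fit0$n_iterations, 2)
  expect_true(fit0$converged)
})

test_that("estimated latencies stay inside the search windows", {
  cfg <- sim_config(n_subjects = 1, trials_per_condition = 20, seed = 51,
                    noise_sd = 4, include_mastoids = FALSE,
                    components = controlled_components(latency_sd = 40))
  x <- simulate_subject(cfg)$epochs
  fit <- ride(x, condition = "SEM")
  for (nm in c("C1", "C2")) {
    halfspan <- diff(fit$config$windows[[nm]]) / 2
    expect_true(all(abs(fit$clusters[[nm]]$latencies) <= halfspan))
  }
  expect_equal(fit$clusters$S$latencies, rep(0, sum(x$conditions == "SEM")))
  # accessors
  co <- coef(fit)
  expect_equal(nrow(co), 3 * sum(x$conditions == "SEM"))
  r <- residuals(fit)
  f <- fitted(fit)
  expect_equal(r + f, subset_trials(x, x$conditions == "SEM")$data,
               tolerance = 1e-9)
})
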