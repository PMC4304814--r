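make_sine_recording <- function(freq, fs = 500, secs = 4) {
  t <- seq(0, secs - 1 / fs, by = 1 / fs)
  eeg_recording(rbind(sin(2 * pi * freq * t)), fs, "Cz",
                data.frame(sample_index = integer(), condition = character()))
}

test_that("band-pass keeps 10 Hz and attenuates 100 Hz by >= 20 dB", {
  r10 <- bandpass_filter(make_sine_recording(10))
  mid <- 500:1500  # avoid filter edge transients
  expect_equal(max(abs(r10$samples[1, mid])), 1, tolerance = 0.05)

  r100 <- bandpass_filter(make_sine_recording(100))
  expect_lt(max(abs(r100$samples[1, mid])), 10^(-20 / 20))

  z <- make_sine_recording(10)
  z$samples[] <- 0
  expect_equal(max(abs(bandpass_filter(z)$samples)), 0)

  expect_error(bandpass_filter(make_sine_recording(10), high = 300),
               "Nyquist")
  expect_error(bandpass_filter(make_sine_recording(10), low = 40, high = 30),
               "low < high")
})

test_that("zero-phase contract: a smooth bump's peak does not move", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  bump <- exp(-(t - 1)^2 / (2 * 0.05^2))
  r <- eeg_recording(rbind(bump), fs, "Cz",
                     data.frame(sample_index = integer(),
                                condition = character()))
  f <- bandpass_filter(r)
  expect_lte(abs(which.max(f$samples[1, ]) - which.max(bump)), 1)
})

test_that("mastoid re-referencing zeroes the mastoid mean and is idempotent", {
  set.seed(2)
  x <- tiny_epochs(n_channels = 5, data = array(rnorm(6 * 5 * 50), c(6, 5, 50)),
                   montage = c("Cz", "Pz", "Oz", "M1", "M2"))
  y <- rereference(x, c("M1", "M2"))
  mast <- (y$data[, 4, ] + y$data[, 5, ]) / 2
  expect_lt(max(abs(mast)), 1e-12)
  # already re-referenced -> unchanged
  y2 <- rereference(y, c("M1", "M2"))
  expect_equal(y2$data, y$data, tolerance = 1e-12)
  # linearity: rereference(a * x) == a * rereference(x)
  xs <- x; xs$data <- 3 * xs$data
  expect_equal(rereference(xs, c("M1", "M2"))$data, 3 * y$data,
               tolerance = 1e-12)
  # arithmetic case: constant mastoids 5, target 7 -> 2
  xc <- x; xc$data[] <- 0
  xc$data[, 4, ] <- 5; xc$data[, 5, ] <- 5; xc$data[, 1, ] <- 7
  expect_equal(unique(as.vector(rereference(xc, c("M1", "M2"))$data[, 1, ])), 2)
  expect_error(rereference(x, c("M1", "A9")), "not found")
})

test_that("epoching baselines every trial and skips edge events", {
  fs <- 500
  n <- 2000
  sam <- matrix(rnorm(2 * n), 2, n)
  ev <- data.frame(sample_index = c(1, 300, 1000),
                   condition = c("CON", "SEM", "SEM+SYN"))
  r <- eeg_recording(sam, fs, c("Cz", "Pz"), ev)
  expect_message(x <- epoch_recording(r, c(-200, 1000)), "skipped")
  expect_equal(attr(x, "skipped"), 1L)       # event at sample 1 cannot fit
  expect_equal(dim(x)[1], 2)
  bl <- apply(x$data[, , x$times < 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)

  # constant recording -> all-zero epochs
  rc <- eeg_recording(matrix(7, 1, n), fs, "Cz", ev[2:3, ])
  xc <- epoch_recording(rc)
  expect_lt(max(abs(xc$data)), 1e-12)

  # step at onset: baseline 0, post-onset plateau == step height
  step_sig <- matrix(0, 1, n)
  onset <- 600L
  step_sig[1, onset:n] <- 2.5
  rs <- eeg_recording(step_sig, fs, "Cz",
                      data.frame(sample_index = onset, condition = "CON"))
  xs <- epoch_recording(rs)
  expect_equal(unique(as.vector(xs$data[1, 1, xs$times >= 0])), 2.5)
  expect_lt(abs(mean(xs$data[1, 1, xs$times < 0])), 1e-12)

  # baseline idempotence
  set.seed(4)
  xr <- tiny_epochs(data = array(rnorm(6 * 4 * 50), c(6, 4, 50)))
  b1 <- baseline_correct(xr, c(-20, 0))
  b2 <- baseline_correct(b1, c(-20, 0))
  expect_equal(b1$data, b2$data, tolerance = 1e-12)
})

test_that("artifact rejection removes exactly the offending trials", {
  x <- tiny_epochs(n_trials = 5)
  r0 <- reject_artifacts(x)
  expect_equal(sum(r0$rejected), 0L)
  expect_length(r0$rejected, 5)

  # one trial with a single 81 muV sample at the +/-80 threshold
  x$data[3, 2, 10] <- 81
  r1 <- reject_artifacts(x, 80)
  expect_equal(which(r1$rejected), 3L)
  expect_equal(r1$epochs$conditions, x$conditions[-3])

  # exactly at threshold is kept (strict exceedance)
  x$data[3, 2, 10] <- 80
  expect_equal(sum(reject_artifacts(x, 80)$rejected), 0L)

  # EOG channels are excluded from the screen
  xe <- tiny_epochs(n_trials = 3, n_channels = 3,
                    montage = c("Cz", "Pz", "VEOG"))
  xe$data[2, 3, 5] <- 200
  expect_equal(sum(reject_artifacts(xe)$rejected), 0L)

  # monotonicity: higher threshold never rejects more
  set.seed(6)
  xm <- tiny_epochs(n_trials = 20,
                    data = array(rnorm(20 * 4 * 50, 0, 20), c(20, 4, 50)))
  ns <- vapply(c(60, 80, 120, 200),
               function(th) sum(reject_artifacts(xm, th)$rejected), 0)
  expect_true(all(diff(ns) <= 0))

  xall <- tiny_epochs(n_trials = 2)
  xall$data[] <- 100
  expect_error(reject_artifacts(xall, 80), "all trials rejected")
})

test_that("generator-planted exceedances are exactly the rejected trials", {
  cfg <- sim_config(n_subjects = 1, trials_per_condition = 10, seed = 15,
                    noise_sd = 5, contaminate = 4, include_mastoids = FALSE)
  sim <- simulate_subject(cfg)
  planted <- attr(sim$ground_truth, "contaminated")
  expect_length(planted, 4)
  rej <- reject_artifacts(sim$epochs, 80)
  expect_equal(which(rej$rejected), planted)
})
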