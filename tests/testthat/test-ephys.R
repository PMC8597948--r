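test_that("offset removal and CAR satisfy their postconditions and are idempotent", {
  set.seed(1)
  rec <- raw_recording(matrix(rnorm(8 * 500, mean = rep(1:8, 500)), 8),
                       30000, 1, seq(0, 140, by = 20))
  r1 <- remove_offset(rec)
  expect_equal(max(abs(apply(r1$samples, 1, median))), 0)
  expect_equal(remove_offset(r1)$samples, r1$samples)
  expect_equal(remove_offset(raw_recording(rbind(c(1, 1, 5), c(0, 0, 0)),
                                           30000, 1, c(0, 20)))$samples[1, ],
               c(0, 0, 4))

  r2 <- common_average_reference(rec)
  expect_equal(max(abs(apply(r2$samples, 2, median))), 0)
  expect_equal(common_average_reference(r2)$samples, r2$samples)
  one_t <- raw_recording(matrix(c(1, 2, 3), 3, 1), 30000, 1, c(0, 20, 40))
  expect_equal(as.numeric(common_average_reference(one_t)$samples), c(-1, 0, 1))
  expect_error(common_average_reference(
    raw_recording(matrix(0, 1, 10), 30000, 1, 0)), ">= 2 channels")

  # identical channels are fully cancelled by CAR
  same <- raw_recording(matrix(rep(rnorm(100), each = 4), 4), 30000, 1,
                        c(0, 20, 40, 60))
  expect_true(all(common_average_reference(same)$samples == 0))

  # gain is applied before preprocessing: thresholds see microvolts
  gain <- raw_recording(matrix(c(10L, 10L, 50L), 1), 30000, uV_per_bit = 2,
                        channel_depth_um = 0)
  expect_equal(as.numeric(remove_offset(gain)$samples), c(0, 0, 80))
})

test_that("band split separates slow and fast components cleanly", {
  fs <- 30000
  t <- seq(1 / fs, 1, by = 1 / fs)
  slow <- sin(2 * pi * 100 * t); fast <- sin(2 * pi * 1000 * t)
  rec <- raw_recording(rbind(slow + fast, slow + fast), fs, 1, c(0, 20))
  sb <- split_bands(rec)
  expect_equal(sb$lfp$sample_rate_hz, 2500)
  expect_equal(sb$ap$sample_rate_hz, fs)
  amp_of <- function(sig, f, tt) sqrt(mean(2 * sig * sin(2 * pi * f * tt))^2 +
                                      mean(2 * sig * cos(2 * pi * f * tt))^2)
  core <- 5000:25000
  tl <- (seq_len(ncol(sb$lfp$samples)) - 1) / 2500
  lcore <- 500:2000
  # the 100 Hz tone stays in the LFP band at >= 95 % amplitude ...
  expect_gt(amp_of(sb$lfp$samples[1, lcore], 100, tl[lcore]), 0.95)
  # ... and both leak across bands at <= -20 dB
  expect_lt(amp_of(sb$ap$samples[1, core], 100, t[core]), 0.1)
  expect_lt(amp_of(sb$lfp$samples[1, lcore], 1000, tl[lcore]), 0.1)
  expect_gt(amp_of(sb$ap$samples[1, core], 1000, t[core]), 0.95)

  # DC never reaches the AP band
  dc <- raw_recording(matrix(7, 2, fs), fs, 1, c(0, 20))
  sdc <- split_bands(dc)
  expect_lt(max(abs(sdc$ap$samples[, core])), 1e-6)

  expect_error(split_bands(raw_recording(matrix(0, 2, 100), 2500, 1,
                                         c(0, 20))), "10 kHz")
})

test_that("multiunit detection thresholds, dead time and amplitudes", {
  fs <- 30000
  z <- matrix(0, 1, fs)
  z[1, 1000:1005] <- -60
  expect_equal(nrow(detect_multiunit(raw_recording(z, fs, 1, 0), -50)$events), 1)
  # the same deflection is invisible at a -70 uV display threshold
  expect_equal(nrow(detect_multiunit(raw_recording(z, fs, 1, 0), -70)$events), 0)
  ev <- detect_multiunit(raw_recording(z, fs, 1, 0), -50)
  expect_equal(ev$events$amplitude_uV, -60)
  expect_equal(ev$events$time_s, 999 / fs)

  expect_equal(nrow(detect_multiunit(raw_recording(matrix(0, 2, 1000), fs, 1,
                                                   c(0, 20)))$events), 0)

  # two crossings within the dead time collapse into one event
  z2 <- matrix(0, 1, fs)
  z2[1, 500:502] <- -80; z2[1, 510:512] <- -90
  ev2 <- detect_multiunit(raw_recording(z2, fs, 1, 0), -50, dead_time_ms = 1)
  expect_equal(nrow(ev2$events), 1)
  expect_equal(ev2$events$amplitude_uV, -90)   # trough within the window
})

test_that("injected spikes are recovered exactly in Gaussian noise", {
  fs <- 30000
  set.seed(42)
  n <- 10 * fs
  x <- rnorm(n, 0, 5)
  shape <- c(-30, -70, -100, -70, -30, 20, 30, 20, 10)
  pos <- round(seq(2000, n - 2000, length.out = 100))
  for (p in pos) x[p:(p + 8)] <- x[p:(p + 8)] + shape
  ev <- detect_multiunit(raw_recording(matrix(x, 1), fs, 1, 0), -50)
  expect_equal(nrow(ev$events), 100)           # all found, none extra
  expect_true(all(abs(ev$events$time_s * fs + 1 - pos) <= 2))
  # Gaussian tail at 10 sigma makes a false crossing essentially impossible:
  # n * pnorm(-50/5) ~ 2e-18 expected false events
  expect_lt(10 * fs * pnorm(-50 / 5), 1e-12)
})

test_that("spike rate maps bin correctly and conserve events", {
  dep <- seq(0, 380, by = 20)
  ev <- event_train(data.frame(channel = 5L,
                               time_s = seq(0.05, 59.95, length.out = 600),
                               amplitude_uV = -80),
                    duration_s = 60, channel_depth_um = dep)
  m <- spike_rate_map(ev, t_bin_s = 10, depth_bin_um = 20)
  row <- findInterval(dep[5], m$depth_edges_um)
  expect_equal(as.numeric(m$rate_hz[row, ]), rep(10, 6))
  expect_equal(sum(m$rate_hz) * 10, 600)

  set.seed(6)
  ev2 <- event_train(data.frame(channel = sample(1:20, 500, TRUE),
                                time_s = runif(500, 0, 55),
                                amplitude_uV = -60),
                     duration_s = 55, channel_depth_um = dep)
  m2 <- spike_rate_map(ev2, t_bin_s = 10, depth_bin_um = 40)
  expect_equal(sum(m2$rate_hz) * 10, 500)

  empty <- event_train(data.frame(channel = integer(0), time_s = numeric(0),
                                  amplitude_uV = numeric(0)),
                       duration_s = 10, channel_depth_um = dep)
  expect_true(all(spike_rate_map(empty)$rate_hz == 0))
})

test_that("depth profiles expose rate, amplitude and LFP power signatures", {
  dep <- seq(0, 780, by = 20)   # 40 channels
  set.seed(7)
  # amplitude steps at 400 um: small units above, large units below,
  # the classic layer-boundary signature
  evs <- do.call(rbind, lapply(1:40, function(ch) {
    n <- 30
    a <- if (dep[ch] < 400) -40 else -90
    data.frame(channel = ch, time_s = runif(n, 0, 60),
               amplitude_uV = a + rnorm(n, 0, 3))
  }))
  ev <- event_train(evs, duration_s = 60, channel_depth_um = dep)
  lfp <- raw_recording(matrix(rnorm(40 * 2500), 40) *
                         ifelse(dep < 400, 1, 4), 2500, 1, dep)
  pr <- depth_profiles(ev, lfp)
  ctr <- profile_centers(pr$amplitude)
  expect_true(all(pr$amplitude$values[ctr < 380] < 60))
  expect_true(all(pr$amplitude$values[ctr > 420] > 60))
  expect_gt(mean(pr$lfp_power$values[ctr > 420]),
            4 * mean(pr$lfp_power$values[ctr < 380]))
  expect_equal(pr$spike_rate$values, rep(30 / 60, 40), tolerance = 1e-12)

  # silent channels give zero rate and amplitude
  silent <- event_train(evs[0, ], duration_s = 60, channel_depth_um = dep)
  pr0 <- depth_profiles(silent)
  expect_true(all(pr0$spike_rate$values == 0))
  expect_true(all(pr0$amplitude$values == 0))
})

test_that("surface detection finds the change point within tolerance", {
  prof <- c(rep(1, 199), rep(10, 101))
  s <- detect_surface(prof)
  expect_equal(s$index, 200)
  expect_gt(s$confidence, 2)

  set.seed(8)
  hits <- vapply(1:20, function(i)
    detect_surface(prof + rnorm(300, 0, 0.5))$index, numeric(1))
  expect_true(all(abs(hits - 200) <= 2))

  expect_error(detect_surface(rep(5, 100)), "no surface transition")
  expect_error(detect_surface(rnorm(100, 0, 0.1) + 5), "no surface transition")

  # profile objects return the surface depth as well
  fp <- feature_profile(seq(-10, 5990, by = 20), c(rep(1, 100), rep(9, 200)),
                        "lfp_power")
  sd2 <- detect_surface(fp)
  expect_equal(sd2$depth_um, 2000)
})

test_that("evoked profiles window, baseline-subtract and conserve counts", {
  dep <- seq(0, 380, by = 20)
  stim <- seq(1, 60, by = 0.2)
  # fixed 3 ms latency on one channel: all events inside a 0-5 ms window
  ev <- event_train(data.frame(channel = 3L, time_s = stim + 0.003,
                               amplitude_uV = -80),
                    duration_s = 61, channel_depth_um = dep)
  e1 <- evoked_profile(ev, stim, window_ms = c(0, 5))
  bin3 <- findInterval(dep[3], e1$profile$depth_edges_um)
  expect_equal(e1$profile$values[bin3], length(stim))
  expect_equal(sum(e1$profile$values), length(stim))
  expect_equal(sum(e1$psth$count), length(stim))
  expect_equal(e1$psth$time_ms[which.max(e1$psth$count)], 3.25)

  # a 10 ms latency response misses the 0-5 ms window but fills 5-20 ms
  ev10 <- event_train(data.frame(channel = 3L, time_s = stim + 0.010,
                                 amplitude_uV = -80),
                      duration_s = 61, channel_depth_um = dep)
  expect_equal(sum(evoked_profile(ev10, stim,
                                  window_ms = c(0, 5))$profile$values), 0)
  expect_equal(sum(evoked_profile(ev10, stim,
                                  window_ms = c(5, 20))$profile$values),
               length(stim))

  expect_error(evoked_profile(ev, numeric(0)), "empty stim")
  empty <- event_train(data.frame(channel = integer(0), time_s = numeric(0),
                                  amplitude_uV = numeric(0)),
                       duration_s = 61, channel_depth_um = dep)
  expect_true(all(evoked_profile(empty, stim)$profile$values == 0))
})

test_that("flat binary recording and event CSV round trips", {
  set.seed(9)
  rec <- raw_recording(matrix(as.integer(round(rnorm(4 * 100, 0, 300))), 4),
                       30000, 0.195, c(0, 20, 40, 60))
  f <- withr::local_tempfile()
  write_recording_bin(rec, f)
  r2 <- read_recording_bin(f)
  expect_identical(matrix(as.integer(r2$samples), 4), rec$samples)
  expect_equal(r2$uV_per_bit, 0.195)
  expect_equal(r2$channel_depth_um, c(0, 20, 40, 60))

  ev <- event_train(data.frame(channel = c(1L, 2L), time_s = c(0.5, 0.7),
                               amplitude_uV = c(-60, -80)))
  fe <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, fe)
  ev2 <- read_events_csv(fe)
  expect_equal(ev2$events, ev$events)

  p <- feature_profile(c(0, 20, 40), c(1, 2), "spike_rate")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, fp)
  expect_equal(read.csv(fp)$depth_um, c(10, 30))
})
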