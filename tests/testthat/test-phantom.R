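# small-grid phantoms keep these tests fast; the full-size presets are
# exercised in the end-to-end accuracy tests

test_that("phantom generation is deterministic under the seed", {
  spec <- small_phantom_spec(seed = 11, n_penetrations = 2)
  b1 <- make_phantom(spec)
  b2 <- make_phantom(spec)
  expect_identical(b1$subject_volume$data, b2$subject_volume$data)
  expect_identical(b1$projection_volume$data, b2$projection_volume$data)
  expect_identical(b1$landmarks$CCF$fixed, b2$landmarks$CCF$fixed)
  expect_identical(b1$penetrations[[2]]$events$events,
                   b2$penetrations[[2]]$events$events)
  expect_identical(b1$recording$samples, b2$recording$samples)

  b3 <- make_phantom(small_phantom_spec(seed = 12, n_penetrations = 2))
  expect_false(identical(b1$subject_volume$data, b3$subject_volume$data))
})

test_that("zero-jitter affine phantom yields exact landmark interpolation", {
  spec <- small_phantom_spec(seed = 13, n_penetrations = 1,
                             landmark_jitter_um = 0, ccf_perturb_um = 0,
                             mri_perturb_um = 0)
  b <- make_phantom(spec)
  # fixed points are the exact map of the moving points
  expect_equal(apply_transform(b$maps$CCF, b$landmarks$CCF$moving),
               b$landmarks$CCF$fixed, tolerance = 1e-12)
  # a TPS fitted on them reproduces the affine map everywhere
  t <- fit_tps(b$landmarks$CCF)
  set.seed(1)
  pts <- cbind(runif(50, 400, 2000), runif(50, 400, 2000),
               runif(50, 400, 3200))
  expect_lt(max(abs(apply_transform(t, pts) -
                    apply_transform(b$maps$CCF, pts))), 1e-6)
  expect_lt(max(abs(t$weights)), 1e-7)
})

test_that("region-dependent spiking matches the requested Poisson rates", {
  spec <- small_phantom_spec(seed = 14, n_penetrations = 1,
                             rates_hz = c("0" = 0.2, "1" = 20, "2" = 1.5,
                                          "3" = 4, "4" = 15, "5" = 6))
  b <- make_phantom(spec)
  pen <- b$penetrations[[1]]
  dur <- pen$events$duration_s
  # channels in the cortex-like layer (rate 20 Hz): counts within 3 sd of
  # the Poisson expectation, pooled over channels
  depth_below <- pen$insertion_depth_um - pen$events$channel_depth_um
  ctx_ch <- which(depth_below > 50 & depth_below < 950)
  cnt <- sum(pen$events$events$channel %in% ctx_ch)
  lam <- 20 * dur * length(ctx_ch)
  expect_lt(abs(cnt - lam), 3 * sqrt(lam) + 0.05 * lam)
  # out-of-brain channels are nearly silent
  out_ch <- which(depth_below < -100)
  if (length(out_ch)) {
    out_rate <- sum(pen$events$events$channel %in% out_ch) /
      (dur * length(out_ch))
    expect_lt(out_rate, 1)
  }
  # thresholded amplitudes respect the -50 uV convention
  expect_true(all(pen$events$events$amplitude_uV <= -50))
})

test_that("true electrode positions lie on the true track at row pitch", {
  b <- make_phantom(small_phantom_spec(seed = 15, n_penetrations = 2))
  pos <- true_site_positions(b, 2)
  pen <- b$penetrations[[2]]
  rel <- sweep(as.matrix(pos[, c("x_um", "y_um", "z_um")]), 2, pen$entry_um)
  along <- rel %*% pen$direction
  perp <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
  expect_lt(max(perp), 1e-3)   # numerically zero at mm-scale coordinates
  expect_equal(as.numeric(along),
               pen$insertion_depth_um - pos$shank_depth_um)
  rows <- pos[seq(1, nrow(pos), by = 2), ]
  expect_equal(unique(round(diff(rows$shank_depth_um), 9)), 20)
})

test_that("the rendered dye tube's centreline matches the true track", {
  spec <- small_phantom_spec(seed = 16, n_penetrations = 1,
                             track_point_jitter_um = 0, tip_smear_um = 0)
  b <- make_phantom(spec)
  pen <- b$penetrations[[1]]
  v <- b$subject_volume
  # intensity-weighted centroid per DV slab, within a box around the track
  err <- c()
  for (dv_lo in seq(600, 1200, by = 200)) {
    depth_mid <- dv_lo + 100 - spec$surface_dv_um
    truth <- pen$entry_um + pen$direction * depth_mid /
      pen$direction[2]            # point at that DV on the true line
    jj <- which(abs((seq_len(dim(v$data)[2]) - 1) * v$spacing[2] -
                    (dv_lo + 100)) <= 100)
    ii <- which(abs((seq_len(dim(v$data)[1]) - 1) * v$spacing[1] -
                    truth[1]) <= 300)
    kk <- which(abs((seq_len(dim(v$data)[3]) - 1) * v$spacing[3] -
                    truth[3]) <= 300)
    blk <- v$data[ii, jj, kk, drop = FALSE] - median(v$data[ii, jj, kk])
    blk[blk < 0] <- 0
    w <- blk / sum(blk)
    xs <- (ii - 1) * v$spacing[1]; zs <- (kk - 1) * v$spacing[3]
    cx <- sum(apply(w, 1, sum) * xs)
    cz <- sum(apply(w, 3, sum) * zs)
    err <- c(err, sqrt((cx - truth[1])^2 + (cz - truth[3])^2))
  }
  expect_lt(max(err), spec$dye_sigma_um / 2)
})

test_that("the phantom raw recording carries the expected signatures", {
  spec <- small_phantom_spec(seed = 17, n_penetrations = 1,
                             raw_duration_s = 1.5)
  b <- make_phantom(spec)
  rec <- b$recording
  expect_s3_class(rec, "raw_recording")
  expect_equal(rec$sample_rate_hz, 30000)
  pen <- b$penetrations[[1]]
  depth_below <- pen$insertion_depth_um - rec$channel_depth_um
  uv <- as_microvolts(rec)
  sds <- apply(uv$samples, 1, sd)
  # the out-of-brain segment above the surface is quieter
  expect_gt(median(sds[depth_below > 200]), 2 * median(sds[depth_below < -200]))
  # multiunit detection on the AP band sees in-brain spikes
  bands <- split_bands(common_average_reference(remove_offset(uv)))
  ev <- detect_multiunit(bands$ap)
  in_rate <- nrow(ev$events[depth_below[ev$events$channel] > 0, ]) /
    sum(depth_below > 0) / rec$duration_s
  out_rate <- nrow(ev$events[depth_below[ev$events$channel] < -100, ]) /
    max(1, sum(depth_below < -100)) / rec$duration_s
  expect_gt(in_rate, 5 * max(out_rate, 0.2))

  # the LFP-power change point recovers the true surface channel
  pw <- rowMeans(bands$lfp$samples^2)
  sdet <- detect_surface(rev(pw))      # orient outside-first
  ch <- length(pw) - sdet$index + 1
  true_ch <- max(which(depth_below >= 0))
  expect_lte(abs(ch - true_ch), 1)
})

test_that("phantom files round-trip through the exchange formats", {
  spec <- small_phantom_spec(seed = 18, n_penetrations = 2)
  b <- make_phantom(spec)
  dir <- withr::local_tempdir()
  write_phantom(b, dir)
  v <- read_volume(file.path(dir, "projection.nrrd"))
  expect_equal(v$data, b$projection_volume$data, tolerance = 1e-12)
  a <- read_volume(file.path(dir, "annot_MRI3D.nrrd"))
  expect_equal(array(as.integer(a$data), dim(a$data)),
               b$atlas$MRI3D$annot$data)
  lm <- read_landmarks_csv(file.path(dir, "landmarks_subject2CCF.csv"))
  expect_equal(lm$moving, b$landmarks$CCF$moving, ignore_attr = TRUE)
  anns <- read_track_annotation_csv(file.path(dir, "tracks.csv"))
  expect_equal(length(anns), 2)
  expect_equal(anns$pen02$manipulator_depth_mm,
               b$penetrations[[2]]$manipulator_depth_mm)
  ev <- read_events_csv(file.path(dir, "events_pen01.csv"))
  expect_equal(nrow(ev$events), nrow(b$penetrations[[1]]$events$events))
  rec <- read_recording_bin(file.path(dir, "raw_pen01.bin"))
  expect_identical(matrix(as.integer(rec$samples), nrow(rec$samples)),
                   b$recording$samples)
})
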