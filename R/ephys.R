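#' Raw extracellular recording
#'
#' Channel-by-time sample matrix with acquisition metadata. Raw int16 samples
#' are converted to microvolts via `uV_per_bit` by [as_microvolts()] (all
#' preprocessing operates in uV, so thresholds are gain independent).
#'
#' @param samples channels x time numeric/integer matrix.
#' @param sample_rate_hz sampling rate (Hz), > 0.
#' @param uV_per_bit microvolts per integer unit (1 if already in uV).
#' @param channel_depth_um per-channel shank depth (um, distance from tip),
#'   strictly monotone.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sample_rate_hz, uV_per_bit = 1,
                          channel_depth_um) {
  samples <- as.matrix(samples)
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (length(channel_depth_um) != nrow(samples))
    stop("channel_depth_um must have one entry per channel (row)")
  d <- diff(channel_depth_um)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("channel_depth_um must be strictly monotone")
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz,
                 uV_per_bit = uV_per_bit,
                 channel_depth_um = as.numeric(channel_depth_um),
                 duration_s = ncol(samples) / sample_rate_hz),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %.3f s @ %g kHz (%g uV/bit)\n",
              nrow(x$samples), x$duration_s, x$sample_rate_hz / 1000,
              x$uV_per_bit))
  invisible(x)
}

#' Convert a recording to microvolts
#' @param rec a [raw_recording()].
#' @return the recording with numeric uV samples and `uV_per_bit = 1`.
#' @export
as_microvolts <- function(rec) {
  if (rec$uV_per_bit != 1 || !is.double(rec$samples)) {
    rec$samples <- rec$samples * rec$uV_per_bit
    rec$uV_per_bit <- 1
  }
  rec
}

#' Remove per-channel baseline offset
#'
#' Subtracts each channel's median over time; idempotent.
#'
#' @param rec a [raw_recording()].
#' @return the offset-corrected recording (in uV).
#' @export
remove_offset <- function(rec) {
  rec <- as_microvolts(rec)
  med <- apply(rec$samples, 1, stats::median)
  rec$samples <- rec$samples - med
  rec
}

#' Common average referencing
#'
#' Subtracts the cross-channel median at every time point, removing noise
#' shared across the probe; idempotent.
#'
#' @param rec a [raw_recording()] with >= 2 channels.
#' @return the referenced recording (in uV).
#' @export
common_average_reference <- function(rec) {
  if (nrow(rec$samples) < 2L)
    stop("common average referencing needs >= 2 channels")
  rec <- as_microvolts(rec)
  med <- apply(rec$samples, 2, stats::median)
  rec$samples <- sweep(rec$samples, 2, med)
  rec
}

#' Split a wide-band recording into AP and LFP bands
#'
#' LFP: zero-phase low-pass at `lfp_cut_hz` then decimation to
#' `lfp_rate_hz`; AP: zero-phase band-pass `ap_band_hz` at the native rate.
#' Zero-phase (forward-backward) order-3 Butterworth filters preserve event
#' timing. When the decimation factor is not an integer the LFP is resampled
#' by interpolation after the anti-alias low-pass (noted in `$resampled`).
#'
#' @param rec a [raw_recording()], at least 10 kHz for a meaningful AP band.
#' @param ap_band_hz AP band corners (Hz), default 300-5000.
#' @param lfp_cut_hz LFP low-pass corner (Hz), default 300.
#' @param lfp_rate_hz LFP output rate (Hz), default 2500.
#' @param order Butterworth order (default 3).
#' @return list with elements `ap` and `lfp`, both [raw_recording()].
#' @export
split_bands <- function(rec, ap_band_hz = c(300, 5000), lfp_cut_hz = 300,
                        lfp_rate_hz = 2500, order = 3) {
  if (rec$sample_rate_hz < 10000)
    stop("sample rate below 10 kHz: AP band would be meaningless")
  rec <- as_microvolts(rec)
  fs <- rec$sample_rate_hz
  bl <- signal::butter(order, lfp_cut_hz / (fs / 2), type = "low")
  hi <- min(ap_band_hz[2], 0.99 * fs / 2)
  bp <- signal::butter(order, c(ap_band_hz[1], hi) / (fs / 2), type = "pass")
  nch <- nrow(rec$samples)
  lfp_full <- matrix(0, nch, ncol(rec$samples))
  ap <- matrix(0, nch, ncol(rec$samples))
  for (ch in seq_len(nch)) {
    x <- rec$samples[ch, ]
    lfp_full[ch, ] <- signal::filtfilt(bl, x)
    ap[ch, ] <- signal::filtfilt(bp, x)
  }
  fct <- fs / lfp_rate_hz
  resampled <- abs(fct - round(fct)) > 1e-9
  if (!resampled) {
    idx <- seq(1, ncol(lfp_full), by = as.integer(round(fct)))
    lfp <- lfp_full[, idx, drop = FALSE]
  } else {
    t_old <- (seq_len(ncol(lfp_full)) - 1) / fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / lfp_rate_hz)
    lfp <- t(apply(lfp_full, 1, function(x)
      stats::approx(t_old, x, xout = t_new)$y))
  }
  lfp <- raw_recording(lfp, lfp_rate_hz, 1, rec$channel_depth_um)
  lfp$resampled <- resampled
  list(ap = raw_recording(ap, fs, 1, rec$channel_depth_um), lfp = lfp)
}

#' Threshold-crossing multiunit detection
#'
#' Registers negative threshold crossings on every channel of the AP band.
#' The event time is the first sub-threshold sample, the amplitude the trough
#' within the dead-time window; further crossings within the dead time of an
#' accepted event are suppressed, so one spike is never counted twice.
#'
#' @param ap AP-band [raw_recording()] in uV (after preprocessing).
#' @param threshold_uV negative threshold, default -50.
#' @param dead_time_ms per-channel refractory window, default 1.
#' @return object of class `event_train`: data.frame `events`
#'   (`channel,time_s,amplitude_uV`) plus threshold/dead-time metadata, the
#'   recording duration and channel depth map.
#' @export
detect_multiunit <- function(ap, threshold_uV = -50, dead_time_ms = 1) {
  if (threshold_uV >= 0) stop("threshold_uV must be negative")
  ap <- as_microvolts(ap)
  fs <- ap$sample_rate_hz
  dead_n <- max(1L, as.integer(round(dead_time_ms / 1000 * fs)))
  res <- vector("list", nrow(ap$samples))
  for (ch in seq_len(nrow(ap$samples))) {
    x <- ap$samples[ch, ]
    below <- x < threshold_uV
    onset <- which(below & !c(FALSE, below[-length(below)]))
    keep <- integer(0); last <- -Inf
    for (i in onset) {
      if (i - last >= dead_n) { keep <- c(keep, i); last <- i }
    }
    if (length(keep)) {
      amp <- vapply(keep, function(i)
        min(x[i:min(length(x), i + dead_n - 1L)]), numeric(1))
      res[[ch]] <- data.frame(channel = ch, time_s = (keep - 1) / fs,
                              amplitude_uV = amp)
    }
  }
  ev <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(channel = integer(0), time_s = numeric(0),
                     amplitude_uV = numeric(0))
  event_train(ev, threshold_uV, dead_time_ms, ap$duration_s,
              ap$channel_depth_um)
}

#' Construct an event train
#' @param events data.frame with `channel,time_s,amplitude_uV`.
#' @param threshold_uV detection threshold.
#' @param dead_time_ms refractory window.
#' @param duration_s recording duration.
#' @param channel_depth_um per-channel shank depth map.
#' @return object of class `event_train`.
#' @export
event_train <- function(events, threshold_uV = -50, dead_time_ms = 1,
                        duration_s = NULL, channel_depth_um = NULL) {
  structure(list(events = events, threshold_uV = threshold_uV,
                 dead_time_ms = dead_time_ms, duration_s = duration_s,
                 channel_depth_um = channel_depth_um),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events on %d channels (threshold %g uV)\n",
              nrow(x$events), length(unique(x$events$channel)), x$threshold_uV))
  invisible(x)
}

# bin edges centred on the depth lattice (centres at multiples of bin_um),
# so a channel sitting exactly on the lattice maps to its own bin centre
depth_edges <- function(depths, bin_um) {
  lo <- round(min(depths) / bin_um) * bin_um
  hi <- round(max(depths) / bin_um) * bin_um
  seq(lo - bin_um / 2, hi + bin_um / 2, by = bin_um)
}

#' Spike-rate map over time and depth
#'
#' Event counts per (depth, time) bin divided by the time-bin width, so the
#' map is in Hz and total events are conserved
#' (`sum(map) * t_bin_s == nrow(events)`).
#'
#' @param events an [event_train()].
#' @param t_bin_s time bin (s), default 10.
#' @param depth_bin_um depth bin (um), default 20.
#' @param channel_depth_um per-channel depth; defaults to the train's map.
#' @param duration_s total duration; defaults to the train's.
#' @return list with `rate_hz` (depth x time matrix), `depth_edges_um`,
#'   `time_edges_s`.
#' @export
spike_rate_map <- function(events, t_bin_s = 10, depth_bin_um = 20,
                           channel_depth_um = events$channel_depth_um,
                           duration_s = events$duration_s) {
  ev <- events$events
  te <- seq(0, max(duration_s, t_bin_s), by = t_bin_s)
  if (te[length(te)] < duration_s) te <- c(te, te[length(te)] + t_bin_s)
  de <- depth_edges(channel_depth_um, depth_bin_um)
  m <- matrix(0, length(de) - 1L, length(te) - 1L)
  if (nrow(ev)) {
    di <- findInterval(channel_depth_um[ev$channel], de,
                       rightmost.closed = TRUE)
    ti <- pmin(findInterval(ev$time_s, te, rightmost.closed = TRUE),
               length(te) - 1L)
    tab <- table(factor(di, levels = seq_len(nrow(m))),
                 factor(ti, levels = seq_len(ncol(m))))
    m <- m + as.matrix(tab)
  }
  list(rate_hz = m / t_bin_s, depth_edges_um = de, time_edges_s = te)
}

#' Per-depth scalar feature profile
#' @param depth_edges_um bin edges (um), length one more than `values`.
#' @param values scalar per bin.
#' @param kind tag: `spike_rate`, `amplitude`, `lfp_power`, `evoked_count`,
#'   `fluorescence`.
#' @return object of class `feature_profile`.
#' @export
feature_profile <- function(depth_edges_um, values, kind = "spike_rate") {
  if (length(values) != length(depth_edges_um) - 1L)
    stop("length(values) must be length(edges) - 1")
  structure(list(depth_edges_um = as.numeric(depth_edges_um),
                 values = as.numeric(values), kind = kind),
            class = "feature_profile")
}

#' Bin centres of a feature profile (um)
#' @param p a [feature_profile()].
#' @return numeric vector of bin centres.
#' @export
profile_centers <- function(p) {
  e <- p$depth_edges_um
  (e[-1] + e[-length(e)]) / 2
}

#' Per-depth feature profiles: spike rate, unit amplitude, LFP power
#'
#' The classic landmark triplet along a penetration: multiunit rate (Hz),
#' median absolute event amplitude (uV) and LFP power (mean squared uV over
#' the LFP band) per depth bin.
#'
#' @param events an [event_train()].
#' @param lfp LFP-band [raw_recording()] (optional; power profile omitted
#'   when missing).
#' @param depth_bin_um depth bin (um), default 20.
#' @param channel_depth_um per-channel depth; defaults to the train's map.
#' @param duration_s duration for the rate denominator; defaults to the
#'   train's.
#' @return named list of [feature_profile()]: `spike_rate`, `amplitude`,
#'   and `lfp_power` when `lfp` is given.
#' @export
depth_profiles <- function(events, lfp = NULL, depth_bin_um = 20,
                           channel_depth_um = events$channel_depth_um,
                           duration_s = events$duration_s) {
  de <- depth_edges(channel_depth_um, depth_bin_um)
  nb <- length(de) - 1L
  ev <- events$events
  ch_bin <- findInterval(channel_depth_um, de, rightmost.closed = TRUE)
  n_ch_bin <- tabulate(ch_bin, nb)
  cnt <- amp <- rep(0, nb)
  if (nrow(ev)) {
    di <- ch_bin[ev$channel]
    cnt <- tabulate(di, nb)
    amp <- vapply(seq_len(nb), function(b) {
      a <- abs(ev$amplitude_uV[di == b])
      if (length(a)) stats::median(a) else 0
    }, numeric(1))
  }
  out <- list(spike_rate = feature_profile(de, cnt / duration_s, "spike_rate"),
              amplitude = feature_profile(de, amp, "amplitude"))
  if (!is.null(lfp)) {
    pw_ch <- rowMeans(as_microvolts(lfp)$samples^2)
    pw <- vapply(seq_len(nb), function(b) {
      v <- pw_ch[ch_bin == b]
      if (length(v)) mean(v) else 0
    }, numeric(1))
    out$lfp_power <- feature_profile(de, pw, "lfp_power")
  }
  out
}

#' Detect the brain-surface transition in a per-channel profile
#'
#' Finds the change point of a profile that spans both out-of-brain channels
#' (low spiking / LFP power in saline or CSF) and in-brain channels. The
#' profile must be ordered from outside the brain (first element) toward the
#' brain. The change point minimizes the two-segment within-sum-of-squares;
#' the surface is the first element exceeding the midpoint between the
#' shallow-plateau and deep-plateau medians. Confidence is the plateau
#' separation divided by the pooled within-plateau spread; below
#' `min_confidence` the transition is rejected.
#'
#' @param profile numeric vector or [feature_profile()] (e.g. LFP power per
#'   channel), ordered outside -> inside.
#' @param min_confidence rejection threshold, default 2.
#' @return list with `index` (element at/after the surface), `confidence`,
#'   `baseline`, `level`, and `depth_um` when a profile object was given.
#' @export
detect_surface <- function(profile, min_confidence = 2) {
  values <- if (inherits(profile, "feature_profile")) profile$values else
    as.numeric(profile)
  n <- length(values)
  if (n < 6L) stop("profile too short for surface detection")
  css <- function(x) { m <- cumsum(x); m2 <- cumsum(x^2)
    list(s = m, s2 = m2) }
  a <- css(values)
  # each plateau must hold several elements: near-single-point "plateaus"
  # make the confidence ratio meaningless on pure noise
  kmin <- min(5L, n %/% 3L)
  ks <- seq.int(kmin, n - kmin)
  sse <- vapply(ks, function(k) {
    s1 <- a$s[k]; q1 <- a$s2[k]
    s2 <- a$s[n] - s1; q2 <- a$s2[n] - q1
    (q1 - s1^2 / k) + (q2 - s2^2 / (n - k))
  }, numeric(1))
  k <- ks[which.min(sse)]
  m1 <- stats::median(values[1:k]); m2 <- stats::median(values[(k + 1):n])
  spread <- sqrt((sum((values[1:k] - m1)^2) +
                  sum((values[(k + 1):n] - m2)^2)) / n)
  conf <- if (spread == 0) {
    if (abs(m2 - m1) == 0) 0 else Inf
  } else abs(m2 - m1) / spread
  if (!is.finite(conf) && abs(m2 - m1) == 0) conf <- 0
  if (conf < min_confidence || m2 <= m1)
    stop(sprintf("no surface transition detected (confidence %.2f)", conf))
  idx <- which(values > (m1 + m2) / 2)[1]
  out <- list(index = idx, confidence = conf, baseline = m1, level = m2)
  if (inherits(profile, "feature_profile"))
    out$depth_um <- profile_centers(profile)[idx]
  out
}

#' Stimulus-evoked activity profile and PSTH
#'
#' Counts multiunit events falling in `window_ms` after each stimulus onset,
#' summed over repetitions and binned by depth, baseline-subtracted with an
#' equal-duration window ending at the stimulus. Typical windows: 0-5 ms for
#' direct/axonal activation, 5-20 ms for synaptically relayed responses. Also
#' returns the pooled peristimulus time histogram at 0.5 ms resolution.
#'
#' @param events an [event_train()].
#' @param stim_times_s stimulus onsets (s), non-empty, within the recording.
#' @param window_ms response window `c(lo, hi)` in ms after onset.
#' @param depth_bin_um depth bin (um), default 20.
#' @param channel_depth_um per-channel depth; defaults to the train's map.
#' @param psth_range_ms PSTH extent around onset, default c(-20, 40).
#' @param psth_bin_ms PSTH bin, default 0.5.
#' @param baseline_subtract subtract the pre-stimulus window (default TRUE).
#' @return list with `profile` (a [feature_profile()], kind `evoked_count`),
#'   `psth` (data.frame `time_ms,count`), `n_stim`.
#' @export
evoked_profile <- function(events, stim_times_s, window_ms = c(5, 20),
                           depth_bin_um = 20,
                           channel_depth_um = events$channel_depth_um,
                           psth_range_ms = c(-20, 40), psth_bin_ms = 0.5,
                           baseline_subtract = TRUE) {
  if (!length(stim_times_s)) stop("empty stim_times")
  ev <- events$events
  de <- depth_edges(channel_depth_um, depth_bin_um)
  nb <- length(de) - 1L
  stim <- sort(as.numeric(stim_times_s))
  w <- (window_ms[2] - window_ms[1]) / 1000
  count_in <- function(lo_s, hi_s) {
    # events with (t - nearest preceding-or-equal-window stimulus) in window
    if (!nrow(ev)) return(rep(0, nb))
    j <- findInterval(ev$time_s - lo_s, stim)
    ok <- j >= 1L
    dt <- ev$time_s - ifelse(ok, stim[pmax(j, 1L)], NA_real_)
    hit <- ok & dt >= lo_s & dt < hi_s
    di <- findInterval(channel_depth_um[ev$channel[hit]], de,
                       rightmost.closed = TRUE)
    tabulate(di, nb)
  }
  resp <- count_in(window_ms[1] / 1000, window_ms[2] / 1000)
  vals <- resp
  if (baseline_subtract) vals <- resp - count_in(-w, 0)
  # pooled PSTH
  pe <- seq(psth_range_ms[1], psth_range_ms[2], by = psth_bin_ms)
  cnt <- rep(0L, length(pe) - 1L)
  if (nrow(ev)) {
    j <- findInterval(ev$time_s - psth_range_ms[1] / 1000, stim)
    ok <- j >= 1L
    dt_ms <- (ev$time_s - stim[pmax(j, 1L)]) * 1000
    keep <- ok & dt_ms >= psth_range_ms[1] & dt_ms < psth_range_ms[2]
    cnt <- tabulate(findInterval(dt_ms[keep], pe), length(pe) - 1L)
  }
  list(profile = feature_profile(de, vals, "evoked_count"),
       psth = data.frame(time_ms = (pe[-1] + pe[-length(pe)]) / 2, count = cnt),
       n_stim = length(stim))
}

# ---- flat-binary recording I/O -------------------------------------------

#' Read a flat binary int16 recording with JSON metadata
#'
#' Channel-major frames (all channels of sample 1, then sample 2, ...) with a
#' sidecar `<path>.json` holding `n_channels`, `sample_rate_hz`, `uV_per_bit`
#' and `channel_depth_um`.
#'
#' @param path binary file path.
#' @return a [raw_recording()].
#' @export
read_recording_bin <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("no metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- file.info(path)$size / 2
  x <- readBin(path, "integer", n = n, size = 2L, signed = TRUE,
               endian = "little")
  raw_recording(matrix(x, nrow = meta$n_channels), meta$sample_rate_hz,
                meta$uV_per_bit, meta$channel_depth_um)
}

#' Write a recording as flat binary int16 plus JSON metadata
#' @param rec a [raw_recording()] (values are rounded to int16 after dividing
#'   by `uV_per_bit` when already in uV).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_bin <- function(rec, path) {
  x <- as.integer(pmin(pmax(round(as.vector(rec$samples)), -32768L), 32767L))
  writeBin(x, path, size = 2L, endian = "little")
  jsonlite::write_json(list(n_channels = nrow(rec$samples),
                            sample_rate_hz = rec$sample_rate_hz,
                            uV_per_bit = rec$uV_per_bit,
                            channel_depth_um = rec$channel_depth_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read events from CSV (`channel,time_s,amplitude_uV`)
#' @param path CSV path.
#' @param ... passed to [event_train()].
#' @return an [event_train()].
#' @export
read_events_csv <- function(path, ...) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_train(d[, c("channel", "time_s", "amplitude_uV")], ...)
}

#' Write events to CSV
#' @param events an [event_train()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events$events, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature profile to CSV (`depth_um,value`)
#' @param p a [feature_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path) {
  utils::write.csv(data.frame(depth_um = profile_centers(p), value = p$values),
                   path, row.names = FALSE)
  invisible(path)
}
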