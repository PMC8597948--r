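#' Specification of a synthetic localization phantom
#'
#' Describes a fully self-contained miniature experiment with known ground
#' truth: a layered toy brain in a subject volume, smooth deformations into
#' an enlarged atlas-like space (`"CCF"`) and a near-undistorted template
#' space (`"MRI3D"`), dye-labelled probe tracks, region-dependent multiunit
#' activity with an out-of-brain segment, fluorescent projection blobs with
#' matched stimulus-evoked responses, and jittered landmark/anchor
#' annotations. Everything downstream of the seed is deterministic.
#'
#' The default geometry is a 200 x 200 x 300 voxel grid at 20 um (4 x 4 x
#' 6 mm), a deliberate miniature of a whole-brain volume, with planar layers:
#' cortex 0-1 mm below the surface, a white-matter band 1-1.2 mm, a
#' hippocampus-like block 1.2-2.2 mm, a thalamus-like block 2.2-3.4 mm and
#' brainstem below. The atlas space is globally enlarged by `ccf_scale`
#' (default 1.15, the typical enlargement of cleared/averaged templates
#' against the in vivo brain) plus a low-order smooth perturbation;
#' the template space is near-identity.
#'
#' @param dims grid dimensions (ML, DV, AP), default c(200, 200, 300).
#' @param spacing_um voxel spacing (um), default 20.
#' @param surface_dv_um DV coordinate of the (planar) brain surface.
#' @param ccf_scale,ccf_perturb_um atlas-space global scale and smooth
#'   perturbation amplitude (um).
#' @param mri_scale,mri_perturb_um template-space scale and perturbation.
#' @param n_penetrations number of probe penetrations.
#' @param insertion_depth_um range (um) of insertion depths (surface to tip).
#' @param max_tilt_deg maximum tilt of the insertion axis from vertical.
#' @param track_point_spacing_um spacing of annotated centerline points.
#' @param track_point_jitter_um annotation jitter sigma (um).
#' @param tip_smear_um sigma of the dye-tip depth error (um); emulates bright
#'   dye spreading beyond the tip or a dim tip.
#' @param n_landmarks landmarks per space pair.
#' @param landmark_jitter_um landmark placement jitter sigma (um).
#' @param anchor_depths_um electrophysiological landmark depths below the
#'   surface (um); 0 is the brain surface.
#' @param anchor_jitter_um anchor identification jitter sigma (um).
#' @param dye_sigma_um radial sigma of the rendered dye tube.
#' @param dye_tip_brightness brightness factor of the tip ball.
#' @param rates_hz,amplitudes_uV named per-label firing rate and unit
#'   amplitude (name "0" = outside the brain).
#' @param noise_sigma_uV in-brain raw noise sigma; out-of-brain noise is
#'   one third of it.
#' @param raw_duration_s duration of the rendered raw recording (first
#'   penetration only; event trains cover the full duration).
#' @param n_stims,stim_interval_s photostimulus count and spacing.
#' @param blob_depths_um projection-blob centre depths below the surface.
#' @param blob_sigma_um blob radial sigma (um).
#' @param blob_response_p peak per-stimulus response probability.
#' @param blob_latency_ms,latency_jitter_ms evoked latency and jitter.
#' @param evoked_window_ms response window used downstream.
#' @param seed RNG seed; same (spec, seed) gives bit-identical bundles.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(200L, 200L, 300L), spacing_um = c(20, 20, 20),
                         surface_dv_um = 400,
                         ccf_scale = 1.15, ccf_perturb_um = 120,
                         mri_scale = 1.0, mri_perturb_um = 10,
                         n_penetrations = 17L,
                         insertion_depth_um = c(3000, 3400),
                         max_tilt_deg = 8,
                         track_point_spacing_um = 200,
                         track_point_jitter_um = 20,
                         tip_smear_um = 100,
                         n_landmarks = 250L, landmark_jitter_um = 50,
                         anchor_depths_um = c(0, 2200),
                         anchor_jitter_um = 30,
                         dye_sigma_um = 40, dye_tip_brightness = 2,
                         rates_hz = c("0" = 0.2, "1" = 8, "2" = 1.5,
                                      "3" = 4, "4" = 15, "5" = 6),
                         amplitudes_uV = c("0" = 55, "1" = 120, "2" = 60,
                                           "3" = 150, "4" = 130, "5" = 100),
                         noise_sigma_uV = 12,
                         raw_duration_s = 2,
                         n_stims = 300L, stim_interval_s = 0.2,
                         blob_depths_um = c(1600, 2800), blob_sigma_um = 150,
                         blob_response_p = 0.6,
                         blob_latency_ms = 8, latency_jitter_ms = 0.3,
                         evoked_window_ms = c(5, 20),
                         seed = 7L) {
  spec <- as.list(environment())
  spec$dims <- as.integer(dims)
  if (any(spacing_um <= 0) || any(dims < 10))
    stop("invalid phantom grid")
  if (max(insertion_depth_um) + surface_dv_um > dims[2] * spacing_um[2])
    stop("insertion depth exceeds the grid's DV extent")
  jit <- c(track_point_jitter_um, tip_smear_um, landmark_jitter_um,
           anchor_jitter_um, latency_jitter_ms)
  if (any(jit < 0)) stop("jitter sigmas must be >= 0")
  spec$layers <- data.frame(
    label = 1:5,
    acronym = c("CTX", "WM", "HPC", "TH", "BS"),
    name = c("cortex-like layer", "white-matter band", "hippocampus-like block",
             "thalamus-like block", "brainstem-like block"),
    top_um = c(0, 1000, 1200, 2200, 3400),
    stringsAsFactors = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

#' Named phantom presets
#'
#' \describe{
#'   \item{`"exact"`}{no noise anywhere: zero jitters, zero tip smear and a
#'     pure-affine (scale-only) deformation, so landmark interpolation is
#'     exact and any residual error is pipeline arithmetic.}
#'   \item{`"realistic"`}{50 um landmark jitter, 30 um anchor jitter, 20 um
#'     track-point jitter, 100 um dye-tip smear, 15% atlas enlargement with a
#'     120 um smooth perturbation.}
#'   \item{`"hard"`}{the realistic preset with all noise sources doubled.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(name = c("exact", "realistic", "hard"), seed = 7L) {
  name <- match.arg(name)
  switch(name,
    exact = phantom_spec(ccf_perturb_um = 0, mri_perturb_um = 0,
                         track_point_jitter_um = 0, tip_smear_um = 0,
                         landmark_jitter_um = 0, anchor_jitter_um = 0,
                         latency_jitter_ms = 0, seed = seed),
    realistic = phantom_spec(seed = seed),
    hard = phantom_spec(ccf_perturb_um = 240, mri_perturb_um = 20,
                        track_point_jitter_um = 40, tip_smear_um = 200,
                        landmark_jitter_um = 100, anchor_jitter_um = 60,
                        noise_sigma_uV = 24, seed = seed))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}

# region label of subject-space points: planar layers below the surface
phantom_label_subject <- function(spec, pts) {
  depth <- pts[, 2] - spec$surface_dv_um
  lab <- findInterval(depth, c(spec$layers$top_um, Inf))
  lab[depth < 0] <- 0L
  lab[lab > nrow(spec$layers)] <- nrow(spec$layers)
  as.integer(lab)
}

phantom_map <- function(spec, which = c("ccf", "mri")) {
  which <- match.arg(which)
  ext <- spec$dims * spec$spacing_um
  if (which == "ccf") {
    dims_f <- as.integer(ceiling(spec$dims * max(1.2, spec$ccf_scale)))
    ext_f <- dims_f * spec$spacing_um
    poly_map(scale = spec$ccf_scale,
             center_moving = c(ext[1] / 2, 0, ext[3] / 2),
             center_fixed = c(ext_f[1] / 2, 0, ext_f[3] / 2),
             amp_um = spec$ccf_perturb_um,
             period_um = ext,
             moving_space = "subject", fixed_space = "CCF")
  } else {
    poly_map(scale = spec$mri_scale,
             center_moving = c(ext[1] / 2, 0, ext[3] / 2),
             center_fixed = c(ext[1] / 2, 0, ext[3] / 2),
             amp_um = spec$mri_perturb_um,
             period_um = ext * c(0.8, 1.1, 0.9),
             moving_space = "subject", fixed_space = "MRI3D")
  }
}

# label every voxel of the target grid by inverse-mapping its centre into
# the subject space; chunked over AP slabs to bound memory
phantom_annotation <- function(spec, map, dims_f, space) {
  sp <- spec$spacing_um
  lab <- array(0L, dims_f)
  xs <- (seq_len(dims_f[1]) - 1) * sp[1]
  ys <- (seq_len(dims_f[2]) - 1) * sp[2]
  slab <- max(1L, floor(2e6 / (dims_f[1] * dims_f[2])))
  k <- 1L
  while (k <= dims_f[3]) {
    kk <- k:min(dims_f[3], k + slab - 1L)
    zs <- (kk - 1) * sp[3]
    pts <- cbind(rep(xs, times = dims_f[2] * length(kk)),
                 rep(rep(ys, each = dims_f[1]), times = length(kk)),
                 rep(zs, each = dims_f[1] * dims_f[2]))
    sub <- if (map$amp == 0) {
      sweep(sweep(pts, 2, map$center_fixed, "-") / map$scale, 2,
            map$center_moving, "+")
    } else invert_points(map, pts, tol = 1e-6)
    lab[, , kk] <- phantom_label_subject(spec, sub)
    k <- kk[length(kk)] + 1L
  }
  annotation_volume(lab, sp, spec$layers[, c("label", "acronym", "name")],
                    space = space)
}

phantom_template <- function(spec, annot) {
  base <- c(5, 40, 90, 35, 50, 45)   # out + 5 layers, arbitrary a.u.
  tpl <- array(base[annot$data + 1L], dim(annot$data))
  volume3d(tpl, annot$spacing, annot$axis_order, annot$origin, annot$space)
}

# add a Gaussian tube along segment p0 -> p1 (plus a brighter smeared tip
# ball) into a subject-space array; only voxels near the segment are touched
render_tube <- function(arr, spacing, p0, p1, sigma, amp,
                        tip_brightness = 1, tip_sigma = sigma) {
  dm <- dim(arr)
  pad <- 4 * max(sigma, tip_sigma)
  lo <- pmax(floor((pmin(p0, p1) - pad) / spacing) + 1, 1)
  hi <- pmin(ceiling((pmax(p0, p1) + pad) / spacing) + 1, dm)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- (ii - 1) * spacing[1]; ys <- (jj - 1) * spacing[2]
  zs <- (kk - 1) * spacing[3]
  pts <- cbind(rep(xs, times = length(jj) * length(kk)),
               rep(rep(ys, each = length(ii)), times = length(kk)),
               rep(zs, each = length(ii) * length(jj)))
  u <- (p1 - p0); L <- sqrt(sum(u^2)); u <- u / L
  rel <- sweep(pts, 2, p0)
  t <- pmin(pmax(rel %*% u, 0), L)
  d2 <- rowSums(rel^2) - t^2
  add <- amp * exp(-pmax(d2, 0) / (2 * sigma^2))
  if (tip_brightness > 1) {
    d2tip <- rowSums(sweep(pts, 2, p1)^2)
    add <- add + amp * (tip_brightness - 1) * exp(-d2tip / (2 * tip_sigma^2))
  }
  arr[ii, jj, kk] <- arr[ii, jj, kk] + array(add, c(length(ii), length(jj),
                                                    length(kk)))
  arr
}

render_ball <- function(arr, spacing, center, sigma, amp) {
  dm <- dim(arr)
  pad <- 4 * sigma
  lo <- pmax(floor((center - pad) / spacing) + 1, 1)
  hi <- pmin(ceiling((center + pad) / spacing) + 1, dm)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- (ii - 1) * spacing[1] - center[1]
  ys <- (jj - 1) * spacing[2] - center[2]
  zs <- (kk - 1) * spacing[3] - center[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  arr[ii, jj, kk] <- arr[ii, jj, kk] + amp * exp(-d2 / (2 * sigma^2))
  arr
}

#' Generate a synthetic phantom bundle
#'
#' Builds every artefact of a miniature localization experiment from a
#' [phantom_spec()]: layered annotation + template volumes in the enlarged
#' atlas space and the near-undistorted template space, the subject volume
#' (region-dependent autofluorescence plus dye tubes with bright smeared
#' tips), the projection (eYFP-like) volume with Gaussian blobs on each true
#' track, jittered landmark sets into both spaces, per-penetration annotated
#' centerline points, ground-truth geometry, full-duration multiunit event
#' trains with stimulus-evoked responses at the blob depths, and a rendered
#' raw recording for the first penetration (with a low-noise out-of-brain
#' segment above the surface).
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_bundle`; see the fields in the source
#'   and the methods vignette.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sp <- spec$spacing_um
    ext <- spec$dims * sp
    map_ccf <- phantom_map(spec, "ccf")
    map_mri <- phantom_map(spec, "mri")
    dims_ccf <- as.integer(ceiling(spec$dims * max(1.2, spec$ccf_scale)))
    annot_ccf <- phantom_annotation(spec, map_ccf, dims_ccf, "CCF")
    annot_mri <- phantom_annotation(spec, map_mri, spec$dims, "MRI3D")

    # subject volume: label-dependent autofluorescence + noise
    xs <- (seq_len(spec$dims[1]) - 1) * sp[1]
    ys <- (seq_len(spec$dims[2]) - 1) * sp[2]
    depth_lab <- phantom_label_subject(
      spec, cbind(0, ys, 0))          # planar layers: label depends on DV only
    base <- c(5, 40, 90, 35, 50, 45)
    subj <- array(rep(base[depth_lab + 1L], each = spec$dims[1]),
                  spec$dims)
    subj <- subj + array(stats::rnorm(prod(spec$dims), 0, 2), spec$dims)

    # penetrations
    np <- spec$n_penetrations
    ml <- ext[1] * stats::runif(np, 0.3, 0.7)
    ap <- ext[3] * stats::runif(np, 0.25, 0.75)
    tilt <- spec$max_tilt_deg * pi / 180 * stats::runif(np)
    azim <- stats::runif(np, 0, 2 * pi)
    depth <- stats::runif(np, spec$insertion_depth_um[1],
                          spec$insertion_depth_um[2])
    n_rows <- 192L
    row_depth <- (seq_len(n_rows) - 1) * 20
    pens <- vector("list", np)
    proj <- array(0, spec$dims)
    stim_times <- 0.5 + (seq_len(spec$n_stims) - 1) * spec$stim_interval_s
    duration <- max(stim_times) + 0.5
    for (i in seq_len(np)) {
      dir <- c(sin(tilt[i]) * cos(azim[i]), cos(tilt[i]),
               sin(tilt[i]) * sin(azim[i]))
      entry <- c(ml[i], spec$surface_dv_um, ap[i])
      tip <- entry + dir * depth[i]
      # dye tube into the subject volume
      subj <- render_tube(subj, sp, entry, tip, spec$dye_sigma_um, 60,
                          tip_brightness = spec$dye_tip_brightness,
                          tip_sigma = spec$dye_sigma_um +
                            spec$tip_smear_um / 2)
      # projection blobs on the true track
      for (b in spec$blob_depths_um)
        proj <- render_ball(proj, sp, entry + dir * b, spec$blob_sigma_um, 1)
      # annotated centerline points with jitter; tip depth error ~ tip smear
      tip_err <- stats::rnorm(1, 0, spec$tip_smear_um)
      for (try in 1:20) {
        tip_est <- depth[i] + tip_err
        # a dim tip ends the visible dye early: drop points beyond it
        s_ann <- seq(0, depth[i], by = spec$track_point_spacing_um)
        s_ann <- s_ann[s_ann < tip_est - spec$track_point_spacing_um / 4]
        s_ann <- c(s_ann, tip_est)
        pts <- sweep(s_ann %o% dir, 2, entry, "+") +
          matrix(stats::rnorm(3 * length(s_ann), 0,
                              spec$track_point_jitter_um), ncol = 3)
        ann <- tryCatch(track_annotation(pts, space = "subject",
                                         penetration_id = sprintf("pen%02d", i),
                                         manipulator_depth_mm = depth[i] / 1000),
                        error = function(e) NULL)
        if (!is.null(ann)) break
      }
      if (is.null(ann)) stop("could not draw a monotone track annotation")
      # anchor jitters (shared between target spaces)
      n_anch <- length(spec$anchor_depths_um)
      anch_jit_probe <- stats::rnorm(n_anch, 0, spec$anchor_jitter_um)
      anch_jit_track <- stats::rnorm(n_anch, 0, spec$anchor_jitter_um)
      # multiunit events over the full duration
      ch_sub_depth <- depth[i] - row_depth        # depth below surface
      lab <- phantom_label_subject(
        spec, cbind(0, spec$surface_dv_um + ch_sub_depth, 0))
      rate <- unname(spec$rates_hz[as.character(lab)])
      ampm <- unname(spec$amplitudes_uV[as.character(lab)])
      ev <- vector("list", n_rows)
      for (ch in seq_len(n_rows)) {
        n_bg <- stats::rpois(1, rate[ch] * duration)
        tt <- stats::runif(n_bg, 0, duration)
        aa <- -pmax(ampm[ch] * stats::runif(n_bg, 0.8, 1.5), 51)
        # evoked component at the blob depths
        for (b in spec$blob_depths_um) {
          w <- exp(-(ch_sub_depth[ch] - b)^2 / (2 * spec$blob_sigma_um^2))
          p <- spec$blob_response_p * w
          if (p > 0.005) {
            hit <- stats::runif(spec$n_stims) < p
            if (any(hit)) {
              te <- stim_times[hit] + spec$blob_latency_ms / 1000 +
                stats::rnorm(sum(hit), 0, spec$latency_jitter_ms / 1000)
              tt <- c(tt, te)
              aa <- c(aa, -pmax(ampm[ch] * stats::runif(sum(hit), 0.8, 1.5), 51))
            }
          }
        }
        if (length(tt))
          ev[[ch]] <- data.frame(channel = ch, time_s = tt, amplitude_uV = aa)
      }
      ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
      ev <- ev[order(ev$channel, ev$time_s), ]
      rownames(ev) <- NULL
      pens[[i]] <- list(
        id = sprintf("pen%02d", i), entry_um = entry, direction = dir,
        insertion_depth_um = depth[i], manipulator_depth_mm = depth[i] / 1000,
        tip_error_um = tip_err, annotation = ann,
        anchor_depths_um = spec$anchor_depths_um,
        anchor_jit_probe_um = anch_jit_probe,
        anchor_jit_track_um = anch_jit_track,
        blob_depths_um = spec$blob_depths_um,
        events = event_train(ev, threshold_uV = -50, dead_time_ms = 1,
                             duration_s = duration,
                             channel_depth_um = row_depth),
        stim_times_s = stim_times)
    }

    recording <- phantom_raw_recording(spec, pens[[1]], row_depth, stim_times)

    structure(list(
      spec = spec,
      region_table = spec$layers[, c("label", "acronym", "name")],
      maps = list(CCF = map_ccf, MRI3D = map_mri),
      atlas = list(
        CCF = list(annot = annot_ccf, template = phantom_template(spec, annot_ccf)),
        MRI3D = list(annot = annot_mri, template = phantom_template(spec, annot_mri))),
      landmarks = list(
        CCF = phantom_landmarks(spec, map_ccf),
        MRI3D = phantom_landmarks(spec, map_mri)),
      subject_volume = volume3d(subj, sp, space = "subject"),
      projection_volume = volume3d(proj, sp, space = "subject"),
      penetrations = pens,
      recording = recording),
      class = "phantom_bundle")
  })
}

phantom_landmarks <- function(spec, map) {
  ext <- spec$dims * spec$spacing_um
  n <- spec$n_landmarks
  mv <- cbind(stats::runif(n, 0.1 * ext[1], 0.9 * ext[1]),
              stats::runif(n, spec$surface_dv_um, 0.95 * ext[2]),
              stats::runif(n, 0.1 * ext[3], 0.9 * ext[3]))
  fx <- apply_transform(map, mv) +
    matrix(stats::rnorm(3 * n, 0, spec$landmark_jitter_um), ncol = 3)
  landmark_set(mv, fx, moving_space = "subject", fixed_space = map$fixed_space)
}

# render a short raw int16 recording for one penetration: Gaussian noise
# (lower above the brain surface), background spikes at the region rates and
# evoked spikes, as biphasic templates at 30 kHz
phantom_raw_recording <- function(spec, pen, row_depth, stim_times) {
  fs <- 30000
  n_t <- round(spec$raw_duration_s * fs)
  n_ch <- length(row_depth)
  ch_sub_depth <- pen$insertion_depth_um - row_depth
  lab <- phantom_label_subject(
    spec, cbind(0, spec$surface_dv_um + ch_sub_depth, 0))
  rate <- unname(spec$rates_hz[as.character(lab)])
  ampm <- unname(spec$amplitudes_uV[as.character(lab)])
  sig <- ifelse(lab == 0L, spec$noise_sigma_uV / 3, spec$noise_sigma_uV)
  tpl <- c(-0.25, -0.6, -1, -0.7, -0.3, 0.15, 0.25, 0.15, 0.05)
  x <- matrix(stats::rnorm(n_ch * n_t), n_ch) * sig
  stim_in <- stim_times[stim_times < spec$raw_duration_s - 0.05]
  for (ch in seq_len(n_ch)) {
    n_bg <- stats::rpois(1, rate[ch] * spec$raw_duration_s)
    tt <- stats::runif(n_bg, 0, spec$raw_duration_s - 0.001)
    for (b in spec$blob_depths_um) {
      w <- exp(-(ch_sub_depth[ch] - b)^2 / (2 * spec$blob_sigma_um^2))
      p <- spec$blob_response_p * w
      if (p > 0.005 && length(stim_in)) {
        hit <- stats::runif(length(stim_in)) < p
        tt <- c(tt, stim_in[hit] + spec$blob_latency_ms / 1000)
      }
    }
    if (length(tt)) {
      amp <- pmax(ampm[ch] * stats::runif(length(tt), 0.8, 1.5), 55)
      i0 <- round(tt * fs) + 1L
      for (j in seq_along(i0)) {
        idx <- i0[j]:min(n_t, i0[j] + length(tpl) - 1L)
        x[ch, idx] <- x[ch, idx] + amp[j] * tpl[seq_along(idx)]
      }
    }
  }
  uv_bit <- 0.195
  raw_recording(matrix(as.integer(round(x / uv_bit)), n_ch), fs, uv_bit,
                row_depth)
}

#' Ground-truth electrode positions of a phantom penetration
#'
#' Positions the probe physically occupies on the true (noise-free) track:
#' site at shank depth `d` sits `insertion_depth - tip_offset - d` below the
#' surface along the insertion axis. Sites above the surface are flagged.
#'
#' @param bundle a [make_phantom()] bundle.
#' @param pen_index penetration index.
#' @param geom a [probe_geometry()], default Neuropixels 1.0.
#' @param banks banks to include, default 1.
#' @return data.frame `site`, `shank_depth_um`, `x_um,y_um,z_um` (subject
#'   space), `depth_below_surface_um`, `in_brain`.
#' @export
true_site_positions <- function(bundle, pen_index, geom = neuropixels_1_0(),
                                banks = 1L) {
  pen <- bundle$penetrations[[pen_index]]
  sel <- which(geom$banks %in% banks)
  d <- geom$site_depth_um[sel]
  below <- pen$insertion_depth_um - geom$tip_offset_um - d
  pos <- sweep(below %o% pen$direction, 2, pen$entry_um, "+")
  data.frame(site = sel, shank_depth_um = d,
             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
             depth_below_surface_um = below, in_brain = below >= 0)
}

#' Write a phantom bundle to disk in the package's exchange formats
#'
#' Volumes as NRRD, region table / landmarks / track points / events / stim
#' times as CSV, the raw recording as flat binary int16 + JSON.
#'
#' @param bundle a [make_phantom()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_volume(bundle$subject_volume, p("subject.nrrd"))
  write_volume(bundle$projection_volume, p("projection.nrrd"))
  for (s in names(bundle$atlas)) {
    write_volume(bundle$atlas[[s]]$annot, p(sprintf("annot_%s.nrrd", s)))
    write_volume(bundle$atlas[[s]]$template, p(sprintf("template_%s.nrrd", s)))
    write_landmarks_csv(bundle$landmarks[[s]],
                        p(sprintf("landmarks_subject2%s.csv", s)))
  }
  utils::write.csv(bundle$region_table, p("regions.csv"), row.names = FALSE)
  tracks <- do.call(rbind, lapply(bundle$penetrations, function(pen)
    data.frame(penetration_id = pen$id,
               order = seq_len(nrow(pen$annotation$points)),
               x_um = pen$annotation$points[, 1],
               y_um = pen$annotation$points[, 2],
               z_um = pen$annotation$points[, 3])))
  utils::write.csv(tracks, p("tracks.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(space = "subject",
         manipulator_depth_mm = stats::setNames(
           lapply(bundle$penetrations, `[[`, "manipulator_depth_mm"),
           vapply(bundle$penetrations, `[[`, "", "id"))),
    p("tracks.csv.json"), auto_unbox = TRUE, digits = NA)
  for (pen in bundle$penetrations)
    write_events_csv(pen$events, p(sprintf("events_%s.csv", pen$id)))
  utils::write.csv(data.frame(time_s = bundle$penetrations[[1]]$stim_times_s),
                   p("stims.csv"), row.names = FALSE)
  write_recording_bin(bundle$recording, p("raw_pen01.bin"))
  invisible(dir)
}
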