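#' Arc length of the track point nearest to a 3D point
#'
#' @param track a `probe_track`.
#' @param point_um micron coordinate in the track's space.
#' @return entry-based arc length (um) of the nearest dense sample.
#' @export
nearest_arclength <- function(track, point_um) {
  d2 <- rowSums(sweep(track$samples, 2, as.numeric(point_um))^2)
  track$arclength[which.min(d2)]
}

#' Localize one phantom penetration in a target space
#'
#' Runs the full localization workflow on a phantom penetration: fit (or
#' reuse) the landmark TPS into the target space, build the track from the
#' annotated centerline points and project it, place electrodes from the dye
#' tip, convert the penetration's electrophysiological landmarks into
#' anchors (their stored jitters emulate manual landmark identification),
#' re-anchor the electrodes, and assign atlas regions.
#'
#' @param bundle a [make_phantom()] bundle.
#' @param pen_index penetration index.
#' @param space `"MRI3D"` (default; the near-undistorted template space, the
#'   recommended workflow) or `"CCF"` (direct placement in the enlarged atlas
#'   space).
#' @param geom a [probe_geometry()].
#' @param banks banks to localize.
#' @param tps optional pre-fitted TPS for the space (saves refitting when
#'   localizing many penetrations).
#' @param anchored use electrophysiological anchors (default TRUE); FALSE
#'   stops after the raw tip placement.
#' @return list with `localization` (an `electrode_localization`), `track`
#'   (projected `probe_track`), `anchors`, `surface_arclength_um` and
#'   `tip_vs_manipulator_mm`.
#' @export
localize_penetration <- function(bundle, pen_index, space = c("MRI3D", "CCF"),
                                 geom = neuropixels_1_0(), banks = 1L,
                                 tps = NULL, anchored = TRUE) {
  space <- match.arg(space)
  pen <- bundle$penetrations[[pen_index]]
  if (is.null(tps)) tps <- fit_tps(bundle$landmarks[[space]])
  track_t <- project_track(build_track(pen$annotation), tps)
  placement <- place_from_tip(track_t, geom, banks = banks)
  # anchors: true landmark points identified on the reconstructed track,
  # displaced by the penetration's stored anchor jitters
  a_depth <- pen$anchor_depths_um
  probe_d <- pen$insertion_depth_um - a_depth + pen$anchor_jit_probe_um
  s_entry <- vapply(seq_along(a_depth), function(j) {
    p_sub <- pen$entry_um + pen$direction * a_depth[j]
    nearest_arclength(track_t, apply_transform(tps, p_sub))
  }, numeric(1))
  anchors <- ephys_anchor(probe_d,
                          tipward(track_t, s_entry) + pen$anchor_jit_track_um,
                          label = c("surface", paste0("lm",
                                    seq_along(a_depth)[-1]))[seq_along(a_depth)])
  annot <- bundle$atlas[[space]]$annot
  loc <- if (anchored) anchor_electrodes(placement, anchors, annot = annot)
         else assign_regions(placement, annot)
  surf_s <- s_entry[which.min(a_depth)]
  list(localization = loc, track = track_t, anchors = anchors,
       surface_arclength_um = surf_s,
       tip_vs_manipulator_mm = tip_vs_manipulator(track_t, surf_s,
                                                  pen$manipulator_depth_mm))
}

#' Groundtruth accuracy assessment over a phantom bundle
#'
#' For every penetration: localize the electrodes in the target space,
#' sample the projection (eYFP-like) volume along the localized sites (via
#' the fitted inverse TPS back into the subject volume), compute the
#' stimulus-evoked multiunit profile, fit `K`-term Gaussian models to both,
#' match peaks, and summarize the per-penetration mean absolute
#' peak-location differences. Also audits the reconstructed tip depth
#' against the manipulator reading in the chosen space.
#'
#' @param bundle a [make_phantom()] bundle.
#' @param space `"MRI3D"` (default) or `"CCF"`.
#' @param geom a [probe_geometry()].
#' @param K Gaussian components per profile; defaults to the phantom's blob
#'   count.
#' @param pen_indices penetrations to include (default all).
#' @return list with `accuracy` (an [accuracy_summary()] result),
#'   `per_penetration` data.frame (id, mean |diff| mm, n matched pairs, tip
#'   audit mm), and `details` per penetration (fits and matches).
#' @export
groundtruth_assessment <- function(bundle, space = c("MRI3D", "CCF"),
                                   geom = neuropixels_1_0(), K = NULL,
                                   pen_indices = seq_along(bundle$penetrations)) {
  space <- match.arg(space)
  spec <- bundle$spec
  if (is.null(K)) K <- length(spec$blob_depths_um)
  tps <- fit_tps(bundle$landmarks[[space]])
  inv_tps <- invert_transform(bundle$landmarks[[space]])
  diffs <- tips <- numeric(0)
  ids <- character(0); npairs <- integer(0)
  details <- list()
  for (i in pen_indices) {
    pen <- bundle$penetrations[[i]]
    lp <- localize_penetration(bundle, i, space, geom, tps = tps)
    fluor <- fluorescence_profile(bundle$projection_volume, lp$localization,
                                  transform_to_vol = inv_tps)
    ev <- evoked_profile(pen$events, pen$stim_times_s,
                         window_ms = spec$evoked_window_ms)
    fit_f <- fit_multigauss(fluor, K)
    fit_e <- fit_multigauss(ev$profile, K)
    mp <- match_peaks(fit_f, fit_e)
    diffs <- c(diffs, mean(mp$pairs$abs_diff_mm))
    tips <- c(tips, lp$tip_vs_manipulator_mm)
    ids <- c(ids, pen$id); npairs <- c(npairs, nrow(mp$pairs))
    details[[pen$id]] <- list(fluor_fit = fit_f, evoked_fit = fit_e,
                              matches = mp, localization = lp$localization)
  }
  list(accuracy = accuracy_summary(diffs),
       per_penetration = data.frame(id = ids, mean_abs_diff_mm = diffs,
                                    n_pairs = npairs,
                                    tip_vs_manipulator_mm = tips,
                                    stringsAsFactors = FALSE),
       space = space, details = details)
}
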