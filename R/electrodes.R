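#' Probe site geometry
#'
#' Describes where each recording site sits along the shank: `site_depth_um`
#' is the distance from the probe-tip reference to the site's row (row 1 at
#' the tip reference), `tip_offset_um` the distance from the physical tip to
#' the first site row (0 by default; real probes have a tip taper), and
#' `banks` the bank index of each site.
#'
#' @param site_depth_um per-site distance from the tip reference (um),
#'   non-negative and non-decreasing.
#' @param sites_per_row sites sharing one row depth.
#' @param row_pitch_um row spacing (um).
#' @param banks integer bank index per site.
#' @param tip_offset_um physical tip to first row distance (um).
#' @param name geometry tag.
#' @return object of class `probe_geometry`.
#' @export
probe_geometry <- function(site_depth_um, sites_per_row, row_pitch_um, banks,
                           tip_offset_um = 0, name = "custom") {
  if (any(site_depth_um < 0) || any(diff(site_depth_um) < 0))
    stop("site depths must be non-negative and non-decreasing")
  if (length(banks) != length(site_depth_um)) stop("banks length mismatch")
  structure(list(site_depth_um = as.numeric(site_depth_um),
                 sites_per_row = sites_per_row, row_pitch_um = row_pitch_um,
                 banks = as.integer(banks), tip_offset_um = tip_offset_um,
                 name = name),
            class = "probe_geometry")
}

#' Neuropixels 1.0 factory geometry
#'
#' 960 sites in 480 rows of 2 at 20 um row pitch (9.6 mm full span), grouped
#' from the tip into banks of 384, 384 and 192 sites; the first bank spans
#' 3.84 mm from the tip.
#'
#' @param tip_offset_um physical tip to first row distance (default 0).
#' @return a [probe_geometry()].
#' @export
neuropixels_1_0 <- function(tip_offset_um = 0) {
  n <- 960L
  rows <- rep(seq_len(n / 2L), each = 2L)
  banks <- rep(c(1L, 2L, 3L), times = c(384L, 384L, 192L))
  probe_geometry(site_depth_um = (rows - 1) * 20,
                 sites_per_row = 2L, row_pitch_um = 20,
                 banks = banks, tip_offset_um = tip_offset_um,
                 name = "neuropixels-1.0")
}

#' Shank span of a bank (or of the full array) in mm
#' @param geom a [probe_geometry()].
#' @param bank bank index, or `NULL` for the full array.
#' @return span in mm (number of rows times the row pitch).
#' @export
bank_span_mm <- function(geom, bank = NULL) {
  sel <- if (is.null(bank)) rep(TRUE, length(geom$banks)) else geom$banks == bank
  n_rows <- length(unique(geom$site_depth_um[sel]))
  n_rows * geom$row_pitch_um / 1000
}

#' Place electrodes along a track starting at the dye tip
#'
#' Each site is assigned the track arc length
#' `tip_arclength - tip_offset - site_depth`, i.e. electrodes are laid out
#' from the end of the reconstructed track using the known interelectrode
#' spacing. Sites landing at negative arc length sit above the track start
#' and are flagged out-of-volume.
#'
#' @param track a `probe_track` (its last point is the tip estimate).
#' @param geom a [probe_geometry()].
#' @param banks bank indices to localize (default 1, the tip bank).
#' @param annot optional `annotation_volume` in the track's space for region
#'   assignment.
#' @return an `electrode_localization`: data.frame `sites` with per-site
#'   `site`, `bank`, `shank_depth_um`, `arclength_um`, `x_um`,`y_um`,`z_um`,
#'   `extrapolated`, `out_of_volume` (+ `region` when `annot` given), plus
#'   attributes `space`, `method`, `segment_scaling`.
#' @export
place_from_tip <- function(track, geom, banks = 1L, annot = NULL) {
  sel <- which(geom$banks %in% banks)
  depth <- geom$site_depth_um[sel]
  arc <- track$tip_arclength - geom$tip_offset_um - depth
  loc <- point_at_arclength(track, arc)
  sites <- data.frame(site = sel, bank = geom$banks[sel],
                      shank_depth_um = depth, arclength_um = arc,
                      x_um = loc$points[, 1], y_um = loc$points[, 2],
                      z_um = loc$points[, 3],
                      extrapolated = loc$extrapolated,
                      out_of_volume = arc < 0)
  electrode_localization(sites, track, method = "raw")
}

electrode_localization <- function(sites, track, method, segment_scaling = NULL) {
  structure(list(sites = sites, track = track, space = track$space,
                 method = method, segment_scaling = segment_scaling),
            class = "electrode_localization")
}

#' @export
print.electrode_localization <- function(x, ...) {
  cat(sprintf("<electrode_localization> %d sites on '%s' in %s (method: %s)\n",
              nrow(x$sites), x$track$penetration_id, x$space, x$method))
  invisible(x)
}

#' Region-boundary crossings along a track
#'
#' Walks the densely sampled track through an annotation volume and reports
#' every change of region label, ordered by arc length — the candidate anchor
#' targets (the first `outside -> region` crossing is the brain surface).
#'
#' @param track a `probe_track` in `annot`'s space.
#' @param annot an `annotation_volume`.
#' @return data.frame `arclength_um`, `label_before`, `label_after` (possibly
#'   0 rows for a single-region track).
#' @export
boundary_positions <- function(track, annot) {
  if (!identical(track$space, annot$space))
    stop(sprintf("track in '%s' but annotation in '%s'", track$space, annot$space))
  lab <- lookup_region(annot, track$samples)
  chg <- which(diff(lab) != 0L)
  data.frame(arclength_um = (track$arclength[chg] + track$arclength[chg + 1L]) / 2,
             label_before = lab[chg], label_after = lab[chg + 1L])
}

#' Electrophysiological anchor
#'
#' Ties a position on the shank to a position on the reconstructed track.
#' Both coordinates are measured from the tip end: `probe_depth_um` is the
#' distance from the probe tip along the shank of the anchored feature, and
#' `track_tipward_um` the distance along the track from the dye-tip end
#' toward the brain surface. For an anchor known at entry-based arc length
#' `s`, `track_tipward_um = tip_arclength - s` (see [tipward()]).
#'
#' @param probe_depth_um distance from tip along the shank (um).
#' @param track_tipward_um matched distance from the track tip (um).
#' @param label landmark tag (e.g. `"surface"`, `"HPC/TH"`).
#' @return data.frame of class `ephys_anchor` rows.
#' @export
ephys_anchor <- function(probe_depth_um, track_tipward_um, label = NA_character_) {
  if (any(probe_depth_um < 0))
    stop("anchor coordinates must be non-negative")
  structure(data.frame(probe_depth_um = as.numeric(probe_depth_um),
                       track_tipward_um = as.numeric(track_tipward_um),
                       label = rep_len(label, length(probe_depth_um)),
                       stringsAsFactors = FALSE),
            class = c("ephys_anchor", "data.frame"))
}

#' Convert entry-based arc length to tipward distance
#' @param track a `probe_track`.
#' @param s_um entry-based arc length (um).
#' @return distance from the track tip (um).
#' @export
tipward <- function(track, s_um) track$tip_arclength - s_um

#' Per-segment anchor scaling factors
#'
#' Track-distance per shank-distance between consecutive anchors; the mean
#' factor can be reused as `fallback_scale` for single-anchor penetrations in
#' the same brain.
#'
#' @param anchors an [ephys_anchor()] table (>= 2 rows, distinct depths).
#' @return list with `factors` (per consecutive pair) and `mean_factor`.
#' @export
scaling_factors <- function(anchors) {
  a <- anchors[order(anchors$probe_depth_um), ]
  if (nrow(a) < 2L) stop("need >= 2 anchors to compute scaling factors")
  dd <- diff(a$probe_depth_um); ds <- diff(a$track_tipward_um)
  if (any(dd == 0)) stop("duplicate anchor probe depths")
  f <- ds / dd
  if (any(f <= 0)) {
    bad <- which(f <= 0)[1]
    stop(sprintf(
      "anchors %d and %d are in reversed track order (scaling factor %.3g <= 0)",
      bad, bad + 1L, f[bad]))
  }
  list(factors = f, mean_factor = mean(f))
}

#' Anchor electrodes to electrophysiological landmarks
#'
#' Piecewise-linear remapping of shank depth to track position: between two
#' consecutive anchors the interelectrode distances are scaled by a common
#' factor so that each anchored electrode sits exactly at its landmark;
#' outside the anchor range the nearest segment's factor extrapolates the
#' mapping. With a single anchor, `fallback_scale` (e.g. the mean factor from
#' sibling penetrations in the same brain, see [scaling_factors()]) is
#' applied around it.
#'
#' @param placement an `electrode_localization` (typically from
#'   [place_from_tip()]).
#' @param anchors an [ephys_anchor()] table sorted by (or sortable to)
#'   increasing probe depth, distinct depths, >= 1 row.
#' @param fallback_scale scaling factor used when only one anchor is given.
#' @param annot optional `annotation_volume` for region reassignment.
#' @return a re-anchored `electrode_localization` (method `"anchored"` or
#'   `"single-anchor"`), with per-segment factors in `$segment_scaling`.
#' @export
anchor_electrodes <- function(placement, anchors, fallback_scale = NULL,
                              annot = NULL) {
  stopifnot(inherits(placement, "electrode_localization"))
  if (nrow(anchors) < 1L)
    stop("no anchors given; use place_from_tip() output directly instead")
  a <- anchors[order(anchors$probe_depth_um), ]
  if (anyDuplicated(a$probe_depth_um)) stop("duplicate anchor probe depths")
  d <- placement$sites$shank_depth_um
  if (nrow(a) == 1L) {
    if (is.null(fallback_scale))
      stop("single anchor requires a fallback_scale (e.g. the mean scaling ",
           "factor from sibling penetrations)")
    s_tip <- a$track_tipward_um[1] + (d - a$probe_depth_um[1]) * fallback_scale
    seg <- fallback_scale
    method <- "single-anchor"
  } else {
    sf <- scaling_factors(a)   # also validates ordering
    nd <- nrow(a)
    # segment index for each site: nearest segment outside the anchor range
    k <- findInterval(d, a$probe_depth_um, rightmost.closed = FALSE)
    k <- pmin(pmax(k, 1L), nd - 1L)
    s_tip <- a$track_tipward_um[k] +
      (d - a$probe_depth_um[k]) * sf$factors[k]
    seg <- sf$factors
    method <- "anchored"
  }
  tr <- placement$track
  arc <- tr$tip_arclength - s_tip
  loc <- point_at_arclength(tr, arc)
  sites <- placement$sites
  sites$arclength_um <- arc
  sites$x_um <- loc$points[, 1]; sites$y_um <- loc$points[, 2]
  sites$z_um <- loc$points[, 3]
  sites$extrapolated <- loc$extrapolated
  sites$out_of_volume <- arc < 0
  out <- electrode_localization(sites, tr, method, segment_scaling = seg)
  if (!is.null(annot)) out <- assign_regions(out, annot)
  out
}

#' Assign atlas regions to localized electrodes
#'
#' Optionally maps site coordinates into the annotation's space first, then
#' labels every site by nearest-voxel lookup and summarizes contiguous runs
#' of equal labels as a per-probe region table.
#'
#' @param placement an `electrode_localization`.
#' @param annot an `annotation_volume`.
#' @param transform_to_annot optional transform from the placement's space to
#'   `annot`'s space (omit when they already agree).
#' @return the placement with a `region` column and attribute
#'   `region_runs` (data.frame label, acronym, first site, last site, depth
#'   range on the shank).
#' @export
assign_regions <- function(placement, annot, transform_to_annot = NULL) {
  pts <- as.matrix(placement$sites[, c("x_um", "y_um", "z_um")])
  if (!is.null(transform_to_annot)) {
    if (!identical(placement$space, transform_to_annot$moving_space))
      stop(sprintf("placement in '%s' but transform maps from '%s'",
                   placement$space, transform_to_annot$moving_space))
    if (!identical(transform_to_annot$fixed_space, annot$space))
      stop(sprintf("transform lands in '%s' but annotation is in '%s'",
                   transform_to_annot$fixed_space, annot$space))
    pts <- apply_transform(transform_to_annot, pts)
  } else if (!identical(placement$space, annot$space)) {
    stop(sprintf("placement in '%s' but annotation in '%s'; pass transform_to_annot",
                 placement$space, annot$space))
  }
  lab <- lookup_region(annot, pts)
  placement$sites$region <- lab
  ord <- order(placement$sites$shank_depth_um)
  r <- rle(lab[ord])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  placement$region_runs <- data.frame(
    label = r$values,
    acronym = region_info(annot, r$values)$acronym,
    from_site = placement$sites$site[ord][starts],
    to_site = placement$sites$site[ord][ends],
    from_depth_um = placement$sites$shank_depth_um[ord][starts],
    to_depth_um = placement$sites$shank_depth_um[ord][ends],
    stringsAsFactors = FALSE)
  placement
}

#' Read an anchor CSV (`penetration_id,probe_depth_um,track_tipward_um,label`)
#' @param path CSV path.
#' @return named list of [ephys_anchor()] tables, one per penetration.
#' @export
read_anchors_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("penetration_id", "probe_depth_um", "track_tipward_um")
  if (!all(need %in% names(d))) stop("anchor CSV lacks columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  lapply(split(d, d$penetration_id), function(dd)
    ephys_anchor(dd$probe_depth_um, dd$track_tipward_um,
                 dd$label %||% NA_character_))
}

#' Write per-site localization CSV
#'
#' Columns `site_id,shank_depth_um,arclength_um,x_um,y_um,z_um,space,
#' region_label,method` — one file per space.
#'
#' @param placement an `electrode_localization`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localization_csv <- function(placement, path) {
  s <- placement$sites
  utils::write.csv(data.frame(
    site_id = s$site, shank_depth_um = s$shank_depth_um,
    arclength_um = s$arclength_um, x_um = s$x_um, y_um = s$y_um, z_um = s$z_um,
    space = placement$space,
    region_label = if (is.null(s$region)) NA_integer_ else s$region,
    method = placement$method), path, row.names = FALSE)
  invisible(path)
}
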