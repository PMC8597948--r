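#' Manually annotated probe-track centerline points
#'
#' Ordered micron points along the dye-labelled probe track, from the brain
#' entry toward the tip (the last point is the tip estimate: the depth at
#' which dye fluorescence is no longer visible). Points must advance
#' monotonically along the first-to-last chord; violations indicate annotation
#' errors.
#'
#' @param points_um n x 3 matrix (n >= 2) of micron coordinates, entry first.
#' @param space space label.
#' @param penetration_id identifier.
#' @param manipulator_depth_mm optional micromanipulator insertion-depth
#'   reading (mm), used by [tip_vs_manipulator()].
#' @return object of class `track_annotation`.
#' @export
track_annotation <- function(points_um, space = "subject",
                             penetration_id = "pen1",
                             manipulator_depth_mm = NULL) {
  p <- as_points(points_um)
  if (nrow(p) < 2L) stop("track annotation needs >= 2 points")
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("consecutive annotated points coincide")
  chord <- p[nrow(p), ] - p[1, ]
  prog <- as.numeric(p %*% chord)
  if (any(diff(prog) <= 0))
    stop("annotated points do not advance monotonically along the insertion")
  structure(list(points = p, space = space, penetration_id = penetration_id,
                 manipulator_depth_mm = manipulator_depth_mm),
            class = "track_annotation")
}

#' Build an arc-length parametrized probe track
#'
#' Linearly interpolates the annotated centerline points and resamples the
#' polyline at `step_um`, keeping the final annotated point (the tip estimate)
#' as the exact last sample. Arc length is 0 at the brain-entry end and equals
#' the exact polyline length at the tip.
#'
#' @param ann a [track_annotation()].
#' @param step_um resampling step (um), default 1.
#' @return object of class `probe_track` with `samples` (n x 3 um),
#'   `arclength` (um), `tip_arclength`, `space`, `penetration_id`.
#' @export
build_track <- function(ann, step_um = 1) {
  stopifnot(inherits(ann, "track_annotation"))
  p <- ann$points
  cum <- c(0, unname(cumsum(sqrt(rowSums(diff(p)^2)))))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step_um)
  if (s[length(s)] < total) s <- c(s, total)
  samples <- cbind(stats::approx(cum, p[, 1], xout = s)$y,
                   stats::approx(cum, p[, 2], xout = s)$y,
                   stats::approx(cum, p[, 3], xout = s)$y)
  # recompute arc length of the resampled polyline; identical to s because
  # resampling subdivides straight segments
  structure(list(samples = samples, arclength = s, tip_arclength = total,
                 space = ann$space, penetration_id = ann$penetration_id,
                 manipulator_depth_mm = ann$manipulator_depth_mm),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("<probe_track> '%s' in %s: %.1f um over %d samples\n",
              x$penetration_id, x$space, x$tip_arclength, nrow(x$samples)))
  invisible(x)
}

#' Project a probe track into another space
#'
#' Maps the dense track samples through a transform and recomputes the arc
#' length in the target space. Warping does not preserve length: a track
#' projected into an enlarged atlas space is longer than in the subject.
#'
#' @param track a [build_track()] result (or a [track_annotation()], which is
#'   built with `step_um` first).
#' @param transform transform whose moving space matches the track's space.
#' @param step_um resampling step when `track` is an annotation.
#' @return a `probe_track` in the transform's fixed space.
#' @export
project_track <- function(track, transform, step_um = 1) {
  if (inherits(track, "track_annotation")) track <- build_track(track, step_um)
  stopifnot(inherits(track, "probe_track"))
  if (!identical(track$space, transform$moving_space))
    stop(sprintf("track is in space '%s' but transform maps from '%s'",
                 track$space, transform$moving_space))
  s2 <- apply_transform(transform, track$samples)
  arc <- c(0, cumsum(sqrt(rowSums(diff(s2)^2))))
  structure(list(samples = s2, arclength = arc,
                 tip_arclength = arc[length(arc)],
                 space = transform$fixed_space,
                 penetration_id = track$penetration_id,
                 manipulator_depth_mm = track$manipulator_depth_mm),
            class = "probe_track")
}

#' Point on a track at given arc length
#'
#' Linear interpolation between bracketing samples. Queries beyond the tip (or
#' before the entry) extend the terminal segment linearly and are flagged:
#' dye-tip estimates can be short, so anchoring may push electrodes past the
#' visible dye end.
#'
#' @param track a `probe_track`.
#' @param s_um arc-length positions (um), vectorized.
#' @return list with `points` (n x 3) and logical `extrapolated`.
#' @export
point_at_arclength <- function(track, s_um) {
  s <- as.numeric(s_um)
  arc <- track$arclength; P <- track$samples
  n <- nrow(P)
  ex_lo <- s < 0; ex_hi <- s > track$tip_arclength
  sc <- pmin(pmax(s, 0), track$tip_arclength)
  pts <- cbind(stats::approx(arc, P[, 1], xout = sc)$y,
               stats::approx(arc, P[, 2], xout = sc)$y,
               stats::approx(arc, P[, 3], xout = sc)$y)
  if (any(ex_hi)) {
    dirv <- P[n, ] - P[n - 1, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    pts[ex_hi, ] <- rep(P[n, ], each = sum(ex_hi)) +
      (s[ex_hi] - track$tip_arclength) %o% dirv
  }
  if (any(ex_lo)) {
    dirv <- P[2, ] - P[1, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    pts[ex_lo, ] <- rep(P[1, ], each = sum(ex_lo)) + s[ex_lo] %o% dirv
  }
  list(points = pts, extrapolated = ex_lo | ex_hi)
}

#' Audit histology tip depth against the micromanipulator reading
#'
#' Difference between the insertion depth implied by the reconstructed track
#' (tip arc length minus the arc length of the brain-surface crossing, in mm)
#' and the manipulator reading. Positive values mean the histology estimate is
#' deeper than the manipulator depth, the signature of probe localization in
#' an enlarged atlas space.
#'
#' @param track a `probe_track`.
#' @param surface_s_um arc length (um) of the brain-surface crossing.
#' @param manipulator_depth_mm manipulator reading (mm); defaults to the value
#'   carried by the track.
#' @return difference in mm.
#' @export
tip_vs_manipulator <- function(track, surface_s_um,
                               manipulator_depth_mm = track$manipulator_depth_mm) {
  if (is.null(manipulator_depth_mm))
    stop("no manipulator depth reading available")
  (track$tip_arclength - surface_s_um) / 1000 - manipulator_depth_mm
}

#' Read a track annotation CSV
#'
#' Columns `penetration_id,order,x_um,y_um,z_um`; an optional JSON sidecar
#' `<path>.json` supplies `space` and `manipulator_depth_mm` (either as
#' scalars or as per-penetration maps).
#'
#' @param path CSV path.
#' @return named list of [track_annotation()], one per penetration.
#' @export
read_track_annotation_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("penetration_id", "order", "x_um", "y_um", "z_um")
  if (!all(need %in% names(d))) stop("track CSV lacks columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else list()
  get1 <- function(x, id) if (is.null(x)) NULL else
    if (length(x) > 1 || !is.null(names(x))) x[[id]] else x
  out <- lapply(split(d, d$penetration_id), function(dd) {
    dd <- dd[order(dd$order), ]
    track_annotation(as.matrix(dd[, c("x_um", "y_um", "z_um")]),
                     space = get1(meta$space, dd$penetration_id[1]) %||% "subject",
                     penetration_id = dd$penetration_id[1],
                     manipulator_depth_mm = get1(meta$manipulator_depth_mm,
                                                 dd$penetration_id[1]))
  })
  out
}

#' Export a track as a JSON polyline with arc length
#' @param track a `probe_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_json <- function(track, path) {
  jsonlite::write_json(list(penetration_id = track$penetration_id,
                            space = track$space,
                            tip_arclength_um = track$tip_arclength,
                            arclength_um = track$arclength,
                            points_um = track$samples),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
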