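#' 3D image volume with anatomical metadata
#'
#' A `volume3d` wraps a 3D numeric array together with the per-axis voxel
#' spacing in micrometres, a fixed anatomical axis order, the micron offset of
#' the centre of voxel (1,1,1), and the name of the coordinate space the
#' volume lives in (e.g. `"subject"`, `"CCF"`, `"MRI3D"`).
#'
#' Voxel coordinates refer to voxel centres: voxel `(i,j,k)` (1-based) is
#' centred at `origin + (c(i,j,k) - 1) * spacing` micrometres and owns the
#' half-open box `[centre - spacing/2, centre + spacing/2)` on every axis, so
#' points on a voxel boundary deterministically belong to the higher-index
#' voxel.
#'
#' @param data 3D numeric or integer array.
#' @param spacing_um numeric length-3, micrometres per voxel on each axis;
#'   all strictly positive.
#' @param axis_order character length-3 axis tags, default `c("ML","DV","AP")`.
#' @param origin_um micron coordinate of the centre of voxel (1,1,1).
#' @param space name of the coordinate space.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing_um, axis_order = c("ML", "DV", "AP"),
                     origin_um = c(0, 0, 0), space = "subject") {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("`spacing_um` must be 3 positive numbers")
  if (length(axis_order) != 3L) stop("`axis_order` must have length 3")
  if (any(dim(data) < 1L)) stop("all data dimensions must be >= 1")
  structure(list(data = data, spacing = spacing_um,
                 axis_order = as.character(axis_order),
                 origin = as.numeric(origin_um), space = space),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s space '%s': %s voxels @ %s um (%s)\n",
              class(x)[1], paste(x$axis_order, collapse = "/"), x$space,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              if (is.null(x$region_table)) "intensity" else
                sprintf("%d regions", nrow(x$region_table))))
  invisible(x)
}

#' Annotation (region label) volume
#'
#' An integer-labelled `volume3d` carrying a region table. Label 0 is reserved
#' for "outside the brain" and must not appear in the region table; every
#' nonzero label present in the grid must.
#'
#' @inheritParams volume3d
#' @param labels 3D integer array of region labels.
#' @param region_table data.frame with columns `label`, `acronym`, `name`.
#' @return Object of class `c("annotation_volume", "volume3d")`.
#' @export
annotation_volume <- function(labels, spacing_um, region_table,
                              axis_order = c("ML", "DV", "AP"),
                              origin_um = c(0, 0, 0), space = "CCF") {
  v <- volume3d(labels, spacing_um, axis_order, origin_um, space)
  if (!all(c("label", "acronym", "name") %in% names(region_table)))
    stop("region_table needs columns label, acronym, name")
  region_table$label <- as.integer(region_table$label)
  if (any(region_table$label == 0L))
    stop("outside_label 0 must not appear in the region table")
  present <- unique(as.integer(labels))
  missing_lab <- setdiff(setdiff(present, 0L), region_table$label)
  if (length(missing_lab))
    stop("labels in grid but not in region_table: ",
         paste(missing_lab, collapse = ", "))
  v$region_table <- region_table
  v$outside_label <- 0L
  class(v) <- c("annotation_volume", class(v))
  v
}

#' Convert micron coordinates to (continuous) voxel indices
#'
#' @param vol a `volume3d`.
#' @param points_um n x 3 matrix of micron coordinates (a length-3 vector is
#'   treated as one point).
#' @return n x 3 matrix of continuous 1-based voxel indices; the nearest voxel
#'   is `floor(index + 0.5)`.
#' @export
micron_to_voxel <- function(vol, points_um) {
  p <- as_points(points_um)
  sweep(sweep(p, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' Convert 1-based voxel indices to micron coordinates of voxel centres
#'
#' @inheritParams micron_to_voxel
#' @param idx n x 3 matrix of (possibly fractional) 1-based voxel indices.
#' @return n x 3 matrix of micron coordinates.
#' @export
voxel_to_micron <- function(vol, idx) {
  p <- as_points(idx)
  sweep(sweep(p - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("points must be n x 3")
  storage.mode(p) <- "double"
  p
}

#' Look up the region label at micron coordinates
#'
#' Returns the label of the voxel owning each point under the half-open
#' voxel-ownership rule; points outside the grid's bounding box map to the
#' outside label (0).
#'
#' @param annot an `annotation_volume`.
#' @param points_um n x 3 matrix of micron coordinates in `annot`'s space.
#' @return integer vector of region labels.
#' @export
lookup_region <- function(annot, points_um) {
  stopifnot(inherits(annot, "annotation_volume"))
  idx <- floor(micron_to_voxel(annot, points_um) + 0.5)
  dm <- dim(annot$data)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
            idx[, 2] >= 1 & idx[, 2] <= dm[2] &
            idx[, 3] >= 1 & idx[, 3] <= dm[3]
  out <- rep.int(annot$outside_label, nrow(idx))
  if (any(inside))
    out[inside] <- annot$data[cbind(idx[inside, 1], idx[inside, 2], idx[inside, 3])]
  as.integer(out)
}

#' Region metadata for labels
#'
#' @param annot an `annotation_volume`.
#' @param labels integer labels.
#' @return data.frame with `label`, `acronym`, `name`; the outside label maps
#'   to acronym `"out"`.
#' @export
region_info <- function(annot, labels) {
  rt <- rbind(data.frame(label = annot$outside_label, acronym = "out",
                         name = "outside brain", stringsAsFactors = FALSE),
              annot$region_table[, c("label", "acronym", "name")])
  rt[match(as.integer(labels), rt$label), , drop = FALSE]
}

#' Downsample a volume by integer block-mean pooling
#'
#' Pools `factors[1] x factors[2] x factors[3]` blocks by their mean; trailing
#' partial blocks are averaged over the voxels available. Output spacing is
#' input spacing times the factors, and the origin moves to the centre of the
#' first block.
#'
#' @param vol a `volume3d`.
#' @param factors integer length-3 pooling factors, all >= 1.
#' @return a `volume3d` at the coarser resolution.
#' @export
downsample_volume <- function(vol, factors) {
  f <- factors
  if (length(f) != 3L || any(f < 1) || any(f != round(f)))
    stop("`factors` must be 3 positive integers")
  f <- as.integer(f)
  if (all(f == 1L)) return(vol)
  dm <- dim(vol$data)
  nd <- as.integer(ceiling(dm / f))
  # sum over blocks one axis at a time via rowsum on the unfolded array
  x <- vol$data
  cnt <- array(1, dm)
  pool_axis <- function(a, axis) {
    d <- dim(a)
    grp <- rep(seq_len(nd[axis]), each = f[axis], length.out = d[axis])
    ap <- aperm(a, c(axis, setdiff(1:3, axis)))
    m <- matrix(ap, nrow = d[axis])
    s <- rowsum(m, grp)
    out <- array(s, c(nd[axis], d[setdiff(1:3, axis)]))
    aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) { x <- pool_axis(x, ax); cnt <- pool_axis(cnt, ax) }
  new_origin <- vol$origin + (f - 1) / 2 * vol$spacing
  volume3d(x / cnt, vol$spacing * f, vol$axis_order, new_origin, vol$space)
}

#' Trilinear sampling of a volume at micron coordinates
#'
#' Samples the intensity at arbitrary micron points by trilinear interpolation
#' between the 8 surrounding voxel centres. Points outside the grid of voxel
#' centres return `fill`.
#'
#' @param vol a `volume3d`.
#' @param points_um n x 3 matrix of micron coordinates.
#' @param fill value for out-of-grid samples (default 0).
#' @return numeric vector of sampled intensities.
#' @export
sample_trilinear <- function(vol, points_um, fill = 0) {
  idx <- micron_to_voxel(vol, points_um)
  dm <- dim(vol$data)
  i0 <- floor(idx)
  frac <- idx - i0
  inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
            idx[, 2] >= 1 & idx[, 2] <= dm[2] &
            idx[, 3] >= 1 & idx[, 3] <= dm[3]
  out <- rep.int(as.numeric(fill), nrow(idx))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  fr <- frac[inside, , drop = FALSE]
  # clamp so that i0 and i0+1 are valid even exactly on the last centre
  for (a in 1:3) {
    hi <- i0[, a] >= dm[a]
    i0[hi, a] <- dm[a] - 1L
    fr[hi, a] <- 1
    lo <- i0[, a] < 1L        # point exactly at index 1 gives i0 = 1, fine;
    i0[lo, a] <- 1L           # guard degenerate dm == 1
    fr[lo, a] <- 0
  }
  acc <- numeric(nrow(i0))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    keep <- w > 0
    if (any(keep)) {
      ii <- cbind(pmin(i0[keep, 1] + dx, dm[1]),
                  pmin(i0[keep, 2] + dy, dm[2]),
                  pmin(i0[keep, 3] + dz, dm[3]))
      acc[keep] <- acc[keep] + w[keep] * vol$data[ii]
    }
  }
  out[inside] <- acc
  out
}
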