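#' Resample a volume into a target grid through an inverse transform
#'
#' Pull-back resampling: every voxel centre of the target grid is mapped
#' through `inverse_t` (which must map target space -> source space), and the
#' source volume is sampled there by trilinear interpolation. Samples falling
#' outside the source volume are filled with 0.
#'
#' @param vol source [volume3d()].
#' @param inverse_t transform mapping the target space into `vol`'s space.
#' @param target_grid either a `volume3d` whose grid is copied, or a list with
#'   `dims`, `spacing_um` and optionally `origin_um`, `space`.
#' @param fill fill value outside the source volume.
#' @return a `volume3d` on the target grid.
#' @export
warp_volume <- function(vol, inverse_t, target_grid, fill = 0) {
  if (inherits(target_grid, "volume3d")) {
    dims <- dim(target_grid$data); spacing <- target_grid$spacing
    origin <- target_grid$origin; space <- target_grid$space
  } else {
    dims <- as.integer(target_grid$dims)
    spacing <- as.numeric(target_grid$spacing_um)
    origin <- as.numeric(target_grid$origin_um %||% c(0, 0, 0))
    space <- target_grid$space %||% "target"
  }
  if (!is.null(inverse_t$fixed_space) && !is.null(vol$space) &&
      !identical(inverse_t$fixed_space, vol$space))
    stop(sprintf("inverse transform lands in '%s' but source volume is in '%s'",
                 inverse_t$fixed_space, vol$space))
  out <- array(0, dims)
  n_slab <- max(1L, floor(2e6 / (dims[1] * dims[2])))
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  k <- 1L
  while (k <= dims[3]) {
    kk <- k:min(dims[3], k + n_slab - 1L)
    zs <- origin[3] + (kk - 1) * spacing[3]
    pts <- cbind(rep(xs, times = dims[2] * length(kk)),
                 rep(rep(ys, each = dims[1]), times = length(kk)),
                 rep(zs, each = dims[1] * dims[2]))
    src <- apply_transform(inverse_t, pts)
    out[, , kk] <- sample_trilinear(vol, src, fill = fill)
    k <- kk[length(kk)] + 1L
  }
  volume3d(out, spacing, vol$axis_order, origin, space)
}
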