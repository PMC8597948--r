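#' Landmark correspondence set between two named spaces
#'
#' @param moving n x 3 matrix of micron coordinates in the moving space.
#' @param fixed n x 3 matrix of corresponding points in the fixed space.
#' @param names optional per-pair names; must be unique when given.
#' @param moving_space,fixed_space space labels.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(moving, fixed, names = NULL,
                         moving_space = "subject", fixed_space = "CCF") {
  moving <- as_points(moving); fixed <- as_points(fixed)
  if (nrow(moving) != nrow(fixed)) stop("moving and fixed differ in length")
  if (!is.null(names)) {
    if (length(names) != nrow(moving)) stop("names length mismatch")
    if (anyDuplicated(names)) stop("landmark names must be unique")
  }
  structure(list(moving = moving, fixed = fixed, names = names,
                 moving_space = moving_space, fixed_space = fixed_space),
            class = "landmark_set")
}

#' Swap the moving and fixed sides of a landmark set
#' @param lm a [landmark_set()].
#' @return a `landmark_set` with the roles of the spaces exchanged.
#' @export
swap_landmarks <- function(lm) {
  landmark_set(lm$fixed, lm$moving, lm$names, lm$fixed_space, lm$moving_space)
}

tps_kernel <- function(r, kernel) {
  switch(kernel, r = r, r3 = r^3, stop("unknown TPS kernel: ", kernel))
}

#' Fit a 3D thin-plate-spline transform to landmark pairs
#'
#' Solves the standard TPS linear system (radial kernel block plus affine
#' polynomial block with the usual side conditions) so that, with `lambda = 0`,
#' the transform interpolates every landmark pair exactly. The default kernel
#' is the 3D biharmonic spline `U(r) = r`; `kernel = "r3"` selects `U(r) = r^3`.
#'
#' @param landmarks a [landmark_set()] with at least 4 non-coplanar pairs and
#'   no duplicated moving points (closer than 1e-6 um).
#' @param lambda smoothing regularization added to the kernel diagonal;
#'   0 (default) gives exact interpolation.
#' @param kernel `"r"` (default) or `"r3"`.
#' @return object of class `tps_transform`.
#' @export
fit_tps <- function(landmarks, lambda = 0, kernel = c("r", "r3")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(landmarks, "landmark_set"))
  C <- landmarks$moving; Fx <- landmarks$fixed
  n <- nrow(C)
  if (n < 4L)
    stop("degenerate landmark configuration: need >= 4 non-coplanar pairs, got ", n)
  D <- as.matrix(stats::dist(C))
  if (min(D[upper.tri(D)]) < 1e-6)
    stop("duplicate moving points (closer than 1e-6 um)")
  P <- cbind(1, C)
  if (qr(P)$rank < 4L)
    stop("degenerate landmark configuration: moving points are coplanar or collinear")
  # solve in centred/scaled moving coordinates for numerical conditioning
  ctr <- colMeans(C)
  scl <- mean(sqrt(rowSums(sweep(C, 2, ctr)^2)))
  if (scl == 0) scl <- 1
  Cn <- sweep(C, 2, ctr) / scl
  Dn <- as.matrix(stats::dist(Cn))
  K <- tps_kernel(Dn, kernel)
  if (lambda > 0) K <- K + diag(lambda, n)
  Pn <- cbind(1, Cn)
  A <- rbind(cbind(K, Pn), cbind(t(Pn), matrix(0, 4, 4)))
  rhs <- rbind(Fx, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular TPS system (degenerate landmark geometry): ",
         conditionMessage(e)))
  sol <- sol + solve(A, rhs - A %*% sol)   # one iterative-refinement step
  t <- structure(list(control_points = C, weights = sol[seq_len(n), , drop = FALSE],
                      affine_coef = sol[n + 1:4, , drop = FALSE],
                      kernel = kernel, lambda = lambda,
                      norm_center = ctr, norm_scale = scl,
                      moving_space = landmarks$moving_space,
                      fixed_space = landmarks$fixed_space),
                 class = "tps_transform")
  if (lambda == 0) {
    res <- sqrt(rowSums((apply_transform(t, C) - Fx)^2))
    if (max(res) > 1e-6)
      stop(sprintf("TPS interpolation failed: max residual %.3g um", max(res)))
  }
  t
}

#' Affine part of a TPS transform
#' @param t a `tps_transform`.
#' @return list with 3x3 `matrix` and length-3 `translation`.
#' @export
tps_affine <- function(t) {
  M <- t(t$affine_coef[2:4, , drop = FALSE]) / t$norm_scale
  list(matrix = M,
       translation = as.numeric(t$affine_coef[1, ]) -
         as.numeric(M %*% t$norm_center))
}

#' Identity transform between (possibly identically named) spaces
#' @param moving_space,fixed_space space labels.
#' @return object of class `identity_transform`.
#' @export
identity_transform <- function(moving_space = "subject", fixed_space = moving_space) {
  structure(list(moving_space = moving_space, fixed_space = fixed_space),
            class = "identity_transform")
}

#' Chain transforms across spaces
#'
#' Components apply in order; adjacent space labels must agree, so a chain
#' fitted subject to CCF and CCF to MRI3D maps subject points into MRI3D.
#'
#' @param ... transforms, or a single list of transforms.
#' @return object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], c(
    "tps_transform", "identity_transform", "poly_map", "transform_chain")))
    parts <- parts[[1]]
  if (!length(parts)) stop("empty transform chain")
  for (i in seq_along(parts)[-1]) {
    if (!identical(parts[[i - 1]]$fixed_space, parts[[i]]$moving_space))
      stop(sprintf("chain space mismatch at link %d: '%s' != '%s'", i,
                   parts[[i - 1]]$fixed_space, parts[[i]]$moving_space))
  }
  structure(list(parts = parts,
                 moving_space = parts[[1]]$moving_space,
                 fixed_space = parts[[length(parts)]]$fixed_space),
            class = "transform_chain")
}

#' Apply a transform to points
#'
#' @param t a `tps_transform`, `identity_transform`, `poly_map` or
#'   `transform_chain`.
#' @param points n x 3 matrix of micron coordinates in `t`'s moving space.
#' @param space optional label of the points' space; if given it must match
#'   `t$moving_space`.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(t, points, space = NULL) {
  if (!is.null(space) && !identical(space, t$moving_space))
    stop(sprintf("points are in space '%s' but transform maps from '%s'",
                 space, t$moving_space))
  UseMethod("apply_transform")
}

#' @export
apply_transform.identity_transform <- function(t, points, space = NULL) {
  as_points(points)
}

#' @export
apply_transform.tps_transform <- function(t, points, space = NULL) {
  p <- sweep(as_points(points), 2, t$norm_center) / t$norm_scale
  Cn <- sweep(t$control_points, 2, t$norm_center) / t$norm_scale
  out <- cbind(1, p) %*% t$affine_coef
  W <- t$weights
  # per-control-point distances: slower than one matrix product via the
  # |x|^2 + |c|^2 - 2xc expansion but free of its cancellation error, which
  # would otherwise dominate the micron-scale interpolation residual
  for (j in seq_len(nrow(Cn))) {
    dx <- p[, 1] - Cn[j, 1]; dy <- p[, 2] - Cn[j, 2]; dz <- p[, 3] - Cn[j, 3]
    U <- tps_kernel(sqrt(dx * dx + dy * dy + dz * dz), t$kernel)
    out <- out + U %o% W[j, ]
  }
  out
}

#' @export
apply_transform.transform_chain <- function(t, points, space = NULL) {
  p <- as_points(points)
  for (part in t$parts) p <- apply_transform(part, p)
  p
}

#' Fit the approximate inverse of a landmark-based transform
#'
#' Fits a TPS on the swapped pairs. This is an approximate inverse of the
#' forward fit: exact at the landmarks, approximate in between.
#'
#' @inheritParams fit_tps
#' @return a `tps_transform` mapping fixed space back to moving space.
#' @export
invert_transform <- function(landmarks, lambda = 0, kernel = c("r", "r3")) {
  fit_tps(swap_landmarks(landmarks), lambda = lambda, kernel = match.arg(kernel))
}

#' Held-out landmark residuals of a fitted transform
#'
#' Evaluates the transform at held-out moving points and reports the Euclidean
#' distance to the known fixed partners, sorted worst-first to guide iterative
#' landmark placement.
#'
#' @param t a transform.
#' @param heldout a [landmark_set()] in the same space pair.
#' @return list with data.frame `residuals` (name, residual_um, sorted
#'   decreasing) and `summary` (max/mean/median in um).
#' @export
landmark_residuals <- function(t, heldout) {
  stopifnot(inherits(heldout, "landmark_set"))
  if (nrow(heldout$moving) == 0L) stop("empty held-out landmark set")
  pred <- apply_transform(t, heldout$moving)
  res <- sqrt(rowSums((pred - heldout$fixed)^2))
  ord <- order(res, decreasing = TRUE)
  list(residuals = data.frame(
         name = (heldout$names %||% paste0("pair", seq_along(res)))[ord],
         residual_um = res[ord], stringsAsFactors = FALSE),
       summary = c(max = max(res), mean = mean(res), median = stats::median(res)))
}

# ---- smooth analytic deformation (used as phantom ground truth) -----------

#' Smooth analytic deformation map: global scale plus low-order sine field
#'
#' `f(x) = center_fixed + scale * (x - center_moving) + perturbation(x)`, with
#' a low-order product-of-sines perturbation of amplitude `amp_um` and spatial
#' period `period_um` per axis. Amplitudes small against `scale * period`
#' keep the Jacobian positive, so the map is invertible; [invert_points()]
#' recovers preimages by fixed-point iteration.
#'
#' @param scale global scale factor.
#' @param center_moving,center_fixed micron centres in each space.
#' @param amp_um perturbation amplitude (um); 0 gives a pure affine map.
#' @param period_um length-3 perturbation period per axis (um).
#' @param phase length-3 phase offsets (radians).
#' @param moving_space,fixed_space space labels.
#' @return object of class `poly_map`.
#' @export
poly_map <- function(scale = 1, center_moving = c(0, 0, 0),
                     center_fixed = center_moving, amp_um = 0,
                     period_um = c(4000, 4000, 6000), phase = c(0, 1, 2),
                     moving_space = "subject", fixed_space = "CCF") {
  structure(list(scale = scale, center_moving = as.numeric(center_moving),
                 center_fixed = as.numeric(center_fixed), amp = amp_um,
                 period = as.numeric(period_um), phase = as.numeric(phase),
                 moving_space = moving_space, fixed_space = fixed_space),
            class = "poly_map")
}

poly_perturbation <- function(m, p) {
  if (m$amp == 0) return(0)
  u <- 2 * pi * sweep(p, 2, m$period, "/")
  # each displacement component varies along its own axis, so the local
  # scale (not just the local shear) is spatially nonuniform
  m$amp * cbind(sin(u[, 1] + m$phase[1]) * cos(u[, 2]),
                sin(u[, 2] + m$phase[2]) * cos(u[, 3]),
                sin(u[, 3] + m$phase[3]) * cos(u[, 1]))
}

#' @export
apply_transform.poly_map <- function(t, points, space = NULL) {
  p <- as_points(points)
  out <- sweep(sweep(p, 2, t$center_moving, "-") * t$scale, 2, t$center_fixed, "+")
  out + poly_perturbation(t, p)
}

#' Numerically invert a smooth analytic deformation at given points
#'
#' @param map a [poly_map()].
#' @param points_fixed n x 3 micron coordinates in the fixed space.
#' @param tol convergence tolerance (um).
#' @param max_iter iteration cap.
#' @return n x 3 preimages in the moving space.
#' @export
invert_points <- function(map, points_fixed, tol = 1e-8, max_iter = 60L) {
  y <- as_points(points_fixed)
  x <- sweep(sweep(y, 2, map$center_fixed, "-") / map$scale, 2,
             map$center_moving, "+")
  for (k in seq_len(max_iter)) {
    r <- apply_transform(map, x) - y
    if (max(abs(r)) < tol) break
    x <- x - r / map$scale
  }
  x
}

# ---- serialization --------------------------------------------------------

#' Write a TPS transform to JSON
#' @param t a `tps_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "tps_transform"))
  jsonlite::write_json(list(
    type = "tps", kernel = t$kernel, lambda = t$lambda,
    moving_space = t$moving_space, fixed_space = t$fixed_space,
    control_points = t$control_points, weights = t$weights,
    affine_coef = t$affine_coef, norm_center = t$norm_center,
    norm_scale = t$norm_scale), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a TPS transform from JSON
#' @param path JSON path written by [write_transform_json()].
#' @return a `tps_transform`.
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "tps")) stop("not a TPS transform JSON")
  structure(list(control_points = as.matrix(j$control_points),
                 weights = as.matrix(j$weights),
                 affine_coef = as.matrix(j$affine_coef),
                 norm_center = as.numeric(j$norm_center),
                 norm_scale = j$norm_scale,
                 kernel = j$kernel, lambda = j$lambda,
                 moving_space = j$moving_space, fixed_space = j$fixed_space),
            class = "tps_transform")
}

#' Read a landmark CSV
#'
#' Expected columns: `name,moving_x,moving_y,moving_z,fixed_x,fixed_y,fixed_z`
#' (micrometres).
#'
#' @param path CSV path.
#' @param moving_space,fixed_space space labels to attach.
#' @return a [landmark_set()].
#' @export
read_landmarks_csv <- function(path, moving_space = "subject", fixed_space = "CCF") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("moving_x", "moving_y", "moving_z", "fixed_x", "fixed_y", "fixed_z")
  if (!all(need %in% names(d))) stop("landmark CSV lacks columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  landmark_set(as.matrix(d[, need[1:3]]), as.matrix(d[, need[4:6]]),
               names = d$name, moving_space = moving_space,
               fixed_space = fixed_space)
}

#' Write a landmark CSV
#' @param lm a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(lm, path) {
  d <- data.frame(name = lm$names %||% paste0("pair", seq_len(nrow(lm$moving))),
                  moving_x = lm$moving[, 1], moving_y = lm$moving[, 2],
                  moving_z = lm$moving[, 3], fixed_x = lm$fixed[, 1],
                  fixed_y = lm$fixed[, 2], fixed_z = lm$fixed[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Import point pairs from the two-row-header CSV dialect of landmark GUIs
#'
#' Accepts files whose first header row tags column groups (`moving`/`fixed`)
#' and second header row the coordinate axes, followed by one row per pair:
#' `name` in the first column, then the moving xyz and fixed xyz.
#'
#' @inheritParams read_landmarks_csv
#' @return a [landmark_set()].
#' @export
read_landmarks_gui <- function(path, moving_space = "subject", fixed_space = "CCF") {
  raw <- utils::read.csv(path, header = FALSE, skip = 2, stringsAsFactors = FALSE)
  numcols <- which(vapply(raw, function(col)
    all(!is.na(suppressWarnings(as.numeric(col)))), logical(1)))
  if (length(numcols) < 6L) stop("could not find 6 numeric coordinate columns")
  numcols <- numcols[seq_len(6L)]
  m <- as.matrix(vapply(raw[numcols], as.numeric, numeric(nrow(raw))))
  m <- matrix(m, ncol = 6)
  nm <- if (!1L %in% numcols) as.character(raw[[1]]) else NULL
  landmark_set(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], names = nm,
               moving_space = moving_space, fixed_space = fixed_space)
}
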