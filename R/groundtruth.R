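#' Fluorescence intensity along localized electrodes
#'
#' Samples an image volume (e.g. the eYFP projection channel) at every
#' localized site: mean intensity over a small sphere of `radius_um` around
#' the site's 3D coordinate (trilinear-sampled 7-point quadrature: centre
#' plus the six axis points at the radius), normalized to [0, 1] across the
#' probe. Sites outside the volume become missing values and are excluded
#' from downstream fits.
#'
#' @param vol a [volume3d()].
#' @param localization an `electrode_localization` whose coordinates are in
#'   `vol`'s space, or mapped there via `transform_to_vol`.
#' @param radius_um sampling radius (um), default 20 (one row pitch).
#' @param transform_to_vol optional transform from the localization's space
#'   into `vol`'s space.
#' @return data.frame of class `site_profile`: `site`, `shank_depth_um`,
#'   `value` (normalized), `missing`.
#' @export
fluorescence_profile <- function(vol, localization, radius_um = 20,
                                 transform_to_vol = NULL) {
  pts <- as.matrix(localization$sites[, c("x_um", "y_um", "z_um")])
  if (!is.null(transform_to_vol)) pts <- apply_transform(transform_to_vol, pts)
  offs <- rbind(c(0, 0, 0),
                radius_um * rbind(diag(3), -diag(3)))
  acc <- matrix(NA_real_, nrow(pts), nrow(offs))
  for (q in seq_len(nrow(offs)))
    acc[, q] <- sample_trilinear(vol, sweep(pts, 2, offs[q, ], "+"), fill = NA)
  val <- rowMeans(acc)                     # NA if any quadrature point outside
  miss <- !is.finite(val)
  if (all(miss)) stop("all sites fall outside the volume")
  rng <- range(val[!miss])
  norm <- if (diff(rng) > 0) (val - rng[1]) / diff(rng) else
    rep(0, length(val))
  norm[miss] <- NA_real_
  structure(data.frame(site = localization$sites$site,
                       shank_depth_um = localization$sites$shank_depth_um,
                       value = norm, missing = miss),
            class = c("site_profile", "data.frame"))
}

as_xy_profile <- function(profile) {
  if (inherits(profile, "feature_profile")) {
    list(x = profile_centers(profile) / 1000, y = profile$values)
  } else if (is.data.frame(profile) && all(c("shank_depth_um", "value") %in%
                                           names(profile))) {
    keep <- is.finite(profile$value)
    list(x = profile$shank_depth_um[keep] / 1000, y = profile$value[keep])
  } else if (is.list(profile) && all(c("x_mm", "values") %in% names(profile))) {
    list(x = as.numeric(profile$x_mm), y = as.numeric(profile$values))
  } else stop("unsupported profile type")
}

#' Fit a multi-term Gaussian model to a depth profile
#'
#' Nonlinear least squares of `sum_k A_k exp(-(x - mu_k)^2 / (2 sigma_k^2)) + c`
#' against a per-depth profile (x in mm along the shank). The component count
#' `K` is chosen by the analyst from the profile's appearance. Initialization
#' uses the K largest local maxima; a few perturbed restarts guard against
#' poor starts.
#'
#' @param profile a [feature_profile()], a [fluorescence_profile()] result, or
#'   `list(x_mm=, values=)`.
#' @param K number of Gaussian components (>= 1).
#' @param max_restarts extra multi-start attempts, default 4.
#' @return object of class `multigauss_fit`: data.frame `components`
#'   (`amplitude`, `mean_mm`, `sigma_mm`, sorted by mean), `offset`, `K`,
#'   `residual_norm`, `converged`.
#' @export
fit_multigauss <- function(profile, K, max_restarts = 4) {
  xy <- as_xy_profile(profile)
  x <- xy$x; y <- xy$y
  if (K < 1) stop("K must be >= 1")
  if (length(x) < 3 * K + 1)
    stop(sprintf("profile has %d informative points; need >= %d for K = %d",
                 length(x), 3 * K + 1, K))
  if (stats::sd(y) == 0)
    stop("flat or degenerate profile: nothing to fit")
  ord <- order(x); x <- x[ord]; y <- y[ord]
  rng <- diff(range(x))
  dx <- stats::median(diff(unique(x)))
  # local maxima of a lightly smoothed copy, largest first
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  loc <- which(diff(sign(diff(ys))) < 0) + 1L
  loc <- loc[order(ys[loc], decreasing = TRUE)]
  if (!length(loc)) loc <- which.max(y)
  # greedy pick of the K tallest maxima with a minimum mutual separation, so
  # two starts never sit on one and the same bump
  sep <- max(3 * dx, 0.05 * rng)
  picked <- integer(0)
  for (l in loc) {
    if (!length(picked) || all(abs(x[l] - x[picked]) >= sep))
      picked <- c(picked, l)
    if (length(picked) == K) break
  }
  mu0 <- x[picked]
  while (length(mu0) < K)
    mu0 <- c(mu0, stats::quantile(x, (length(mu0) + 0.5) / K, names = FALSE))
  base <- min(y)
  model <- function(par) {
    A <- par[1:K]; mu <- par[K + 1:K]; sg <- par[2 * K + 1:K]
    c0 <- par[3 * K + 1]
    m <- rep(c0, length(x))
    for (k in seq_len(K)) m <- m + A[k] * exp(-(x - mu[k])^2 / (2 * sg[k]^2))
    m
  }
  fit_once <- function(mu_init, sg_init) {
    amp_rng <- max(y) - base
    par0 <- c(rep(amp_rng, K), mu_init, rep(sg_init, K), base)
    lower <- c(rep(0, K), rep(min(x) - rng / 2, K), rep(dx / 2, K),
               base - amp_rng)
    # a component wider than ~half the profile is a baseline, not a peak
    upper <- c(rep(4 * amp_rng, K), rep(max(x) + rng / 2, K), rep(rng / 1.5, K),
               max(y))
    fit <- tryCatch(minpack.lm::nls.lm(
      par0, lower, upper, fn = function(p) model(p) - y,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    fit
  }
  best <- NULL; best_rn <- Inf
  # start narrow: broad starts let the optimizer merge neighbouring peaks
  sg0 <- max(2 * dx, rng / (20 * K))
  starts <- list(list(mu = mu0, sg = sg0))
  for (r in seq_len(max_restarts)) {
    starts <- c(starts, list(list(
      mu = if (r %% 2) mu0 else
        sort(stats::quantile(x, (seq_len(K) - 0.5) / K, names = FALSE)),
      sg = sg0 * 2^(r - 1))))
  }
  for (s in starts) {
    f <- fit_once(pmin(pmax(s$mu, min(x)), max(x)), s$sg)
    if (is.null(f)) next
    rn <- sqrt(sum(f$fvec^2))
    if (rn < best_rn) { best <- f; best_rn <- rn }
    if (best_rn < 1e-8 * length(x)) break
  }
  if (is.null(best)) stop("multi-Gaussian fit failed on all starts")
  par <- best$par
  comp <- data.frame(amplitude = par[1:K], mean_mm = par[K + 1:K],
                     sigma_mm = par[2 * K + 1:K])
  comp <- comp[order(comp$mean_mm), , drop = FALSE]
  rownames(comp) <- NULL
  in_range <- all(comp$mean_mm > min(x) - 3 * comp$sigma_mm &
                  comp$mean_mm < max(x) + 3 * comp$sigma_mm)
  structure(list(components = comp, offset = par[3 * K + 1], K = K,
                 residual_norm = best_rn,
                 converged = best$info %in% 1:4 && in_range),
            class = "multigauss_fit")
}

#' @export
print.multigauss_fit <- function(x, ...) {
  cat(sprintf("<multigauss_fit> K=%d, residual %.4g, %s\n", x$K,
              x$residual_norm, if (x$converged) "converged" else "NOT converged"))
  print(x$components)
  invisible(x)
}

#' Match peaks between two multi-Gaussian fits
#'
#' Greedy nearest-mean matching: the closest pair of fitted means is matched
#' first, each peak used at most once; unmatched peaks are reported and never
#' enter the accuracy statistic.
#'
#' @param fit_a,fit_b converged [fit_multigauss()] results (e.g. fluorescence
#'   and evoked activity along the same probe).
#' @return list with `pairs` (data.frame `mean_a_mm`, `mean_b_mm`,
#'   `abs_diff_mm`), `unmatched_a`, `unmatched_b` (mean positions, mm).
#' @export
match_peaks <- function(fit_a, fit_b) {
  if (!fit_a$converged || !fit_b$converged)
    stop("both fits must have converged before matching peaks")
  ma <- fit_a$components$mean_mm; mb <- fit_b$components$mean_mm
  D <- abs(outer(ma, mb, "-"))
  pairs <- NULL
  while (length(ma) && length(mb) && any(is.finite(D))) {
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(mean_a_mm = ma[ij[1]], mean_b_mm = mb[ij[2]],
                                     abs_diff_mm = D[ij[1], ij[2]]))
    D[ij[1], ] <- Inf; D[, ij[2]] <- Inf
    if (all(!is.finite(D))) break
  }
  matched_a <- if (is.null(pairs)) numeric(0) else pairs$mean_a_mm
  matched_b <- if (is.null(pairs)) numeric(0) else pairs$mean_b_mm
  list(pairs = pairs %||% data.frame(mean_a_mm = numeric(0),
                                     mean_b_mm = numeric(0),
                                     abs_diff_mm = numeric(0)),
       unmatched_a = setdiff(ma, matched_a),
       unmatched_b = setdiff(mb, matched_b))
}

#' Localization accuracy summary across penetrations
#'
#' Mean and sample SD (n - 1 denominator) of per-penetration absolute
#' peak-location differences (one value per penetration: the mean of its
#' matched pairs).
#'
#' @param per_penetration_diffs_mm numeric vector, one |difference| (mm) per
#'   penetration.
#' @return object of class `accuracy_result`: `mean_mm`, `sd_mm`,
#'   `n_penetrations`, `diffs_mm`, `single_penetration` flag.
#' @export
accuracy_summary <- function(per_penetration_diffs_mm) {
  d <- as.numeric(per_penetration_diffs_mm)
  if (!length(d)) stop("no penetrations")
  if (any(d < 0)) stop("absolute differences must be >= 0")
  single <- length(d) == 1L
  structure(list(mean_mm = mean(d), sd_mm = if (single) 0 else stats::sd(d),
                 n_penetrations = length(d), diffs_mm = d,
                 single_penetration = single),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("localization accuracy: %.3f +/- %.3f mm (mean +/- SD, n = %d)\n",
              x$mean_mm, x$sd_mm, x$n_penetrations))
  invisible(x)
}

#' Paired comparison of per-penetration errors between two methods
#'
#' Standard two-tailed paired t test on per-penetration error pairs (e.g.
#' electrodes placed in the undeformed template space versus directly in the
#' atlas space).
#'
#' @param errors_a,errors_b equal-length (>= 2) numeric vectors, paired by
#'   penetration.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_comparison <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("error vectors must be paired: unequal lengths")
  if (length(errors_a) < 2L) stop("need >= 2 pairs")
  if (stats::sd(errors_a - errors_b) == 0)
    stop("degenerate case: paired differences have zero variance")
  ht <- stats::t.test(errors_a, errors_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}
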