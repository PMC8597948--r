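# small deterministic fixtures shared across test files

tiny_annotation <- function(seed = 1, dims = c(8, 8, 8), spacing = c(10, 10, 10)) {
  set.seed(seed)
  labs <- array(sample(0:3, prod(dims), replace = TRUE), dims)
  annotation_volume(labs, spacing,
                    data.frame(label = 1:3, acronym = c("A", "B", "C"),
                               name = c("reg A", "reg B", "reg C")))
}

# two-layer annotation with a planar boundary at a given DV coordinate
layered_annotation <- function(boundary_dv_um, dims = c(20, 40, 20),
                               spacing = c(20, 20, 20), space = "subject") {
  dv <- (seq_len(dims[2]) - 1) * spacing[2]
  lab <- ifelse(dv < boundary_dv_um, 1L, 2L)
  labs <- aperm(array(rep(lab, each = dims[1]), c(dims[1], dims[2], dims[3])),
                c(1, 2, 3))
  annotation_volume(labs, spacing,
                    data.frame(label = 1:2, acronym = c("UP", "LO"),
                               name = c("upper", "lower")), space = space)
}

straight_track <- function(length_um = 5000, step_um = 1, space = "subject") {
  build_track(track_annotation(rbind(c(0, 0, 0), c(0, length_um, 0)),
                               space = space), step_um = step_um)
}

# landmark set generated by a known smooth deformation of seeded points
deformed_landmarks <- function(n, map, seed = 1, jitter_um = 0,
                               lo = c(200, 200, 200), hi = c(5800, 5800, 5800)) {
  set.seed(seed)
  mv <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
              runif(n, lo[3], hi[3]))
  fx <- apply_transform(map, mv)
  if (jitter_um > 0) fx <- fx + matrix(rnorm(3 * n, 0, jitter_um), ncol = 3)
  landmark_set(mv, fx, moving_space = map$moving_space,
               fixed_space = map$fixed_space)
}

small_phantom_spec <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(dims = c(60, 60, 90), spacing_um = c(40, 40, 40),
         insertion_depth_um = c(1400, 1800),
         anchor_depths_um = c(0, 1000),
         blob_depths_um = c(600, 1200),
         n_penetrations = 4, n_landmarks = 120, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}
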