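bootstrap_pairs <- rbind(
  c(5700, 3820, 4240), c(5700, 1780, 7600), c(5700, 5260, 5160),
  c(4000, 6000, 8000), c(7400, 6000, 8000), c(2000, 2500, 6000),
  c(9400, 2500, 6000))

test_that("TPS on identical pairs is the identity map", {
  t <- fit_tps(landmark_set(bootstrap_pairs, bootstrap_pairs))
  set.seed(1)
  probe <- cbind(runif(100, 0, 11000), runif(100, 0, 8000),
                 runif(100, 0, 13000))
  expect_lt(max(abs(apply_transform(t, probe) - probe)), 1e-6)
  expect_lt(max(abs(t$weights)), 1e-8)
})

test_that("TPS reproduces an affine generator exactly on held-out points", {
  set.seed(2)
  mv <- matrix(runif(30, 0, 5000), 10)
  A <- matrix(c(1.1, 0.02, 0, 0.01, 0.95, 0.03, 0, 0.02, 1.2), 3)
  b <- c(100, -50, 20)
  fx <- mv %*% A + rep(b, each = nrow(mv))
  t <- fit_tps(landmark_set(mv, fx))
  held <- matrix(runif(300, 0, 5000), 100)
  expect_lt(max(abs(apply_transform(t, held) -
                    (held %*% A + rep(b, each = 100)))), 1e-6)
  expect_lt(max(abs(t$weights)), 1e-8)
  aff <- tps_affine(t)
  expect_equal(aff$matrix, t(A), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(aff$translation, b, tolerance = 1e-6)
})

test_that("degenerate landmark configurations raise descriptive errors", {
  m <- matrix(runif(9, 0, 100), 3)
  expect_error(fit_tps(landmark_set(m, m)), ">= 4 non-coplanar")
  cop <- cbind(runif(6, 0, 100), runif(6, 0, 100), 5)
  expect_error(fit_tps(landmark_set(cop, cop)), "coplanar")
  dup <- rbind(bootstrap_pairs, bootstrap_pairs[1, ] + 1e-9)
  expect_error(fit_tps(landmark_set(dup, dup)), "duplicate")
})

test_that("interpolation and side conditions hold across random fits", {
  for (seed in 1:5) {
    map <- poly_map(1 + 0.05 * seed, c(3000, 2000, 3000),
                    c(3100, 2100, 3200), amp_um = 30 * seed)
    lm <- deformed_landmarks(40 + 10 * seed, map, seed = seed)
    t <- fit_tps(lm)
    res <- sqrt(rowSums((apply_transform(t, lm$moving) - lm$fixed)^2))
    expect_lt(max(res), 1e-6)
    expect_lt(max(abs(colSums(t$weights))), 1e-8)
    Cn <- sweep(t$control_points, 2, t$norm_center) / t$norm_scale
    expect_lt(max(abs(t(Cn) %*% t$weights)), 1e-8)
  }
})

test_that("forward/inverse round trip is exact at landmarks, small inside", {
  map <- poly_map(1.12, c(3000, 3000, 3000), c(3200, 3100, 3300),
                  amp_um = 80)
  lm <- deformed_landmarks(150, map, seed = 7)
  fwd <- fit_tps(lm)
  inv <- invert_transform(lm)
  back <- apply_transform(inv, apply_transform(fwd, lm$moving))
  expect_lt(max(abs(back - lm$moving)), 1e-6)

  # interior points of the smooth deformation: median error well below the
  # ~450 um landmark spacing of this configuration
  set.seed(8)
  interior <- cbind(runif(100, 1000, 5000), runif(100, 1000, 5000),
                    runif(100, 1000, 5000))
  rt <- apply_transform(inv, apply_transform(fwd, interior))
  med <- median(sqrt(rowSums((rt - interior)^2)))
  expect_lt(med, 0.02 * 450)

  # swapped identity pairs remain the identity
  ti <- invert_transform(landmark_set(bootstrap_pairs, bootstrap_pairs))
  expect_lt(max(abs(apply_transform(ti, interior) - interior)), 1e-6)
})

test_that("transform chains compose in order and validate space labels", {
  m1 <- poly_map(1.1, c(0, 0, 0), c(0, 0, 0), amp_um = 40,
                 moving_space = "subject", fixed_space = "CCF")
  m2 <- poly_map(0.95, c(0, 0, 0), c(100, 0, 0), amp_um = 20,
                 moving_space = "CCF", fixed_space = "MRI3D")
  ch <- transform_chain(m1, m2)
  set.seed(9)
  p <- matrix(runif(60, 0, 4000), 20)
  expect_identical(apply_transform(ch, p),
                   apply_transform(m2, apply_transform(m1, p)))
  expect_error(transform_chain(m2, m1), "space mismatch")
  expect_error(apply_transform(m1, p, space = "CCF"), "maps from")

  # chained landmark fits recover a composed ground-truth map to < 1 um
  lm1 <- deformed_landmarks(120, m1, seed = 10, lo = c(500, 500, 500),
                            hi = c(3500, 3500, 3500))
  fx2 <- apply_transform(m2, lm1$fixed)
  lm2 <- landmark_set(lm1$fixed, fx2, moving_space = "CCF",
                      fixed_space = "MRI3D")
  ch2 <- transform_chain(fit_tps(lm1), fit_tps(lm2))
  truth <- apply_transform(m2, apply_transform(m1, lm1$moving))
  expect_lt(max(abs(apply_transform(ch2, lm1$moving) - truth)), 1e-6)
})

test_that("held-out residuals shrink as the training landmark set grows", {
  map <- poly_map(1.15, c(3000, 3000, 3000), c(3300, 3200, 3400),
                  amp_um = 150)
  held <- deformed_landmarks(200, map, seed = 20)
  meds <- vapply(c(7, 50, 200), function(n) {
    train <- deformed_landmarks(n, map, seed = 21)
    landmark_residuals(fit_tps(train), held)$summary[["median"]]
  }, numeric(1))
  expect_true(all(diff(meds) < 0))

  # residuals at training points are zero; empty held-out set errors
  train <- deformed_landmarks(30, map, seed = 22)
  t <- fit_tps(train)
  expect_lt(landmark_residuals(t, train)$summary[["max"]], 1e-6)
  expect_error(landmark_residuals(t, landmark_set(matrix(0, 0, 3),
                                                  matrix(0, 0, 3))), "empty")
})

test_that("dense landmark sets reach sub-voxel held-out accuracy", {
  # 250 landmarks on a smooth 15%-scale deformation: median held-out
  # residual below one 20 um voxel
  map <- poly_map(1.15, c(2000, 2000, 3000), c(2300, 2200, 3400),
                  amp_um = 120, period_um = c(4000, 4000, 6000))
  train <- deformed_landmarks(250, map, seed = 30, lo = c(200, 200, 200),
                              hi = c(3800, 3800, 5800))
  held <- deformed_landmarks(150, map, seed = 31, lo = c(400, 400, 400),
                             hi = c(3600, 3600, 5600))
  med <- landmark_residuals(fit_tps(train), held)$summary[["median"]]
  expect_lt(med, 20)
})

test_that("warp_volume resamples through the inverse transform", {
  set.seed(12)
  v <- volume3d(array(rnorm(4000), c(20, 20, 10)), c(10, 10, 10))
  idt <- identity_transform("subject")
  same <- warp_volume(v, idt, v)
  expect_equal(same$data, v$data, tolerance = 1e-12)

  # pure translation by exactly one voxel shifts the grid, zero-fills borders
  shift <- poly_map(1, c(0, 0, 0), c(10, 0, 0), amp_um = 0,
                    moving_space = "subject", fixed_space = "subject")
  w <- warp_volume(v, shift, v)
  expect_equal(w$data[1:19, , ], v$data[2:20, , ], tolerance = 1e-9)
  expect_true(all(w$data[20, , ] == 0))

  # 1.25x enlargement of a sphere: thresholded volume ratio ~ 1.25^3
  sph <- array(0, c(40, 40, 40))
  ctr <- c(195, 195, 195)
  for (k in 1:40) {
    xy <- as.matrix(expand.grid(x = (1:40 - 1) * 10, y = (1:40 - 1) * 10))
    d2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2 + ((k - 1) * 10 - ctr[3])^2
    sph[, , k] <- matrix(as.numeric(d2 <= 120^2), 40, 40)
  }
  vs <- volume3d(sph, c(10, 10, 10))
  inv <- poly_map(1 / 1.25, ctr, ctr, amp_um = 0,
                  moving_space = "subject", fixed_space = "subject")
  big <- warp_volume(vs, inv, vs)
  r_in <- (3 / (4 * pi) * sum(vs$data > 0.5) * 1000)^(1 / 3)
  r_out <- (3 / (4 * pi) * sum(big$data > 0.5) * 1000)^(1 / 3)
  expect_lt(abs(r_out / r_in - 1.25), 10 / r_in)   # within one voxel
})

test_that("transform JSON serialization round-trips evaluation", {
  map <- poly_map(1.08, c(1000, 1000, 1000), c(1100, 900, 1200), amp_um = 60)
  lm <- deformed_landmarks(60, map, seed = 13)
  t <- fit_tps(lm)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(t, f)
  t2 <- read_transform_json(f)
  p <- matrix(runif(30, 0, 3000), 10)
  expect_equal(apply_transform(t2, p), apply_transform(t, p),
               tolerance = 1e-9)
})

test_that("landmark CSV formats round-trip, including the GUI dialect", {
  lm <- landmark_set(bootstrap_pairs, bootstrap_pairs + 10,
                     names = paste0("lm", 1:7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(lm, f)
  lm2 <- read_landmarks_csv(f)
  expect_equal(lm2$moving, lm$moving, ignore_attr = TRUE)
  expect_equal(lm2$fixed, lm$fixed, ignore_attr = TRUE)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",moving,moving,moving,fixed,fixed,fixed",
               "name,x,y,z,x,y,z",
               "p1,1,2,3,4,5,6", "p2,7,8,9,10,11,12"), g)
  lmg <- read_landmarks_gui(g)
  expect_equal(lmg$moving, rbind(c(1, 2, 3), c(7, 8, 9)), ignore_attr = TRUE)
  expect_equal(lmg$names, c("p1", "p2"))
})
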