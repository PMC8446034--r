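test_that("preprocessing at target geometry is an identity resample", {
  set.seed(1)
  px <- matrix(runif(64 * 64, 0, 65535), 64, 64)
  roi <- roi_image(px, pixel_spacing = 0.15, site = "hip_left")
  out <- preprocess_roi(roi, size = 64)
  rng <- range(px)
  expect_equal(out$pixels, (px - rng[1]) / (rng[2] - rng[1]), tolerance = 1e-12)
})

test_that("spacing correction preserves physical extent", {
  # 32 px at 0.30 mm spans 9.6 mm = 64 px at 0.15 mm
  ramp <- outer(seq_len(32), seq_len(32), function(r, cc) 100 * r + 40 * cc)
  roi <- roi_image(ramp, pixel_spacing = 0.30, site = "hip_left")
  out <- preprocess_roi(roi, size = 64)
  expect_identical(dim(out$pixels), c(64L, 64L))
  expect_equal(out$pixel_spacing, 0.15)
  # bilinear resampling reproduces an affine ramp exactly in the interior
  interior <- out$pixels[3:62, 3:62]
  rng <- range(ramp)
  expected <- outer(3:62, 3:62, function(r, cc) {
    # output centre (0-based) k maps to input coordinate (k + .5)/2 - .5
    ri <- (r - 1 + 0.5) / 2 - 0.5; ci <- (cc - 1 + 0.5) / 2 - 0.5
    (100 * (ri + 1) + 40 * (ci + 1) - rng[1]) / diff(rng)
  })
  expect_equal(interior, expected, tolerance = 1e-12)
})

test_that("constant images normalise to the documented 0.5 fallback", {
  roi <- roi_image(matrix(1234, 40, 40), pixel_spacing = 0.15, site = "hip_left")
  out <- preprocess_roi(roi, size = 40)
  expect_true(all(out$pixels == 0.5))
})

test_that("preprocessing is idempotent", {
  r <- generate_phantom_roi(phantom_spec(0.8, noise_sd = 300, seed = 3), 48)
  g1 <- preprocess_roi(r, size = 96)
  g2 <- preprocess_roi(g1, size = 96)
  expect_identical(g1, g2)
})

test_that("letterboxing pads the short axis symmetrically with zeros", {
  px <- matrix(runif(30 * 60, 100, 60000), 30, 60)
  roi <- roi_image(px, pixel_spacing = 0.15, site = "hip_left")
  out <- preprocess_roi(roi, size = 60)
  expect_identical(dim(out$pixels), c(60L, 60L))
  expect_true(all(out$pixels[1:15, ] == 0))
  expect_true(all(out$pixels[46:60, ] == 0))
})

test_that("augmentation with zero ranges is the exact identity", {
  px <- matrix(runif(32 * 32), 32, 32)
  out <- augment_roi(px, augment_ranges(0, 0, 0, 0), seed = 5)
  expect_equal(unclass(out)[seq_along(px)], as.vector(px), tolerance = 1e-12)
})

test_that("augmentation is deterministic in its seed", {
  px <- matrix(runif(32 * 32), 32, 32)
  a <- augment_roi(px, seed = 11)
  b <- augment_roi(px, seed = 11)
  expect_identical(a, b)
  expect_false(identical(augment_roi(px, seed = 12), a))
})

test_that("an explicit 90-degree rotation matches the coordinate oracle", {
  n <- 11
  px <- matrix(runif(n * n), n, n)
  cx <- (n - 1) / 2
  # inverse map for +90 deg rotation about the centre: (x,y) -> (y, 2c - x)
  M <- matrix(c(0, 1, 0,
                -1, 0, 2 * cx), 2, 3, byrow = TRUE)
  out <- augment_roi(px, transform = M)
  expected <- matrix(NA_real_, n, n)
  for (r in seq_len(n)) for (cc in seq_len(n)) {
    xs <- cc - 1; ys <- r - 1
    xi <- ys; yi <- 2 * cx - xs # the same affine, applied per coordinate
    expected[r, cc] <- px[yi + 1, xi + 1]
  }
  expect_equal(unclass(out)[seq_along(px)], as.vector(expected), tolerance = 1e-12)
})

test_that("fold partition is seeded, balanced, and reproducible", {
  for (n in c(9, 20, 43)) {
    f1 <- osteoscreen:::fold_partition(n, 4, seed = 3)
    f2 <- osteoscreen:::fold_partition(n, 4, seed = 3)
    expect_identical(f1, f2)
    sizes <- tabulate(f1, 4)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sum(sizes), n)
  }
  expect_false(identical(osteoscreen:::fold_partition(20, 4, 3),
                         osteoscreen:::fold_partition(20, 4, 4)))
})

make_phantom_set <- function(n, noise_sd = 400, size = 48, seed = 100) {
  set.seed(seed)
  bmd <- runif(n, 0.3, 1.4)
  lv <- sample(c("L1", "L2", "L3", "L4"), n, replace = TRUE)
  rois <- lapply(seq_len(n), function(i)
    generate_phantom_roi(phantom_spec(bmd[i], noise_sd = noise_sd,
                                      seed = seed + i), size,
                         site = "vertebra", level = lv[i]))
  list(rois = rois, bmd = bmd)
}

test_that("training loss decreases monotonically and folds are logged", {
  d <- make_phantom_set(24)
  ens <- fit_bmd_ensemble(d$rois, d$bmd,
                          bmd_config(input_size = 96, seed = 9, epochs = 15))
  expect_identical(dim(ens$training_log), c(15L, 4L))
  for (m in 1:4) expect_true(all(diff(ens$training_log[, m]) <= 1e-8))
})

test_that("ensemble prediction is the member mean, bounded by member range", {
  d <- make_phantom_set(24)
  ens <- fit_bmd_ensemble(d$rois, d$bmd, bmd_config(input_size = 96, seed = 9))
  p <- predict(ens, d$rois[1:6])
  members <- as.matrix(p[, c("member1", "member2", "member3", "member4")])
  expect_equal(p$predicted_bmd, rowMeans(members), tolerance = 1e-12)
  expect_true(all(p$predicted_bmd >= apply(members, 1, min) - 1e-12))
  expect_true(all(p$predicted_bmd <= apply(members, 1, max) + 1e-12))
  expect_true(all(p$predicted_bmd > 0))
})

test_that("refitting with the same config reproduces the ensemble", {
  d <- make_phantom_set(16)
  cfg <- bmd_config(input_size = 96, seed = 21, epochs = 10)
  e1 <- fit_bmd_ensemble(d$rois, d$bmd, cfg)
  e2 <- fit_bmd_ensemble(d$rois, d$bmd, cfg)
  expect_identical(e1$folds, e2$folds)
  expect_equal(e1$members, e2$members, tolerance = 1e-12)
})

test_that("site mismatches and undersized datasets are rejected", {
  d <- make_phantom_set(12)
  ens <- fit_bmd_ensemble(d$rois, d$bmd, bmd_config(input_size = 96, seed = 2))
  hip <- generate_phantom_roi(phantom_spec(0.9), 48, site = "hip_left")
  expect_error(predict(ens, hip), "does not match ensemble site")
  expect_error(predict_bmd(hip, ens), "does not match")
  expect_error(fit_bmd_ensemble(d$rois[1:4], d$bmd[1:4], bmd_config()),
               "at least 8")
  mixed <- c(d$rois[1:7], list(hip))
  expect_error(fit_bmd_ensemble(mixed, rep(0.8, 8), bmd_config(input_size = 96)),
               "one site family")
})
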