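# Edge derivation, TTA round trips, the composed geometric augmentation,
# and the rigid moving-least-squares deformation.

test_that("edge derivation handles empty, full-frame, and square masks", {
  z <- matrix(0, 16, 16)
  expect_equal(derive_edge(z), z)
  full <- matrix(1, 16, 16)
  e1 <- derive_edge(full, thickness = 1)
  inner <- matrix(0, 16, 16)
  inner[2:15, 2:15] <- 1
  expect_equal(e1, full - inner)  # only the frame border remains
  sq <- matrix(0, 32, 32)
  sq[12:21, 12:21] <- 1  # centred 10x10 square
  expect_equal(sum(derive_edge(sq, thickness = 1)), 36)
  expect_error(derive_edge(matrix(0.5, 4, 4)), "binary")
})

test_that("edges are binary and confined to a 3-px band of the boundary", {
  set.seed(71)
  for (i in 1:5) {
    smp <- generate_sample(easy_spec(100 + i))
    e <- smp$edge
    expect_true(all(e %in% c(0, 1)))
    expect_gt(sum(e), 0)
    # band: dilate the mask's 1-px boundary 3 times, edge must sit inside
    boundary <- derive_edge(smp$mask, thickness = 1) +
      (cc_ns$dilate_cross(smp$mask) - smp$mask)
    band <- boundary
    for (k in 1:3) band <- cc_ns$dilate_cross(band)
    expect_true(all(e <= band))
  }
})

test_that("all six TTA transforms invert bit-exactly on arbitrary arrays", {
  set.seed(72)
  x <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  m <- matrix(rbinom(144, 1, 0.3), 12, 12)
  for (nm in tta_transforms()$name) {
    expect_identical(tta_invert(tta_apply(x, nm), nm), x)
    expect_identical(tta_invert(tta_apply(m, nm), nm), m)
    # involution for the flips
    if (nm %in% c("hflip", "vflip"))
      expect_identical(tta_apply(tta_apply(m, nm), nm), m)
  }
})

test_that("TTA averaging is exact for constant and equivariant predictors", {
  set.seed(73)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  const_model <- function(im) matrix(0.42, 16, 16)
  expect_equal(predict_tta(const_model, img), matrix(0.42, 16, 16))
  # per-pixel channel mean commutes with every axis-aligned transform
  equiv_model <- function(im) apply(im, c(1, 2), mean)
  expect_equal(predict_tta(equiv_model, img), equiv_model(img),
               tolerance = 1e-12)
})

test_that("augmentation is seed-reproducible and keeps the mask binary", {
  set.seed(74)
  smp <- generate_sample(easy_spec(7, image_size = 96))
  a1 <- augment_train(smp, rng_seed = 99, out_size = 64,
                      params = augment_params(gt_pad = 8))
  a2 <- augment_train(smp, rng_seed = 99, out_size = 64,
                      params = augment_params(gt_pad = 8))
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_equal(dim(a1$image), c(64, 64, 3))
})

test_that("with all transforms disabled augmentation reduces to a resize", {
  set.seed(75)
  smp <- generate_sample(easy_spec(8, image_size = 96))
  off <- augment_params(hflip = FALSE, vflip = FALSE, scale_range = NULL,
                        rot_range = NULL, gt_crop = FALSE, mls = FALSE)
  a <- augment_train(smp, rng_seed = 1, params = off, out_size = 64)
  r <- resize_sample(smp, 64)
  expect_equal(a$image, r$image, tolerance = 1e-12)
  expect_identical(a$mask, r$mask)
  expect_true(all(a$mask %in% c(0, 1)))
})

test_that("image and mask stay geometrically aligned through augmentation", {
  set.seed(76)
  for (i in 1:3) {
    smp <- generate_sample(easy_spec(20 + i, image_size = 96))
    # encode the mask into an image channel; after augmentation the decoded
    # channel must match the transformed mask (same transform path)
    probe <- smp
    probe$image[, , 1] <- smp$mask
    a <- augment_train(probe, rng_seed = 300 + i, out_size = 64,
                       params = augment_params(gt_pad = 8, mls = FALSE))
    decoded <- (a$image[, , 1] >= 0.5) * 1
    cc <- confusion(decoded, a$mask)
    m <- metrics_from_counts(cc)
    expect_gte(m$JA, 0.93)  # bilinear vs nearest differ only on the boundary
  }
})

test_that("empty-mask samples skip the ground-truth crop with a message", {
  set.seed(77)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  smp <- image_sample(img, matrix(0, 48, 48))
  expect_message(
    a <- augment_train(smp, rng_seed = 5, out_size = 32,
                       params = augment_params(mls = FALSE)),
    "skipped")
  expect_equal(dim(a$mask), c(32, 32))
})

test_that("rigid MLS: zero displacement is the identity, uniform shift is a translation", {
  set.seed(78)
  smp <- generate_sample(easy_spec(9, image_size = 48))
  g <- as.matrix(expand.grid(r = c(8, 24, 40), c = c(8, 24, 40)))
  w0 <- rigid_mls_warp(smp$image, smp$mask, g, matrix(0, 9, 2))
  rr <- matrix(rep(1:48, 48), 48, 48)
  expect_lt(max(abs(w0$sr - rr)), 1e-8)
  expect_identical(w0$mask, smp$mask)
  # all handles moved by the same vector -> a global translation
  t_vec <- c(3, -2)
  wt <- rigid_mls_warp(smp$image, smp$mask, g,
                       matrix(rep(t_vec, each = 9), 9, 2))
  expect_lt(max(abs((wt$sr - rr) - (-t_vec[1]))), 1e-6)
  interior <- smp$mask[4:45, 4:45]
  shifted <- wt$mask[(4:45) + t_vec[1], (4:45) + t_vec[2]]
  expect_equal(shifted, interior)
  expect_error(rigid_mls_warp(smp$image, smp$mask, g[1:2, ],
                              matrix(0, 2, 2)), "3 control points")
})

test_that("random MLS warps keep the mask binary with bounded area change", {
  set.seed(79)
  for (i in 1:5) {
    smp <- generate_sample(easy_spec(30 + i, image_size = 64))
    g <- as.matrix(expand.grid(r = seq(8, 56, length.out = 4),
                               c = seq(8, 56, length.out = 4)))
    d <- matrix(runif(32, -3.2, 3.2), 16, 2)  # 5% of the 64-px side
    w <- rigid_mls_warp(smp$image, smp$mask, g, d)
    expect_true(all(w$mask %in% c(0, 1)))
    a0 <- sum(smp$mask)
    expect_lt(abs(sum(w$mask) - a0) / a0, 0.2)
  }
})
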