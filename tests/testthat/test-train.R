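# Trainer: learning-rate schedule, loss descent on a small smoke problem,
# ablation structure, checkpoint round trips, deterministic evaluation,
# file prediction.

test_that("the learning rate decays exponentially per epoch", {
  set.seed(91)
  data <- easy_samples(300 + 1:8)
  tc <- train_config(batch_size = 4, epochs = 3, lr = 1e-4, lr_decay = 0.9,
                     mode = "seg_only", seed = 1, augment = NULL)
  res <- train_lesion_net(tiny_cfg(), tc, data)
  expect_equal(res$history$lr, 1e-4 * 0.9^(0:2), tolerance = 1e-12)
})

test_that("a short run decreases the training loss on easy data", {
  set.seed(92)
  data <- easy_samples(400 + 1:24)
  tc <- train_config(batch_size = 8, epochs = 4, lr = 1e-3, mode = "full",
                     seed = 2, augment = NULL)
  res <- train_lesion_net(tiny_cfg(), tc, data)
  expect_lt(res$history$loss[4], res$history$loss[1])
  expect_true(all(is.finite(res$history$loss)))
})

test_that("ablation variants assemble with strictly decreasing capacity", {
  set.seed(93)
  cfg <- tiny_cfg()
  n_full <- cc_ns$n_params(cc_ns$model_modules(build_lesion_net(cfg, "full")))
  n_se <- cc_ns$n_params(cc_ns$model_modules(build_lesion_net(cfg, "seg_edge")))
  n_s <- cc_ns$n_params(cc_ns$model_modules(build_lesion_net(cfg, "seg_only")))
  expect_gt(n_full, n_se)  # the aggregation head is extra
  expect_gt(n_se, n_s)     # the edge subnet is extra
})

test_that("checkpoints round-trip weights, config and predictions", {
  set.seed(94)
  cfg <- tiny_cfg()
  model <- build_lesion_net(cfg, "full")
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p0 <- predict_probability(model, img)$seg
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  restored <- load_checkpoint(ck)
  expect_equal(restored$mode, "full")
  expect_identical(predict_probability(restored, img)$seg, p0)
})

test_that("two runs with identical config and seed give identical metrics", {
  data <- easy_samples(500 + 1:12)
  val <- easy_samples(600 + 1:4)
  run <- function() {
    tc <- train_config(batch_size = 4, epochs = 2, lr = 1e-3,
                       mode = "seg_edge", seed = 7, augment = augment_params(
                         scale_range = NULL, rot_range = NULL,
                         gt_crop = FALSE, mls = FALSE))
    res <- train_lesion_net(tiny_cfg(), tc, data, val_data = val)
    evaluate_lesion_net(res$model, val)
  }
  expect_identical(run(), run())
})

test_that("an oracle predictor scores a perfect Jaccard through the TTA path", {
  set.seed(95)
  smp <- generate_sample(easy_spec(61))
  probe <- smp$image
  probe[, , 1] <- smp$mask  # encode the truth so the oracle is equivariant
  oracle <- function(img) img[, , 1]
  p <- predict_tta(oracle, probe)
  m <- metrics_from_counts(confusion(p, smp$mask))
  expect_equal(m$JA, 1)
})

test_that("file prediction writes maps at native resolution and survives bad files", {
  set.seed(96)
  cfg <- tiny_cfg()
  model <- build_lesion_net(cfg, "full")
  dir <- file.path(tempdir(), "predout")
  smp <- generate_sample(easy_spec(62, image_size = 96))
  img_path <- file.path(tempdir(), "in96.png")
  png::writePNG(smp$image, img_path)
  bad_path <- file.path(tempdir(), "missing.png")
  res <- suppressWarnings(predict_images(model, c(img_path, bad_path), dir))
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$prob[2]))
  prob <- png::readPNG(res$prob[1])
  expect_equal(dim(prob)[1:2], c(96, 96))  # resized back to native size
  mask <- png::readPNG(res$mask[1])
  expect_true(all(mask %in% c(0, 1)))
})

test_that("empty training data is a configuration error", {
  tc <- train_config(epochs = 1, mode = "seg_only", seed = 1)
  expect_error(train_lesion_net(tiny_cfg(), tc, list()), "empty")
})
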