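# Encoder: configuration contract, stage shape progression, dilation
# bookkeeping, pyramid pooling output width, determinism.

test_that("net_config validates its invariants", {
  expect_error(net_config(input_size = 100), "multiple of 8")
  expect_error(net_config(width_mult = 0), "width_mult")
  expect_error(net_config(conv4_blocks = 0), "conv4_blocks")
  cfg <- net_config(input_size = 64, width_mult = 1 / 8, conv4_blocks = 2)
  expect_equal(cfg$feature_size, 8L)
  expect_equal(cfg$ch(128), 16L)
  expect_equal(cfg$ch(1024), 128L)
})

test_that("tiny-config stage shapes follow the /2, /4, /8, /8, /8 progression", {
  set.seed(21)
  tab <- audit_shapes(tiny_cfg())
  get <- function(st) unlist(tab[tab$stage == st, c("channels", "height", "width")])
  expect_equal(unname(get("conv1")), c(8, 32, 32))
  expect_equal(unname(get("conv2")), c(32, 16, 16))
  expect_equal(unname(get("conv3")), c(64, 8, 8))
  expect_equal(unname(get("conv4")), c(128, 8, 8))
  expect_equal(unname(get("F")), c(16, 8, 8))   # 128/8 channels, 64/8 px
})

test_that("shape contract holds over a grid of configurations", {
  set.seed(22)
  grid <- list(list(s = 32L, w = 1 / 16), list(s = 48L, w = 1 / 8),
               list(s = 64L, w = 1 / 4))
  for (g in grid) {
    cfg <- net_config(input_size = g$s, width_mult = g$w, conv4_blocks = 1)
    tab <- audit_shapes(cfg, mode = "seg_only")
    sizes <- tab$height[match(c("conv1", "conv2", "conv3", "conv4", "F"),
                              tab$stage)]
    expect_equal(sizes, c(g$s / 2, g$s / 4, g$s / 8, g$s / 8, g$s / 8))
    expect_equal(tab$channels[tab$stage == "F"],
                 max(1, round(128 * g$w)))
  }
})

test_that("undilated conv4 halves the spatial size (negative control)", {
  set.seed(23)
  cfg <- tiny_cfg()
  dilated <- build_backbone(cfg, dilated_conv4 = TRUE)
  undilated <- build_backbone(cfg, dilated_conv4 = FALSE)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f_dil <- forward_backbone(dilated, x)
  f_und <- forward_backbone(undilated, x)
  expect_equal(dim(f_dil)[1:2], c(8, 8))
  expect_equal(dim(f_und)[1:2], c(4, 4))
})

test_that("PPM output channels equal the configured width regardless of bins", {
  set.seed(24)
  for (bins in list(c(1L, 2L), c(1L, 2L, 3L, 6L))) {
    cfg <- net_config(input_size = 32, width_mult = 1 / 8, conv4_blocks = 1,
                      ppm_bins = bins)
    f <- forward_backbone(build_backbone(cfg), array(runif(32 * 32 * 3),
                                                     c(32, 32, 3)))
    expect_equal(dim(f)[3], cfg$ch(128))
  }
})

test_that("encoder forward is finite, deterministic, and input-sensitive", {
  set.seed(25)
  model <- build_backbone(tiny_cfg())
  zeros <- array(0, c(64, 64, 3))
  f0 <- forward_backbone(model, zeros)
  expect_true(all(is.finite(f0)))
  expect_identical(forward_backbone(model, zeros), f0)  # bit-identical repeat
  one_px <- zeros
  one_px[32, 32, 1] <- 1
  expect_false(identical(forward_backbone(model, one_px), f0))
})

test_that("wrong input size raises a shape error naming the expected size", {
  set.seed(26)
  model <- build_backbone(tiny_cfg())
  expect_error(forward_backbone(model, array(0, c(32, 32, 3))), "64x64")
})
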