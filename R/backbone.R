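# Encoder: truncated residual network (Conv1..Conv4, with Conv4 switched to
# stride 1 / dilation 2 so the feature resolution stays at input/8) followed
# by a pyramid pooling module (PPM) producing the shared feature map F.

#' Network configuration
#'
#' Width/depth/input-size knobs for the segmentation network. The defaults
#' instantiate the full-size architecture: a 448x448 input, stage widths
#' 64/256/512/1024, 23 dilated residual blocks in Conv4, pyramid pooling
#' with bin sizes 1, 2, 3 and 6, and a 128-channel shared feature map.
#' `width_mult` scales every channel count (the decoder bottleneck included),
#' which lets the same architecture run at CPU-test size, e.g.
#' `net_config(input_size = 64, width_mult = 1/8, conv4_blocks = 2)`.
#'
#' @param input_size square input side in pixels; must be divisible by 8
#'   (the encoder reduces resolution three times by 2x).
#' @param width_mult positive channel multiplier; every scaled count is
#'   rounded and floored at 1.
#' @param conv4_blocks number of residual blocks in the dilated Conv4 stage.
#' @param ppm_bins integer vector of pyramid pooling bin sizes.
#' @param ppm_out_channels channels of the shared feature map F (before
#'   width scaling).
#' @param edge_thickness thickness in pixels of the derived edge ground
#'   truth used during training.
#' @return an object of class `net_config`.
#' @export
#' @examples
#' cfg <- net_config(input_size = 64, width_mult = 1 / 8, conv4_blocks = 2)
#' cfg$feature_size  # input_size / 8
net_config <- function(input_size = 448L, width_mult = 1, conv4_blocks = 23L,
                       ppm_bins = c(1L, 2L, 3L, 6L), ppm_out_channels = 128L,
                       edge_thickness = 2L) {
  input_size <- as.integer(input_size)
  if (is.na(input_size) || input_size <= 0 || input_size %% 8L != 0L)
    stop("configuration error: input_size must be a positive multiple of 8, got ",
         input_size)
  if (!is.numeric(width_mult) || width_mult <= 0)
    stop("configuration error: width_mult must be positive")
  if (conv4_blocks < 1L) stop("configuration error: conv4_blocks must be >= 1")
  ch <- function(n) max(1L, as.integer(round(n * width_mult)))
  cfg <- list(
    input_size = input_size,
    width_mult = width_mult,
    conv4_blocks = as.integer(conv4_blocks),
    ppm_bins = as.integer(ppm_bins),
    ppm_out_channels = as.integer(ppm_out_channels),
    edge_thickness = as.integer(edge_thickness),
    ch = ch,
    feature_size = input_size %/% 8L
  )
  class(cfg) <- "net_config"
  cfg
}

#' @export
print.net_config <- function(x, ...) {
  cat("<net_config> input", x$input_size, "| width_mult", x$width_mult,
      "| conv4_blocks", x$conv4_blocks, "| F:",
      paste0("(", x$ch(x$ppm_out_channels), ",", x$feature_size, ",",
             x$feature_size, ")"), "\n")
  invisible(x)
}

#' Build the encoder (residual stages + pyramid pooling)
#'
#' Conv1 is a stride-2 7x7 convolution followed by a stride-2 3x3 max-pool;
#' Conv2 (3 blocks) runs at input/4, Conv3 (4 blocks, first stride 2) at
#' input/8, and Conv4 (`cfg$conv4_blocks` blocks) keeps input/8 by using
#' stride 1 with dilation 2 in its 3x3 convolutions. The pyramid pooling
#' module pools Conv4's output at each bin size, reduces each pooled map by
#' a 1x1 convolution to `ppm_out_channels / 4` channels, upsamples back,
#' concatenates with the Conv4 map and fuses with a 3x3 convolution to
#' `ppm_out_channels`.
#'
#' Weights are He-initialised from the current RNG state; an optional hook
#' (`load_state()` on a checkpoint) restores externally supplied weights.
#'
#' @param cfg a [net_config()].
#' @param dilated_conv4 if `FALSE`, Conv4 instead uses the classification
#'   layout (first block stride 2, no dilation), halving its resolution; a
#'   negative control used to verify the dilation bookkeeping.
#' @return a backbone model object.
#' @export
build_backbone <- function(cfg, dilated_conv4 = TRUE) {
  stopifnot(inherits(cfg, "net_config"))
  ch <- cfg$ch
  c64 <- ch(64); c256 <- ch(256); c512 <- ch(512); c1024 <- ch(1024)
  m64 <- ch(64); m128 <- ch(128); m256 <- ch(256)
  stem <- new_sequential(new_conv2d(3L, c64, k = 7L, stride = 2L, pad = 3L),
                         new_batchnorm(c64), new_relu())
  conv2 <- do.call(new_sequential, c(
    list(new_bottleneck(c64, m64, c256)),
    lapply(seq_len(2), function(i) new_bottleneck(c256, m64, c256))))
  conv3 <- do.call(new_sequential, c(
    list(new_bottleneck(c256, m128, c512, stride = 2L)),
    lapply(seq_len(3), function(i) new_bottleneck(c512, m128, c512))))
  s4 <- if (dilated_conv4) 1L else 2L
  d4 <- if (dilated_conv4) 2L else 1L
  conv4 <- do.call(new_sequential, c(
    list(new_bottleneck(c512, m256, c1024, stride = s4, dil = d4)),
    if (cfg$conv4_blocks > 1L)
      lapply(seq_len(cfg$conv4_blocks - 1L),
             function(i) new_bottleneck(c1024, m256, c1024, dil = d4))))
  f_ch <- ch(cfg$ppm_out_channels)
  bin_ch <- max(1L, as.integer(round(f_ch / length(cfg$ppm_bins))))
  ppm_branches <- lapply(cfg$ppm_bins, function(b)
    new_sequential(new_conv2d(c1024, bin_ch, k = 1L),
                   new_batchnorm(bin_ch), new_relu()))
  names(ppm_branches) <- paste0("bin", cfg$ppm_bins)
  ppm_fuse <- conv_bn_relu(c1024 + bin_ch * length(cfg$ppm_bins), f_ch, k = 3L)
  model <- list(cfg = cfg, stem = stem, conv2 = conv2, conv3 = conv3,
                conv4 = conv4, ppm_branches = ppm_branches,
                ppm_fuse = ppm_fuse, dilated_conv4 = dilated_conv4)
  class(model) <- "cclseg_backbone"
  model
}

# Forward pass through all stages; returns the list of stage outputs
# (ag nodes) so callers can audit shapes or pick up F.
backbone_stages <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  conv1 <- model$stem$forward(x, training)
  pooled <- ag_maxpool(conv1, k = 3L, stride = 2L, pad = 1L)
  conv2 <- model$conv2$forward(pooled, training)
  conv3 <- model$conv3$forward(conv2, training)
  conv4 <- model$conv4$forward(conv3, training)
  d4 <- dim(ag_value(conv4))
  pyramid <- lapply(seq_along(cfg$ppm_bins), function(i) {
    b <- cfg$ppm_bins[i]
    p <- ag_avgpool_adaptive(conv4, b)
    p <- model$ppm_branches[[i]]$forward(p, training)
    ag_resize_bilinear(p, d4[1], d4[2])
  })
  fused <- model$ppm_fuse$forward(ag_concat_c(c(list(conv4), pyramid)), training)
  list(conv1 = conv1, conv2 = conv2, conv3 = conv3, conv4 = conv4, F = fused)
}

#' Run the encoder on an image batch
#'
#' @param model a backbone from [build_backbone()].
#' @param image array `(H, W, 3)` or batch `(H, W, 3, N)` with
#'   `H == W == cfg$input_size`, values in `[0, 1]`.
#' @param training logical; `FALSE` (default) uses frozen batch-norm
#'   statistics and records no gradients.
#' @return the shared feature map F as an array `(S/8, S/8, C_F, N)`.
#' @export
forward_backbone <- function(model, image, training = FALSE) {
  x <- as_batch(image)
  d <- dim(ag_value(x))
  s <- model$cfg$input_size
  if (d[1] != s || d[2] != s)
    stop("shape error: expected ", s, "x", s, " input, got ", d[1], "x", d[2])
  if (training) {
    backbone_stages(model, x, training = TRUE)$F
  } else {
    ag_no_grad(ag_value(backbone_stages(model, x)$F))
  }
}

# Coerce (H,W,C) or (H,W,C,N) numeric arrays (or ag nodes) to a 4-d batch.
as_batch <- function(x) {
  if (inherits(x, "ag")) return(x)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("shape error: expected an (H,W,C) or (H,W,C,N) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  new_ag(x)
}
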