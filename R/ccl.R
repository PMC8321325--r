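# Cross-connected decoder branches: the Seg subnet and the Edge subnet are
# parallel stacks of three residual up-blocks. After the first stage, each
# branch's next block receives the element-wise sum of its own previous
# output and the other branch's previous output (the cross-connection), so
# edge evidence flows into the mask decoder and vice versa.

#' Residual up-block of the decoder branches
#'
#' The block keeps its channel count so the skip connection is addable:
#' 1x1 convolution (same width), 3x3 convolution shrunk to the bottleneck
#' width (32 at default scale), 1x1 convolution back to the block width,
#' each followed by batch norm (ReLU after the first two); the input is then
#' added back and the result upsampled 2x by bilinear interpolation. There
#' is no activation after the skip-add, so a zero-weight block is exactly a
#' 2x upsampling of its input.
#'
#' @param channels block input/output channels (128 at default width).
#' @param bottleneck 3x3 stage channels (32 at default width).
#' @return a layer object; apply with `residual_up_block(layer, x)`.
#' @export
new_residual_up_block <- function(channels, bottleneck) {
  l <- new.env(parent = emptyenv())
  l$type <- "sequential"  # reuse sequential param walking
  l$layers <- list(new_conv2d(channels, channels, k = 1L),
                   new_batchnorm(channels), new_relu(),
                   new_conv2d(channels, bottleneck, k = 3L),
                   new_batchnorm(bottleneck), new_relu(),
                   new_conv2d(bottleneck, channels, k = 1L),
                   new_batchnorm(channels))
  l$channels <- channels
  l$bottleneck <- bottleneck
  l$forward <- function(x, training = FALSE) {
    out <- x
    for (sub in l$layers) out <- sub$forward(out, training)
    d <- dim(ag_value(x))
    ag_resize_bilinear(ag_add(out, x), 2L * d[1], 2L * d[2])
  }
  class(l) <- "cclseg_layer"
  l
}

#' Apply a residual up-block
#'
#' @param block a block from [new_residual_up_block()].
#' @param x input array `(H, W, C)` or `(H, W, C, N)` (or an `ag` node)
#'   with `C == block$channels`.
#' @param training logical batch-norm mode.
#' @return array (or `ag` node, if `x` was one) of shape `(2H, 2W, C, N)`.
#' @export
residual_up_block <- function(block, x, training = FALSE) {
  was_ag <- inherits(x, "ag")
  xb <- as_batch(x)
  d <- dim(ag_value(xb))
  if (d[3] != block$channels)
    stop("shape error: block expects ", block$channels, " channels, got ", d[3])
  if (was_ag) block$forward(xb, training)
  else ag_no_grad(ag_value(block$forward(xb)))
}

#' Build the two cross-connected decoder branches
#'
#' @param cfg a [net_config()].
#' @param edge_branch include the Edge subnet (`FALSE` for the
#'   segmentation-only ablation).
#' @param cross_connect fuse the branches' intermediate maps (`FALSE`
#'   decouples them; automatically `FALSE` when `edge_branch` is).
#' @return a CCL module.
#' @export
build_ccl <- function(cfg, edge_branch = TRUE, cross_connect = TRUE) {
  stopifnot(inherits(cfg, "net_config"))
  chn <- cfg$ch(cfg$ppm_out_channels)
  btl <- cfg$ch(32)
  mk_branch <- function() lapply(1:3, function(i) new_residual_up_block(chn, btl))
  mod <- list(cfg = cfg,
              seg = mk_branch(),
              edge = if (edge_branch) mk_branch(),
              cross = cross_connect && edge_branch)
  class(mod) <- "cclseg_ccl"
  mod
}

#' Run the decoder branches on the shared feature map
#'
#' Stage 1 applies each branch's first block to F directly. At stage k > 1
#' the Seg block receives `s_{k-1} + e_{k-1}` and the Edge block receives
#' `e_{k-1} + s_{k-1}` (element-wise sums of the already-upsampled previous
#' outputs), which keeps the printed channel widths intact.
#'
#' @param ccl module from [build_ccl()].
#' @param f shared feature map (array or `ag` node), `(S/8, S/8, C_F, N)`.
#' @param training logical batch-norm mode.
#' @return list with elements `seg` and `edge` (the latter `NULL` without an
#'   edge branch), each a list of the three stage outputs; arrays when `f`
#'   was an array, `ag` nodes when it was a node.
#' @export
forward_ccl <- function(ccl, f, training = FALSE) {
  was_ag <- inherits(f, "ag")
  run <- function() {
    fb <- as_batch(f)
    s <- list(ccl$seg[[1]]$forward(fb, training))
    e <- if (!is.null(ccl$edge)) list(ccl$edge[[1]]$forward(fb, training))
    for (k in 2:3) {
      s_in <- if (ccl$cross) ag_add(s[[k - 1]], e[[k - 1]]) else s[[k - 1]]
      s[[k]] <- ccl$seg[[k]]$forward(s_in, training)
      if (!is.null(e)) {
        e_in <- if (ccl$cross) ag_add(e[[k - 1]], s[[k - 1]]) else e[[k - 1]]
        e[[k]] <- ccl$edge[[k]]$forward(e_in, training)
      }
    }
    list(seg = s, edge = e)
  }
  if (was_ag) run()
  else ag_no_grad({
    r <- run()
    list(seg = lapply(r$seg, ag_value),
         edge = if (!is.null(r$edge)) lapply(r$edge, ag_value))
  })
}
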