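# Multi-scale feature aggregation head. Each decoder stage output receives
# a per-scale prediction head (3x3 conv + BN + ReLU, then 3x3 conv to depth
# one); a fourth map is a direct 1x1 convolution of the last stage. The
# four logit maps are upsampled to full resolution, concatenated and fused
# by a learned 1x1 convolution; a single sigmoid is applied at the end, so
# the aggregation weights act on logits. One head object serves BOTH the
# segmentation and the edge branch (shared parameters).

#' Build the multi-scale aggregation head
#'
#' @param cfg a [net_config()].
#' @return an MSFA module (shared between the two task branches).
#' @export
build_msfa <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  chn <- cfg$ch(cfg$ppm_out_channels)
  mk_head <- function() {
    l <- new.env(parent = emptyenv())
    l$type <- "sequential"
    l$layers <- list(new_conv2d(chn, chn, k = 3L),
                     new_batchnorm(chn), new_relu(),
                     new_conv2d(chn, 1L, k = 3L, bias = TRUE))
    l$forward <- function(x, training = FALSE) {
      for (sub in l$layers) x <- sub$forward(x, training)
      x
    }
    class(l) <- "cclseg_layer"
    l
  }
  mod <- list(cfg = cfg,
              heads = list(mk_head(), mk_head(), mk_head()),
              direct = new_conv2d(chn, 1L, k = 1L, bias = TRUE),
              aggregate = new_conv2d(4L, 1L, k = 1L, bias = TRUE))
  class(mod) <- "cclseg_msfa"
  mod
}

#' Per-scale prediction head
#'
#' Applies one scale's head: 3x3 convolution keeping the branch width, batch
#' norm, ReLU, then a 3x3 convolution to a single channel. Output is on the
#' logit scale (no sigmoid).
#'
#' @param msfa module from [build_msfa()].
#' @param x feature map `(H, W, C)` / `(H, W, C, N)` with the branch width.
#' @param scale which head to apply (1..3).
#' @param training logical batch-norm mode.
#' @return single-channel map `(H, W, 1, N)`.
#' @export
conv_block_predict <- function(msfa, x, scale = 1L, training = FALSE) {
  was_ag <- inherits(x, "ag")
  xb <- as_batch(x)
  y <- msfa$heads[[scale]]$forward(xb, training)
  if (was_ag) y else ag_no_grad(ag_value(y))
}

# Internal: full-resolution probability map from one branch pyramid.
msfa_forward_ag <- function(msfa, pyramid, training = FALSE,
                            return_stack = FALSE) {
  s <- msfa$cfg$input_size
  logits <- lapply(1:3, function(k)
    msfa$heads[[k]]$forward(pyramid[[k]], training))
  logits[[4]] <- msfa$direct$forward(pyramid[[3]], training)
  up <- lapply(logits, function(l) ag_resize_bilinear(l, s, s))
  stack <- ag_concat_c(up)
  out <- ag_sigmoid(msfa$aggregate$forward(stack, training))
  if (return_stack) list(prob = out, stack = stack) else out
}

#' Aggregate a branch pyramid into one probability map
#'
#' @param msfa module from [build_msfa()].
#' @param pyramid list of the three stage outputs of one branch (arrays or
#'   `ag` nodes), as returned by [forward_ccl()].
#' @param training logical batch-norm mode.
#' @param return_stack also return the pre-aggregation `(S, S, 4, N)` logit
#'   stack (for shape audits).
#' @return probability map `(S, S, 1, N)` with values strictly in (0, 1);
#'   with `return_stack = TRUE`, a list `prob` / `stack`.
#' @export
forward_msfa <- function(msfa, pyramid, training = FALSE,
                         return_stack = FALSE) {
  was_ag <- inherits(pyramid[[1]], "ag")
  if (was_ag)
    return(msfa_forward_ag(msfa, pyramid, training, return_stack))
  ag_no_grad({
    pyr <- lapply(pyramid, as_batch)
    r <- msfa_forward_ag(msfa, pyr, training, return_stack)
    if (return_stack) list(prob = ag_value(r$prob), stack = ag_value(r$stack))
    else ag_value(r)
  })
}

# Minimal head used when the MSFA module is ablated: 1x1 conv + sigmoid on
# the last stage output of a branch. Shared between branches, mirroring the
# MSFA sharing.
build_simple_head <- function(cfg) {
  mod <- list(cfg = cfg,
              conv = new_conv2d(cfg$ch(cfg$ppm_out_channels), 1L, k = 1L,
                                bias = TRUE))
  class(mod) <- "cclseg_simple_head"
  mod
}

simple_head_forward <- function(head, pyramid, training = FALSE) {
  ag_sigmoid(head$conv$forward(pyramid[[3]], training))
}
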