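# Whole-model assembly and the three ablation configurations:
#   seg_only : encoder + PPM + Seg subnet, simple 1x1 prediction head
#   seg_edge : + Edge subnet with cross-connections, simple shared head
#   full     : + multi-scale feature aggregation head (shared)

#' Build the full segmentation network
#'
#' @param cfg a [net_config()].
#' @param mode ablation mode: `"full"`, `"seg_edge"` or `"seg_only"`.
#' @return a model object holding the encoder, decoder branches and head.
#' @export
build_lesion_net <- function(cfg, mode = c("full", "seg_edge", "seg_only")) {
  mode <- match.arg(mode)
  backbone <- build_backbone(cfg)
  ccl <- build_ccl(cfg, edge_branch = mode != "seg_only",
                   cross_connect = mode != "seg_only")
  head <- if (mode == "full") build_msfa(cfg) else build_simple_head(cfg)
  model <- list(cfg = cfg, mode = mode, backbone = backbone, ccl = ccl,
                head = head)
  class(model) <- "cclseg_net"
  model
}

#' @export
print.cclseg_net <- function(x, ...) {
  cat("<cclseg_net mode=", x$mode, ", input ", x$cfg$input_size, "px, ",
      format(n_params(model_modules(x)), big.mark = ","),
      " parameters>\n", sep = "")
  invisible(x)
}

model_modules <- function(model) {
  mods <- list(backbone = list(stem = model$backbone$stem,
                               conv2 = model$backbone$conv2,
                               conv3 = model$backbone$conv3,
                               conv4 = model$backbone$conv4,
                               ppm_branches = model$backbone$ppm_branches,
                               ppm_fuse = model$backbone$ppm_fuse),
               seg = model$ccl$seg)
  if (!is.null(model$ccl$edge)) mods$edge <- model$ccl$edge
  if (inherits(model$head, "cclseg_msfa"))
    mods$head <- list(heads = model$head$heads, direct = model$head$direct,
                      aggregate = model$head$aggregate)
  else mods$head <- list(conv = model$head$conv)
  mods
}

model_params <- function(model) collect_params(model_modules(model))

# Differentiable forward pass over an ag batch. Returns ag nodes.
net_forward_ag <- function(model, x, training = FALSE) {
  f <- backbone_stages(model$backbone, x, training)$F
  pyr <- forward_ccl(model$ccl, f, training)
  if (inherits(model$head, "cclseg_msfa")) {
    seg <- forward_msfa(model$head, pyr$seg, training)
    edge <- if (!is.null(pyr$edge)) forward_msfa(model$head, pyr$edge, training)
  } else {
    seg <- simple_head_forward(model$head, pyr$seg, training)
    edge <- if (!is.null(pyr$edge))
      simple_head_forward(model$head, pyr$edge, training)
  }
  list(seg = seg, edge = edge)
}

#' Predict segmentation (and edge) probability maps
#'
#' Inference-mode forward pass: frozen batch-norm statistics, no gradient
#' graph, deterministic for fixed weights and input.
#'
#' @param model a [build_lesion_net()] model.
#' @param image `(H, W, 3)` array or `(H, W, 3, N)` batch in `[0, 1]`, with
#'   `H == W == cfg$input_size`.
#' @return list with `seg` (array `(S, S, 1, N)` of probabilities) and
#'   `edge` (same, or `NULL` in `seg_only` mode).
#' @export
predict_probability <- function(model, image) {
  x <- as_batch(image)
  d <- dim(ag_value(x))
  s <- model$cfg$input_size
  if (d[1] != s || d[2] != s)
    stop("shape error: expected ", s, "x", s, " input, got ", d[1], "x", d[2])
  ag_no_grad({
    out <- net_forward_ag(model, x, training = FALSE)
    list(seg = ag_value(out$seg),
         edge = if (!is.null(out$edge)) ag_value(out$edge))
  })
}

#' Audit every printed tensor shape of the architecture
#'
#' Runs a single random image through the network in inference mode and
#' records the (channels, height, width) of each named stage: the encoder
#' stages Conv1..Conv4, the shared feature map F, the three decoder outputs
#' of each branch, and (in `full` mode) the pre-aggregation four-channel
#' stack and final prediction. At the default configuration this reproduces
#' the published architecture table, e.g. Conv4 `(1024, 56, 56)` and F
#' `(128, 56, 56)` for a 448x448 input.
#'
#' @param cfg a [net_config()].
#' @param mode ablation mode (default `"full"`).
#' @param model optionally, an already-built model (saves rebuild time).
#' @return `data.frame` with columns `stage`, `channels`, `height`, `width`.
#' @export
audit_shapes <- function(cfg = net_config(), mode = "full", model = NULL) {
  if (is.null(model)) model <- build_lesion_net(cfg, mode)
  s <- cfg$input_size
  x <- array(stats::runif(s * s * 3), c(s, s, 3, 1))
  rows <- list()
  add <- function(stage, v) {
    d <- dim(v)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, channels = d[3],
                                             height = d[1], width = d[2])
  }
  ag_no_grad({
    st <- backbone_stages(model$backbone, as_batch(x))
    for (nm in names(st)) add(nm, ag_value(st[[nm]]))
    pyr <- forward_ccl(model$ccl, st$F)
    for (k in 1:3) add(paste0("S_conv", k), ag_value(pyr$seg[[k]]))
    if (!is.null(pyr$edge))
      for (k in 1:3) add(paste0("E_conv", k), ag_value(pyr$edge[[k]]))
    if (inherits(model$head, "cclseg_msfa")) {
      r <- forward_msfa(model$head, pyr$seg, return_stack = TRUE)
      add("msfa_stack", ag_value(r$stack))
      add("prediction", ag_value(r$prob))
    } else {
      add("prediction", ag_value(simple_head_forward(model$head, pyr$seg)))
    }
  })
  do.call(rbind, rows)
}
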