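# Network building blocks: conv / batch-norm layers as environments holding
# `ag` leaf parameters, plus composite blocks (conv-BN-ReLU stacks and
# residual bottlenecks). Parameter collection walks these recursively for
# the optimiser and for checkpoint (de)serialisation.

he_init <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        c(kh, kw, cin, cout))
}

new_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = NULL, dil = 1L,
                       bias = FALSE) {
  if (is.null(pad)) pad <- ((k - 1L) %/% 2L) * dil  # "same" at stride 1
  l <- new.env(parent = emptyenv())
  l$type <- "conv2d"
  l$w <- ag_leaf(he_init(k, k, cin, cout))
  l$b <- if (bias) ag_leaf(numeric(cout)) else NULL
  l$stride <- stride; l$pad <- pad; l$dil <- dil
  l$forward <- function(x, training = FALSE)
    ag_conv2d(x, l$w, l$b, stride = l$stride, pad = l$pad, dil = l$dil)
  class(l) <- "cclseg_layer"
  l
}

new_batchnorm <- function(ch) {
  l <- new.env(parent = emptyenv())
  l$type <- "batchnorm"
  l$gamma <- ag_leaf(rep(1, ch))
  l$beta <- ag_leaf(rep(0, ch))
  l$running_mean <- rep(0, ch)
  l$running_var <- rep(1, ch)
  l$forward <- function(x, training = FALSE)
    ag_batchnorm(x, l$gamma, l$beta, l, training)
  class(l) <- "cclseg_layer"
  l
}

new_relu <- function() {
  l <- new.env(parent = emptyenv())
  l$type <- "relu"
  l$forward <- function(x, training = FALSE) ag_relu(x)
  class(l) <- "cclseg_layer"
  l
}

new_sequential <- function(...) {
  l <- new.env(parent = emptyenv())
  l$type <- "sequential"
  l$layers <- list(...)
  l$forward <- function(x, training = FALSE) {
    for (sub in l$layers) x <- sub$forward(x, training)
    x
  }
  class(l) <- "cclseg_layer"
  l
}

conv_bn_relu <- function(cin, cout, k = 3L, stride = 1L, pad = NULL, dil = 1L) {
  new_sequential(new_conv2d(cin, cout, k, stride, pad, dil),
                 new_batchnorm(cout), new_relu())
}

# Standard bottleneck residual block (1x1 reduce, 3x3, 1x1 expand) with a
# projection shortcut when shape changes; post-add ReLU.
new_bottleneck <- function(cin, mid, cout, stride = 1L, dil = 1L) {
  l <- new.env(parent = emptyenv())
  l$type <- "bottleneck"
  l$conv1 <- new_conv2d(cin, mid, k = 1L, stride = 1L)
  l$bn1 <- new_batchnorm(mid)
  l$conv2 <- new_conv2d(mid, mid, k = 3L, stride = stride, dil = dil)
  l$bn2 <- new_batchnorm(mid)
  l$conv3 <- new_conv2d(mid, cout, k = 1L)
  l$bn3 <- new_batchnorm(cout)
  if (cin != cout || stride != 1L) {
    l$proj <- new_conv2d(cin, cout, k = 1L, stride = stride)
    l$proj_bn <- new_batchnorm(cout)
  }
  l$forward <- function(x, training = FALSE) {
    out <- ag_relu(l$bn1$forward(l$conv1$forward(x), training))
    out <- ag_relu(l$bn2$forward(l$conv2$forward(out), training))
    out <- l$bn3$forward(l$conv3$forward(out), training)
    sc <- if (is.null(l$proj)) x
          else l$proj_bn$forward(l$proj$forward(x), training)
    ag_relu(ag_add(out, sc))
  }
  class(l) <- "cclseg_layer"
  l
}

# Depth-first parameter collection, stable order, named by path.
collect_params <- function(layer, prefix = "") {
  out <- list()
  push <- function(name, p) {
    if (!is.null(p)) out[[paste0(prefix, name)]] <<- p
  }
  if (is.list(layer) && !inherits(layer, "cclseg_layer")) {
    nms <- if (is.null(names(layer))) as.character(seq_along(layer))
           else names(layer)
    for (i in seq_along(layer))
      out <- c(out, collect_params(layer[[i]], paste0(prefix, nms[i], ".")))
    return(out)
  }
  if (!inherits(layer, "cclseg_layer")) return(out)
  switch(layer$type,
    conv2d = { push("w", layer$w); push("b", layer$b) },
    batchnorm = { push("gamma", layer$gamma); push("beta", layer$beta) },
    relu = NULL,
    sequential = {
      for (i in seq_along(layer$layers))
        out <- c(out, collect_params(layer$layers[[i]],
                                     paste0(prefix, "l", i, ".")))
    },
    bottleneck = {
      for (nm in c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3",
                   "proj", "proj_bn"))
        if (!is.null(layer[[nm]]))
          out <- c(out, collect_params(layer[[nm]], paste0(prefix, nm, ".")))
    },
    stop("unknown layer type: ", layer$type)
  )
  out
}

# Running statistics live outside the parameter list; collect them for
# checkpoints by walking the same paths.
collect_bn_stats <- function(layer, prefix = "") {
  out <- list()
  if (is.list(layer) && !inherits(layer, "cclseg_layer")) {
    nms <- if (is.null(names(layer))) as.character(seq_along(layer))
           else names(layer)
    for (i in seq_along(layer))
      out <- c(out, collect_bn_stats(layer[[i]], paste0(prefix, nms[i], ".")))
    return(out)
  }
  if (!inherits(layer, "cclseg_layer")) return(out)
  if (layer$type == "batchnorm") {
    out[[paste0(prefix, "running_mean")]] <- layer$running_mean
    out[[paste0(prefix, "running_var")]] <- layer$running_var
  } else if (layer$type == "sequential") {
    for (i in seq_along(layer$layers))
      out <- c(out, collect_bn_stats(layer$layers[[i]],
                                     paste0(prefix, "l", i, ".")))
  } else if (layer$type == "bottleneck") {
    for (nm in c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3",
                 "proj", "proj_bn"))
      if (!is.null(layer[[nm]]))
        out <- c(out, collect_bn_stats(layer[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

restore_bn_stats <- function(layer, stats, prefix = "") {
  if (is.list(layer) && !inherits(layer, "cclseg_layer")) {
    nms <- if (is.null(names(layer))) as.character(seq_along(layer))
           else names(layer)
    for (i in seq_along(layer))
      restore_bn_stats(layer[[i]], stats, paste0(prefix, nms[i], "."))
    return(invisible(NULL))
  }
  if (!inherits(layer, "cclseg_layer")) return(invisible(NULL))
  if (layer$type == "batchnorm") {
    rm_ <- stats[[paste0(prefix, "running_mean")]]
    rv_ <- stats[[paste0(prefix, "running_var")]]
    if (!is.null(rm_)) layer$running_mean <- rm_
    if (!is.null(rv_)) layer$running_var <- rv_
  } else if (layer$type == "sequential") {
    for (i in seq_along(layer$layers))
      restore_bn_stats(layer$layers[[i]], stats, paste0(prefix, "l", i, "."))
  } else if (layer$type == "bottleneck") {
    for (nm in c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3",
                 "proj", "proj_bn"))
      if (!is.null(layer[[nm]]))
        restore_bn_stats(layer[[nm]], stats, paste0(prefix, nm, "."))
  }
  invisible(NULL)
}

# Zero every parameter of a (sub)module in place; used in tests and for
# structural identities (a zeroed residual path reduces to its skip).
zero_params <- function(layer) {
  for (p in collect_params(layer)) p$value <- p$value * 0
  invisible(NULL)
}

n_params <- function(layer) {
  sum(vapply(collect_params(layer), function(p) length(p$value), numeric(1)))
}
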