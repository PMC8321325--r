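# Define-by-run automatic differentiation over dense arrays.
#
# Every tensor in the network is an `ag` node: an environment holding the
# value (an R array, layout (H, W, C, N)), the list of parent nodes, and a
# closure that maps the node's output gradient to per-parent gradients.
# backward() runs reverse-mode accumulation in topological order.
# Gradient recording can be switched off (inference) with ag_no_grad(),
# in which case ops return detached nodes and intermediates are free to be
# garbage-collected.

.ag_state <- new.env(parent = emptyenv())
.ag_state$grad_enabled <- TRUE
.ag_state$next_id <- 1L

ag_grad_enabled <- function() .ag_state$grad_enabled

#' Evaluate an expression with gradient recording disabled
#'
#' Used for inference and shape audits: forward passes inside `expr` build no
#' computation graph, so intermediate feature maps can be reclaimed as soon
#' as they go out of scope.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag_state$grad_enabled
  .ag_state$grad_enabled <- FALSE
  on.exit(.ag_state$grad_enabled <- old)
  expr
}

new_ag <- function(value, parents = list(), bw = NULL, requires = FALSE) {
  node <- new.env(parent = emptyenv())
  node$id <- .ag_state$next_id
  .ag_state$next_id <- .ag_state$next_id + 1L
  node$value <- value
  node$grad <- NULL
  req <- requires || any(vapply(parents, function(p) p$req, logical(1)))
  if (!ag_grad_enabled() && !requires) req <- FALSE
  node$req <- req
  if (req) {
    node$parents <- parents
    node$bw <- bw
  } else {
    node$parents <- list()
    node$bw <- NULL
  }
  class(node) <- "ag"
  node
}

#' @export
print.ag <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag tensor ", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$req) " (grad)" else "", ">\n", sep = "")
  invisible(x)
}

ag_leaf <- function(value) new_ag(value, requires = TRUE)

ag_value <- function(x) if (inherits(x, "ag")) x$value else x

as_ag <- function(x) if (inherits(x, "ag")) x else new_ag(x)

# Reverse-mode accumulation from a scalar root.
ag_backward <- function(root, grad = 1) {
  stopifnot(inherits(root, "ag"))
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (p$req && is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  # post-order: parents first; traverse reversed for reverse mode
  root$grad <- grad
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$grad) || is.null(node$bw)) next
    gs <- node$bw(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$req || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!identical(node, root)) node$grad <- NULL  # free memory
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- differentiable operations ------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- ag_value(x)
  wv <- ag_value(w)
  bv <- if (is.null(b)) numeric(0) else ag_value(b)
  # The backward pass rebuilds the patch matrix rather than caching it:
  # a per-sample patch matrix stays cache-hot, while retaining all layers'
  # stacked patches between the passes is memory-bandwidth-bound and slower.
  r <- .conv2d_fw(xv, wv, bv, as.integer(stride), as.integer(pad),
                  as.integer(dil), FALSE)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  need_gx <- inherits(x, "ag") && x$req
  kcache <- r$K
  new_ag(r$y, parents, function(g) {
    gr <- .conv2d_bw(xv, wv, g, as.integer(stride), as.integer(pad),
                     as.integer(dil), !is.null(b), need_gx, kcache)
    gx <- if (need_gx) gr$gx
    if (is.null(b)) list(gx, gr$gw) else list(gx, gr$gw, gr$gb)
  })
}

ag_relu <- function(x) {
  xv <- ag_value(x)
  new_ag(.relu_fw(xv), list(x), function(g) list(.relu_bw(xv, g)))
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-ag_value(x)))
  # keep the output strictly inside (0, 1): extreme logits saturate to
  # exactly 0/1 in double precision, which downstream logs cannot take
  y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  dim(y) <- dim(ag_value(x))
  new_ag(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_add <- function(x, y) {
  new_ag(ag_value(x) + ag_value(y), list(x, y), function(g) list(g, g))
}

ag_scale <- function(x, a) {
  new_ag(ag_value(x) * a, list(x), function(g) list(g * a))
}

ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  xv <- ag_value(x)
  r <- .maxpool_fw(xv, as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(xv)
  new_ag(r$y, list(x), function(g) list(.maxpool_bw(r$idx, g, xd)))
}

ag_avgpool_adaptive <- function(x, oh, ow = oh) {
  xv <- ag_value(x)
  xd <- dim(xv)
  y <- .avgpool_adaptive_fw(xv, as.integer(oh), as.integer(ow))
  new_ag(y, list(x), function(g) list(.avgpool_adaptive_bw(g, xd)))
}

ag_resize_bilinear <- function(x, oh, ow = oh) {
  xv <- ag_value(x)
  xd <- dim(xv)
  if (oh == xd[1] && ow == xd[2]) return(x)
  y <- .resize_bilinear_fw(xv, as.integer(oh), as.integer(ow))
  new_ag(y, list(x), function(g) list(.resize_bilinear_bw(g, xd)))
}

# Concatenate along the channel axis (3rd).
ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  new_ag(y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      ci <- chans[i]
      gi <- g[, , at + seq_len(ci), , drop = FALSE]
      dim(gi) <- c(d1[1], d1[2], ci, d1[4])
      out[[i]] <- gi
      at <- at + ci
    }
    out
  })
}

# Batch normalisation over (H, W, N) per channel.
# `layer` carries running statistics (plain numeric vectors) and is updated
# in place during training.
ag_batchnorm <- function(x, gamma, beta, layer, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x)
  d <- dim(xv)
  m_count <- d[1] * d[2] * d[4]
  gv <- ag_value(gamma); bv <- ag_value(beta)
  if (training) {
    mo <- .bn_moments(xv)
    mu <- mo$mean; var_b <- mo$var
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    # unbiased variance for the running estimate, biased for normalisation
    unb <- if (m_count > 1) var_b * m_count / (m_count - 1) else var_b
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * unb
  } else {
    mu <- layer$running_mean
    var_b <- layer$running_var
  }
  istd <- 1 / sqrt(var_b + eps)
  keep <- ag_grad_enabled() && training
  r <- .bn_norm(xv, mu, istd, gv, bv, keep)
  xhat <- r$xhat
  new_ag(r$y, list(x, gamma, beta), function(g) {
    gr <- .bn_bw(if (keep) xhat else r$y * 0, g, gv, istd, training)
    # ggamma in eval mode still needs xhat; recompute cheaply
    if (!keep) {
      h <- .bn_norm(xv, mu, istd, rep(1, length(gv)), rep(0, length(gv)),
                    FALSE)$y
      gr$ggamma <- as.numeric(.bn_moments(h * g)$mean) * m_count
    }
    list(gr$gx, gr$ggamma, gr$gbeta)
  })
}

# Class-balanced binary cross-entropy over a batch, mean of per-image
# losses; weights w1 = Nneg/N, w0 = Npos/N computed from each image's target.
ag_balanced_bce <- function(pred, target, eps = 1e-7) {
  pv <- ag_value(pred)
  d <- dim(pv)
  npx <- d[1] * d[2] * d[3]
  B <- d[4]
  pm <- pv
  dim(pm) <- c(npx, B)
  tm <- target
  dim(tm) <- c(npx, B)
  h <- pmin(pmax(pm, eps), 1 - eps)
  npos <- colSums(tm)
  w1 <- (npx - npos) / npx   # foreground weight = Nneg/N
  w0 <- npos / npx           # background weight = Npos/N
  per_img <- -(colSums(tm * log(h)) * w1 + colSums((1 - tm) * log(1 - h)) * w0) / npx
  loss <- mean(per_img)
  unclamped <- (pm > eps) & (pm < 1 - eps)
  new_ag(loss, list(pred), function(g) {
    gh <- -(sweep(tm / h, 2, w1, `*`) - sweep((1 - tm) / (1 - h), 2, w0, `*`)) / npx / B
    gh[!unclamped] <- 0
    gx <- g * gh
    dim(gx) <- d
    list(gx)
  })
}
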