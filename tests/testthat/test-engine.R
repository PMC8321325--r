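# The differentiable compute engine: every analytic backward pass is
# checked against central-difference numerical gradients on small random
# tensors, through a nonlinear readout so errors cannot cancel.

sin_loss <- function(node) {
  v <- cc_ns$ag_value(node)
  cc_ns$new_ag(sum(sin(v)), list(node), function(g) list(g * cos(v)))
}

test_that("convolution gradients match numerical differentiation", {
  set.seed(11)
  cases <- list(
    list(k = 3L, stride = 1L, pad = 1L, dil = 1L, bias = TRUE),
    list(k = 1L, stride = 1L, pad = 0L, dil = 1L, bias = FALSE),  # GEMM path
    list(k = 3L, stride = 2L, pad = 1L, dil = 1L, bias = FALSE),
    list(k = 3L, stride = 1L, pad = 2L, dil = 2L, bias = TRUE))   # dilated
  for (cs in cases) {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    w <- array(rnorm(cs$k * cs$k * 2 * 3), c(cs$k, cs$k, 2, 3))
    b <- if (cs$bias) rnorm(3)
    fwd <- function(xx, ww, bb) {
      bv <- if (is.null(bb)) numeric(0) else bb
      sum(sin(cc_ns$.conv2d_fw(xx, ww, bv, cs$stride, cs$pad, cs$dil, FALSE)$y))
    }
    xa <- cc_ns$new_ag(x, requires = TRUE)
    wa <- cc_ns$ag_leaf(w)
    ba <- if (cs$bias) cc_ns$ag_leaf(b)
    y <- cc_ns$ag_conv2d(xa, wa, ba, cs$stride, cs$pad, cs$dil)
    cc_ns$ag_backward(sin_loss(y))
    expect_lt(max(abs(xa$grad - num_grad(function(z) fwd(z, w, b), x))), 1e-6)
    expect_lt(max(abs(wa$grad - num_grad(function(z) fwd(x, z, b), w))), 1e-6)
    if (cs$bias)
      expect_lt(max(abs(ba$grad - num_grad(function(z) fwd(x, w, z), b))), 1e-6)
  }
})

test_that("batch-norm gradients match numerical differentiation (training mode)", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gm <- rnorm(3, 1, 0.1)
  bt <- rnorm(3, 0, 0.1)
  run <- function(xx, g2, b2) {
    bn <- cc_ns$new_batchnorm(3)
    bn$gamma$value <- g2
    bn$beta$value <- b2
    sum(sin(cc_ns$ag_value(
      cc_ns$ag_batchnorm(cc_ns$new_ag(xx), bn$gamma, bn$beta, bn, TRUE))))
  }
  bn <- cc_ns$new_batchnorm(3)
  bn$gamma$value <- gm
  bn$beta$value <- bt
  xa <- cc_ns$new_ag(x, requires = TRUE)
  y <- cc_ns$ag_batchnorm(xa, bn$gamma, bn$beta, bn, TRUE)
  cc_ns$ag_backward(sin_loss(y))
  expect_lt(max(abs(xa$grad - num_grad(function(z) run(z, gm, bt), x))), 1e-6)
  expect_lt(max(abs(bn$gamma$grad -
                      num_grad(function(z) run(x, z, bt), gm))), 1e-6)
  expect_lt(max(abs(bn$beta$grad -
                      num_grad(function(z) run(x, gm, z), bt))), 1e-6)
})

test_that("pooling and bilinear-resize gradients match numerical differentiation", {
  set.seed(13)
  ops <- list(
    maxpool = list(ag = function(z) cc_ns$ag_maxpool(z, 3, 2, 1),
                   raw = function(z) cc_ns$.maxpool_fw(z, 3L, 2L, 1L)$y),
    avgpool = list(ag = function(z) cc_ns$ag_avgpool_adaptive(z, 2),
                   raw = function(z) cc_ns$.avgpool_adaptive_fw(z, 2L, 2L)),
    upsample = list(ag = function(z) cc_ns$ag_resize_bilinear(z, 9, 9),
                    raw = function(z) cc_ns$.resize_bilinear_fw(z, 9L, 9L)))
  for (nm in names(ops)) {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    xa <- cc_ns$new_ag(x, requires = TRUE)
    cc_ns$ag_backward(sin_loss(ops[[nm]]$ag(xa)))
    ng <- num_grad(function(z) sum(sin(ops[[nm]]$raw(z))), x)
    expect_lt(max(abs(xa$grad - ng)), 1e-6)
  }
})

test_that("the batched balanced-BCE node agrees with the scalar loss and its gradient", {
  set.seed(14)
  p <- array(runif(4 * 4 * 1 * 2, 0.05, 0.95), c(4, 4, 1, 2))
  t <- array(rbinom(32, 1, 0.4), c(4, 4, 1, 2))
  pa <- cc_ns$new_ag(p, requires = TRUE)
  loss <- cc_ns$ag_balanced_bce(pa, t)
  cc_ns$ag_backward(loss)
  per_image <- function(z) {
    zz <- z
    dim(zz) <- dim(p)
    mean(sapply(1:2, function(n) balanced_bce(zz[, , , n], t[, , , n])))
  }
  expect_equal(cc_ns$ag_value(loss), per_image(p), tolerance = 1e-12)
  expect_lt(max(abs(pa$grad - num_grad(per_image, p))), 1e-6)
})

test_that("reverse-mode accumulation handles shared nodes (diamond graphs)", {
  x <- cc_ns$new_ag(matrix(2, 1, 1), requires = TRUE)
  y <- cc_ns$ag_add(x, x)            # dy/dx = 2
  z <- cc_ns$ag_add(y, cc_ns$ag_scale(x, 3))  # z = 2x + 3x
  cc_ns$ag_backward(cc_ns$new_ag(sum(cc_ns$ag_value(z)), list(z),
                                 function(g) list(matrix(g, 1, 1))))
  expect_equal(as.numeric(x$grad), 5)
})
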