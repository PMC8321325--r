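# Class-balanced cross-entropy: closed forms, a brute-force per-pixel
# oracle, degenerate masks, monotonicity; the joint two-task objective.

# independent oracle: explicit double loop over pixels
brute_bce <- function(pred, target, eps = 1e-7) {
  n <- length(target)
  npos <- sum(target)
  w1 <- (n - npos) / n
  w0 <- npos / n
  acc <- 0
  for (i in seq_len(nrow(target)))
    for (j in seq_len(ncol(target))) {
      h <- min(max(pred[i, j], eps), 1 - eps)
      y <- target[i, j]
      acc <- acc + w1 * y * log(h) + w0 * (1 - y) * log(1 - h)
    }
  -acc / n
}

test_that("constant-0.5 predictions give the closed form 2p(1-p)ln2", {
  for (p in seq(0.1, 0.9, by = 0.1)) {
    n <- 100
    npos <- round(p * n)
    target <- matrix(c(rep(1, npos), rep(0, n - npos)), 10, 10)
    pfrac <- npos / n
    l <- balanced_bce(matrix(0.5, 10, 10), target)
    expect_equal(l, 2 * pfrac * (1 - pfrac) * log(2), tolerance = 1e-12)
  }
  # p = 0.5 evaluates to ln2 / 2
  target <- matrix(rep(c(1, 0), 50), 10, 10)
  expect_equal(balanced_bce(matrix(0.5, 10, 10), target), log(2) / 2,
               tolerance = 1e-12)
})

test_that("loss matches the brute-force pixel loop on random 8x8 instances", {
  set.seed(51)
  for (i in 1:100) {
    pred <- matrix(runif(64, 0.01, 0.99), 8, 8)
    target <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    l <- balanced_bce(pred, target)
    b <- brute_bce(pred, target)
    expect_equal(l, b, tolerance = 1e-6 * max(1, abs(b)))
  }
})

test_that("hand-computed 2x2 case reproduces the weighted sum", {
  target <- matrix(c(1, 0, 0, 0), 2, 2)
  l <- balanced_bce(matrix(0.8, 2, 2), target)
  expect_equal(l, -(0.75 * log(0.8) + 3 * 0.25 * log(0.2)) / 4,
               tolerance = 1e-12)
})

test_that("weights are per-image inverse class frequencies summing to one", {
  set.seed(52)
  for (i in 1:20) {
    target <- matrix(rbinom(36, 1, runif(1)), 6, 6)
    w <- loss_weights(target)
    expect_equal(w$w1 + w$w0, 1)
    expect_equal(w$w1, sum(target == 0) / 36)
  }
})

test_that("perfect predictions give ~zero loss; degenerate masks are finite", {
  target <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(balanced_bce(target, target), 1e-5)
  # all-background and all-foreground masks: vanished class has zero weight
  expect_equal(balanced_bce(matrix(0.3, 2, 2), matrix(0, 2, 2)), 0)
  expect_equal(balanced_bce(matrix(0.3, 2, 2), matrix(1, 2, 2)), 0)
  expect_error(balanced_bce(matrix(0.5, 2, 2), matrix(0.5, 2, 2)), "binary")
})

test_that("moving predictions toward the target never increases the loss", {
  set.seed(53)
  for (i in 1:20) {
    target <- matrix(rbinom(64, 1, 0.4), 8, 8)
    pred <- matrix(runif(64, 0.05, 0.95), 8, 8)
    l0 <- balanced_bce(pred, target)
    for (step in c(0.25, 0.5, 1)) {
      better <- pred + step * (target - pred)
      l1 <- balanced_bce(better, target)
      expect_lte(l1, l0 + 1e-12)
      l0 <- l1
    }
  }
})

test_that("joint loss is alpha * l_seg + l_edge, as printed", {
  expect_equal(joint_loss(1, 2, 0.05), 2.05)
  expect_equal(joint_loss(3, 0, 0.25), 0.75)
  for (a in c(0.005, 0.05, 0.25, 0.5))  # the configurable balance sweep
    expect_equal(joint_loss(1.5, 0.7, a), a * 1.5 + 0.7)
  expect_error(joint_loss(Inf, 1, 0.05))
})
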