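# Training objective: class-balanced binary cross-entropy per task and the
# alpha-weighted joint loss. The balance weights are recomputed from each
# image's own ground truth (w1 = Nneg/N on foreground, w0 = Npos/N on
# background), so sparse targets — edges especially — still contribute.

#' Class-balance weights of a ground-truth mask
#'
#' @param target binary array/matrix (values 0/1).
#' @return list with `w1` (foreground weight, `Nneg/N`), `w0` (background
#'   weight, `Npos/N`), `npos`, `nneg`; `w1 + w0 == 1`.
#' @export
loss_weights <- function(target) {
  v <- as.numeric(target)
  if (any(v != 0 & v != 1)) stop("validation error: target must be binary")
  n <- length(v)
  npos <- sum(v)
  list(w1 = (n - npos) / n, w0 = npos / n, npos = npos, nneg = n - npos)
}

#' Class-balanced binary cross-entropy
#'
#' `l = -(1/N) * sum( w1 * y * log h + w0 * (1-y) * log(1-h) )` with the
#' weights computed from `target` itself. Predictions are clamped to
#' `[eps, 1-eps]` before the logs, so degenerate all-foreground or
#' all-background masks are well defined (the vanished class has weight 0
#' and no pixels).
#'
#' @param pred probability array in `(0, 1)`, same shape as `target`.
#' @param target binary array.
#' @param eps clamping constant (default `1e-7`).
#' @return nonnegative scalar loss; ~0 iff `pred` matches `target` pointwise.
#' @export
#' @examples
#' t <- matrix(c(1, 0, 0, 0), 2)
#' balanced_bce(matrix(0.8, 2, 2), t)
balanced_bce <- function(pred, target, eps = 1e-7) {
  p <- as.numeric(pred)
  y <- as.numeric(target)
  if (length(p) != length(y))
    stop("shape error: pred and target sizes differ")
  if (any(y != 0 & y != 1)) stop("validation error: target must be binary")
  w <- loss_weights(y)
  h <- pmin(pmax(p, eps), 1 - eps)
  -mean(w$w1 * y * log(h) + w$w0 * (1 - y) * log(1 - h))
}

#' Joint two-task loss
#'
#' `L = alpha * l_seg + l_edge`: the task-balance weight multiplies the
#' segmentation term, as printed; the default `alpha = 0.05` keeps the two
#' terms in a similar range because the edge target is far sparser.
#'
#' @param l_seg segmentation loss (scalar).
#' @param l_edge edge-prediction loss (scalar).
#' @param alpha task balance weight, `> 0`.
#' @return scalar joint loss.
#' @export
joint_loss <- function(l_seg, l_edge, alpha = 0.05) {
  stopifnot(is.finite(l_seg), is.finite(l_edge), alpha > 0)
  alpha * l_seg + l_edge
}
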