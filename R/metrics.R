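# Confusion-count evaluation metrics: Jaccard (JA), Dice (DC), accuracy
# (ACC), sensitivity (SEN), specificity (SPE), per image and averaged over
# a dataset (reported x100 in summaries, as is conventional for this
# benchmark).

#' Confusion counts of a probability map against a binary truth
#'
#' @param pred probability (or binary) map.
#' @param truth binary map of the same shape.
#' @param thr binarisation threshold (default 0.5); prediction is
#'   `pred >= thr`.
#' @return object of class `confusion_counts` with integer `TP`, `TN`,
#'   `FP`, `FN` (summing to the pixel count) and the threshold used.
#' @export
confusion <- function(pred, truth, thr = 0.5) {
  if (length(pred) != length(truth))
    stop("shape error: pred and truth sizes differ")
  y <- as.numeric(truth)
  if (any(y != 0 & y != 1)) stop("validation error: truth must be binary")
  p <- as.numeric(pred) >= thr
  counts <- list(TP = sum(p & y == 1), TN = sum(!p & y == 0),
                 FP = sum(p & y == 0), FN = sum(!p & y == 1),
                 threshold = thr)
  class(counts) <- "confusion_counts"
  counts
}

#' Segmentation metrics from confusion counts
#'
#' `JA = TP/(TP+FP+FN)`, `DC = 2TP/(2TP+FP+FN)`, `ACC = (TP+TN)/total`,
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`. A degenerate denominator (e.g.
#' sensitivity with no foreground pixels) scores 1 when the condition is
#' vacuously met — nothing to find and nothing (wrongly) found — and 0
#' otherwise; such rows carry `degenerate = TRUE`.
#'
#' @param counts a `confusion_counts` (or list with TP/TN/FP/FN).
#' @return named list `JA`, `DC`, `ACC`, `SEN`, `SPE`, `degenerate`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  ratio <- function(num, den, vacuous) {
    if (den == 0) {
      degenerate <<- TRUE
      return(if (vacuous) 1 else 0)
    }
    num / den
  }
  list(JA = ratio(tp, tp + fp + fn, vacuous = fp == 0),
       DC = ratio(2 * tp, 2 * tp + fp + fn, vacuous = fp == 0),
       ACC = ratio(tp + tn, tp + tn + fp + fn, vacuous = TRUE),
       SEN = ratio(tp, tp + fn, vacuous = fp == 0),
       SPE = ratio(tn, tn + fp, vacuous = fn == 0),
       degenerate = degenerate)
}

#' Per-image metric table with a mean summary row
#'
#' @param preds list of probability maps.
#' @param truths list of binary masks (same order).
#' @param ids character image identifiers.
#' @param thr binarisation threshold.
#' @return `data.frame` with columns `image_id`, `TP`, `TN`, `FP`, `FN`,
#'   `JA`, `DC`, `ACC`, `SEN`, `SPE`, `degenerate`; the final row
#'   (`image_id == "mean"`) holds the across-image means of the five
#'   metrics.
#' @export
metric_table <- function(preds, truths, ids = NULL, thr = 0.5) {
  stopifnot(length(preds) == length(truths))
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusion(preds[[i]], truths[[i]], thr)
    m <- metrics_from_counts(cc)
    data.frame(image_id = ids[i], TP = cc$TP, TN = cc$TN, FP = cc$FP,
               FN = cc$FN, JA = m$JA, DC = m$DC, ACC = m$ACC, SEN = m$SEN,
               SPE = m$SPE, degenerate = m$degenerate)
  })
  tab <- do.call(rbind, rows)
  means <- colMeans(tab[, c("JA", "DC", "ACC", "SEN", "SPE")])
  tab <- rbind(tab, data.frame(image_id = "mean", TP = NA, TN = NA, FP = NA,
                               FN = NA, JA = means["JA"], DC = means["DC"],
                               ACC = means["ACC"], SEN = means["SEN"],
                               SPE = means["SPE"], degenerate = FALSE))
  rownames(tab) <- NULL
  tab
}
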