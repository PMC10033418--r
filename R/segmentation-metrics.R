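#' Segmentation agreement metrics (DICE, IoU, precision, recall)
#'
#' One-vs-rest confusion counts per foreground class: `dice = 2TP / (2TP +
#' FP + FN)`, `iou = TP / (TP + FP + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`.  The macro average is taken over the foreground
#' classes; a pixel-pooled (micro) average over foreground is also reported.
#' A class absent from both prediction and truth is vacuously perfect (all
#' metrics 1), which keeps macro averages defined on sparse tiles.
#'
#' @param pred,truth integer label maps of identical shape, values in
#'   `0 .. n_classes - 1` (0 = background).
#' @param n_classes total number of classes including background.
#' @return object of class `seg_metrics`: `per_class` data.frame, `macro`
#'   and `micro` named vectors (`dice`, `iou`, `precision`, `recall`).
#' @export
evaluate_segmentation <- function(pred, truth, n_classes = 3) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch between pred and truth")
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (any(pred < 0 | pred >= n_classes) || any(truth < 0 | truth >= n_classes))
    stop("labels must be in 0 .. n_classes - 1")
  fgc <- seq_len(n_classes - 1)
  per <- lapply(fgc, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (tp + fp + fn == 0) {
      data.frame(class = k, tp = 0, fp = 0, fn = 0,
                 dice = 1, iou = 1, precision = 1, recall = 1)
    } else {
      data.frame(class = k, tp = tp, fp = fp, fn = fn,
                 dice = 2 * tp / (2 * tp + fp + fn),
                 iou = tp / (tp + fp + fn),
                 precision = if (tp + fp > 0) tp / (tp + fp) else 1,
                 recall = if (tp + fn > 0) tp / (tp + fn) else 1)
    }
  })
  per <- do.call(rbind, per)
  macro <- c(dice = mean(per$dice), iou = mean(per$iou),
             precision = mean(per$precision), recall = mean(per$recall))
  TP <- sum(per$tp); FP <- sum(per$fp); FN <- sum(per$fn)
  micro <- if (TP + FP + FN == 0) {
    c(dice = 1, iou = 1, precision = 1, recall = 1)
  } else {
    c(dice = 2 * TP / (2 * TP + FP + FN), iou = TP / (TP + FP + FN),
      precision = if (TP + FP > 0) TP / (TP + FP) else 1,
      recall = if (TP + FN > 0) TP / (TP + FN) else 1)
  }
  structure(list(per_class = per, macro = macro, micro = micro),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat("<seg_metrics> macro over foreground classes:\n")
  print(round(x$macro, 4))
  invisible(x)
}

#' Otsu threshold of a numeric array
#'
#' Maximizes between-class variance on a 256-bin histogram; used as the
#' automatic threshold for 3D volumes (2D frames go through the same code).
#'
#' @param x numeric vector/array.
#' @param n_bins histogram resolution.
#' @return threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) stop("constant input has no Otsu threshold")
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1), n_bins),
                  nbins = n_bins)
  p <- cnt / sum(cnt)
  mids <- (head(edges, -1) + edges[-1]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}
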