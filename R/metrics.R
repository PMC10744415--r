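#' Per-class confusion counts
#'
#' Exact integer confusion counts for a predicted vs true label mask, one row
#' per class, treating that class as positive: TP, FP, FN, TN pixel counts.
#'
#' @param prediction,truth `H x W` integer matrices with entries in
#'   `0..num_classes-1`.
#' @param num_classes Number of classes `K` (default 2).
#' @return An object of class `confusion_counts`: a `K x 4` integer matrix
#'   with columns `tp`, `fp`, `fn`, `tn` and one row per class.
#' @examples
#' truth <- matrix(c(0, 1, 1, 0), 2, 2)
#' pred <- matrix(c(0, 1, 0, 0), 2, 2)
#' confusion(pred, truth)
#' @export
confusion <- function(prediction, truth, num_classes = 2L) {
  check_scalar_number(num_classes, "num_classes", lo = 2, integer = TRUE)
  if (!is.matrix(prediction) || !is.matrix(truth) ||
      !identical(dim(prediction), dim(truth)))
    stop_invalid("prediction and truth must be matrices of equal shape")
  if (any(prediction < 0) || any(prediction >= num_classes) ||
      any(truth < 0) || any(truth >= num_classes) ||
      any(prediction != round(prediction)) || any(truth != round(truth)))
    stop_invalid("labels must be integers in [0, num_classes)")
  n <- length(truth)
  # joint histogram of (pred, truth) pairs
  joint <- tabulate(prediction * num_classes + truth + 1L,
                    nbins = num_classes^2)
  joint <- matrix(joint, num_classes, num_classes, byrow = TRUE) # pred x truth
  counts <- matrix(0L, num_classes, 4L,
                   dimnames = list(paste0("class", seq_len(num_classes) - 1L),
                                   c("tp", "fp", "fn", "tn")))
  for (k in seq_len(num_classes)) {
    tp <- joint[k, k]
    fp <- sum(joint[k, ]) - tp
    fn <- sum(joint[, k]) - tp
    counts[k, ] <- c(tp, fp, fn, n - tp - fp - fn)
  }
  structure(counts, class = c("confusion_counts", class(counts)))
}

check_counts <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    stop_invalid("counts must come from confusion()")
  invisible(counts)
}

# per-class ratios with the empty-union convention: a class absent from both
# prediction and truth (TP + FP + FN == 0) scores 1
per_class_iou <- function(counts) {
  u <- counts[, "tp"] + counts[, "fp"] + counts[, "fn"]
  ifelse(u == 0, 1, counts[, "tp"] / ifelse(u == 0, 1, u))
}
per_class_dsc <- function(counts) {
  u <- 2 * counts[, "tp"] + counts[, "fp"] + counts[, "fn"]
  ifelse(u == 0, 1, 2 * counts[, "tp"] / ifelse(u == 0, 1, u))
}

#' Mean intersection over union
#'
#' `(1/K) * sum_k TP_k / (TP_k + FP_k + FN_k)`, averaging the per-class IoU
#' over classes. A class with empty union contributes 1.
#'
#' @param counts A [confusion()] result.
#' @return Mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(counts) {
  check_counts(counts)
  mean(per_class_iou(counts))
}

#' Mean Dice similarity coefficient
#'
#' `(1/K) * sum_k 2 TP_k / (2 TP_k + FP_k + FN_k)`; per class,
#' `DSC_k = 2 IoU_k / (1 + IoU_k)`. A class with empty union contributes 1.
#'
#' @param counts A [confusion()] result.
#' @return Mean DSC in `[0, 1]`.
#' @export
mean_dsc <- function(counts) {
  check_counts(counts)
  mean(per_class_dsc(counts))
}

#' Balanced accuracy with the foreground as positive class
#'
#' `(TPR + TNR) / 2` for the binary case, with class 1 (the instrument) as
#' positive. An empty denominator (no foreground, or no background, in the
#' truth) contributes 1, consistent with the empty-class convention of the
#' overlap metrics.
#'
#' @param counts A binary (K = 2) [confusion()] result.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy_fg <- function(counts) {
  check_counts(counts)
  if (nrow(counts) != 2L)
    stop_invalid("balanced accuracy (fg.) requires K = 2")
  tp <- counts[2L, "tp"]; fn <- counts[2L, "fn"]
  tn <- counts[2L, "tn"]; fp <- counts[2L, "fp"]
  tpr <- if (tp + fn == 0) 1 else tp / (tp + fn)
  tnr <- if (tn + fp == 0) 1 else tn / (tn + fp)
  (tpr + tnr) / 2
}

metrics_from_counts <- function(counts) {
  iou <- per_class_iou(counts)
  dsc <- per_class_dsc(counts)
  list(iou = unname(iou), dsc = unname(dsc),
       mean_iou = mean(iou), mean_dsc = mean(dsc),
       balanced_accuracy_fg = if (nrow(counts) == 2L)
         balanced_accuracy_fg(counts) else NA_real_)
}

#' Evaluate a model on a dataset
#'
#' Predicts every frame, accumulates per-class confusion counts, and reports
#' both aggregations: `macro` (metrics computed per frame, then averaged
#' across frames — the default headline numbers) and `micro` (counts summed
#' over all frames before the ratios are taken).
#'
#' @param model A `seg_model`.
#' @param dataset A `seg_dataset` (see [generate_scenes()] /
#'   [read_dataset()]), or a list with elements `images` and `masks`.
#' @return An object of class `metrics_report`: a list with elements
#'   `macro`, `micro` (each holding `iou`, `dsc`, `mean_iou`, `mean_dsc`,
#'   `balanced_accuracy_fg`), `counts` (pooled confusion counts) and
#'   `n_frames`.
#' @export
evaluate_model <- function(model, dataset) {
  if (length(dataset$images) == 0L) stop_invalid("dataset is empty")
  k <- model$config$num_classes
  pooled <- NULL
  frame_metrics <- vector("list", length(dataset$images))
  for (i in seq_along(dataset$images)) {
    pred <- predict(model, dataset$images[[i]])
    truth <- dataset$masks[[i]]
    storage.mode(truth) <- "integer"
    cc <- confusion(pred, truth, k)
    pooled <- if (is.null(pooled)) cc else {
      s <- unclass(cc) + unclass(pooled)
      structure(s, class = class(cc))
    }
    frame_metrics[[i]] <- metrics_from_counts(cc)
  }
  macro <- list(
    iou = Reduce(`+`, lapply(frame_metrics, `[[`, "iou")) /
      length(frame_metrics),
    dsc = Reduce(`+`, lapply(frame_metrics, `[[`, "dsc")) /
      length(frame_metrics),
    mean_iou = mean(vapply(frame_metrics, `[[`, numeric(1), "mean_iou")),
    mean_dsc = mean(vapply(frame_metrics, `[[`, numeric(1), "mean_dsc")),
    balanced_accuracy_fg =
      mean(vapply(frame_metrics, `[[`, numeric(1), "balanced_accuracy_fg")))
  structure(list(macro = macro, micro = metrics_from_counts(pooled),
                 counts = pooled, n_frames = length(dataset$images)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Segmentation metrics over %d frames (macro / micro):\n", x$n_frames))
  cat(sprintf("  mean IoU:               %.4f / %.4f\n",
              x$macro$mean_iou, x$micro$mean_iou))
  cat(sprintf("  mean DSC:               %.4f / %.4f\n",
              x$macro$mean_dsc, x$micro$mean_dsc))
  cat(sprintf("  balanced accuracy (fg): %.4f / %.4f\n",
              x$macro$balanced_accuracy_fg, x$micro$balanced_accuracy_fg))
  invisible(x)
}
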