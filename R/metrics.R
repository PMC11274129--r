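# Detection evaluation: precision / recall / average precision / mAP and
# the multi-threshold mAP50-95, COCO-style (all-point interpolation with a
# monotone precision envelope; classes without ground truth are excluded
# from the mean).

#' Match detections to ground truth
#'
#' Greedy one-to-one matching within one image: detections are processed
#' in order of descending confidence; each matches the highest-IoU not yet
#' matched ground-truth box of its class when that IoU is at least
#' `iou_thr` (a true positive), otherwise it is a false positive.
#' Unmatched truths are false negatives.
#'
#' @param dets data.frame with x1, y1, x2, y2, conf, class_id.
#' @param truths data.frame with x1, y1, x2, y2, class_id.
#' @param iou_thr IoU matching threshold.
#' @return a match ledger: list with `tp`, `fp`, `fn` counts, and `flags`
#'   (logical TP flag per detection, in descending-confidence order,
#'   alongside `conf` and `class_id`).
#' @export
match_detections <- function(dets, truths, iou_thr = 0.5) {
  ord <- if (nrow(dets)) order(-dets$conf, seq_len(nrow(dets))) else integer(0)
  dets <- dets[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(truths))
  flags <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!matched & truths$class_id == dets$class_id[i])
    if (!length(cand)) next
    ious <- vapply(cand, function(t)
      box_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
              as.numeric(truths[t, c("x1", "y1", "x2", "y2")])), numeric(1))
    j <- which.max(ious)
    if (ious[j] >= iou_thr) {
      matched[cand[j]] <- TRUE
      flags[i] <- TRUE
    }
  }
  tp <- sum(flags)
  structure(list(tp = tp, fp = nrow(dets) - tp, fn = nrow(truths) - tp,
                 flags = flags, conf = dets$conf, class_id = dets$class_id,
                 n_truths = nrow(truths)),
            class = "mlyolo_ledger")
}

#' Precision and recall of a match ledger
#'
#' `TP / (TP + FP)` and `TP / (TP + FN)`. Precision is 0 by convention
#' when no detections were made.
#'
#' @param ledger result of [match_detections()].
#' @return value in `[0, 1]`.
#' @export
precision <- function(ledger) {
  if (ledger$tp + ledger$fp == 0) return(0)
  ledger$tp / (ledger$tp + ledger$fp)
}

#' @rdname precision
#' @export
recall <- function(ledger) {
  if (ledger$tp + ledger$fn == 0) return(0)
  ledger$tp / (ledger$tp + ledger$fn)
}

#' Average precision from ranked match flags
#'
#' Area under the precision-recall curve by all-point interpolation: the
#' precision envelope is made monotone non-increasing from the right and
#' integrated over the exact recall steps.
#'
#' @param flags logical TP flags in descending-confidence order.
#' @param n_truths number of ground-truth boxes of the class (>= 1).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(flags, n_truths) {
  if (n_truths < 1) stop("average_precision: n_truths must be >= 1")
  if (!length(flags)) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  rec <- tp / n_truths
  prec <- tp / (tp + fp)
  penv <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * penv)
}

#' Mean of per-class average precisions
#' @param aps numeric vector of per-class APs (empty classes excluded).
#' @return unweighted mean.
#' @export
mean_ap <- function(aps) {
  if (!length(aps)) stop("mean_ap: need at least one evaluated class")
  mean(aps)
}

# Pool detections across images for one class/threshold and compute AP.
class_ap <- function(dets, truths, cl, iou_thr) {
  td <- dets[dets$class_id == cl, , drop = FALSE]
  n_tr <- sum(truths$class_id == cl)
  if (n_tr == 0) return(NA_real_)
  if (!nrow(td)) return(0)
  ord <- order(-td$conf, seq_len(nrow(td)))
  td <- td[ord, , drop = FALSE]
  flags <- logical(nrow(td))
  matched <- list()
  for (i in seq_len(nrow(td))) {
    img <- td$image[i]
    cand <- which(truths$class_id == cl & truths$image == img)
    cand <- setdiff(cand, matched[[as.character(img)]])
    if (!length(cand)) next
    ious <- vapply(cand, function(t)
      box_iou(as.numeric(td[i, c("x1", "y1", "x2", "y2")]),
              as.numeric(truths[t, c("x1", "y1", "x2", "y2")])), numeric(1))
    j <- which.max(ious)
    if (ious[j] >= iou_thr) {
      matched[[as.character(img)]] <- c(matched[[as.character(img)]], cand[j])
      flags[i] <- TRUE
    }
  }
  average_precision(flags, n_tr)
}

#' Evaluate detections against ground truth over a dataset
#'
#' Computes per-class AP at each IoU threshold (detections pooled across
#' images and ranked by confidence), mAP at 0.50, mAP averaged over
#' 0.50:0.05:0.95, and precision/recall at an operating confidence.
#'
#' @param dets data.frame with image, x1, y1, x2, y2, conf, class_id.
#' @param truths data.frame with image, x1, y1, x2, y2, class_id.
#' @param iou_thresholds IoU thresholds (default the COCO ladder).
#' @param conf_operating confidence used for the precision/recall point.
#' @return an `mlyolo_eval` list: `ap` (class x threshold matrix),
#'   `map50`, `map50_95`, `precision`, `recall`, `classes`.
#' @export
evaluate_detections <- function(dets, truths,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                conf_operating = 0.25) {
  classes <- sort(unique(truths$class_id))
  ap <- matrix(NA_real_, length(classes), length(iou_thresholds),
               dimnames = list(as.character(classes),
                               sprintf("%.2f", iou_thresholds)))
  for (ci in seq_along(classes))
    for (ti in seq_along(iou_thresholds))
      ap[ci, ti] <- class_ap(dets, truths, classes[ci], iou_thresholds[ti])
  keep <- !is.na(ap[, 1])
  opd <- dets[dets$conf >= conf_operating, , drop = FALSE]
  led <- local({
    tp <- 0L; fpn <- 0L
    for (img in unique(c(truths$image, opd$image))) {
      l <- match_detections(opd[opd$image == img, , drop = FALSE],
                            truths[truths$image == img, , drop = FALSE], 0.5)
      tp <- tp + l$tp; fpn <- fpn + l$fp
    }
    list(tp = tp, fp = fpn, fn = nrow(truths) - tp)
  })
  structure(list(
    ap = ap, classes = classes,
    map50 = mean(ap[keep, 1]),
    map50_95 = mean(rowMeans(ap[keep, , drop = FALSE])),
    precision = if (led$tp + led$fp == 0) 0 else led$tp / (led$tp + led$fp),
    recall = if (led$tp + led$fn == 0) 0 else led$tp / (led$tp + led$fn)),
    class = "mlyolo_eval")
}

#' @export
print.mlyolo_eval <- function(x, ...) {
  cat(sprintf("mAP50 %.4f  mAP50-95 %.4f  P %.4f  R %.4f\n",
              x$map50, x$map50_95, x$precision, x$recall))
  cat("per-class AP50:", paste(sprintf("%s=%.3f", rownames(x$ap), x$ap[, 1]),
                               collapse = "  "), "\n")
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param ev an `mlyolo_eval`.
#' @param path output file.
#' @export
write_eval_report <- function(ev, path) {
  jsonlite::write_json(list(
    map50 = ev$map50, map50_95 = ev$map50_95,
    precision = ev$precision, recall = ev$recall,
    per_class_ap50 = as.list(setNames(ev$ap[, 1], rownames(ev$ap)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
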