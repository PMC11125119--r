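#' Match scored detections to ground truth
#'
#' Standard COCO-style greedy matching at a fixed IoU threshold:
#' predictions are taken in descending score order and each is matched to
#' the highest-IoU not-yet-matched ground-truth instance of its own
#' category (within its own image) with IoU at or above the threshold.
#' Duplicate detections of an already matched truth count as false
#' positives. `mode` selects box IoU or mask pixel IoU.
#'
#' @param preds,truths Either flat lists of `feedscan_annotation` (one
#'   image) or lists of such per-image lists; `preds` and `truths` must
#'   index the same images.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @param mode `"box"` or `"mask"`.
#' @return A `match_table`: data frame with one row per prediction
#'   (`category`, `score`, logical `tp`) plus attribute `n_truth`, the
#'   per-category ground-truth counts.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5,
                             mode = c("box", "mask")) {
  mode <- match.arg(mode)
  preds <- as_image_list(preds); truths <- as_image_list(truths)
  stopifnot(length(preds) == length(truths))
  rows <- list()
  n_truth <- setNames(c(0L, 0L), feedscan_categories())
  for (img in seq_along(preds)) {
    p <- preds[[img]]; g <- truths[[img]]
    for (a in g) n_truth[a$category] <- n_truth[a$category] + 1L
    if (!length(p)) next
    sc <- vapply(p, ann_score, numeric(1))
    ord <- order(sc, decreasing = TRUE)
    used <- rep(FALSE, length(g))
    for (i in ord) {
      best <- 0; best_j <- 0L
      for (j in seq_along(g)) {
        if (used[j] || g[[j]]$category != p[[i]]$category) next
        ov <- pair_iou(p[[i]], g[[j]], mode)
        if (ov >= iou_threshold && ov > best) { best <- ov; best_j <- j }
      }
      if (best_j > 0L) used[best_j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        category = p[[i]]$category, score = sc[i], tp = best_j > 0L)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), score = numeric(0), tp = logical(0))
  structure(tab, n_truth = n_truth, class = c("match_table", class(tab)))
}

ann_score <- function(a) if (is.na(a$score)) 1 else a$score

pair_iou <- function(a, b, mode) {
  if (mode == "box") {
    iou(a$bbox, b$bbox)
  } else {
    inter <- sum(a$mask & b$mask)
    un <- sum(a$mask | b$mask)
    if (un == 0) 0 else inter / un
  }
}

as_image_list <- function(x) {
  if (!length(x)) return(list(x))
  if (inherits(x[[1]], "feedscan_annotation")) list(x) else x
}

#' Precision and recall of a match table
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`, pooled over categories.
#' With no predictions at all, precision is defined as 1.
#'
#' @param table A `match_table` from [match_detections()].
#' @return Named numeric `c(precision =, recall =)`.
#' @export
precision_recall <- function(table) {
  tp <- sum(table$tp); fp <- sum(!table$tp)
  n_truth <- sum(attr(table, "n_truth"))
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (n_truth == 0) 0 else tp / n_truth
  c(precision = p, recall = r)
}

#' Average precision over the score sweep
#'
#' Area under the precision-recall curve obtained by sweeping the score
#' threshold over the ranked detections, with right-max (monotone)
#' precision interpolation and all-point area, the continuous AP variant.
#' Restricted to one category when `category` is given, otherwise pooled
#' over categories (matching is always per category).
#'
#' @inheritParams match_detections
#' @param category Optional single category to evaluate.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(preds, truths, iou_threshold = 0.5,
                              mode = c("box", "mask"), category = NULL) {
  mode <- match.arg(mode)
  tab <- match_detections(preds, truths, iou_threshold, mode)
  n_truth <- attr(tab, "n_truth")
  if (!is.null(category)) {
    tab <- tab[tab$category == category, , drop = FALSE]
    n_truth <- n_truth[category]
  }
  n_gt <- sum(n_truth)
  if (n_gt == 0) stop("average precision needs at least one ground-truth instance",
                      call. = FALSE)
  if (nrow(tab) == 0) return(0)
  ord <- order(tab$score, decreasing = TRUE)
  tp <- cumsum(tab$tp[ord]); fp <- cumsum(!tab$tp[ord])
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # right-max envelope, then all-point area over recall increments
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Mean average precision over the two categories
#'
#' Unweighted mean of the per-category AP of `"head"` and `"feed trough"`,
#' reported in percent. Both categories must be present in the ground
#' truth.
#'
#' @inheritParams match_detections
#' @return mAP in percent (0–100).
#' @export
mean_ap <- function(preds, truths, iou_threshold = 0.5,
                    mode = c("box", "mask")) {
  mode <- match.arg(mode)
  tab <- match_detections(preds, truths, iou_threshold, mode)
  n_truth <- attr(tab, "n_truth")
  if (any(n_truth == 0)) {
    stop("ground truth must contain both categories; missing: ",
         paste(names(n_truth)[n_truth == 0], collapse = ", "), call. = FALSE)
  }
  aps <- vapply(feedscan_categories(), function(ct)
    average_precision(preds, truths, iou_threshold, mode, category = ct),
    numeric(1))
  mean(aps) * 100
}

#' Per-category evaluation report
#'
#' Convenience wrapper producing the per-category AP for boxes and masks
#' plus their means, the shape of a model-comparison table row.
#'
#' @inheritParams match_detections
#' @return Data frame with columns `category`, `ap_box`, `ap_mask`, plus a
#'   `"mean"` row (values in percent).
#' @export
eval_report <- function(preds, truths, iou_threshold = 0.5) {
  cats <- feedscan_categories()
  ap_box <- vapply(cats, function(ct)
    100 * average_precision(preds, truths, iou_threshold, "box", ct), numeric(1))
  ap_mask <- vapply(cats, function(ct)
    100 * average_precision(preds, truths, iou_threshold, "mask", ct), numeric(1))
  rbind(data.frame(category = cats, ap_box = ap_box, ap_mask = ap_mask,
                   row.names = NULL),
        data.frame(category = "mean", ap_box = mean(ap_box),
                   ap_mask = mean(ap_mask)))
}
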