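#' Predict instances in an image
#'
#' Full inference pipeline: backbone + pyramid features, region proposals
#' (per-level top scoring anchors, decoded, clipped and NMS-merged), RoI
#' classification and box refinement, per-class NMS at `nms_iou`, and the
#' multi-stage mask branch pasted back to image resolution. Deterministic
#' given weights and input.
#'
#' @param object A `feedscan_model`.
#' @param image `H x W x 3` array, values 0–255.
#' @param score_threshold,nms_iou Overrides of the config thresholds.
#' @param max_detections Cap on returned instances.
#' @param ... Unused.
#' @return List of scored [instance_annotation()] objects, scores sorted
#'   descending (a `DetectionResult`).
#' @export
predict.feedscan_model <- function(object, image,
                                   score_threshold = NULL, nms_iou = NULL,
                                   max_detections = 20L, ...) {
  model <- object
  cfg <- model$config
  if (is.null(score_threshold)) score_threshold <- cfg$score_threshold
  if (is.null(nms_iou)) nms_iou <- cfg$nms_iou
  h <- dim(image)[1]; w <- dim(image)[2]
  feats <- forward_features(model, image)

  props <- generate_proposals(model, feats, h, w)
  if (nrow(props$boxes) == 0L) return(list())

  dets <- roi_classify(model, feats, props$boxes, h, w,
                       score_threshold, nms_iou, max_detections)
  if (nrow(dets$boxes) == 0L) return(list())

  sem <- semantic_forward(model$params$mask, feats)
  out <- list()
  for (i in seq_len(nrow(dets$boxes))) {
    box <- dets$boxes[i, ]
    mb <- mask_branch_forward(model$params$mask, feats, sem$feat, box)
    final <- mb$logits[[length(mb$logits)]]
    prob <- sigmoid(final[, , dets$classes[i]])
    full <- paste_mask(prob, box, h, w)
    if (!any(full)) {  # degenerate mask head output: fall back to the box
      full <- box_fill_mask(box, h, w)
    }
    out[[length(out) + 1L]] <- instance_annotation(
      feedscan_categories()[dets$classes[i]], full, score = dets$scores[i])
  }
  ord <- order(vapply(out, function(a) a$score, numeric(1)), decreasing = TRUE)
  out[ord]
}

generate_proposals <- function(model, feats, h, w,
                               pre_nms_top = 300L, post_nms_top = 100L,
                               proposal_nms = 0.7) {
  cfg <- model$config
  boxes <- NULL; scores <- numeric(0)
  for (nm in names(feats)) {
    feat <- feats[[nm]]
    stride <- attr(feat, "stage")
    out <- rpn_forward_level(model$params$rpn, feat)
    hf <- dim(feat)[1]; wf <- dim(feat)[2]
    sc <- as.vector(out$cls)                 # (h, w, a) column-major
    top <- order(sc, decreasing = TRUE)[seq_len(min(pre_nms_top, length(sc)))]
    for (idx in top) {
      ai <- (idx - 1) %/% (hf * wf) + 1
      wi <- ((idx - 1) %% (hf * wf)) %/% hf + 1
      hi <- (idx - 1) %% hf + 1
      anchor <- level_anchor_box(hi, wi, ai, stride, cfg$anchor_ratios)
      delta <- out$reg[hi, wi, (4 * (ai - 1) + 1):(4 * ai)]
      bx <- clip_box(decode_box(anchor, delta), h, w)
      if (bx[3] - bx[1] < 2 || bx[4] - bx[2] < 2) next
      boxes <- rbind(boxes, bx)
      scores <- c(scores, sigmoid(sc[idx]))
    }
  }
  if (is.null(boxes)) return(list(boxes = matrix(0, 0, 4), scores = numeric(0)))
  keep <- nms(boxes, scores, proposal_nms)
  keep <- keep[seq_len(min(post_nms_top, length(keep)))]
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep])
}

roi_classify <- function(model, feats, proposals, h, w,
                         score_threshold, nms_iou, max_detections) {
  cfg <- model$config
  X <- t(vapply(seq_len(nrow(proposals)), function(i)
    as.vector(roi_features(feats, proposals[i, ], cfg$box_roi)),
    numeric(cfg$fpn_channels * cfg$box_roi^2)))
  out <- box_head_forward(model$params$box, X)
  probs <- t(apply(out$cls, 1, softmax))
  boxes <- NULL; scores <- numeric(0); classes <- integer(0)
  for (i in seq_len(nrow(proposals))) {
    cls <- which.max(probs[i, seq_len(cfg$n_classes)])
    sc <- probs[i, cls]
    if (sc < score_threshold) next
    delta <- out$reg[i, (4 * (cls - 1) + 1):(4 * cls)]
    bx <- clip_box(decode_box(proposals[i, ], delta), h, w)
    if (bx[3] - bx[1] < 1 || bx[4] - bx[2] < 1) next
    boxes <- rbind(boxes, bx); scores <- c(scores, sc); classes <- c(classes, cls)
  }
  if (is.null(boxes)) {
    return(list(boxes = matrix(0, 0, 4), scores = numeric(0),
                classes = integer(0)))
  }
  keep <- integer(0)
  for (cls in unique(classes)) {
    idx <- which(classes == cls)
    k <- nms(boxes[idx, , drop = FALSE], scores[idx], nms_iou)
    keep <- c(keep, idx[k])
  }
  keep <- keep[order(scores[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(max_detections, length(keep)))]
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep],
       classes = classes[keep])
}

# Paste a [0,1] mask probability grid predicted over `box` into an H x W
# logical canvas.
paste_mask <- function(prob, box, h, w, threshold = 0.5) {
  x1 <- max(floor(box[1]), 0); y1 <- max(floor(box[2]), 0)
  x2 <- min(ceiling(box[3]), w); y2 <- min(ceiling(box[4]), h)
  out <- matrix(FALSE, h, w)
  bw <- x2 - x1; bh <- y2 - y1
  if (bw < 1 || bh < 1) return(out)
  pr <- cpp_bilinear_resize(array(prob, dim = c(dim(prob), 1L)), bh, bw)[, , 1]
  out[(y1 + 1):y2, (x1 + 1):x2] <- pr >= threshold
  out
}

box_fill_mask <- function(box, h, w) {
  out <- matrix(FALSE, h, w)
  x1 <- max(floor(box[1]), 0); y1 <- max(floor(box[2]), 0)
  x2 <- min(ceiling(box[3]), w); y2 <- min(ceiling(box[4]), h)
  if (x2 > x1 && y2 > y1) out[(y1 + 1):y2, (x1 + 1):x2] <- TRUE
  out
}
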