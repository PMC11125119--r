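#' Assign a detected head to its feeding fence
#'
#' A cow feeds through exactly one fence, so the head mask is assigned to
#' the fence strip containing the largest share of its pixels, provided
#' that share is at least half; heads mostly outside the layout are
#' unassigned. This operationalizes "head and fence have the same
#' coordinates" as a majority pixel-overlap test, the only reading robust
#' to mask noise.
#'
#' @param head A `"head"` [instance_annotation()].
#' @param layout A [fence_layout()].
#' @return The fence id, or `NA_integer_` when no fence holds a majority.
#' @export
assign_fence <- function(head, layout) {
  if (!any(head$mask)) stop("empty head mask", call. = FALSE)
  total <- sum(head$mask)
  shares <- vapply(layout$ids, function(f)
    sum(head$mask & fence_region_mask(layout, f)) / total, numeric(1))
  best <- which.max(shares)
  if (shares[best] >= 0.5) layout$ids[best] else NA_integer_
}

#' Jaw region of a head mask
#'
#' The jaw is taken as the geometrically lowest part of the head: the
#' subset of head-mask pixels whose row lies in the lowest `fraction` of
#' the mask's tight bounding box (image-down = jaw-down convention). Always
#' a subset of the input mask; `fraction = 1` is the identity.
#'
#' @param head_mask Non-empty logical matrix.
#' @param fraction Height fraction in `(0, 1]` (default 1/3).
#' @return Logical matrix of the jaw pixels.
#' @export
jaw_region <- function(head_mask, fraction = 1 / 3) {
  if (!any(head_mask)) stop("empty head mask", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  bb <- mask_bbox(head_mask)                 # half-open rows [y1, y2)
  cut <- bb[4] - fraction * (bb[4] - bb[2])  # rows with y >= cut are jaw
  rows <- seq_len(nrow(head_mask)) - 1       # 0-based row coordinate y
  keep <- rows >= cut - 1e-9
  out <- head_mask
  out[!keep, ] <- FALSE
  out
}

#' Per-frame feeding state from segmentation results
#'
#' Implements the mask-overlap decision: a fence is feeding in a frame iff
#' some sufficiently confident head is assigned to it and that head's jaw
#' region overlaps the detected feed-pile mask (clipped to the fence
#' region, by default) in at least `min_contact_px` pixels. Fences with no
#' assigned head are not feeding; if no feed-pile instance is detected at
#' all, every fence is not feeding.
#'
#' @param detections List of scored `feedscan_annotation` (a
#'   `DetectionResult`, or ground-truth annotations whose `NA` scores are
#'   treated as certain).
#' @param layout A [fence_layout()].
#' @param jaw_fraction Height fraction defining the jaw region.
#' @param min_contact_px Minimum jaw-pile intersection, in pixels.
#' @param score_floor Detections scoring below this are ignored.
#' @param clip_pile_to_fence If `TRUE` (default) the pile mask is restricted
#'   to the head's fence strip before the contact test.
#' @return Named logical vector, one entry per fence id.
#' @export
frame_feeding_state <- function(detections, layout, jaw_fraction = 1 / 3,
                                min_contact_px = 20, score_floor = 0.3,
                                clip_pile_to_fence = TRUE) {
  state <- setNames(rep(FALSE, length(layout$ids)), layout$ids)
  if (!length(detections)) return(state)
  scores <- vapply(detections, ann_score, numeric(1))
  keep <- detections[scores >= score_floor]
  cats <- vapply(keep, function(a) a$category, character(1))
  piles <- keep[cats == "feed trough"]
  heads <- keep[cats == "head"]
  if (!length(piles) || !length(heads)) return(state)
  pile_union <- Reduce(`|`, lapply(piles, function(a) a$mask))
  for (h in heads) {
    f <- assign_fence(h, layout)
    if (is.na(f)) next
    jaw <- jaw_region(h$mask, jaw_fraction)
    pile <- pile_union
    if (clip_pile_to_fence) pile <- pile & fence_region_mask(layout, f)
    if (sum(jaw & pile) >= min_contact_px) state[as.character(f)] <- TRUE
  }
  state
}

#' Aggregate per-frame feeding states into a timeline
#'
#' Each processed frame represents its whole stride window, so the feeding
#' time of a fence is `(number of TRUE flags) * stride / fps` seconds.
#'
#' @param frame_states Logical matrix (processed frames x fences, fence ids
#'   as column names) or a list of per-frame named logical vectors as
#'   produced by [frame_feeding_state()].
#' @param fps Capture frame rate (frames per second), `> 0`.
#' @param stride Gap between processed frames in original-frame units.
#' @return A `feeding_timeline`: list with `flags`, `fps`, `stride`,
#'   per-fence `feeding_frames` and `feeding_time_s`.
#' @export
accumulate_timeline <- function(frame_states, fps, stride = 1) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  stopifnot(stride >= 1)
  if (is.list(frame_states)) frame_states <- do.call(rbind, frame_states)
  stopifnot(is.matrix(frame_states))
  frames_true <- colSums(frame_states)
  structure(list(flags = frame_states, fps = fps, stride = stride,
                 feeding_frames = frames_true,
                 feeding_time_s = frames_true * stride / fps),
            class = "feeding_timeline")
}

#' @export
print.feeding_timeline <- function(x, ...) {
  cat(sprintf("<feeding_timeline: %d frames x %d fences @ %g fps, stride %d>\n",
              nrow(x$flags), ncol(x$flags), x$fps, x$stride))
  print(data.frame(fence = colnames(x$flags),
                   feeding_frames = x$feeding_frames,
                   feeding_time_s = x$feeding_time_s, row.names = NULL))
  invisible(x)
}

#' Mean absolute error of feeding times
#'
#' `MAE = mean(|predicted - actual|)`, the timeline-accuracy measure for
#' per-cow feeding times in seconds.
#'
#' @param predicted,actual Equal-length numeric vectors (seconds).
#' @return Non-negative scalar.
#' @examples
#' mae(c(43.3, 58.2, 56.0, 53.7, 21.7), c(41, 56, 56, 52, 19))  # 1.78
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) stop("need at least one sample", call. = FALSE)
  mean(abs(predicted - actual))
}
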