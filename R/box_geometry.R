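#' Bounding-box geometry and regression losses
#'
#' Boxes are numeric vectors `c(x1, y1, x2, y2)` in 0-based, half-open pixel
#' coordinates (`x2`/`y2` exclusive), so the area is `(x2 - x1) * (y2 - y1)`
#' with no `+1` convention. `iou()` is the intersection-over-union of the two
#' boxes; `giou()` is its generalized form, which subtracts from the IoU the
#' fraction of the smallest enclosing box `C` not covered by the union, so
#' that disjoint boxes still carry a useful (negative) signal; `giou_loss()`
#' is `1 - giou()`, the quantity minimized by the box-regression head; and
#' `l1_box_loss()` is the coordinate-wise absolute-difference baseline it
#' replaces.
#'
#' When both boxes have zero area the IoU is defined as 0.
#'
#' @param a,b Numeric boxes `c(x1, y1, x2, y2)` with `x1 <= x2`, `y1 <= y2`.
#' @return `iou()` in `[0, 1]`; `giou()` in `(-1, 1]`; `giou_loss()` in
#'   `[0, 2)`; `l1_box_loss()` a non-negative scalar.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))   # 1/7
#' giou(c(0, 0, 1, 1), c(2, 2, 3, 3))  # -7/9
#' giou_loss(c(0, 0, 1, 1), c(0, 0, 1, 1))
#' @export
iou <- function(a, b) {
  check_box(a); check_box(b)
  inter <- box_intersection_area(a, b)
  u <- box_area(a) + box_area(b) - inter
  if (u <= 0) return(0)
  inter / u
}

#' @rdname iou
#' @export
giou <- function(a, b) {
  check_box(a); check_box(b)
  inter <- box_intersection_area(a, b)
  u <- box_area(a) + box_area(b) - inter
  iou_val <- if (u <= 0) 0 else inter / u
  ac <- box_area(enclosing_box(a, b))
  if (ac <= 0) return(iou_val)
  iou_val - (ac - u) / ac
}

#' @rdname iou
#' @export
giou_loss <- function(a, b) 1 - giou(a, b)

#' @rdname iou
#' @export
l1_box_loss <- function(a, b) {
  check_box(a); check_box(b)
  sum(abs(a - b))
}

box_area <- function(a) max(a[3] - a[1], 0) * max(a[4] - a[2], 0)

box_intersection_area <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

enclosing_box <- function(a, b) {
  c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
}

check_box <- function(a) {
  if (!is.numeric(a) || length(a) != 4L) {
    stop("a box must be a numeric vector c(x1, y1, x2, y2)", call. = FALSE)
  }
  if (any(!is.finite(a))) stop("box coordinates must be finite", call. = FALSE)
  if (a[3] < a[1] || a[4] < a[2]) {
    stop("invalid box: requires x1 <= x2 and y1 <= y2", call. = FALSE)
  }
  invisible(a)
}

# Gradient of giou_loss(a, b) with respect to the four coordinates of the
# predicted box a. Piecewise-smooth; at ties the subgradient used matches
# the min/max branch taken by the forward pass.
giou_loss_grad <- function(a, b) {
  eps <- 1e-12
  ap <- box_area(a); ag <- box_area(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- if (iw > 0 && ih > 0) iw * ih else 0
  u <- ap + ag - inter
  cb <- enclosing_box(a, b)
  ac <- box_area(cb)

  # d(area of a)/d coords
  dap <- c(-(a[4] - a[2]), -(a[3] - a[1]), a[4] - a[2], a[3] - a[1])
  # d inter / d coords of a (zero where b's edge is the active one)
  dint <- numeric(4)
  if (inter > 0) {
    dint[1] <- if (a[1] > b[1]) -ih else 0
    dint[2] <- if (a[2] > b[2]) -iw else 0
    dint[3] <- if (a[3] < b[3])  ih else 0
    dint[4] <- if (a[4] < b[4])  iw else 0
  }
  du <- dap - dint
  # d ac / d coords of a (active only where a defines the hull edge)
  cw <- cb[3] - cb[1]; ch <- cb[4] - cb[2]
  dac <- c(if (a[1] < b[1]) -ch else 0,
           if (a[2] < b[2]) -cw else 0,
           if (a[3] > b[3])  ch else 0,
           if (a[4] > b[4])  cw else 0)

  diou <- if (u > eps) (dint * u - inter * du) / (u * u) else numeric(4)
  dpen <- if (ac > eps) (du * ac - u * dac) / (ac * ac) else numeric(4)
  # giou = iou - (ac - u)/ac = iou - 1 + u/ac ; loss = 1 - giou
  -(diou + dpen)
}

#' Greedy non-maximum suppression
#'
#' Standard descending-score greedy NMS on boxes: a box is kept unless its
#' IoU with an already kept box exceeds `iou_threshold`.
#'
#' @param boxes Numeric matrix, one `c(x1, y1, x2, y2)` row per box.
#' @param scores Numeric vector of confidences, one per row.
#' @param iou_threshold Overlap above which the lower-scored box is dropped.
#' @return Integer indices of the kept rows, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  stopifnot(is.matrix(boxes), ncol(boxes) == 4L, nrow(boxes) == length(scores))
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      if (iou(boxes[i, ], boxes[j, ]) > iou_threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}
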