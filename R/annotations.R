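#' Instance annotations and detection results
#'
#' An instance annotation couples a category label (`"head"` or
#' `"feed trough"`), a binary mask, the tight bounding box of that mask, and
#' optionally a confidence score (predictions only). Masks are logical
#' `H x W` matrices aligned to the image: `mask[r, c]` covers the pixel at
#' 0-based coordinates `x = c - 1`, `y = r - 1`. Boxes are `c(x1, y1, x2,
#' y2)`, 0-based and half-open, so a mask's tight box always satisfies
#' `box == mask_bbox(mask)`.
#'
#' @param category `"head"` or `"feed trough"`.
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @param score Optional confidence in `[0, 1]`; `NA` for ground truth.
#' @param bbox Optional box override; defaults to the mask's tight box.
#' @return An object of class `feedscan_annotation`: a list with elements
#'   `category`, `bbox`, `mask`, `score`.
#' @export
instance_annotation <- function(category, mask, score = NA_real_, bbox = NULL) {
  category <- match.arg(category, feedscan_categories())
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  if (!any(mask)) stop("mask must contain at least one TRUE pixel", call. = FALSE)
  if (is.null(bbox)) bbox <- mask_bbox(mask)
  structure(
    list(category = category, bbox = bbox, mask = mask, score = score),
    class = "feedscan_annotation"
  )
}

#' @export
format.feedscan_annotation <- function(x, ...) {
  sprintf("<%s box=[%.1f,%.1f,%.1f,%.1f] area=%dpx score=%s>",
          x$category, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4],
          sum(x$mask), if (is.na(x$score)) "NA" else sprintf("%.3f", x$score))
}

#' @export
print.feedscan_annotation <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' The fixed annotation vocabulary
#'
#' Feeding scenes are annotated with exactly two categories: the cow head
#' region reaching through the restriction fence (id 1) and the band-shaped
#' feed pile below it (id 2).
#'
#' @return Character vector `c("head", "feed trough")`, in category-id order.
#' @export
feedscan_categories <- function() c("head", "feed trough")

#' Tight bounding box of a binary mask
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return `c(x1, y1, x2, y2)` in 0-based half-open pixel coordinates.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

#' Fence layout of the feeding barrier
#'
#' Fences are fixed barn infrastructure, so their image-plane footprint is a
#' static per-camera configuration rather than a detected category. The
#' layout divides the canvas into vertical strips, one per fence, each with a
#' stable id.
#'
#' @param n_fences Number of fence positions.
#' @param width,height Canvas size in pixels.
#' @return Object of class `fence_layout`: list with `ids` and an
#'   `n_fences x 4` matrix `regions` of `c(x1, y1, x2, y2)` strips.
#' @export
fence_layout <- function(n_fences, width, height) {
  stopifnot(n_fences >= 1, width >= n_fences, height >= 1)
  edges <- round(seq(0, width, length.out = n_fences + 1))
  regions <- cbind(edges[-length(edges)], 0, edges[-1], height)
  colnames(regions) <- c("x1", "y1", "x2", "y2")
  structure(list(ids = seq_len(n_fences), regions = regions,
                 width = width, height = height),
            class = "fence_layout")
}

#' @export
print.fence_layout <- function(x, ...) {
  cat(sprintf("<fence_layout: %d strips on %dx%d canvas>\n",
              length(x$ids), x$height, x$width))
  invisible(x)
}

# Logical mask of one fence strip, canvas-sized.
fence_region_mask <- function(layout, fence_id) {
  r <- layout$regions[match(fence_id, layout$ids), ]
  m <- matrix(FALSE, layout$height, layout$width)
  m[, (r[1] + 1):r[3]] <- TRUE
  m
}

read_fence_layout <- function(path) {
  y <- yaml::read_yaml(path)
  fence_layout(y$n_fences, y$width, y$height)
}

write_fence_layout <- function(layout, path) {
  yaml::write_yaml(list(n_fences = length(layout$ids),
                        width = layout$width, height = layout$height), path)
  invisible(path)
}
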