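#' Dataset index of images and instance annotations
#'
#' A dataset index is the in-memory form of a COCO-dialect annotation file:
#' a list of records, each `list(image =, height =, width =, annotations =)`,
#' over the fixed ordered category pair `("head", "feed trough")` with
#' category ids 1 and 2.
#'
#' @param records List of records as above.
#' @return Object of class `dataset_index`.
#' @export
dataset_index <- function(records) {
  stopifnot(is.list(records))
  structure(list(records = records, categories = feedscan_categories()),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  n_ann <- sum(vapply(x$records, function(r) length(r$annotations), integer(1)))
  cat(sprintf("<dataset_index: %d images, %d annotations>\n",
              length(x$records), n_ann))
  invisible(x)
}

#' Read and write COCO-dialect instance annotations
#'
#' The on-disk dialect is standard COCO JSON: `images`, `categories`
#' (exactly `head` = 1 and `feed trough` = 2), and `annotations` whose
#' `segmentation` is either a polygon (list of flat `x0,y0,x1,y1,...`
#' vertex vectors, 0-based pixel coordinates) or an uncompressed run-length
#' encoding (`{size: [h, w], counts: [...]}` in column-major order starting
#' with the zero run). Masks are decoded to binary grids on read; boxes are
#' `[x, y, w, h]` on disk and tight half-open `c(x1, y1, x2, y2)` in memory.
#' `write_annotations()` always writes RLE, so read-write-read is the
#' identity on the data model.
#'
#' @param path JSON file path.
#' @return `read_annotations()`: a [dataset_index()].
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::read_json(path)
  cats <- vapply(doc$categories, function(ct) ct$name, character(1))
  ids <- vapply(doc$categories, function(ct) as.integer(ct$id), integer(1))
  bad <- setdiff(cats, feedscan_categories())
  if (length(bad)) {
    stop("unknown category name(s): ", paste(bad, collapse = ", "),
         " (expected 'head', 'feed trough')", call. = FALSE)
  }
  cat_by_id <- setNames(cats, ids)

  records <- list()
  img_pos <- integer(0)
  for (im in doc$images) {
    records[[length(records) + 1L]] <-
      list(image = im$file_name, height = as.integer(im$height),
           width = as.integer(im$width), annotations = list())
    img_pos[as.character(im$id)] <- length(records)
  }
  for (an in doc$annotations) {
    pos <- img_pos[as.character(an$image_id)]
    if (is.na(pos)) {
      stop("annotation references unknown image id ", an$image_id, call. = FALSE)
    }
    rec <- records[[pos]]
    mask <- decode_segmentation(an$segmentation, rec$height, rec$width)
    score <- if (!is.null(an$score)) as.numeric(an$score) else NA_real_
    rec$annotations[[length(rec$annotations) + 1L]] <-
      instance_annotation(cat_by_id[[as.character(an$category_id)]], mask,
                          score = score)
    records[[pos]] <- rec
  }
  dataset_index(records)
}

#' @rdname read_annotations
#' @param index A [dataset_index()].
#' @export
write_annotations <- function(index, path) {
  stopifnot(inherits(index, "dataset_index"))
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(index$records)) {
    rec <- index$records[[i]]
    images[[i]] <- list(id = i, file_name = rec$image,
                        height = rec$height, width = rec$width)
    for (a in rec$annotations) {
      aid <- aid + 1L
      entry <- list(
        id = aid, image_id = i,
        category_id = match(a$category, feedscan_categories()),
        bbox = c(a$bbox[1], a$bbox[2],
                 a$bbox[3] - a$bbox[1], a$bbox[4] - a$bbox[2]),
        area = sum(a$mask),
        segmentation = rle_encode(a$mask),
        iscrowd = 0L)
      if (!is.na(a$score)) entry$score <- a$score
      annotations[[aid]] <- entry
    }
  }
  doc <- list(
    images = images,
    categories = list(list(id = 1L, name = "head"),
                      list(id = 2L, name = "feed trough")),
    annotations = annotations)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

decode_segmentation <- function(seg, height, width) {
  if (!is.null(seg$counts)) {
    rle_decode(list(size = unlist(seg$size), counts = unlist(seg$counts)))
  } else {
    polys <- lapply(seg, function(p) as.numeric(unlist(p)))
    if (!length(polys) || any(vapply(polys, length, integer(1)) < 6) ||
        any(vapply(polys, length, integer(1)) %% 2 != 0)) {
      stop("malformed polygon segmentation: each ring needs >= 3 (x, y) pairs",
           call. = FALSE)
    }
    m <- matrix(FALSE, height, width)
    for (p in polys) m <- m | rasterize_polygon(p, height, width)
    m
  }
}

#' Run-length encoding of binary masks
#'
#' Uncompressed COCO-style RLE: the mask is flattened in column-major order
#' and stored as alternating run lengths, starting with the run of zeros
#' (possibly length 0).
#'
#' @param mask Logical matrix.
#' @return `rle_encode()`: list with `size = c(h, w)` and integer `counts`.
#' @export
rle_encode <- function(mask) {
  v <- as.integer(as.vector(mask))     # R matrices are column-major already
  r <- rle(v)
  counts <- r$lengths
  if (length(r$values) && r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' @rdname rle_encode
#' @param rle List with `size` and `counts` as produced by `rle_encode()`.
#' @export
rle_decode <- function(rle) {
  size <- as.integer(rle$size); counts <- as.integer(rle$counts)
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  if (length(vals) != prod(size)) {
    stop("RLE counts do not cover the mask size", call. = FALSE)
  }
  matrix(as.logical(vals), size[1], size[2])
}

#' Rasterize a polygon ring to a binary mask
#'
#' Even-odd scanline fill: a pixel is inside when its centre
#' `(x + 0.5, y + 0.5)` (0-based coordinates) lies inside the ring.
#'
#' @param poly Flat numeric vector `x0, y0, x1, y1, ...` of vertices.
#' @param height,width Mask size in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_polygon <- function(poly, height, width) {
  xs <- poly[seq(1, length(poly), 2)]
  ys <- poly[seq(2, length(poly), 2)]
  n <- length(xs)
  m <- matrix(FALSE, height, width)
  for (row in seq_len(height)) {
    yc <- row - 1 + 0.5
    crossings <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      y1 <- ys[j]; y2 <- ys[i]
      if ((y1 <= yc) != (y2 <= yc)) {
        x <- xs[j] + (yc - y1) / (y2 - y1) * (xs[i] - xs[j])
        crossings <- c(crossings, x)
      }
      j <- i
    }
    if (length(crossings) >= 2) {
      crossings <- sort(crossings)
      for (k in seq(1, length(crossings) - 1, 2)) {
        lo <- ceiling(crossings[k] - 0.5) + 1      # first pixel centre inside
        hi <- floor(crossings[k + 1] - 0.5 + 1)    # last pixel centre inside
        lo <- max(lo, 1L); hi <- min(hi, width)
        if (lo <= hi) m[row, lo:hi] <- TRUE
      }
    }
  }
  m
}
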