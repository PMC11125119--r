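#' Deterministic train/validation/test split
#'
#' Shuffles the records under `seed` and partitions them by the given
#' ratios. Validation and test sizes are floors of their shares and the
#' remainder goes to the training split, so 1000 records at 8:1:1 give
#' 800/100/100 and 11 records give 9/1/1.
#'
#' @param index A [dataset_index()].
#' @param ratios Positive `c(train, val, test)` weights (normalized
#'   internally).
#' @param seed Integer seed.
#' @return Named list of three disjoint `dataset_index` objects: `train`,
#'   `val`, `test`.
#' @export
split_dataset <- function(index, ratios = c(8, 1, 1), seed = 1) {
  stopifnot(inherits(index, "dataset_index"), length(ratios) == 3)
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  n <- length(index$records)
  if (n == 0L) stop("empty dataset index", call. = FALSE)
  ratios <- ratios / sum(ratios)
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_val - n_test
  perm <- local_seed(seed, sample.int(n))
  pick <- function(idx) dataset_index(index$records[sort(idx)])
  list(train = pick(perm[seq_len(n_train)]),
       val = pick(perm[n_train + seq_len(n_val)]),
       test = pick(perm[n_train + n_val + seq_len(n_test)]))
}

#' Mosaic augmentation
#'
#' Stitches four images into one training canvas: each input is resized to
#' a square tile of side `out_size[1]`, the four tiles are laid out in a
#' 2x2 grid around a drawn centre on a double-size canvas, a random
#' scale/translation affine is applied, and the result is cropped to
#' `out_size` (rows x cols; the reference size 800 x 1333 mirrors the
#' training resolution). Annotation masks ride through the same transform;
#' instances whose clipped mask is empty are dropped, and every surviving
#' box is recomputed as the tight box of its transformed mask.
#'
#' @param inputs List of exactly four `list(image =, annotations =)` pairs.
#' @param out_size Output `c(rows, cols)`.
#' @param seed Integer seed.
#' @param scale_range,translate_range Affine jitter ranges: scale drawn
#'   uniformly from `scale_range`, translation (fraction of the stitched
#'   canvas) from `+/- translate_range`.
#' @param center Optional tile-centre as fractions of the stitched canvas;
#'   `NULL` draws it uniformly from `[0.4, 0.6]^2`. `c(0.5, 0.5)` gives the
#'   exact centred 2x2 split.
#' @return `list(image =, annotations =)` at `out_size`.
#' @export
mosaic_augment <- function(inputs, out_size = c(800, 1333), seed = 1,
                           scale_range = c(0.8, 1.2),
                           translate_range = 0.1, center = NULL) {
  if (length(inputs) != 4L) stop("mosaic requires exactly four inputs", call. = FALSE)
  t_side <- out_size[1]
  canvas_side <- 2L * t_side
  local_seed(seed, {
    if (is.null(center)) center <- runif(2, 0.4, 0.6)
    s <- runif(1, scale_range[1], scale_range[2])
    tr <- runif(2, -translate_range, translate_range) * canvas_side
    cy <- round(center[1] * canvas_side); cx <- round(center[2] * canvas_side)

    canvas <- array(114, dim = c(canvas_side, canvas_side, 3))
    placed <- list()   # per input: row/col offset of its resized tile
    # quadrant corners: tiles meet at (cy, cx)
    offs <- list(c(cy - t_side, cx - t_side), c(cy - t_side, cx),
                 c(cy, cx - t_side), c(cy, cx))
    for (i in 1:4) {
      img <- as_image_array(inputs[[i]]$image)
      tile <- resize_image(img, t_side, t_side)
      o <- offs[[i]]
      rr <- (o[1] + 1):(o[1] + t_side); cc <- (o[2] + 1):(o[2] + t_side)
      rok <- rr >= 1 & rr <= canvas_side; cok <- cc >= 1 & cc <= canvas_side
      canvas[rr[rok], cc[cok], ] <- tile[which(rok), which(cok), , drop = FALSE]
      placed[[i]] <- list(off = o, h = dim(img)[1], w = dim(img)[2])
    }

    # Inverse-mapped nearest sampling of the affine (scale s, shift tr),
    # then crop to out_size: output (r, c) <- canvas((r - tr_y)/s, (c - tr_x)/s).
    src_r <- pmin(pmax(round((seq_len(out_size[1]) - tr[1]) / s), 1L), canvas_side)
    src_c <- pmin(pmax(round((seq_len(out_size[2]) - tr[2]) / s), 1L), canvas_side)
    in_r <- (seq_len(out_size[1]) - tr[1]) / s >= 0.5 &
      (seq_len(out_size[1]) - tr[1]) / s <= canvas_side + 0.5
    in_c <- (seq_len(out_size[2]) - tr[2]) / s >= 0.5 &
      (seq_len(out_size[2]) - tr[2]) / s <= canvas_side + 0.5
    out_img <- array(114, dim = c(out_size[1], out_size[2], 3))
    out_img[in_r, in_c, ] <- canvas[src_r[in_r], src_c[in_c], , drop = FALSE]
    out_img <- round(pmin(pmax(out_img, 0), 255))
    storage.mode(out_img) <- "integer"

    out_anns <- list()
    for (i in 1:4) {
      p <- placed[[i]]
      tile_r <- resize_index(t_side, p$h); tile_c <- resize_index(t_side, p$w)
      for (a in inputs[[i]]$annotations) {
        big <- matrix(FALSE, canvas_side, canvas_side)
        rr <- (p$off[1] + 1):(p$off[1] + t_side)
        cc <- (p$off[2] + 1):(p$off[2] + t_side)
        rok <- rr >= 1 & rr <= canvas_side; cok <- cc >= 1 & cc <= canvas_side
        tile_mask <- a$mask[tile_r, tile_c, drop = FALSE]
        big[rr[rok], cc[cok]] <- tile_mask[which(rok), which(cok), drop = FALSE]
        out_mask <- matrix(FALSE, out_size[1], out_size[2])
        out_mask[in_r, in_c] <- big[src_r[in_r], src_c[in_c], drop = FALSE]
        if (any(out_mask)) {
          out_anns[[length(out_anns) + 1L]] <-
            instance_annotation(a$category, out_mask, score = a$score)
        }
      }
    }
    list(image = out_img, annotations = out_anns)
  })
}

#' Horizontal-flip augmentation
#'
#' Reverses image columns and remaps every mask and box with
#' `x -> W - x`; applying it twice is the identity.
#'
#' @param image `H x W x 3` array.
#' @param annotations List of `feedscan_annotation`.
#' @return `list(image =, annotations =)`.
#' @export
hflip_augment <- function(image, annotations = list()) {
  w <- dim(image)[2]
  flipped <- image[, w:1, , drop = FALSE]
  anns <- lapply(annotations, function(a) {
    instance_annotation(a$category, a$mask[, w:1, drop = FALSE],
                        score = a$score)
  })
  list(image = flipped, annotations = anns)
}

# Bilinear image resize (masks use resize_index for nearest-neighbour).
resize_image <- function(img, h, w) {
  out <- cpp_bilinear_resize(as_image_array(img), h, w)
  array(out, dim = c(h, w, dim(img)[3]))
}

# Nearest source indices mapping an axis of length n_src onto n_out samples.
resize_index <- function(n_out, n_src) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_src / n_out) + 1L, 1L), n_src)
}
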