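#' Image-pair similarity: mean squared error and peak signal-to-noise ratio
#'
#' Video of cows at the fence is highly redundant frame to frame; these two
#' measures quantify how quickly a clip decorrelates with frame gap and
#' justify a frame-extraction stride. `mse()` is the squared intensity
#' difference averaged over all `M x N` pixel positions and the three colour
#' channels; `psnr()` is `10 * log10(MAX_I^2 / MSE)` in dB with `MAX_I = 255`
#' for 8-bit capture. Identical images have MSE 0 and PSNR `Inf`.
#'
#' @param a,b Images as numeric `H x W x 3` arrays with values in
#'   `[0, 255]`; shapes must match.
#' @return `mse()`: non-negative scalar. `psnr()`: dB value, `Inf` for
#'   identical images.
#' @examples
#' a <- array(0, c(2, 2, 3)); b <- a + 10
#' mse(a, b)    # 100
#' psnr(a, b)   # 10 * log10(255^2 / 100) ~ 28.13 dB
#' @export
mse <- function(a, b) {
  a <- as_image_array(a); b <- as_image_array(b)
  if (!identical(dim(a), dim(b))) {
    stop("image shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  mean((a - b)^2)
}

#' @rdname mse
#' @export
psnr <- function(a, b) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

as_image_array <- function(a) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (!is.array(a) || length(dim(a)) != 3L) {
    stop("an image must be an H x W x C array", call. = FALSE)
  }
  storage.mode(a) <- "double"
  a
}

#' Frame-gap similarity curve of a clip
#'
#' For each candidate gap `g`, averages `mse`/`psnr` over all frame pairs
#' `(t, t + g)` in the clip. Plotting MSE against the gap and looking for
#' the point where the curve stops surging is how the default extraction
#' stride of 600 frames was chosen for 20 fps barn footage; the stride
#' itself stays a configuration value.
#'
#' Pairs with infinite PSNR (identical frames) are excluded from the PSNR
#' average; if all pairs at a gap are identical the PSNR entry is `Inf`.
#'
#' @param clip A `feedscan_clip` (list of frames + `fps`) or a plain list of
#'   images.
#' @param intervals Strictly increasing integer frame gaps, all smaller than
#'   the clip length.
#' @return Data frame with columns `gap`, `mse`, `psnr_db`.
#' @export
interval_curve <- function(clip, intervals) {
  frames <- clip_frames(clip)
  if (length(frames) == 0L) stop("empty clip", call. = FALSE)
  intervals <- as.integer(intervals)
  stopifnot(all(diff(intervals) > 0), all(intervals >= 1))
  if (max(intervals) >= length(frames)) {
    stop("max gap must be smaller than the clip length", call. = FALSE)
  }
  rows <- lapply(intervals, function(g) {
    idx <- seq_len(length(frames) - g)
    ms <- vapply(idx, function(t) mse(frames[[t]], frames[[t + g]]), numeric(1))
    ps <- 10 * log10(255^2 / ms[ms > 0])
    data.frame(gap = g, mse = mean(ms),
               psnr_db = if (length(ps)) mean(ps) else Inf)
  })
  do.call(rbind, rows)
}

#' Extract frames at a fixed stride
#'
#' Removes frame redundancy by keeping frames `0, stride, 2*stride, ...`
#' (0-based), i.e. `floor((n - 1) / stride) + 1` frames from an `n`-frame
#' clip.
#'
#' @param clip A `feedscan_clip` or list of frames.
#' @param stride Positive integer frame stride (default 600, the plateau
#'   gap for 20 fps feeding footage).
#' @return List of the extracted frames.
#' @export
extract_frames <- function(clip, stride = 600) {
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  frames <- clip_frames(clip)
  frames[seq(1L, length(frames), by = as.integer(stride))]
}

clip_frames <- function(clip) {
  if (inherits(clip, "feedscan_clip")) clip$frames
  else if (is.list(clip)) clip
  else stop("not a clip: expected a feedscan_clip or a list of frames",
            call. = FALSE)
}

#' Read a clip from a directory of numbered PNG frames
#'
#' Counterpart of [write_clip()]: reads `frame_*.png` in lexical order plus
#' the `clip.yaml` fps sidecar.
#'
#' @param dir Directory holding the frames.
#' @return A `feedscan_clip`.
#' @export
read_clip <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no frame_*.png files in ", dir, call. = FALSE)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
    img <- round(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE] * 255)
    storage.mode(img) <- "integer"
    img
  })
  meta <- file.path(dir, "clip.yaml")
  fps <- if (file.exists(meta)) yaml::read_yaml(meta)$fps else NA_real_
  structure(list(frames = frames, fps = fps), class = "feedscan_clip")
}
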