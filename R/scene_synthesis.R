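#' Synthetic barn-scene configuration
#'
#' The generator emulates the geometry of a feeding barn seen from the feed
#' alley: a band-shaped feed pile with an irregular upper boundary along the
#' lower part of the frame, a row of vertical fence strips, and up to one
#' elliptical cow head per fence, its darker lower third standing in for the
#' jaw. Day / dim / night regimes are a global intensity scale plus additive
#' Gaussian pixel noise; no photorealism is attempted.
#'
#' @param canvas_size `c(height, width)` in pixels, both `>= 64`.
#' @param n_fences Number of fence strips.
#' @param n_heads Number of cow heads (`<= n_fences`; at most one per fence).
#' @param pile_band `c(top_fraction, bottom_fraction, roughness_px)`: the
#'   pile occupies rows between the two canvas-height fractions, with a
#'   sinusoid + noise upper boundary of the given amplitude in pixels.
#' @param illumination `"day"`, `"dim"` or `"night"` (intensity scales 1.0,
#'   0.55, 0.25).
#' @param noise_sd Standard deviation of the additive pixel noise (8-bit
#'   intensity units).
#' @param seed Integer seed; identical config + seed reproduces identical
#'   scenes bit for bit.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(canvas_size = c(128, 160), n_fences = 4, n_heads = 2,
                         pile_band = c(0.62, 0.95, 3), illumination = "day",
                         noise_sd = 4, seed = 1) {
  illumination <- match.arg(illumination, c("day", "dim", "night"))
  stopifnot(length(canvas_size) == 2, length(pile_band) == 3)
  if (any(canvas_size < 64)) stop("canvas dimensions must be >= 64 px", call. = FALSE)
  if (n_heads > n_fences) stop("n_heads must be <= n_fences", call. = FALSE)
  if (!(pile_band[1] > 0 && pile_band[2] < 1 && pile_band[1] < pile_band[2])) {
    stop("pile band fractions must satisfy 0 < top < bottom < 1", call. = FALSE)
  }
  structure(list(canvas_size = as.integer(canvas_size),
                 n_fences = as.integer(n_fences),
                 n_heads = as.integer(n_heads),
                 pile_band = as.numeric(pile_band),
                 illumination = illumination,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

illumination_scale <- function(illumination) {
  c(day = 1.0, dim = 0.55, night = 0.25)[[illumination]]
}

# Evaluate code with a private, restored RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Upper boundary row (1-based) of the pile for each column.
pile_top_rows <- function(config, phase = 0) {
  h <- config$canvas_size[1]; w <- config$canvas_size[2]
  top <- config$pile_band[1]; amp <- config$pile_band[3]
  x <- seq_len(w)
  wobble <- amp * sin(2 * pi * x / max(24, w / 3) + phase) +
    amp * 0.5 * sin(2 * pi * x / 11 + 2 * phase)
  rows <- round(h * top + wobble)
  pmax(2L, pmin(as.integer(rows), as.integer(h * config$pile_band[2]) - 2L))
}

pile_mask_from_rows <- function(config, top_rows) {
  h <- config$canvas_size[1]; w <- config$canvas_size[2]
  bottom <- as.integer(round(h * config$pile_band[2]))
  row_idx <- matrix(seq_len(h), h, w)
  top_mat <- matrix(top_rows, h, w, byrow = TRUE)
  row_idx > top_mat & row_idx <= bottom
}

# Geometry of one head: an ellipse centred in its fence strip whose bottom
# either overlaps the pile boundary (feeding) or sits clear above it. The
# feeding depth is calibrated against the actual pile mask so the jaw
# (lowest third of the head) intersects it in at least `min_contact_px`
# pixels — the boundary is wavy, so a nominal offset is not enough — while
# the idle position sits strictly above every pile pixel (zero overlap).
head_geometry <- function(config, layout, fence_id, top_rows, pile_mask,
                          gap_px = 6L, min_contact_px = 30L) {
  strip <- layout$regions[fence_id, ]
  sw <- strip[3] - strip[1]
  rx <- floor(sw * 0.32)
  ry <- floor(config$canvas_size[1] * 0.16)
  if (rx < 3 || ry < 3) {
    stop("heads cannot fit in fences: strips too narrow for this canvas",
         call. = FALSE)
  }
  cx <- (strip[1] + strip[3]) / 2            # 0-based x centre
  cols <- pmax(1L, pmin(config$canvas_size[2],
                        as.integer(floor(cx - rx)):as.integer(ceiling(cx + rx)) + 1L))
  boundary <- min(top_rows[cols])
  idle_bottom <- boundary - gap_px
  if (idle_bottom - 2 * ry < 2) {
    stop("heads cannot fit in fences: no room above the pile", call. = FALSE)
  }
  geom <- list(cx = cx, rx = rx, ry = ry, idle_bottom = idle_bottom)
  feed_bottom <- boundary + 2L
  repeat {
    m <- head_mask_at(config, c(geom, feed_bottom = feed_bottom), feed_bottom)
    if (sum(jaw_region(m) & pile_mask) >= min_contact_px ||
        feed_bottom >= boundary + ry) break
    feed_bottom <- feed_bottom + 1L
  }
  geom$feed_bottom <- feed_bottom
  geom
}

ellipse_mask <- function(h, w, cx, cy, rx, ry) {
  cc <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  rr <- matrix(seq_len(h) - 1, h, w)
  ((cc - cx) / rx)^2 + ((rr - cy) / ry)^2 <= 1
}

head_mask_at <- function(config, geom, bottom_row) {
  cy <- bottom_row - 1 - geom$ry         # 0-based y centre; bottom_row 1-based
  ellipse_mask(config$canvas_size[1], config$canvas_size[2],
               geom$cx, cy, geom$rx, geom$ry)
}

# Paint one frame given the static pile and per-head masks. Returns an
# integer H x W x 3 array with values in 0..255.
render_frame <- function(config, pile_mask, head_masks) {
  h <- config$canvas_size[1]; w <- config$canvas_size[2]
  img <- array(0, dim = c(h, w, 3))
  base <- c(122, 126, 130)                      # concrete background
  pile_col <- c(156, 112, 58)                   # spread feed
  head_col <- c(70, 58, 50)                     # cow head
  for (k in 1:3) {
    m <- matrix(base[k], h, w)
    m[pile_mask] <- pile_col[k]
    img[, , k] <- m
  }
  # fence posts: light vertical bars above the pile at strip edges
  layout <- fence_layout(config$n_fences, w, h)
  post_x <- unique(as.vector(layout$regions[, c(1, 3)]))
  post_x <- post_x[post_x > 0 & post_x < w]
  pile_top <- apply(pile_mask, 2, function(col) {
    i <- which(col); if (length(i)) min(i) else h
  })
  for (px in post_x) {
    cols <- pmax(1L, pmin(w, px:(px + 1L)))
    for (cl in cols) img[seq_len(max(pile_top[cl] - 1L, 1L)), cl, ] <- 190
  }
  for (hm in head_masks) {
    if (is.null(hm)) next
    bb <- mask_bbox(hm)
    jaw_rows <- (bb[2] + (bb[4] - bb[2]) * 2 / 3) < matrix(seq_len(h) - 1, h, w)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[hm] <- head_col[k]
      ch[hm & jaw_rows] <- head_col[k] * 0.6    # darker jaw third
      img[, , k] <- ch
    }
  }
  img <- img * illumination_scale(config$illumination)
  img <- img + array(rnorm(length(img), 0, config$noise_sd), dim = dim(img))
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  img
}

#' Render a synthetic feeding scene with pixel-accurate ground truth
#'
#' Draws the feed pile as a horizontal band with a sinusoid + noise upper
#' boundary and places one elliptical head per occupied fence. For each head
#' a flag decides whether its jaw (lower third) is lowered onto the pile —
#' in which case head and pile masks intersect by construction — or held
#' clear above it. Output is bit-for-bit reproducible from the config.
#'
#' @param config A [scene_config()].
#' @param feeding Optional logical vector of length `n_heads` forcing each
#'   head's feeding flag; `NULL` draws the flags at random.
#' @return A list with `image` (integer `H x W x 3` array, 0–255) and
#'   `truth`, a `scene_truth` list carrying `annotations` (the feed-trough
#'   annotation first, then one `"head"` annotation per head), `fence_layout`,
#'   `head_fences` (fence id of each head), and per-fence logical
#'   `feeding_state`.
#' @export
make_scene <- function(config, feeding = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(feeding)) stopifnot(length(feeding) == config$n_heads)
  local_seed(config$seed, {
    h <- config$canvas_size[1]; w <- config$canvas_size[2]
    layout <- fence_layout(config$n_fences, w, h)
    top_rows <- pile_top_rows(config, phase = runif(1, 0, 2 * pi))
    pile_mask <- pile_mask_from_rows(config, top_rows)

    fences <- sort(sample(config$n_fences, config$n_heads))
    if (is.null(feeding)) feeding <- runif(config$n_heads) < 0.5

    head_masks <- list(); head_fence <- integer(0)
    for (i in seq_along(fences)) {
      geom <- head_geometry(config, layout, fences[i], top_rows, pile_mask)
      bottom <- if (feeding[i]) geom$feed_bottom else geom$idle_bottom
      head_masks[[i]] <- head_mask_at(config, geom, bottom)
      head_fence[i] <- fences[i]
    }

    img <- render_frame(config, pile_mask, head_masks)

    anns <- list(instance_annotation("feed trough", pile_mask))
    for (i in seq_along(head_masks)) {
      anns[[length(anns) + 1L]] <- instance_annotation("head", head_masks[[i]])
    }
    state <- setNames(rep(FALSE, config$n_fences), layout$ids)
    if (length(fences)) state[fences] <- feeding
    truth <- structure(list(annotations = anns, fence_layout = layout,
                            head_fences = head_fence, feeding_state = state),
                       class = "scene_truth")
    list(image = img, truth = truth)
  })
}

#' Render a feeding clip with a known per-fence feeding schedule
#'
#' Heads translate vertically between an idle position (jaw clear of the
#' pile) and a feeding position (jaw overlapping the pile boundary) so that
#' jaw–pile mask contact occurs during, and only during, the scheduled
#' frames. Ground-truth feeding time per fence is therefore exactly the sum
#' of its interval lengths divided by `fps`.
#'
#' @param config A [scene_config()]; `n_heads` is ignored — a head is placed
#'   in every fence named by `schedule`, plus the first unnamed fences up to
#'   `n_heads` total.
#' @param n_frames Number of frames to render.
#' @param fps Frame rate in frames per second.
#' @param schedule Named list: for fence id `f`, `schedule[[as.character(f)]]`
#'   is a 2-column matrix (or list of pairs) of half-open `[start, end)`
#'   feeding intervals in 0-based frame indices. Intervals for one fence must
#'   not overlap and must lie within `[0, n_frames)`.
#' @return List with `clip` (class `feedscan_clip`: list of frames plus
#'   `fps`) and `truth` carrying `fence_layout`, the per-frame per-fence
#'   logical matrix `feeding_state`, per-fence `feeding_time_s`, and
#'   `frame_annotations` (ground-truth annotations for every frame).
#' @export
make_feeding_clip <- function(config, n_frames, fps, schedule = list()) {
  stopifnot(inherits(config, "scene_config"), n_frames >= 1, fps > 0)
  sched <- normalize_schedule(schedule, n_frames, config$n_fences)
  local_seed(config$seed, {
    h <- config$canvas_size[1]; w <- config$canvas_size[2]
    layout <- fence_layout(config$n_fences, w, h)
    top_rows <- pile_top_rows(config, phase = runif(1, 0, 2 * pi))
    pile_mask <- pile_mask_from_rows(config, top_rows)

    occupied <- sort(unique(c(as.integer(names(sched)),
                              head(setdiff(seq_len(config$n_fences),
                                           as.integer(names(sched))),
                                   max(0L, config$n_heads - length(sched))))))
    geoms <- lapply(occupied, function(f)
      head_geometry(config, layout, f, top_rows, pile_mask))

    state <- matrix(FALSE, n_frames, config$n_fences,
                    dimnames = list(NULL, layout$ids))
    for (f in names(sched)) {
      for (k in seq_len(nrow(sched[[f]]))) {
        iv <- sched[[f]][k, ]
        state[(iv[1] + 1):iv[2], as.integer(f)] <- TRUE
      }
    }

    frames <- vector("list", n_frames)
    frame_annotations <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      head_masks <- vector("list", length(occupied))
      for (i in seq_along(occupied)) {
        feeding_now <- state[t, occupied[i]]
        bottom <- if (feeding_now) geoms[[i]]$feed_bottom else geoms[[i]]$idle_bottom
        head_masks[[i]] <- head_mask_at(config, geoms[[i]], bottom)
      }
      frames[[t]] <- render_frame(config, pile_mask, head_masks)
      anns <- list(instance_annotation("feed trough", pile_mask))
      for (hm in head_masks) {
        anns[[length(anns) + 1L]] <- instance_annotation("head", hm)
      }
      frame_annotations[[t]] <- anns
    }

    feeding_time <- colSums(state) / fps
    clip <- structure(list(frames = frames, fps = fps), class = "feedscan_clip")
    truth <- structure(list(fence_layout = layout, head_fences = occupied,
                            feeding_state = state,
                            feeding_time_s = feeding_time,
                            frame_annotations = frame_annotations),
                       class = "scene_truth")
    list(clip = clip, truth = truth)
  })
}

normalize_schedule <- function(schedule, n_frames, n_fences) {
  if (length(schedule) && is.null(names(schedule))) {
    stop("schedule must be a named list keyed by fence id", call. = FALSE)
  }
  out <- list()
  for (f in names(schedule)) {
    iv <- schedule[[f]]
    if (is.list(iv)) iv <- do.call(rbind, iv)
    iv <- matrix(as.integer(iv), ncol = 2)
    if (!(as.integer(f) %in% seq_len(n_fences))) {
      stop("schedule names a fence outside the layout: ", f, call. = FALSE)
    }
    if (any(iv[, 1] < 0 | iv[, 2] > n_frames | iv[, 1] >= iv[, 2])) {
      stop("intervals must be half-open [start, end) within [0, n_frames)",
           call. = FALSE)
    }
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("overlapping feeding intervals for fence ", f, call. = FALSE)
    }
    out[[f]] <- iv
  }
  out
}

#' Perturb ground truth into a scored detection set
#'
#' Builds a prediction set with known defects — box/mask jitter, deleted
#' instances, and spurious detections — so that its average precision against
#' the original truth can be computed independently by a threshold-sweep
#' oracle.
#'
#' @param truth A `scene_truth` from [make_scene()].
#' @param jitter_px Standard deviation (pixels) of the integer translation
#'   applied to each kept instance.
#' @param score_fn Function `n -> n` scores for the kept (true) detections.
#' @param n_false_positives Number of spurious elliptical detections added.
#' @param n_misses Number of ground-truth instances dropped.
#' @param seed Integer seed.
#' @return List of scored `feedscan_annotation` objects.
#' @export
make_detection_set <- function(truth, jitter_px = 0,
                               score_fn = function(n) runif(n, 0.6, 1),
                               n_false_positives = 0, n_misses = 0, seed = 1) {
  stopifnot(inherits(truth, "scene_truth"), jitter_px >= 0)
  anns <- truth$annotations
  h <- nrow(anns[[1]]$mask); w <- ncol(anns[[1]]$mask)
  local_seed(seed, {
    keep <- seq_along(anns)
    if (n_misses > 0) {
      keep <- sort(sample(keep, max(0L, length(anns) - n_misses)))
    }
    dets <- list()
    scores <- score_fn(length(keep))
    for (i in seq_along(keep)) {
      a <- anns[[keep[i]]]
      m <- a$mask
      if (jitter_px > 0) {
        m <- shift_mask(m, round(rnorm(1, 0, jitter_px)),
                        round(rnorm(1, 0, jitter_px)))
        if (!any(m)) m <- a$mask   # a jitter that empties the mask is retried as identity
      }
      dets[[length(dets) + 1L]] <- instance_annotation(a$category, m,
                                                       score = scores[i])
    }
    if (n_false_positives > 0) {
      for (k in seq_len(n_false_positives)) {
        cx <- runif(1, 10, w - 10); cy <- runif(1, 10, h - 10)
        m <- ellipse_mask(h, w, cx, cy, runif(1, 4, 12), runif(1, 4, 12))
        if (!any(m)) m[round(cy), round(cx)] <- TRUE
        dets[[length(dets) + 1L]] <- instance_annotation(
          sample(feedscan_categories(), 1), m, score = runif(1, 0.05, 0.55))
      }
    }
    dets[order(vapply(dets, function(d) d$score, numeric(1)),
               decreasing = TRUE)]
  })
}

# Translate a logical mask by (dx, dy) pixels, clipping at the canvas edge.
shift_mask <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  rok <- src_r >= 1 & src_r <= h; cok <- src_c >= 1 & src_c <= w
  out[rok, cok] <- mask[src_r[rok], src_c[cok]]
  out
}

#' Write a scene or clip to disk as PNG plus sidecars
#'
#' Images are written as PNG, clips as numbered PNG frames with an `fps`
#' YAML sidecar; the fence layout goes to `fences.yaml` and annotations to a
#' COCO-dialect `annotations.json`.
#'
#' @param scene Result of [make_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(aperm(array(scene$image / 255, dim = dim(scene$image)),
                      c(1, 2, 3)),
                file.path(dir, "scene.png"))
  write_fence_layout(scene$truth$fence_layout, file.path(dir, "fences.yaml"))
  idx <- dataset_index(list(list(image = "scene.png",
                                 height = dim(scene$image)[1],
                                 width = dim(scene$image)[2],
                                 annotations = scene$truth$annotations)))
  write_annotations(idx, file.path(dir, "annotations.json"))
  invisible(dir)
}

#' @rdname write_scene
#' @param clip_result Result of [make_feeding_clip()].
#' @export
write_clip <- function(clip_result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- clip_result$clip$frames
  for (t in seq_along(frames)) {
    png::writePNG(frames[[t]] / 255,
                  file.path(dir, sprintf("frame_%05d.png", t - 1L)))
  }
  yaml::write_yaml(list(fps = clip_result$clip$fps,
                        n_frames = length(frames)),
                   file.path(dir, "clip.yaml"))
  write_fence_layout(clip_result$truth$fence_layout,
                     file.path(dir, "fences.yaml"))
  invisible(dir)
}
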