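small_cfg <- function(n_fences = 4, n_heads = 2, ...) {
  scene_config(canvas_size = c(96, 128), n_fences = n_fences,
               n_heads = n_heads, ...)
}

test_that("identical config and seed reproduce scenes bit for bit", {
  a <- make_scene(small_cfg(seed = 5))
  b <- make_scene(small_cfg(seed = 5))
  expect_identical(a, b)
  c <- make_scene(small_cfg(seed = 6))
  expect_false(identical(a$image, c$image))
})

test_that("a scene with no heads carries exactly the feed-trough annotation", {
  s <- make_scene(small_cfg(n_heads = 0, seed = 2))
  expect_length(s$truth$annotations, 1)
  expect_equal(s$truth$annotations[[1]]$category, "feed trough")
  expect_false(any(s$truth$feeding_state))
})

test_that("feeding heads intersect the pile and idle heads do not", {
  s <- make_scene(scene_config(canvas_size = c(96, 128), n_fences = 4,
                               n_heads = 4, seed = 9), feeding = rep(TRUE, 4))
  anns <- s$truth$annotations
  expect_length(anns, 5)
  pile <- anns[[1]]$mask
  for (i in 2:5) {
    inter <- sum(anns[[i]]$mask & pile)   # direct pixel enumeration
    expect_gte(inter, 1)
    expect_gte(sum(jaw_region(anns[[i]]$mask) & pile), 20)
  }
  s0 <- make_scene(scene_config(canvas_size = c(96, 128), n_fences = 4,
                                n_heads = 4, seed = 9),
                   feeding = rep(FALSE, 4))
  for (i in 2:5) {
    expect_equal(sum(s0$truth$annotations[[i]]$mask &
                       s0$truth$annotations[[1]]$mask), 0)
  }
})

test_that("every annotation box is the tight box of its mask and heads sit in one fence", {
  s <- make_scene(small_cfg(n_heads = 4, n_fences = 4, seed = 13))
  for (a in s$truth$annotations) expect_equal(a$bbox, mask_bbox(a$mask))
  layout <- s$truth$fence_layout
  for (i in seq_along(s$truth$head_fences)) {
    hm <- s$truth$annotations[[i + 1]]$mask
    inside <- vapply(layout$ids, function(f)
      sum(hm & feedscan:::fence_region_mask(layout, f)), numeric(1))
    expect_equal(sum(inside > 0), 1)   # fully within exactly one strip
    expect_equal(which(inside > 0), s$truth$head_fences[i])
  }
})

test_that("geometrically impossible configs are rejected", {
  expect_error(make_scene(scene_config(canvas_size = c(64, 64), n_fences = 10,
                                       n_heads = 10, seed = 1)),
               "cannot fit")
  expect_error(scene_config(n_heads = 5, n_fences = 4), "n_heads")
  expect_error(scene_config(pile_band = c(0.9, 0.5, 3)), "top < bottom")
  expect_error(scene_config(canvas_size = c(32, 128)), ">= 64")
})

test_that("clip ground-truth feeding time follows the schedule arithmetic", {
  cfg <- scene_config(canvas_size = c(64, 64), n_fences = 1, n_heads = 1,
                      seed = 4)
  r <- make_feeding_clip(cfg, n_frames = 600, fps = 20,
                         schedule = list("1" = rbind(c(0, 600))))
  expect_equal(unname(r$truth$feeding_time_s), 30)
  expect_length(r$clip$frames, 600)

  r0 <- make_feeding_clip(cfg, n_frames = 20, fps = 20, schedule = list())
  expect_false(any(r0$truth$feeding_state))
  expect_equal(unname(r0$truth$feeding_time_s), 0)
})

test_that("per-fence clip times match a brute-force frame recount", {
  cfg <- scene_config(canvas_size = c(96, 128), n_fences = 3, n_heads = 2,
                      seed = 8)
  sched <- list("1" = rbind(c(0, 7), c(12, 18)), "3" = rbind(c(5, 25)))
  r <- make_feeding_clip(cfg, n_frames = 30, fps = 10, schedule = sched)
  # brute-force: recount scheduled frames per fence
  for (f in 1:3) {
    n_frames <- 0
    for (t in 0:29) {
      iv <- sched[[as.character(f)]]
      if (!is.null(iv)) {
        for (k in seq_len(nrow(iv))) {
          if (t >= iv[k, 1] && t < iv[k, 2]) n_frames <- n_frames + 1
        }
      }
    }
    expect_equal(unname(r$truth$feeding_time_s[f]), n_frames / 10)
  }
  # schedule fidelity: jaw-pile intersection frame by frame equals schedule
  for (t in seq_len(30)) {
    anns <- r$truth$frame_annotations[[t]]
    pile <- anns[[1]]$mask
    for (i in seq_along(r$truth$head_fences)) {
      f <- r$truth$head_fences[i]
      touching <- sum(anns[[i + 1]]$mask & pile) > 0
      expect_identical(touching, unname(r$truth$feeding_state[t, f]))
    }
  }
})

test_that("overlapping or out-of-range schedules are rejected", {
  cfg <- scene_config(canvas_size = c(64, 64), n_fences = 2, seed = 1)
  expect_error(make_feeding_clip(cfg, 10, 10,
                                 schedule = list("1" = rbind(c(0, 5), c(3, 8)))),
               "overlapping")
  expect_error(make_feeding_clip(cfg, 10, 10,
                                 schedule = list("1" = rbind(c(5, 12)))),
               "half-open")
})

test_that("unperturbed detection sets achieve AP 1 and emptied sets AP 0", {
  s <- make_scene(small_cfg(n_heads = 3, seed = 3))
  perfect <- make_detection_set(s$truth, seed = 1)
  expect_equal(average_precision(perfect, s$truth$annotations, 0.5, "box"), 1)
  expect_equal(average_precision(perfect, s$truth$annotations, 0.99, "mask"), 1)
  none <- make_detection_set(s$truth, n_misses = 4, seed = 1)
  expect_length(none, 0)
  expect_equal(average_precision(none, s$truth$annotations, 0.5, "box"), 0)
})

test_that("detection-set perturbations are seed-deterministic", {
  s <- make_scene(small_cfg(n_heads = 2, seed = 3))
  d1 <- make_detection_set(s$truth, jitter_px = 2, n_false_positives = 3,
                           n_misses = 1, seed = 42)
  d2 <- make_detection_set(s$truth, jitter_px = 2, n_false_positives = 3,
                           n_misses = 1, seed = 42)
  expect_identical(d1, d2)
  expect_length(d1, 2 + 3)   # 2 kept after one miss + 3 false positives
})

test_that("scenes and clips round-trip through the PNG writers", {
  dir <- withr::local_tempdir()
  s <- make_scene(small_cfg(seed = 2))
  write_scene(s, dir)
  expect_true(file.exists(file.path(dir, "scene.png")))
  idx <- read_annotations(file.path(dir, "annotations.json"))
  expect_length(idx$records[[1]]$annotations, length(s$truth$annotations))

  r <- make_feeding_clip(scene_config(canvas_size = c(64, 64), n_fences = 1,
                                      n_heads = 1, seed = 1), 3, 10,
                         schedule = list("1" = rbind(c(0, 2))))
  write_clip(r, file.path(dir, "clip"))
  back <- read_clip(file.path(dir, "clip"))
  expect_length(back$frames, 3)
  expect_equal(back$fps, 10)
  expect_identical(back$frames[[2]], r$clip$frames[[2]])
})
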