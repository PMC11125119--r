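test_that("heads are assigned to the majority fence", {
  layout <- fence_layout(4, 100, 60)
  m <- matrix(FALSE, 60, 100); m[10:20, 30:45] <- TRUE  # inside fence 2 (x 25-50)
  expect_equal(assign_fence(instance_annotation("head", m), layout), 2)

  straddle <- matrix(FALSE, 60, 100); straddle[10:20, 44:53] <- TRUE
  # x 43..53: 7 columns in fence 2 (x<50), 3 in fence 3 -> majority fence 2
  expect_equal(assign_fence(instance_annotation("head", straddle), layout), 2)
  counts <- vapply(1:4, function(f)
    sum(straddle & feedscan:::fence_region_mask(layout, f)), numeric(1))
  expect_equal(which.max(counts), 2)   # pixel-count oracle

  outside <- matrix(FALSE, 60, 100); outside[1:5, 1:5] <- TRUE
  small_layout <- structure(list(ids = 1:2,
                                 regions = cbind(c(40, 70), 0, c(60, 90), 60),
                                 width = 100, height = 60),
                            class = "fence_layout")
  expect_true(is.na(assign_fence(instance_annotation("head", outside),
                                 small_layout)))
  expect_error(assign_fence(list(mask = matrix(FALSE, 2, 2)), layout), "empty")
})

test_that("jaw_region keeps the lowest fraction of the head box", {
  m <- matrix(FALSE, 40, 20); m[6:35, 4:12] <- TRUE   # 30 rows tall
  expect_identical(jaw_region(m, 1), m)
  j <- jaw_region(m, 1 / 3)
  expect_equal(sort(unique(which(j, arr.ind = TRUE)[, 1])), 26:35)  # bottom 10 rows
  expect_true(all(j[!m] == FALSE))

  set.seed(4)
  blob <- matrix(runif(40 * 20) > 0.6, 40, 20)
  blob[1, ] <- TRUE  # ensure non-empty with known top
  jb <- jaw_region(blob, 0.4)
  bb <- mask_bbox(blob)
  cut <- bb[4] - 0.4 * (bb[4] - bb[2])
  manual <- blob
  for (r in seq_len(40)) if ((r - 1) < cut - 1e-9) manual[r, ] <- FALSE
  expect_identical(jb, manual)                       # row-filter recount
  # nesting: f1 <= f2 implies jaw(f1) subset of jaw(f2)
  expect_true(all(!(jaw_region(blob, 0.2) & !jaw_region(blob, 0.5))))
  expect_error(jaw_region(matrix(FALSE, 3, 3)), "empty")
})

test_that("frame feeding state follows the contact definition", {
  layout <- fence_layout(2, 80, 60)
  head <- matrix(FALSE, 60, 80); head[10:40, 10:30] <- TRUE
  pile_touch <- matrix(FALSE, 60, 80); pile_touch[35:55, 1:80] <- TRUE
  pile_clear <- matrix(FALSE, 60, 80); pile_clear[50:59, 1:80] <- TRUE
  dets_touch <- list(instance_annotation("head", head, score = 0.9),
                     instance_annotation("feed trough", pile_touch, score = 0.9))
  st <- frame_feeding_state(dets_touch, layout, min_contact_px = 20)
  expect_equal(unname(st), c(TRUE, FALSE))
  # jaw rows are 31..40 -> overlap rows 35..40, far more than 50 px
  expect_gte(sum(jaw_region(head) & pile_touch), 50)

  dets_clear <- list(instance_annotation("head", head, score = 0.9),
                     instance_annotation("feed trough", pile_clear, score = 0.9))
  expect_false(any(frame_feeding_state(dets_clear, layout)))
  # no pile detected at all -> all fences false
  expect_false(any(frame_feeding_state(dets_touch[1], layout)))
  # below the score floor the head is ignored
  low <- list(instance_annotation("head", head, score = 0.1),
              dets_touch[[2]])
  expect_false(any(frame_feeding_state(low, layout, score_floor = 0.3)))
  # threshold boundary: tau above the true overlap turns the state off
  ov <- sum(jaw_region(head) & pile_touch)
  expect_false(any(frame_feeding_state(dets_touch, layout,
                                       min_contact_px = ov + 1)))
})

test_that("timelines accumulate flags to seconds with stride scaling", {
  flags <- matrix(FALSE, 600, 2, dimnames = list(NULL, 1:2))
  flags[, 1] <- TRUE
  tl <- accumulate_timeline(flags, fps = 20, stride = 1)
  expect_equal(unname(tl$feeding_time_s), c(30, 0))
  tl5 <- accumulate_timeline(matrix(rep(c(TRUE, FALSE), c(120, 30)), ncol = 1,
                                    dimnames = list(NULL, "1")),
                             fps = 20, stride = 5)
  expect_equal(unname(tl5$feeding_time_s), 30)
  expect_error(accumulate_timeline(flags, fps = 0), "fps")
  # monotonicity: adding a true flag never decreases feeding time
  flags2 <- flags; flags2[1, 2] <- TRUE
  tl2 <- accumulate_timeline(flags2, fps = 20)
  expect_true(all(tl2$feeding_time_s >= tl$feeding_time_s))
})

test_that("mae matches hand-computed values and basic properties", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(2, 4), c(1, 6)), 1.5)
  expect_equal(mae(c(1, -2), c(-1, 2)), mae(c(-1, 2), c(1, -2)))
  expect_error(mae(1:3, 1:2), "equal length")
  expect_error(mae(numeric(0), numeric(0)), "at least one")
})

test_that("perfect masks recover scheduled feeding times exactly at stride 1", {
  for (seed in c(1, 2)) {
    cfg <- scene_config(canvas_size = c(96, 128), n_fences = 3, n_heads = 3,
                        seed = seed)
    sched <- list("1" = rbind(c(0, 4)), "3" = rbind(c(2, 9)))
    r <- make_feeding_clip(cfg, n_frames = 10, fps = 5, schedule = sched)
    states <- lapply(r$truth$frame_annotations, frame_feeding_state,
                     layout = r$truth$fence_layout)
    tl <- accumulate_timeline(states, fps = 5, stride = 1)
    expect_identical(unname(tl$feeding_time_s), unname(r$truth$feeding_time_s))
  }
})
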