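toy_index <- function(n_images = 2, seed = 1) {
  scenes <- lapply(seq_len(n_images), function(i)
    make_scene(scene_config(canvas_size = c(96, 128), n_fences = 3,
                            n_heads = 2, seed = seed + i)))
  dataset_index(lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    list(image = sprintf("scene_%03d.png", i), height = 96L, width = 128L,
         annotations = s$truth$annotations)
  }))
}

test_that("annotation JSON round-trips the data model exactly", {
  idx <- toy_index(2)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(idx, path)
  back <- read_annotations(path)
  expect_length(back$records, 2)
  for (i in 1:2) {
    a0 <- idx$records[[i]]$annotations
    a1 <- back$records[[i]]$annotations
    expect_length(a1, length(a0))
    for (j in seq_along(a0)) {
      expect_identical(a1[[j]]$mask, a0[[j]]$mask)
      expect_equal(a1[[j]]$bbox, a0[[j]]$bbox)
      expect_identical(a1[[j]]$category, a0[[j]]$category)
    }
  }
  # second round trip is the identity on the serialized form
  path2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("unknown categories and malformed polygons are rejected by name", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(images = list(list(id = 1, file_name = "x.png",
                                 height = 10, width = 10)),
              categories = list(list(id = 1, name = "cow")),
              annotations = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_annotations(path), "cow")

  doc$categories <- list(list(id = 1, name = "head"))
  doc$annotations <- list(list(id = 1, image_id = 1, category_id = 1,
                               bbox = c(0, 0, 2, 2),
                               segmentation = list(list(0, 0, 2, 0))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_annotations(path), "polygon")
})

test_that("polygon rasterization agrees with a point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(31)
  for (rep in 1:5) {
    # star-convex random polygon around (10, 8)
    ang <- sort(runif(7, 0, 2 * pi))
    rad <- runif(7, 3, 7)
    xs <- 10 + rad * cos(ang); ys <- 8 + rad * sin(ang)
    poly <- as.vector(rbind(xs, ys))
    m <- rasterize_polygon(poly, 16, 20)
    centers <- expand.grid(x = seq_len(20) - 0.5, y = seq_len(16) - 0.5)
    inside <- mgcv::in.out(cbind(c(xs, xs[1]), c(ys, ys[1])),
                           as.matrix(centers))
    oracle <- matrix(FALSE, 16, 20)
    oracle[cbind(ceiling(centers$y), ceiling(centers$x))] <- inside
    expect_identical(m, oracle)
  }
})

test_that("RLE encoding round-trips and matches polygon rasterization", {
  poly <- c(2, 1, 9, 1, 9, 6, 2, 6)          # axis-aligned rectangle
  m <- rasterize_polygon(poly, 8, 12)
  expect_equal(sum(m), 7 * 5)
  expect_identical(rle_decode(rle_encode(m)), m)
  set.seed(5)
  rnd <- matrix(runif(60) > 0.5, 6, 10)
  expect_identical(rle_decode(rle_encode(rnd)), rnd)
})

test_that("split sizes follow the floor rule with remainder to train", {
  idx1000 <- dataset_index(lapply(1:1000, function(i)
    list(image = paste0(i, ".png"), height = 8L, width = 8L,
         annotations = list())))
  sp <- split_dataset(idx1000, c(8, 1, 1), seed = 3)
  expect_equal(vapply(sp, function(s) length(s$records), integer(1)),
               c(train = 800L, val = 100L, test = 100L))

  idx10 <- dataset_index(idx1000$records[1:10])
  expect_equal(vapply(split_dataset(idx10, c(8, 1, 1), 1),
                      function(s) length(s$records), integer(1)),
               c(train = 8L, val = 1L, test = 1L))
  idx11 <- dataset_index(idx1000$records[1:11])
  expect_equal(vapply(split_dataset(idx11, c(8, 1, 1), 1),
                      function(s) length(s$records), integer(1)),
               c(train = 9L, val = 1L, test = 1L))
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  idx <- toy_index(2)
  idx <- dataset_index(rep(idx$records, 10))  # 20 records
  for (i in seq_along(idx$records)) idx$records[[i]]$image <- paste0("im", i)
  s1 <- split_dataset(idx, c(8, 1, 1), seed = 9)
  s2 <- split_dataset(idx, c(8, 1, 1), seed = 9)
  expect_identical(s1, s2)
  names1 <- lapply(s1, function(s) vapply(s$records, `[[`, "", "image"))
  expect_length(unlist(names1), 20)
  expect_false(any(duplicated(unlist(names1))))
  expect_error(split_dataset(dataset_index(list()), c(8, 1, 1), 1), "empty")
  expect_error(split_dataset(idx, c(8, -1, 1), 1), "positive")
})

test_that("centred identity mosaic tiles four uniform images", {
  cols <- list(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255), c(255, 255, 0))
  inputs <- lapply(cols, function(cc) {
    img <- array(0, dim = c(40, 40, 3))
    for (k in 1:3) img[, , k] <- cc[k]
    list(image = img, annotations = list())
  })
  out <- mosaic_augment(inputs, out_size = c(64, 100), seed = 1,
                        scale_range = c(1, 1), translate_range = 0,
                        center = c(0.5, 0.5))
  expect_equal(dim(out$image), c(64, 100, 3))
  # top-left quadrant of the crop comes from tile 1, right of column 64 from 2
  expect_true(all(out$image[1:64, 1:64, 1] == 255 & out$image[1:64, 1:64, 2] == 0))
  expect_true(all(out$image[1:64, 65:100, 2] == 255))
})

test_that("mosaic drops annotations clipped away and keeps boxes tight", {
  s <- make_scene(scene_config(canvas_size = c(96, 128), n_fences = 2,
                               n_heads = 1, seed = 6))
  one <- list(image = s$image, annotations = s$truth$annotations)
  inputs <- list(one, one, one, one)
  n_in <- length(one$annotations) * 4
  for (seed in c(2, 3, 7)) {
    out <- mosaic_augment(inputs, out_size = c(64, 100), seed = seed)
    expect_lte(length(out$annotations), n_in)
    for (a in out$annotations) {
      expect_equal(a$bbox, mask_bbox(a$mask))   # rasterization oracle
      expect_true(a$category %in% feedscan_categories())
    }
  }
  # an aggressive shift pushes tiles off-canvas: annotations must drop
  out <- mosaic_augment(inputs, out_size = c(32, 50), seed = 1,
                        scale_range = c(1, 1), translate_range = 0,
                        center = c(0.95, 0.95))
  expect_lt(length(out$annotations), n_in)
  expect_error(mosaic_augment(inputs[1:3], c(64, 100)), "four")
})

test_that("horizontal flip is an involution preserving masks and areas", {
  s <- make_scene(scene_config(canvas_size = c(96, 128), n_fences = 3,
                               n_heads = 2, seed = 14))
  f1 <- hflip_augment(s$image, s$truth$annotations)
  f2 <- hflip_augment(f1$image, f1$annotations)
  expect_identical(f2$image, s$image)
  for (j in seq_along(s$truth$annotations)) {
    expect_identical(f2$annotations[[j]]$mask, s$truth$annotations[[j]]$mask)
    expect_equal(sum(f1$annotations[[j]]$mask),
                 sum(s$truth$annotations[[j]]$mask))
    # boxes remap x -> W - x
    b0 <- s$truth$annotations[[j]]$bbox
    b1 <- f1$annotations[[j]]$bbox
    expect_equal(b1[c(1, 3)], c(128 - b0[3], 128 - b0[1]))
  }
  # centred symmetric mask is unchanged
  m <- matrix(FALSE, 8, 8); m[3:5, 3:6] <- TRUE
  ann <- instance_annotation("head", m)
  fl <- hflip_augment(array(0, c(8, 8, 3)), list(ann))
  expect_identical(fl$annotations[[1]]$mask, m)
})
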