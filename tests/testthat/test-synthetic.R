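small_cfg <- function() {
  synth_config(image_size = 128, ear_count_range = c(20, 70),
               ear_length_range = c(8, 18), ear_width_range = c(3, 6))
}

test_that("scenes respect the configured ear-count range and bounds", {
  cfg <- small_cfg()
  for (seed in 1:5) {
    sc <- sample_scene(cfg, seed)
    expect_gte(nrow(sc$boxes), 20)
    expect_lte(nrow(sc$boxes), 70)
    expect_true(all(sc$boxes[, 1] >= 0 & sc$boxes[, 2] >= 0 &
                      sc$boxes[, 3] <= 128 & sc$boxes[, 4] <= 128))
    expect_true(all((sc$boxes[, 3] - sc$boxes[, 1]) > 0 &
                      (sc$boxes[, 4] - sc$boxes[, 2]) > 0))
    expect_identical(dim(sc$image), c(128L, 128L, 3L))
    expect_true(all(sc$image >= 0 & sc$image <= 255))
  }
})

test_that("generation is a pure function of (cfg, seed)", {
  cfg <- small_cfg()
  a <- sample_scene(cfg, 77)
  b <- sample_scene(cfg, 77)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  c <- sample_scene(cfg, 78)
  expect_false(identical(a$image, c$image))
})

test_that("boxes cover the rendered ear pixels", {
  cfg <- small_cfg()
  sc <- sample_scene(cfg, 3)
  covered <- matrix(FALSE, 128, 128)
  for (i in seq_len(nrow(sc$boxes))) {
    b <- sc$boxes[i, ]
    rows <- max(1, floor(b[2]) + 1):min(128, ceiling(b[4]))
    cols <- max(1, floor(b[1]) + 1):min(128, ceiling(b[3]))
    covered[rows, cols] <- TRUE
  }
  ear_pixels <- sc$ear_map > 0
  expect_gte(sum(covered & ear_pixels) / sum(ear_pixels), 0.95)
})

test_that("mean box count matches the uniform 20-70 draw", {
  cfg <- synth_config(image_size = 64, ear_count_range = c(20, 70),
                      ear_length_range = c(4, 8), ear_width_range = c(2, 3),
                      overlap_allowance = 1)
  counts <- vapply(1:200, function(s) nrow(sample_scene(cfg, s)$boxes), 0L)
  expect_gte(mean(counts), 42)
  expect_lte(mean(counts), 48)
})

test_that("make_dataset writes images, labels and a consistent manifest", {
  dir <- file.path(tempdir(), "synthset")
  unlink(dir, recursive = TRUE)
  cfg <- small_cfg()
  man <- make_dataset(cfg, 10, seed = 5, out_dir = dir)
  expect_identical(nrow(man), 10L)
  expect_length(list.files(file.path(dir, "images"), "\\.png$"), 10L)
  expect_length(list.files(file.path(dir, "labels"), "\\.txt$"), 10L)
  expect_identical(sum(man$split == "train"), 8L)
  expect_identical(sum(man$split == "val"), 2L)
  expect_identical(anyDuplicated(man$image_id), 0L)
  # CSV round trip reproduces in-memory boxes exactly
  ann <- read_gwhd_csv(file.path(dir, "annotations.csv"))
  for (i in 1:10) {
    sc <- sample_scene(cfg, 5 + i)
    got <- ann[[sprintf("synth_%05d", i)]]$boxes
    expect_equal(unname(got), unname(sc$boxes), tolerance = 1e-12)
    # YOLO labels agree within the text format's quantization
    yb <- read_yolo_labels(file.path(dir, "labels",
                                     sprintf("synth_%05d.txt", i)), 128, 128)
    expect_equal(unname(yb), unname(sc$boxes), tolerance = 1e-3)
  }
  # PNG round trip
  img <- png::readPNG(man$file[1])
  sc1 <- sample_scene(cfg, 6)
  expect_equal(img[, , 1:3] * 255, sc1$image, ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("mirroring is an involution on images and boxes", {
  sc <- sample_scene(small_cfg(), 9)
  once <- augment(sc, "mirror", seed = 1)
  twice <- augment(once, "mirror", seed = 1)
  expect_identical(twice$image, sc$image)
  expect_equal(twice$boxes, sc$boxes, tolerance = 1e-12, ignore_attr = TRUE)
  # mirrored x-coordinates follow x -> W - x
  expect_equal(once$boxes[, 1], 128 - sc$boxes[, 3], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero rotation is the identity; 90-degree rotation fixes a centered square", {
  sc <- sample_scene(small_cfg(), 10)
  rot0 <- augment(sc, "rotate", seed = 1, rotate_range = c(0, 0))
  expect_identical(rot0$image, sc$image)
  expect_equal(rot0$boxes, sc$boxes, tolerance = 1e-12, ignore_attr = TRUE)
  # a square box centered on a square image is invariant under 90 degrees
  sq <- structure(list(image = sc$image,
                       boxes = matrix(c(44, 44, 84, 84), 1,
                                      dimnames = list(NULL, c("x1", "y1",
                                                              "x2", "y2"))),
                       seed = 1), class = "scene")
  rot90 <- augment(sq, "rotate", seed = 1, rotate_range = c(90, 90))
  expect_equal(unname(rot90$boxes), matrix(c(44, 44, 84, 84), 1),
               tolerance = 1e-9)
})

test_that("saturation changes pixels but never boxes", {
  sc <- sample_scene(small_cfg(), 11)
  out <- augment(sc, "saturation", seed = 2, saturation_range = c(0.5, 0.5))
  expect_equal(out$boxes, sc$boxes, ignore_attr = TRUE)
  expect_false(identical(out$image, sc$image))
  expect_error(augment(sc, "sharpen", seed = 1), "unknown augmentation")
})

test_that("scaling remaps coordinates by the drawn factor", {
  sc <- sample_scene(small_cfg(), 12)
  out <- augment(sc, "scale", seed = 3, scale_range = c(0.5, 0.5))
  expect_identical(dim(out$image), dim(sc$image))
  kept <- out$boxes
  expect_true(all(kept[, 3] <= 64 + 1e-9)) # everything shrank into one corner
})

test_that("mosaic composes quadrants and only ever loses boxes", {
  cfg <- small_cfg()
  scenes <- lapply(1:4, function(i) sample_scene(cfg, 20 + i))
  mz <- mosaic(scenes, seed = 4, center = c(64, 64))
  expect_identical(dim(mz$image), dim(scenes[[1]]$image))
  expect_lte(nrow(mz$boxes), sum(vapply(scenes, function(s) nrow(s$boxes), 0L)))
  expect_true(all(mz$boxes[, 1] >= 0 & mz$boxes[, 3] <= 128 &
                    mz$boxes[, 2] >= 0 & mz$boxes[, 4] <= 128))
  # with the center at the exact middle, each quadrant is a verbatim crop
  # of its source scene
  set.seed(4) # reproduce the sampled crop offsets
  offs <- list()
  for (q in 1:4) {
    offs[[q]] <- c(sample.int(128 - 64 + 1, 1) - 1,
                   sample.int(128 - 64 + 1, 1) - 1)
  }
  expect_identical(mz$image[1:64, 1:64, ],
                   scenes[[1]]$image[offs[[1]][2] + (1:64),
                                     offs[[1]][1] + (1:64), ])
  expect_error(mosaic(scenes[c(1, 1, 2, 3)][1:3], seed = 1), "length")
  bad <- scenes
  bad[[2]] <- sample_scene(synth_config(image_size = 64,
                                        ear_length_range = c(4, 8),
                                        ear_width_range = c(2, 3)), 1)
  expect_error(mosaic(bad, seed = 1), "identical size")
})
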