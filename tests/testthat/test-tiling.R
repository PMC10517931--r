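test_that("tile grids use floor division and drop partial border tiles", {
  cfg <- tiling_config(tile_size_px = 100, model_input_px = 20,
                       background_mean_threshold = 210)
  g <- tile_image(matrix(100, 200, 300), cfg)
  expect_equal(c(g$n_rows, g$n_cols), c(2, 3))
  expect_length(g$patches, 6)

  g1 <- tile_image(matrix(100, 199, 199), tiling_config(100, 20))
  expect_equal(c(g1$n_rows, g1$n_cols), c(1, 1))

  # exhaustive over complete tiles: one more row/col would overflow
  expect_true(g$n_rows * 100 <= 200 && (g$n_rows + 1) * 100 > 200)
  expect_true(g$n_cols * 100 <= 300 && (g$n_cols + 1) * 100 > 300)

  expect_error(tile_image(matrix(100, 99, 300), cfg), "too small")
})

test_that("a single source tile downscales to the configured input size", {
  g <- tile_image(matrix(150, 1000, 1000), tiling_config(1000, 112))
  expect_equal(c(g$n_rows, g$n_cols), c(1, 1))
  expect_equal(dim(g$patches[[1]]), c(112, 112))
  expect_equal(mean(g$patches[[1]]), 150)  # area interpolation preserves mean
})

test_that("background rule is strictly greater than the threshold", {
  cfg <- tiling_config(10, 5)
  img <- rbind(cbind(matrix(255, 10, 10), matrix(100, 10, 10)),
               cbind(matrix(210, 10, 10), matrix(211, 10, 10)))
  g <- tile_image(img, cfg)
  expect_equal(g$background_mask,
               matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
})

test_that("background flags match a brute-force per-tile mean on random images", {
  cfg <- tiling_config(8, 4, background_mean_threshold = 128)
  set.seed(42)
  for (i in 1:100) {
    nr <- sample(2:4, 1) * 8
    nc <- sample(2:4, 1) * 8
    img <- matrix(runif(nr * nc, 0, 255), nr, nc)
    g <- tile_image(img, cfg)
    for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
      m <- mean(img[((r - 1) * 8 + 1):(r * 8), ((c - 1) * 8 + 1):(c * 8)])
      expect_identical(g$background_mask[r, c], m > 128)
    }
  }
})

test_that("ROI extraction grids each ROI independently and keeps its label", {
  cfg <- tiling_config(100, 20)
  images <- list(img1 = matrix(120, 1000, 2000))
  ann <- data.frame(image = "img1", x0 = 0, y0 = 0, x1 = 2000, y1 = 1000,
                    label = "ccRCC")
  ts <- extract_training_tiles(images, ann, cfg)
  expect_equal(length(ts$patches), 10 * 20)
  expect_true(all(ts$info$label == "ccRCC"))
  expect_true(all(ts$info$image == "img1"))

  # fiber keeps its terminal label (collapsed to NT only at root training)
  ann2 <- data.frame(image = "img1", x0 = 0, y0 = 0, x1 = 200, y1 = 100,
                     label = "fiber")
  ts2 <- extract_training_tiles(images, ann2, cfg)
  expect_true(all(ts2$info$label == "fiber"))

  # undersized ROI emits nothing, with a warning
  ann3 <- data.frame(image = "img1", x0 = 0, y0 = 0, x1 = 99, y1 = 99,
                     label = "ccRCC")
  expect_warning(ts3 <- extract_training_tiles(images, ann3, cfg),
                 "smaller than one tile")
  expect_length(ts3$patches, 0)

  expect_error(
    extract_training_tiles(images, data.frame(image = "img1", x0 = 0, y0 = 0,
                                              x1 = 100, y1 = 100,
                                              label = "stroma"), cfg),
    "stroma")
})

test_that("ROI tiles never cross the ROI boundary and are ROI-anchored", {
  cfg <- tiling_config(10, 5)
  set.seed(7)
  img <- matrix(runif(200 * 200, 0, 200), 200, 200)
  ann <- data.frame(image = "a", x0 = 13, y0 = 27, x1 = 58, y1 = 91,
                    label = "papRCC")
  ts <- extract_training_tiles(list(a = img), ann, cfg)
  # 45 x 64 px ROI at tile 10 -> 4 cols x 6 rows
  expect_equal(nrow(ts$info), 24)
  expect_true(all(ann$x0 + ts$info$col * 10 <= ann$x1))
  expect_true(all(ann$y0 + ts$info$row * 10 <= ann$y1))
})

test_that("patient split partitions patients, never tiles", {
  cfg <- tiling_config(10, 5)
  images <- lapply(1:8, function(i) matrix(i * 10, 20, 20))
  names(images) <- paste0("img", 1:8)
  ann <- data.frame(image = names(images), x0 = 0, y0 = 0, x1 = 20, y1 = 20,
                    label = "ccRCC")
  owners <- stats::setNames(paste0("pat", 1:8), names(images))
  ts <- extract_training_tiles(images, ann, cfg, image_patients = owners)

  sp <- split_by_patient(ts, fraction = 0.75, seed = 3)
  expect_equal(length(unique(sp$train$info$patient_id)), 6)
  expect_equal(length(unique(sp$validation$info$patient_id)), 2)

  # reproducible, and disjoint for every seed
  sp2 <- split_by_patient(ts, fraction = 0.75, seed = 3)
  expect_identical(sp$train$info, sp2$train$info)
  for (s in 1:20) {
    spk <- split_by_patient(ts, fraction = 0.5, seed = s)
    expect_length(intersect(spk$train$info$patient_id,
                            spk$validation$info$patient_id), 0)
  }

  one <- extract_training_tiles(images[1], ann[1, ], cfg)
  expect_error(split_by_patient(one, 0.75, 1), "at least 2 patients")
})
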