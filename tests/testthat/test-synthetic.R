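test_that("class textures are seed-deterministic and collapse at zero separability", {
  a <- class_texture("ccRCC", seed = 42)
  b <- class_texture("ccRCC", seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, class_texture("ccRCC", seed = 43)))

  # delta_within = 0: the within-pair siblings share one distribution
  for (s in 1:5) {
    expect_identical(class_texture("chrRCC", delta_within = 0, seed = s),
                     class_texture("ONCO", delta_within = 0, seed = s))
    expect_identical(class_texture("ccRCC", delta_within = 0, seed = s),
                     class_texture("papRCC", delta_within = 0, seed = s))
  }
  expect_true(all(a >= 0 & a <= 255))
})

test_that("cohort generation is reproducible and splits patients 60/40", {
  cfg <- cohort_config(n_per_subtype = 5, seed = 31)
  co <- generate_cohort(cfg)
  expect_length(co$train, 12)
  expect_length(co$test, 8)

  co2 <- generate_cohort(cfg)
  expect_identical(co$train[[1]]$images, co2$train[[1]]$images)
  expect_identical(vapply(co$test, `[[`, "", "patient_id"),
                   vapply(co2$test, `[[`, "", "patient_id"))

  # no patient in both splits; each subtype represented on both sides
  tr <- vapply(co$train, `[[`, "", "patient_id")
  te <- vapply(co$test, `[[`, "", "patient_id")
  expect_length(intersect(tr, te), 0)
  expect_setequal(unique(vapply(co$test, `[[`, "", "subtype")), RCC_SUBTYPES)
})

test_that("ground-truth masks partition every image", {
  fx <- fx_small()
  for (p in fx$cohort$train[1:3]) {
    for (m in p$cell_masks) {
      expect_true(all(m %in% c("background", "tumor", "not_tumor")))
      # margin ring is background, interior is tissue
      expect_true(all(m[1, ] == "background"))
      expect_true(all(m[, 1] == "background"))
      expect_true(all(m[2:(nrow(m) - 1), 2:(ncol(m) - 1)] != "background"))
    }
  }
})

test_that("emitted annotations agree with the underlying textures", {
  fx <- fx_small()
  p <- fx$cohort$train[[1]]
  ts <- extract_training_tiles(p$images, p$annotations, fx$tiling)
  expect_gt(nrow(ts$info), 0)

  # annotations are cell-aligned, so each tumor-ROI tile maps back to an
  # absolute cell that must be marked tumor in the ground-truth mask
  tum <- p$annotations[p$annotations$label %in% RCC_SUBTYPES, , drop = FALSE]
  for (i in seq_len(nrow(tum))) {
    a <- tum[i, ]
    sub <- ts$info[ts$info$image == a$image & ts$info$label == a$label, ]
    cell_r <- a$y0 / fx$config$tile_size_px + sub$row
    cell_c <- a$x0 / fx$config$tile_size_px + sub$col
    expect_true(all(p$cell_masks[[a$image]][cbind(cell_r, cell_c)] == "tumor"))
  }

  # tile counts per label match the mask cell counts (nothing lost to the
  # background rule inside tissue, nothing gained from the margin)
  n_tumor_cells <- sum(vapply(p$cell_masks, function(m) sum(m == "tumor"), 0L))
  expect_equal(sum(ts$info$label %in% RCC_SUBTYPES), n_tumor_cells)
  expect_true(all(ts$info$label %in% c(RCC_SUBTYPES, NOT_TUMOR_TISSUES)))
})

test_that("separability is monotone in the within-pair distance", {
  accs <- vapply(c(0.05, 0.4, 1.0), function(dw) {
    mk <- function(label, seeds) lapply(seeds, function(s)
      class_texture(label, delta_within = dw, seed = s, size = 32))
    train <- c(mk("chrRCC", 1:50), mk("ONCO", 201:250))
    test <- c(mk("chrRCC", 401:440), mk("ONCO", 601:640))
    bb <- texture_backbone()
    clf <- bb$fit(bb$featurize(train), rep(0:1, each = 50), seed = 3)
    mean(predict(clf, bb$featurize(test)) == rep(0:1, each = 40))
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))  # non-decreasing up to sampling noise
  expect_gte(accs[3], 0.95)
})

test_that("mixed-morphology patients carry both super-group textures", {
  fx <- fx_small()
  p <- make_ambiguous_patient(fx$config, balance = 0.5, seed = 9)
  n_tumor <- sum(unlist(lapply(p$cell_masks, function(m) m == "tumor")))
  expect_gt(n_tumor, 0)
  # both super-group textures present: mean intensities of tumor tiles are
  # bimodal around the two pair levels (125 and 175 at full separation)
  tiles <- extract_training_tiles(p$images, p$annotations, fx$tiling,
                                  image_patients = NULL)
  tumor_means <- vapply(
    tiles$patches[tiles$info$label %in% RCC_SUBTYPES], mean, numeric(1))
  expect_gt(sum(tumor_means < 150), 2)
  expect_gt(sum(tumor_means > 150), 2)
  # at balance 1 the patient is single-texture ccRCC
  p1 <- make_ambiguous_patient(fx$config, balance = 1, seed = 9)
  expect_identical(p1$subtype, "ccRCC")
})
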