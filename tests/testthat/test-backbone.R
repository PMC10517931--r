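test_that("random under-sampling equalizes class counts deterministically", {
  labels <- c(rep("A", 1000), rep("B", 300))
  tiles <- as.list(seq_along(labels))
  bal <- balance_by_undersampling(tiles, labels, seed = 9)
  expect_equal(unname(table(bal$labels)), array(c(300L, 300L)))

  bal2 <- balance_by_undersampling(tiles, labels, seed = 9)
  expect_identical(bal$idx, bal2$idx)
  bal3 <- balance_by_undersampling(tiles, labels, seed = 10)
  expect_false(identical(sort(bal$idx), sort(bal3$idx)))

  even <- balance_by_undersampling(as.list(1:100),
                                   rep(c("A", "B"), 50), seed = 1)
  expect_setequal(unlist(even$tiles), 1:100)

  expect_error(balance_by_undersampling(tiles, rep("A", 1300), 1),
               "two label values")
})

test_that("the texture backbone separates well-separated texture classes", {
  mk <- function(label, seeds) lapply(seeds, function(s)
    class_texture(label, delta_between = 1, delta_within = 1, seed = s,
                  size = 32, contrast_jitter_sd = 0.1))
  train <- c(mk("chrRCC", 1:40), mk("ONCO", 101:140))
  test <- c(mk("chrRCC", 501:530), mk("ONCO", 601:630))
  bb <- texture_backbone()
  clf <- bb$fit(bb$featurize(train), rep(0:1, each = 40), seed = 4)
  acc <- mean(predict(clf, bb$featurize(test)) == rep(0:1, each = 30))
  expect_gte(acc, 0.95)
})

test_that("classifiers honor the score/label contract", {
  set.seed(3)
  patches <- lapply(1:30, function(i)
    matrix(runif(64, 0, 255) + (i > 15) * 150, 8, 8))
  bb <- texture_backbone()
  clf <- bb$fit(bb$featurize(patches), rep(0:1, each = 15), seed = 1)
  s <- predict_score(clf, patches)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(predict(clf, patches), as.integer(s >= 0.5))
})

test_that("degenerate constant input falls back to a majority scorer", {
  patches <- lapply(1:10, function(i) matrix(128, 8, 8))
  bb <- texture_backbone()
  expect_warning(clf <- bb$fit(bb$featurize(patches), rep(0:1, each = 5),
                               seed = 1),
                 "constant")
  s <- predict_score(clf, patches)
  expect_true(all(s >= 0 & s <= 1))
  expect_length(s, 10)
})

test_that("stage fitting filters labels and uses the fixed encodings", {
  fx <- fx_small()
  spec <- tree_spec("expert")

  # root groups not-tumor tissues as class 0, every subtype as class 1
  root <- fit_stage(fx$tiles, spec$root, training_config(seed = 2))
  expect_setequal(root$stage$g0, c("fiber", "necrosis", "normal_parenchyma"))
  expect_setequal(root$stage$g1, RCC_SUBTYPES)

  # leaf2 training excludes tiles from outside its pair
  leaf2 <- fit_stage(fx$tiles, spec$leaf2, training_config(seed = 2))
  n_pair <- sum(fx$tiles$info$label %in% c("ccRCC", "papRCC"))
  expect_lte(leaf2$n_trained, n_pair)

  # same seed and data give identical predictions on a probe set
  probe <- tile_features(fx$tiles$patches[1:25])
  leaf2b <- fit_stage(fx$tiles, spec$leaf2, training_config(seed = 2))
  expect_identical(predict(leaf2, probe), predict(leaf2b, probe))

  # missing group fails loudly
  only_cc <- fx$tiles
  keep <- which(only_cc$info$label %in% c("ccRCC", "fiber"))
  only_cc$patches <- only_cc$patches[keep]
  only_cc$info <- only_cc$info[keep, ]
  expect_error(fit_stage(only_cc, spec$leaf2, training_config(seed = 2)),
               "leaf2")
})
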