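test_that("tree topologies match the published layouts", {
  ex <- tree_spec("expert")
  expect_setequal(ex$node$g0, c("chrRCC", "ONCO"))
  expect_setequal(ex$node$g1, c("ccRCC", "papRCC"))
  expect_setequal(c(ex$leaf1$g0, ex$leaf1$g1), c("chrRCC", "ONCO"))
  expect_setequal(c(ex$leaf2$g0, ex$leaf2$g1), c("ccRCC", "papRCC"))

  n1 <- tree_spec("naive1")
  expect_setequal(n1$node$g0, c("papRCC", "ONCO"))
  expect_setequal(n1$node$g1, c("chrRCC", "ccRCC"))
  n2 <- tree_spec("naive2")
  expect_setequal(n2$node$g0, c("papRCC", "chrRCC"))
  expect_setequal(n2$node$g1, c("ONCO", "ccRCC"))

  # every topology: root separates NT from all subtypes; the node groups
  # partition the subtypes; each leaf covers one node group
  for (nm in c("expert", "naive1", "naive2")) {
    sp <- tree_spec(nm)
    expect_setequal(sp$root$g1, RCC_SUBTYPES)
    expect_setequal(c(sp$node$g0, sp$node$g1), RCC_SUBTYPES)
    expect_setequal(c(sp$leaf1$g0, sp$leaf1$g1), sp$node$g0)
    expect_setequal(c(sp$leaf2$g0, sp$leaf2$g1), sp$node$g1)
  }
  expect_error(tree_spec("naive3"))
})

test_that("tree fitting needs every stage populated and is deterministic", {
  fx <- fx_small()
  no_onco <- fx$tiles
  keep <- which(no_onco$info$label != "ONCO")
  no_onco$patches <- no_onco$patches[keep]
  no_onco$info <- no_onco$info[keep, ]
  expect_error(fit_tree(tree_spec("expert"), no_onco), "leaf1")

  t1 <- fit_tree(tree_spec("expert"), fx$tiles, training_config(seed = 5))
  probe_grid <- patient_grids(fx$cohort$test[[1]], fx$tiling)[[1]]
  m1 <- classify_grid(t1, probe_grid)
  m2 <- classify_grid(fx$tree, probe_grid)
  expect_identical(m1$stage3, m2$stage3)
})

test_that("staged maps conserve label flow and never resurrect NT tiles", {
  fx <- fx_small()
  for (p in fx$cohort$test[1:4]) {
    for (g in patient_grids(p, fx$tiling)) {
      for (refine in c(TRUE, FALSE)) {
        maps <- classify_grid(fx$tree, g, refine = refine)
        n_cells <- g$n_rows * g$n_cols
        expect_equal(sum(maps$stage1 == "BACKGROUND"), sum(g$background_mask))
        expect_equal(sum(maps$stage1 %in% c("BACKGROUND", "NT", "T")), n_cells)
        n_bg <- sum(maps$stage3 == "BACKGROUND")
        n_nt <- sum(maps$stage3 == "NT")
        n_tumor <- sum(maps$stage3 %in% RCC_SUBTYPES)
        expect_equal(n_bg + n_nt + n_tumor, n_cells)
        # NT at stage 1 stays NT in the final map
        expect_true(all(maps$stage3[maps$stage1 == "NT"] == "NT"))
        expect_true(all(maps$stage2[maps$stage1 == "NT"] == "NT"))
      }
    }
  }
})

test_that("with refine off and a trusted node, leaves stay in their super-group", {
  fx <- fx_small()
  sp <- fx$tree$spec
  g0 <- sp$node$g0; g1 <- sp$node$g1
  for (p in fx$cohort$test[1:4]) {
    for (g in patient_grids(p, fx$tiling)) {
      maps <- classify_grid(fx$tree, g, refine = FALSE)
      lab0 <- paste(g0, collapse = "+")
      expect_true(all(maps$stage3[maps$stage2 == lab0] %in% g0))
      lab1 <- paste(g1, collapse = "+")
      expect_true(all(maps$stage3[maps$stage2 == lab1] %in% g1))
    }
  }
})

test_that("node imbalance follows |n1 - n0| / (n1 + n0)", {
  mk <- function(n0, n1) {
    m <- matrix("NT", 15, 15)
    if (n0 > 0) m[seq_len(n0)] <- "chrRCC+ONCO"
    if (n1 > 0) m[15 * 15 - seq_len(n1) + 1] <- "ccRCC+papRCC"
    m
  }
  expect_equal(node_imbalance(mk(50, 50)), 0)
  expect_equal(node_imbalance(mk(35, 65)), 0.30)
  expect_equal(node_imbalance(mk(0, 120)), 1)
  expect_true(is.na(node_imbalance(mk(0, 0))))
  # pooling across a patient's images
  expect_equal(node_imbalance(list(mk(10, 0), mk(25, 65))), 0.30)
})

test_that("the 30% rule fires strictly below threshold and modes behave", {
  fx <- fx_small()
  grids <- patient_grids(fx$cohort$test[[1]], fx$tiling)

  # mode=node_pruned must never consult the node classifier
  broken <- fx$tree
  broken$stages$node$model <- NULL
  res <- suppressWarnings(
    classify_patient(broken, grids, pruning_policy("node_pruned")))
  expect_true(res$diagnostics$pruned)
  expect_null(res$maps[[1]]$stage2)
  expect_error(suppressWarnings(
    classify_patient(broken, grids, pruning_policy("unpruned"))))

  # boundary: imbalance exactly at threshold trusts the node
  pol <- pruning_policy("selective", imbalance_threshold = 0.30)
  expect_false(0.30 < pol$imbalance_threshold)
})

test_that("a tumor-free patient yields NO_TUMOR, never a subtype", {
  fx <- fx_small()
  p <- synth_patient("Pfree", "ccRCC", fx$config, seed = 77,
                     tumor_fraction = 0)
  res <- classify_patient(fx$tree, patient_grids(p, fx$tiling))
  expect_identical(res$subtype, "NO_TUMOR")
  expect_true(is.na(res$diagnostics$imbalance))
})
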