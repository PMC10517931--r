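# Shared fixtures, built once per test run and memoised. Two scales are
# used: a small cohort (4 patients per subtype) for unit/structural tests
# and the standard 40-patient cohort for the end-to-end property tests.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fx_small <- function() {
  fx_memo("small", function() {
    config <- cohort_config(n_per_subtype = 4, seed = 11)
    cohort <- generate_cohort(config)
    tiles <- cohort_tiles(cohort)
    tiling <- tiling_config(config$tile_size_px, config$model_input_px)
    tree <- fit_tree(tree_spec("expert"), tiles, training_config(seed = 5))
    list(config = config, cohort = cohort, tiles = tiles, tiling = tiling,
         tree = tree)
  })
}

# the standard evaluation cohort: 10 patients per subtype, 60/40 split
fx_std <- function() {
  fx_memo("std", function() {
    config <- cohort_config(n_per_subtype = 10, seed = 2024)
    cohort <- generate_cohort(config)
    tiles <- cohort_tiles(cohort)
    tiling <- tiling_config(config$tile_size_px, config$model_input_px)
    tcfg <- training_config(seed = 7)
    trees <- list(expert = fit_tree(tree_spec("expert"), tiles, tcfg),
                  naive1 = fit_tree(tree_spec("naive1"), tiles, tcfg),
                  naive2 = fit_tree(tree_spec("naive2"), tiles, tcfg))
    baseline <- fit_flat_baseline(tiles, tcfg)
    truth <- stats::setNames(vapply(cohort$test, `[[`, "", "subtype"),
                             vapply(cohort$test, `[[`, "", "patient_id"))
    grids <- lapply(cohort$test, patient_grids, config = tiling)
    names(grids) <- names(truth)
    list(config = config, cohort = cohort, tiles = tiles, tiling = tiling,
         trees = trees, baseline = baseline, truth = truth, grids = grids)
  })
}

# memoised patient-level evaluation of one arm on the standard cohort
fx_std_eval <- function(arm, refine = TRUE, mode = "selective") {
  key <- paste("eval", arm, refine, mode, sep = "_")
  fx_memo(key, function() {
    fx <- fx_std()
    preds <- vapply(names(fx$truth), function(pid) {
      if (arm == "baseline")
        suppressWarnings(
          classify_patient_flat(fx$baseline, fx$grids[[pid]], refine)$subtype)
      else
        suppressWarnings(
          classify_patient(fx$trees[[arm]], fx$grids[[pid]],
                           pruning_policy(mode), refine)$subtype)
    }, "")
    evaluate_cohort(preds, fx$truth)
  })
}

# full per-patient classification results (maps + diagnostics) for one arm
fx_std_results <- function(arm = "expert", refine = TRUE,
                           mode = "selective") {
  key <- paste("res", arm, refine, mode, sep = "_")
  fx_memo(key, function() {
    fx <- fx_std()
    lapply(names(fx$truth), function(pid)
      suppressWarnings(
        classify_patient(fx$trees[[arm]], fx$grids[[pid]],
                         pruning_policy(mode), refine)))
  })
}
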