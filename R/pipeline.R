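#' Write a synthetic cohort to a directory
#'
#' Materializes a cohort as `images/` (PNG), `annotations.json` (training
#' patients' rectangle ROIs), `manifest.csv` (patient_id, image, split,
#' true_subtype) and `cohort_config.yaml`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent; parent must exist).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dirname(dir)))
    stop("parent directory does not exist: ", dirname(dir))
  dir.create(dir, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  manifest <- NULL
  ann <- NULL
  for (split in c("train", "test")) {
    for (p in cohort[[split]]) {
      for (img_id in names(p$images)) {
        .write_png(p$images[[img_id]],
                   file.path(dir, "images", paste0(img_id, ".png")))
        manifest <- rbind(manifest, data.frame(
          patient_id = p$patient_id, image = paste0(img_id, ".png"),
          split = split, true_subtype = p$subtype, stringsAsFactors = FALSE))
      }
      if (split == "train") ann <- rbind(ann, p$annotations)
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()]: loads manifest, images, annotations and the
#' tiling-relevant configuration.
#'
#' @param dir Cohort directory.
#' @return List with `manifest`, `images` (named list of matrices, names
#'   without extension), `annotations`, `config` (a [cohort_config()]).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "cohort_config.yaml"))
  config <- do.call(cohort_config, cfg)
  images <- list()
  for (f in manifest$image)
    images[[tools::file_path_sans_ext(f)]] <-
      read_raster(file.path(dir, "images", f))
  ann_path <- file.path(dir, "annotations.json")
  annotations <- if (file.exists(ann_path))
    jsonlite::fromJSON(ann_path) else NULL
  list(manifest = manifest, images = images, annotations = annotations,
       config = config)
}

#' Generate a cohort directory (CLI verb)
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_per_subtype Patients per subtype.
#' @param ... Further [cohort_config()] fields.
#' @return The output directory, invisibly.
#' @export
cmd_generate <- function(out_dir, seed = 1L, n_per_subtype = 10L, ...) {
  cohort <- generate_cohort(cohort_config(n_per_subtype = n_per_subtype,
                                          seed = seed, ...))
  write_cohort(cohort, out_dir)
}

#' @noRd
.cohort_tileset_from_dir <- function(dir) {
  co <- read_cohort(dir)
  if (is.null(co$annotations)) stop("cohort at ", dir, " has no annotations")
  train_imgs <- tools::file_path_sans_ext(
    co$manifest$image[co$manifest$split == "train"])
  owners <- stats::setNames(co$manifest$patient_id,
                            tools::file_path_sans_ext(co$manifest$image))
  extract_training_tiles(co$images[train_imgs], co$annotations,
                         .tiling_from_cohort(co$config),
                         image_patients = owners[train_imgs])
}

#' Train a model bundle from a cohort directory (CLI verb)
#'
#' Trains either a decision tree (`tree` of `"expert"`, `"naive1"`,
#' `"naive2"`) or the flat five-class baseline (`tree = "flat"`) on the
#' cohort's training annotations, logging per-stage class counts, and
#' persists the fitted model with its tiling configuration and a version
#' tag as an RDS bundle.
#'
#' @param cohort_dir Cohort directory written by [cmd_generate()].
#' @param model_path Output path for the model bundle (.rds).
#' @param tree Topology name or `"flat"`.
#' @param seed Training seed.
#' @return `model_path`, invisibly.
#' @export
cmd_train <- function(cohort_dir, model_path, tree = "expert", seed = 1L) {
  tiles <- .cohort_tileset_from_dir(cohort_dir)
  co_cfg <- read_cohort(cohort_dir)$config
  tcfg <- training_config(seed = seed)
  model <- if (tree == "flat") fit_flat_baseline(tiles, tcfg)
           else fit_tree(tree_spec(tree), tiles, tcfg)
  bundle <- list(version = "1", kind = if (tree == "flat") "flat" else "tree",
                 name = tree, model = model,
                 tiling = .tiling_from_cohort(co_cfg))
  saveRDS(bundle, model_path)
  invisible(model_path)
}

#' Predict a cohort's test patients (CLI verb)
#'
#' Writes `predictions.csv` (one row per test patient), per-image staged
#' tile-label CSVs under `maps/`, and per-image heatmap overlays under
#' `heatmaps/`.
#'
#' @param model_path Bundle written by [cmd_train()].
#' @param cohort_dir Cohort directory.
#' @param out_dir Output directory.
#' @param policy A [pruning_policy()] (trees only).
#' @param refine Apply Refine?
#' @return The predictions data frame, invisibly.
#' @export
cmd_predict <- function(model_path, cohort_dir, out_dir,
                        policy = pruning_policy(), refine = TRUE) {
  bundle <- readRDS(model_path)
  co <- read_cohort(cohort_dir)
  dir.create(out_dir, showWarnings = FALSE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "heatmaps"), showWarnings = FALSE)
  test <- co$manifest[co$manifest$split == "test", , drop = FALSE]
  preds <- NULL
  for (pid in unique(test$patient_id)) {
    img_ids <- tools::file_path_sans_ext(test$image[test$patient_id == pid])
    grids <- lapply(co$images[img_ids], tile_image, config = bundle$tiling)
    if (bundle$kind == "tree") {
      res <- classify_patient(bundle$model, grids, policy, refine)
      final_maps <- lapply(res$maps, `[[`, "stage3")
      staged <- res$maps
    } else {
      res <- classify_patient_flat(bundle$model, grids, refine)
      final_maps <- res$maps
      staged <- lapply(res$maps, function(m)
        structure(list(stage1 = NULL, stage2 = NULL, stage3 = m),
                  class = "staged_maps"))
      names(staged) <- img_ids
    }
    for (i in seq_along(img_ids)) {
      .write_staged_csv(staged[[i]], img_ids[i],
                        file.path(out_dir, "maps",
                                  paste0(img_ids[i], "_labels.csv")))
      ov <- render_heatmap(co$images[[img_ids[i]]], final_maps[[i]],
                           bundle$tiling$tile_size_px)
      png::writePNG(ov, file.path(out_dir, "heatmaps",
                                  paste0(img_ids[i], "_heatmap.png")))
    }
    truth <- unique(test$true_subtype[test$patient_id == pid])
    preds <- rbind(preds, data.frame(
      patient_id = pid, truth = truth, predicted = res$subtype,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(preds)
}

#' @noRd
.write_staged_csv <- function(staged, image_id, path) {
  rows <- NULL
  for (st in c("stage1", "stage2", "stage3")) {
    m <- staged[[st]]
    if (is.null(m)) next
    rows <- rbind(rows, data.frame(
      image = image_id, row = as.vector(row(m)) - 1L,
      col = as.vector(col(m)) - 1L, stage = st,
      label = as.vector(m), stringsAsFactors = FALSE))
  }
  utils::write.csv(rows[order(rows$stage, rows$row, rows$col), ],
                   path, row.names = FALSE)
}

#' Render a tumor heatmap overlay
#'
#' Alpha-blends the final tile-label map over the source image: healthy
#' (not-tumor) tissue in green, tumor in red with one shade per subtype,
#' background fully transparent.
#'
#' @param image Source raster (matrix or RGB array, 0-255).
#' @param map Final label matrix (subtypes, `"NT"`, `"BACKGROUND"`).
#' @param tile_size_px Tile size used when the map was produced.
#' @return `h x w x 4` RGBA array in `[0, 1]` (overlay only).
#' @export
render_heatmap <- function(image, map, tile_size_px) {
  palette <- list(
    NT = c(0.0, 0.75, 0.0), ccRCC = c(1.0, 0.0, 0.0),
    papRCC = c(1.0, 0.35, 0.0), chrRCC = c(0.8, 0.0, 0.3),
    ONCO = c(0.55, 0.0, 0.0))
  gray <- .to_gray(image) / 255
  h <- nrow(map) * tile_size_px
  w <- ncol(map) * tile_size_px
  out <- array(0, c(h, w, 4))
  for (k in 1:3) out[, , k] <- gray[1:h, 1:w]
  alpha <- 0.45
  for (r in seq_len(nrow(map))) for (c in seq_len(ncol(map))) {
    lab <- map[r, c]
    if (!lab %in% names(palette)) next
    rs <- ((r - 1) * tile_size_px + 1):(r * tile_size_px)
    cs <- ((c - 1) * tile_size_px + 1):(c * tile_size_px)
    for (k in 1:3)
      out[rs, cs, k] <- (1 - alpha) * out[rs, cs, k] + alpha * palette[[lab]][k]
    out[rs, cs, 4] <- 1
  }
  out
}

#' Train and evaluate all ablation arms (CLI verb)
#'
#' On one cohort and seed set, trains the expert and both naive trees plus
#' the flat baseline, and evaluates every arm with and without Refine at
#' patient level; the expert tree is additionally evaluated under the
#' always-trust (`unpruned`) and never-trust (`node_pruned`) node policies.
#'
#' @param cohort A `synthetic_cohort` (or a cohort directory path).
#' @param seed Training seed.
#' @param out_csv Optional path for the resulting table.
#' @return Data frame with one row per (arm, refine) cell: balanced
#'   accuracy, recall spread and MCC.
#' @export
run_ablation <- function(cohort, seed = 1L, out_csv = NULL) {
  if (is.character(cohort))
    stop("pass a synthetic_cohort; for directories use cmd_ablate()")
  tiles <- cohort_tiles(cohort)
  tcfg <- training_config(seed = seed)
  tiling <- .tiling_from_cohort(cohort$config)
  trees <- list(ExpertDT = fit_tree(tree_spec("expert"), tiles, tcfg),
                NaiveDT1 = fit_tree(tree_spec("naive1"), tiles, tcfg),
                NaiveDT2 = fit_tree(tree_spec("naive2"), tiles, tcfg))
  baseline <- fit_flat_baseline(tiles, tcfg)
  truth <- stats::setNames(vapply(cohort$test, `[[`, "", "subtype"),
                           vapply(cohort$test, `[[`, "", "patient_id"))
  grids <- lapply(cohort$test, patient_grids, config = tiling)
  names(grids) <- names(truth)
  eval_arm <- function(predict_one) {
    preds <- vapply(names(truth), function(pid) predict_one(grids[[pid]]), "")
    rep <- evaluate_cohort(preds, truth)
    data.frame(balanced_accuracy = rep$balanced_accuracy,
               recall_std = rep$recall_std, mcc = rep$mcc)
  }
  rows <- NULL
  specs <- list(
    ExpertDT   = list(kind = "tree", tree = "ExpertDT", mode = "selective"),
    NaiveDT1   = list(kind = "tree", tree = "NaiveDT1", mode = "selective"),
    NaiveDT2   = list(kind = "tree", tree = "NaiveDT2", mode = "selective"),
    Baseline   = list(kind = "flat"),
    Unpruned   = list(kind = "tree", tree = "ExpertDT", mode = "unpruned"),
    `Node-pruned` = list(kind = "tree", tree = "ExpertDT", mode = "node_pruned"))
  for (arm in names(specs)) {
    sp <- specs[[arm]]
    for (refine in c(TRUE, FALSE)) {
      cell <- eval_arm(function(g) {
        if (sp$kind == "flat") classify_patient_flat(baseline, g, refine)$subtype
        else classify_patient(trees[[sp$tree]], g,
                              pruning_policy(sp$mode), refine)$subtype
      })
      rows <- rbind(rows, cbind(
        data.frame(arm = arm, refine = ifelse(refine, "with", "without"),
                   stringsAsFactors = FALSE), cell))
    }
  }
  if (!is.null(out_csv))
    utils::write.csv(rows, out_csv, row.names = FALSE)
  rows
}

#' Run the ablation from a cohort directory (CLI verb)
#'
#' @param cohort_dir Cohort directory.
#' @param out_csv Output CSV path.
#' @param seed Training seed.
#' @return The ablation table, invisibly.
#' @export
cmd_ablate <- function(cohort_dir, out_csv, seed = 1L) {
  co <- read_cohort(cohort_dir)
  # rebuild an in-memory cohort view from the directory
  split_pat <- function(split) {
    m <- co$manifest[co$manifest$split == split, , drop = FALSE]
    lapply(unique(m$patient_id), function(pid) {
      img_ids <- tools::file_path_sans_ext(m$image[m$patient_id == pid])
      ann <- co$annotations[co$annotations$image %in% img_ids, , drop = FALSE]
      structure(list(patient_id = pid,
                     subtype = unique(m$true_subtype[m$patient_id == pid]),
                     images = co$images[img_ids], annotations = ann),
                class = "synthetic_patient")
    })
  }
  cohort <- structure(list(train = split_pat("train"),
                           test = split_pat("test"), config = co$config),
                      class = "synthetic_cohort")
  invisible(run_ablation(cohort, seed = seed, out_csv = out_csv))
}
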