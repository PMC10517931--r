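#' Declarative tree topology
#'
#' Returns the published topology of the three-stage decision tree. The
#' expert layout encodes pathologist knowledge: the node separates the
#' super-labels (ccRCC, papRCC) vs (chrRCC, ONCO), deferring the two
#' classically difficult differential diagnoses (chromophobe vs oncocytoma,
#' clear cell vs papillary) to dedicated leaves. The naive layouts are the
#' two other possible node partitions, kept as controls:
#' \describe{
#'   \item{expert}{node (chrRCC, ONCO) | (ccRCC, papRCC); leaf1 chrRCC vs
#'     ONCO; leaf2 ccRCC vs papRCC}
#'   \item{naive1}{node (papRCC, ONCO) | (chrRCC, ccRCC); leaf1 papRCC vs
#'     ONCO; leaf2 chrRCC vs ccRCC}
#'   \item{naive2}{node (papRCC, chrRCC) | (ONCO, ccRCC); leaf1 papRCC vs
#'     chrRCC; leaf2 ONCO vs ccRCC}
#' }
#' All trees share the same root (tumor vs not-tumor); leaf1 always covers
#' the node's group 0, leaf2 its group 1.
#'
#' @param name One of `"expert"`, `"naive1"`, `"naive2"`.
#' @return A `tree_spec`: list of four stage definitions plus the name.
#' @export
tree_spec <- function(name = c("expert", "naive1", "naive2")) {
  name <- match.arg(name)
  root <- .stage_def("root", g0 = NOT_TUMOR_TISSUES, g1 = RCC_SUBTYPES)
  pairs <- switch(name,
    expert = list(n0 = c("chrRCC", "ONCO"),  n1 = c("ccRCC", "papRCC")),
    naive1 = list(n0 = c("papRCC", "ONCO"),  n1 = c("chrRCC", "ccRCC")),
    naive2 = list(n0 = c("papRCC", "chrRCC"), n1 = c("ONCO", "ccRCC")))
  structure(
    list(name = name,
         root = root,
         node = .stage_def("node", g0 = pairs$n0, g1 = pairs$n1),
         leaf1 = .stage_def("leaf1", g0 = pairs$n0[1], g1 = pairs$n0[2]),
         leaf2 = .stage_def("leaf2", g0 = pairs$n1[1], g1 = pairs$n1[2])),
    class = "tree_spec")
}

#' Node-pruning policy
#'
#' Controls the per-patient reliability rule for the node stage. Under the
#' `selective` mode the node's classification is not trusted when the
#' relative difference between the patient's two super-label tile counts,
#' `|n1 - n0| / (n1 + n0)`, falls strictly below `imbalance_threshold`
#' (default 0.30): the node is pruned and tumor tiles are routed from the
#' root directly to both leaves. `unpruned` always trusts the node;
#' `node_pruned` never consults it. A threshold of 0 never fires; a
#' threshold of 1 (or more) means "never trust the node" and reproduces
#' `node_pruned`.
#'
#' @param mode One of `"selective"`, `"unpruned"`, `"node_pruned"`.
#' @param imbalance_threshold Fraction in `[0, 1]`.
#' @return A `pruning_policy`.
#' @export
pruning_policy <- function(mode = c("selective", "unpruned", "node_pruned"),
                           imbalance_threshold = 0.30) {
  mode <- match.arg(mode)
  if (imbalance_threshold < 0 || imbalance_threshold > 1)
    stop("imbalance_threshold must lie in [0, 1]")
  structure(list(mode = mode, imbalance_threshold = imbalance_threshold),
            class = "pruning_policy")
}

#' Fit the full decision tree
#'
#' Fits the four binary stage classifiers independently via [fit_stage()],
#' each on the reduced tile subset showing only its two label groups,
#' balanced by random under-sampling. Features are extracted once and shared
#' across stages. Per-stage seeds are derived deterministically from
#' `config$seed`.
#'
#' @param spec A [tree_spec()].
#' @param tiles Training `tile_set` covering all four subtypes and at least
#'   one not-tumor tissue.
#' @param config A [training_config()].
#' @param backbone A backbone factory such as [texture_backbone()].
#' @return A `fitted_tree`: the spec, four `stage_classifier`s and the tile
#'   geometry they expect.
#' @export
fit_tree <- function(spec, tiles, config = training_config(),
                     backbone = texture_backbone()) {
  stopifnot(inherits(spec, "tree_spec"), inherits(tiles, "tile_set"))
  x <- backbone$featurize(tiles$patches)
  stages <- list()
  for (i in seq_along(c("root", "node", "leaf1", "leaf2"))) {
    nm <- c("root", "node", "leaf1", "leaf2")[i]
    cfg <- config
    cfg$seed <- .derive_seed(config$seed, i)
    stages[[nm]] <- fit_stage(tiles, spec[[nm]], cfg, backbone, features = x)
  }
  structure(list(spec = spec, stages = stages, backbone = backbone,
                 model_input_px = tiles$model_input_px),
            class = "fitted_tree")
}

#' @export
print.fitted_tree <- function(x, ...) {
  cat("fitted_tree '", x$spec$name, "' (input ", x$model_input_px, "px)\n",
      sep = "")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]$stage
    cat("  ", nm, ": ", .group_label(s$g0), " vs ", .group_label(s$g1),
        " (", x$stages[[nm]]$n_trained, " balanced tiles)\n", sep = "")
  }
  invisible(x)
}

# ---- staged classification --------------------------------------------------

# Featurize non-background cells of one grid; returns features plus a
# cell -> feature-row lookup matrix.
#' @noRd
.grid_stage_setup <- function(tree, grid) {
  if (grid$model_input_px != tree$model_input_px)
    stop("tile size mismatch: grid patches are ", grid$model_input_px,
         "px but the tree was fitted on ", tree$model_input_px, "px")
  rowmap <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  cells <- which(!grid$background_mask, arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  x <- NULL
  if (nrow(cells) > 0) {
    idx <- .cell_idx(cells[, 1], cells[, 2], grid$n_cols)
    x <- tree$backbone$featurize(grid$patches[idx])
    rowmap[cells] <- seq_len(nrow(cells))
  }
  list(x = x, rowmap = rowmap)
}

#' @noRd
.stage1_root <- function(tree, grid, setup, refine) {
  map1 <- empty_label_map(grid)
  sel <- !is.na(setup$rowmap)
  if (any(sel)) {
    p <- stats::predict(tree$stages$root$model,
                        setup$x[setup$rowmap[sel], , drop = FALSE])
    map1[sel] <- ifelse(p == 1L, "T", "NT")
  }
  if (refine) map1 <- refine_map(map1, domain = c("T", "NT"))
  map1
}

#' @noRd
.stage2_node <- function(tree, map1, setup, refine) {
  g0 <- .group_label(tree$spec$node$g0)
  g1 <- .group_label(tree$spec$node$g1)
  map2 <- map1
  sel <- map1 == "T"
  if (any(sel)) {
    p <- stats::predict(tree$stages$node$model,
                        setup$x[setup$rowmap[sel], , drop = FALSE])
    map2[sel] <- ifelse(p == 1L, g1, g0)
  }
  if (refine) map2 <- refine_map(map2, domain = c(g0, g1))
  map2
}

# leaves downstream of a trusted node
#' @noRd
.stage3_node_route <- function(tree, map2, setup, refine) {
  map3 <- map2
  for (leaf in c("leaf1", "leaf2")) {
    grp <- if (leaf == "leaf1") tree$spec$node$g0 else tree$spec$node$g1
    sel <- map2 == .group_label(grp)
    if (!any(sel)) next
    clf <- tree$stages[[leaf]]
    p <- stats::predict(clf$model, setup$x[setup$rowmap[sel], , drop = FALSE])
    map3[sel] <- ifelse(p == 1L, clf$stage$g1, clf$stage$g0)
  }
  if (refine) map3 <- refine_map(map3, domain = RCC_SUBTYPES)
  map3
}

# root connected directly to both leaves: each tumor tile takes the label of
# the leaf that is more confident (distance of its score from 0.5); ties go
# to leaf1's decision.
#' @noRd
.stage3_pruned_route <- function(tree, map1, setup, refine) {
  map3 <- map1
  sel <- map1 == "T"
  ties <- 0L
  if (any(sel)) {
    x <- setup$x[setup$rowmap[sel], , drop = FALSE]
    l1 <- tree$stages$leaf1; l2 <- tree$stages$leaf2
    s1 <- predict_score(l1$model, x)
    s2 <- predict_score(l2$model, x)
    lab1 <- ifelse(s1 >= 0.5, l1$stage$g1, l1$stage$g0)
    lab2 <- ifelse(s2 >= 0.5, l2$stage$g1, l2$stage$g0)
    c1 <- 2 * abs(s1 - 0.5)
    c2 <- 2 * abs(s2 - 0.5)
    ties <- sum(c1 == c2)
    map3[sel] <- ifelse(c1 >= c2, lab1, lab2)
  }
  if (refine) map3 <- refine_map(map3, domain = RCC_SUBTYPES)
  list(map = map3, ties = ties)
}

#' Route one tile grid through the tree
#'
#' Stage 1: every non-background tile is labelled tumor (T) or not-tumor
#' (NT) by the root. Stage 2: T tiles receive a super-label from the node.
#' Stage 3: each super-labelled tile is resolved to a final subtype by the
#' matching leaf. After each stage the Refine smoothing is applied on that
#' stage's label domain (when `refine = TRUE`). Background cells and tiles
#' labelled NT at stage 1 are never relabelled by later stages. This is the
#' node-trusting route; per-patient pruning lives in [classify_patient()].
#'
#' @param tree A `fitted_tree`.
#' @param grid A `tile_grid` with patches matching the tree's input size.
#' @param refine Apply Refine after each stage?
#' @return A `staged_maps` list with character matrices `stage1`, `stage2`,
#'   `stage3`.
#' @export
classify_grid <- function(tree, grid, refine = TRUE) {
  setup <- .grid_stage_setup(tree, grid)
  map1 <- .stage1_root(tree, grid, setup, refine)
  map2 <- .stage2_node(tree, map1, setup, refine)
  map3 <- .stage3_node_route(tree, map2, setup, refine)
  structure(list(stage1 = map1, stage2 = map2, stage3 = map3),
            class = "staged_maps")
}

#' Super-label tile imbalance of a patient
#'
#' The relative difference `|n1 - n0| / (n1 + n0)` between the number of
#' tiles assigned to each of the node's two super-labels, pooled over all of
#' the patient's stage-2 maps. 0 means a perfectly ambiguous patient, 1 a
#' unanimous one. Returns `NA` (no tumor evidence) when the patient has no
#' tumor tiles.
#'
#' @param stage2_maps A stage-2 label matrix or list of them (one per image).
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
node_imbalance <- function(stage2_maps) {
  if (is.matrix(stage2_maps)) stage2_maps <- list(stage2_maps)
  labs <- unlist(lapply(stage2_maps, as.vector))
  labs <- labs[!labs %in% c(.SENTINELS, "NT", "T")]
  if (length(labs) == 0L) return(NA_real_)
  counts <- table(labs)
  if (length(counts) == 1L) return(1.0)
  abs(counts[[1]] - counts[[2]]) / sum(counts)
}

#' Classify a patient across all of its images
#'
#' Runs every image grid through the tree and aggregates to a single
#' patient-level subtype by majority voting over final tile labels, NT tiles
#' excluded. Under the `selective` policy the node's classification is
#' trusted only when the pooled super-label imbalance ([node_imbalance()])
#' is not below the threshold; otherwise the node is pruned and each tumor
#' tile is scored by both leaves, keeping the more confident leaf decision.
#'
#' @param tree A `fitted_tree`.
#' @param grids List of `tile_grid`s, one per image (names are image ids).
#' @param policy A [pruning_policy()].
#' @param refine Apply Refine after each stage?
#' @return List with `subtype` (one of the four subtypes or `"NO_TUMOR"`),
#'   `maps` (per-image `staged_maps`; `stage2` is `NULL` when the node was
#'   never consulted) and `diagnostics` (`imbalance`, `pruned`, super-label
#'   `counts`, `leaf_ties`).
#' @export
classify_patient <- function(tree, grids, policy = pruning_policy(),
                             refine = TRUE) {
  stopifnot(inherits(tree, "fitted_tree"), length(grids) >= 1L)
  if (inherits(grids, "tile_grid")) grids <- list(grids)
  setups <- lapply(grids, .grid_stage_setup, tree = tree)
  map1s <- mapply(.stage1_root, grid = grids, setup = setups,
                  MoreArgs = list(tree = tree, refine = refine),
                  SIMPLIFY = FALSE)
  imb <- NA_real_
  map2s <- vector("list", length(grids))
  if (policy$mode != "node_pruned") {
    map2s <- mapply(.stage2_node, map1 = map1s, setup = setups,
                    MoreArgs = list(tree = tree, refine = refine),
                    SIMPLIFY = FALSE)
    imb <- node_imbalance(map2s)
  }
  prune <- switch(policy$mode,
    unpruned = FALSE,
    node_pruned = TRUE,
    selective = policy$imbalance_threshold >= 1 ||
      (!is.na(imb) && imb < policy$imbalance_threshold))
  ties <- 0L
  if (prune) {
    st3 <- mapply(.stage3_pruned_route, map1 = map1s, setup = setups,
                  MoreArgs = list(tree = tree, refine = refine),
                  SIMPLIFY = FALSE)
    map3s <- lapply(st3, `[[`, "map")
    ties <- sum(vapply(st3, `[[`, integer(1), "ties"))
    if (ties > 0L)
      warning(ties, " tile(s) with equal leaf confidences; kept leaf1's decision")
  } else {
    map3s <- mapply(.stage3_node_route, map2 = map2s, setup = setups,
                    MoreArgs = list(tree = tree, refine = refine),
                    SIMPLIFY = FALSE)
  }
  final_labels <- unlist(lapply(map3s, as.vector))
  final_labels <- final_labels[!final_labels %in% .SENTINELS]
  subtype <- if (length(final_labels)) patient_vote(final_labels) else "NO_TUMOR"
  counts <- NULL
  if (policy$mode != "node_pruned") {
    labs <- unlist(lapply(map2s, as.vector))
    counts <- table(labs[!labs %in% c(.SENTINELS, "NT")])
  }
  maps <- lapply(seq_along(grids), function(i) {
    structure(list(stage1 = map1s[[i]], stage2 = map2s[[i]],
                   stage3 = map3s[[i]]), class = "staged_maps")
  })
  names(maps) <- names(grids)
  list(subtype = subtype, maps = maps,
       diagnostics = list(imbalance = unname(imb), pruned = prune,
                          counts = counts, leaf_ties = ties))
}
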