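#' Patient-level majority vote
#'
#' The patient's final diagnosis is the plurality subtype among its
#' tumor-predicted tiles; tiles predicted not-tumor are excluded from the
#' vote. When no tumor tile remains the outcome is `"NO_TUMOR"`, kept
#' distinct from every subtype. Exact ties are broken by subtype prevalence
#' order (ccRCC > papRCC > chrRCC > ONCO) with a warning.
#'
#' @param labels Character vector of final tile labels (subtypes and `"NT"`).
#' @return A single subtype, or `"NO_TUMOR"`.
#' @export
patient_vote <- function(labels) {
  if (length(labels) == 0L) stop("patient vote over an empty tile set")
  votes <- labels[labels %in% RCC_SUBTYPES]
  if (length(votes) == 0L) return("NO_TUMOR")
  counts <- vapply(RCC_SUBTYPES, function(s) sum(votes == s), integer(1))
  top <- which(counts == max(counts))
  if (length(top) > 1L)
    warning("patient vote tie between ",
            paste(RCC_SUBTYPES[top], collapse = ", "),
            "; broken by prevalence order")
  RCC_SUBTYPES[top[1L]]
}

#' Balanced accuracy (average accuracy score)
#'
#' Mean of the per-class recalls of a confusion matrix (rows = truth,
#' columns = prediction), with the population standard deviation of the
#' recalls as spread. Robust to class imbalance: every class weighs equally
#' regardless of prevalence.
#'
#' @param cm Square numeric confusion matrix with row/column names aligned.
#' @return List with `value`, `std` and the per-class `recalls`.
#' @export
balanced_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    nm <- if (!is.null(rownames(cm))) rownames(cm)[rs == 0] else which(rs == 0)
    stop("no patients for true class: ", paste(nm, collapse = ", "))
  }
  recalls <- diag(cm) / rs
  mu <- mean(recalls)
  list(value = mu, std = sqrt(mean((recalls - mu)^2)), recalls = recalls)
}

#' Multiclass Matthews correlation coefficient
#'
#' The covariance-form generalization of the MCC to a K-class confusion
#' matrix (rows = truth, columns = prediction):
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the total, and `p`, `t` the column and row sums.
#' Returns 1 for a perfect diagonal, 0 under independence; degenerate
#' matrices (all mass in a single predicted or true class) yield 0 with a
#' warning.
#'
#' @param cm Square numeric confusion matrix.
#' @return Value in `[-1, 1]`.
#' @export
matthews_cc <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  s <- sum(cm)
  cc <- sum(diag(cm))
  p <- colSums(cm)
  t <- rowSums(cm)
  num <- cc * s - sum(p * t)
  d1 <- s^2 - sum(p^2)
  d2 <- s^2 - sum(t^2)
  if (d1 <= 0 || d2 <= 0) {
    warning("degenerate confusion matrix; MCC defined as 0")
    return(0)
  }
  num / sqrt(d1 * d2)
}

#' Evaluate patient-level predictions against ground truth
#'
#' Builds the confusion matrix over the four subtypes, per-class recalls,
#' balanced accuracy with its across-class standard deviation, the
#' multiclass MCC, and the list of misclassified patients. `"NO_TUMOR"`
#' predictions count as misclassifications for every true subtype and are
#' additionally reported separately (as an extra confusion column and an id
#' list).
#'
#' @param predictions Named character vector, patient id -> predicted
#'   subtype (or `"NO_TUMOR"`).
#' @param truth Named character vector, patient id -> true subtype.
#' @return An `evaluation_report` list: `confusion`, `recalls`,
#'   `balanced_accuracy`, `recall_std`, `mcc`, `misclassified`, `no_tumor`.
#' @export
evaluate_cohort <- function(predictions, truth) {
  ids <- names(truth)
  missing <- setdiff(ids, names(predictions))
  extra <- setdiff(names(predictions), ids)
  if (length(missing) || length(extra))
    stop("patient id mismatch; missing: {",
         paste(missing, collapse = ", "), "} unexpected: {",
         paste(extra, collapse = ", "), "}")
  predictions <- predictions[ids]
  bad <- setdiff(unique(truth), RCC_SUBTYPES)
  if (length(bad)) stop("unknown true subtype(s): ", paste(bad, collapse = ", "))
  pred_levels <- c(RCC_SUBTYPES,
                   if (any(predictions == "NO_TUMOR")) "NO_TUMOR")
  cm <- table(factor(truth, levels = RCC_SUBTYPES),
              factor(predictions, levels = pred_levels))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "prediction")
  rs <- rowSums(cm)
  present <- rs > 0
  recalls <- ifelse(present, diag(cm[, RCC_SUBTYPES, drop = FALSE]) / rs, NA)
  names(recalls) <- RCC_SUBTYPES
  mu <- mean(recalls[present])
  std <- sqrt(mean((recalls[present] - mu)^2))
  # square matrix for the MCC: NO_TUMOR enters as an empty true class
  sq <- cm
  if (ncol(cm) > nrow(cm))
    sq <- rbind(cm, NO_TUMOR = 0)
  mcc <- matthews_cc(sq)
  wrong <- ids[predictions != truth]
  structure(
    list(confusion = cm, recalls = recalls, balanced_accuracy = mu,
         recall_std = std, mcc = mcc, misclassified = wrong,
         no_tumor = ids[predictions == "NO_TUMOR"]),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("balanced accuracy %.3f (+/- %.3f), MCC %.3f, %d misclassified\n",
              x$balanced_accuracy, x$recall_std, x$mcc,
              length(x$misclassified)))
  print(x$confusion)
  invisible(x)
}

# ---- flat multiclass baseline ----------------------------------------------

#' Fit the flat (non-hierarchical) baseline
#'
#' The comparison arm: a single five-class tile classifier (four subtypes
#' plus the not-tumor super-class) built as one-vs-rest over the binary
#' backbone contract, each one-vs-rest problem balanced by random
#' under-sampling. Patient aggregation is the same [patient_vote()] used by
#' the tree.
#'
#' @param tiles Training `tile_set` over the seven terminal labels.
#' @param config A [training_config()].
#' @param backbone A backbone factory.
#' @return A `flat_classifier`.
#' @export
fit_flat_baseline <- function(tiles, config = training_config(),
                              backbone = texture_backbone()) {
  stopifnot(inherits(tiles, "tile_set"))
  classes <- c(RCC_SUBTYPES, "NT")
  lab5 <- ifelse(tiles$info$label %in% NOT_TUMOR_TISSUES, "NT",
                 tiles$info$label)
  x <- backbone$featurize(tiles$patches)
  models <- list()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    if (!any(lab5 == cl))
      stop("baseline: no training tiles for class ", cl)
    y <- as.integer(lab5 == cl)
    bal <- balance_by_undersampling(x, y, seed = .derive_seed(config$seed, 10 + i))
    models[[cl]] <- backbone$fit(bal$tiles, bal$labels,
                                 seed = .derive_seed(config$seed, 10 + i))
  }
  structure(list(classes = classes, models = models, backbone = backbone,
                 model_input_px = tiles$model_input_px),
            class = "flat_classifier")
}

#' Classify a tile grid with the flat baseline
#'
#' Per-tile argmax over the five one-vs-rest scores, followed (optionally)
#' by one Refine pass over the full five-label alphabet.
#'
#' @param clf A `flat_classifier`.
#' @param grid A `tile_grid`.
#' @param refine Apply Refine?
#' @return Character label matrix over subtypes, `"NT"` and `"BACKGROUND"`.
#' @export
classify_grid_flat <- function(clf, grid, refine = TRUE) {
  if (grid$model_input_px != clf$model_input_px)
    stop("tile size mismatch between baseline and grid")
  map <- empty_label_map(grid)
  sel <- !grid$background_mask
  if (any(sel)) {
    cells <- which(sel, arr.ind = TRUE)
    cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
    idx <- .cell_idx(cells[, 1], cells[, 2], grid$n_cols)
    x <- clf$backbone$featurize(grid$patches[idx])
    scores <- vapply(clf$classes, function(cl)
      predict_score(clf$models[[cl]], x), numeric(nrow(x)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
    map[cells] <- clf$classes[max.col(scores, ties.method = "first")]
  }
  if (refine) map <- refine_map(map, domain = clf$classes)
  map
}

#' Patient-level prediction with the flat baseline
#'
#' @param clf A `flat_classifier`.
#' @param grids List of `tile_grid`s, one per image.
#' @param refine Apply Refine?
#' @return List with `subtype` and per-image label `maps`.
#' @export
classify_patient_flat <- function(clf, grids, refine = TRUE) {
  if (inherits(grids, "tile_grid")) grids <- list(grids)
  maps <- lapply(grids, classify_grid_flat, clf = clf, refine = refine)
  labels <- unlist(lapply(maps, as.vector))
  labels <- labels[!labels %in% .SENTINELS]
  subtype <- if (length(labels)) patient_vote(labels) else "NO_TUMOR"
  list(subtype = subtype, maps = maps)
}
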