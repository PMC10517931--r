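#' Training configuration for tree stages
#'
#' Advisory knobs shared by all stage classifiers. Iterative backbones honor
#' the epoch/patience/batch fields; the default texture backbone fits in
#' closed form and uses only the seed.
#'
#' @param seed Integer seed controlling under-sampling and any stochastic
#'   fitting step.
#' @param max_epochs Maximum training epochs for iterative backbones.
#' @param patience Early-stopping patience on the training loss, in epochs.
#' @param batch_size Mini-batch size for iterative backbones.
#' @return An object of class `training_config`.
#' @export
training_config <- function(seed = 1L, max_epochs = 150L, patience = 20L,
                            batch_size = 128L) {
  vals <- c(max_epochs = max_epochs, patience = patience,
            batch_size = batch_size)
  if (any(vals < 1)) stop("max_epochs, patience and batch_size must be >= 1")
  structure(list(seed = as.integer(seed), max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size)),
            class = "training_config")
}

#' Balance a two-class tile set by random under-sampling
#'
#' Both classes are reduced to the size of the minority class by uniform
#' random removal; the retained items are returned shuffled. Deterministic
#' under `seed`.
#'
#' @param tiles List of tiles (or any list/matrix indexed along its first
#'   dimension in parallel with `labels`).
#' @param labels Vector with exactly two distinct values.
#' @param seed Integer seed.
#' @return List with balanced `tiles`, `labels`, and the retained `idx`.
#' @export
balance_by_undersampling <- function(tiles, labels, seed = 1L) {
  counts <- table(labels)
  if (length(counts) != 2L)
    stop("expected exactly two label values, got {",
         paste(names(counts), collapse = ", "), "}")
  m <- min(counts)
  idx <- .with_seed(seed, {
    kept <- unlist(lapply(names(counts), function(l) {
      pool <- which(labels == l)
      if (length(pool) > m) sort(sample(pool, m)) else pool
    }))
    sample(kept)
  })
  picked <- if (is.matrix(tiles)) tiles[idx, , drop = FALSE] else tiles[idx]
  list(tiles = picked, labels = labels[idx], idx = idx)
}

# ---- texture features -------------------------------------------------------

#' Texture feature vectors for image patches
#'
#' Deterministic hand-specified per-tile descriptors: intensity moments and
#' quantiles, an 8-bin intensity histogram, first/second-lag gradient
#' magnitudes along both axes (capturing grain size and anisotropy) and a
#' Laplacian high-frequency energy term. These are the inputs of the default
#' backbone.
#'
#' @param patches List of numeric matrices on the 0-255 scale.
#' @return Numeric matrix, one row per patch.
#' @export
tile_features <- function(patches) {
  feat <- function(p) {
    m <- nrow(p); n <- ncol(p)
    v <- as.vector(p)
    q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
    dh1 <- mean(abs(p[, -1, drop = FALSE] - p[, -n, drop = FALSE]))
    dv1 <- mean(abs(p[-1, , drop = FALSE] - p[-m, , drop = FALSE]))
    dh2 <- mean(abs(p[, -(1:2), drop = FALSE] - p[, -((n - 1):n), drop = FALSE]))
    dv2 <- mean(abs(p[-(1:2), , drop = FALSE] - p[-((m - 1):m), , drop = FALSE]))
    core <- p[2:(m - 1), 2:(n - 1), drop = FALSE]
    lap <- mean(abs(4 * core -
                      p[1:(m - 2), 2:(n - 1)] - p[3:m, 2:(n - 1)] -
                      p[2:(m - 1), 1:(n - 2)] - p[2:(m - 1), 3:n]))
    h <- tabulate(pmin(pmax(floor(v / 32) + 1, 1), 8), 8) / length(v)
    c(mean = mean(v), sd = stats::sd(v), q10 = q[1], q50 = q[2], q90 = q[3],
      dh1 = dh1, dv1 = dv1, dh2 = dh2, dv2 = dv2, lap = lap,
      hist = h)
  }
  out <- t(vapply(patches, feat, numeric(18)))
  rownames(out) <- NULL
  out
}

# ---- the binary classifier contract ----------------------------------------

#' Predict a confidence score in \[0, 1\]
#'
#' Generic of the binary-classifier contract: returns, per tile, the
#' confidence that the tile belongs to class 1. Implementations must satisfy
#' `predict(x) == as.integer(predict_score(x) >= 0.5)`.
#'
#' @param object A fitted binary classifier.
#' @param tiles List of patches or a precomputed feature matrix.
#' @param ... Passed to methods.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_score <- function(object, tiles, ...) UseMethod("predict_score")

#' Default texture backbone
#'
#' A CPU-fast, seed-deterministic stand-in for a convolutional backbone:
#' [tile_features()] descriptors feeding a ridge-penalized logistic
#' regression (glmnet, alpha = 0). Satisfies the binary-classifier contract
#' (`fit`, `predict`, [predict_score()]); any backbone honoring the same
#' contract can replace it, the tree logic being classifier-agnostic.
#'
#' @param lambda Ridge penalty used at prediction time.
#' @return A backbone factory: list with `name`, `featurize(patches)` and
#'   `fit(x, y, seed)`.
#' @importFrom glmnet glmnet
#' @export
texture_backbone <- function(lambda = 1e-3) {
  fit <- function(x, y, seed = 1L) {
    if (length(unique(y)) < 2L)
      stop("binary fit needs both classes present")
    keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
    if (!any(keep)) {
      warning("all features constant; falling back to a majority-class scorer")
      return(structure(list(p = mean(y)), class = c("constant_classifier",
                                                    "binary_classifier")))
    }
    model <- .with_seed(seed, glmnet::glmnet(
      x[, keep, drop = FALSE], factor(y, levels = c(0, 1)),
      family = "binomial", alpha = 0,
      lambda = exp(seq(log(10), log(lambda), length.out = 25))))
    structure(list(model = model, keep = keep, lambda = lambda),
              class = c("texture_classifier", "binary_classifier"))
  }
  structure(list(name = "default_texture", featurize = tile_features,
                 fit = fit),
            class = "backbone_factory")
}

#' @noRd
.as_features <- function(tiles) {
  if (is.matrix(tiles)) tiles else tile_features(tiles)
}

#' @rdname predict_score
#' @export
predict_score.texture_classifier <- function(object, tiles, ...) {
  x <- .as_features(tiles)
  as.numeric(stats::predict(object$model, x[, object$keep, drop = FALSE],
                            s = object$lambda, type = "response"))
}

#' @export
predict.texture_classifier <- function(object, newdata, ...) {
  as.integer(predict_score(object, newdata) >= 0.5)
}

#' @rdname predict_score
#' @export
predict_score.constant_classifier <- function(object, tiles, ...) {
  n <- if (is.matrix(tiles)) nrow(tiles) else length(tiles)
  rep(object$p, n)
}

#' @export
predict.constant_classifier <- function(object, newdata, ...) {
  as.integer(predict_score(object, newdata) >= 0.5)
}

# ---- stage fitting ----------------------------------------------------------

#' @noRd
.stage_def <- function(name, g0, g1) {
  structure(list(name = name, g0 = g0, g1 = g1), class = "stage_def")
}

#' @noRd
.group_label <- function(labels) paste(labels, collapse = "+")

#' Fit one binary tree stage
#'
#' Restricts the tile set to the stage's two label groups, collapses the
#' groups to \{0, 1\} under the stage's fixed encoding, balances the classes
#' by random under-sampling and fits the backbone. The fixed encodings are:
#' tumor = 1 at the root; the (ccRCC, papRCC) super-label = 1 at the expert
#' node; and the second-named subtype of each leaf pair = 1 (ONCO at the
#' expert leaf1, papRCC at the expert leaf2).
#'
#' @param tiles A `tile_set`.
#' @param stage A stage definition (list with `name`, `g0`, `g1` label
#'   groups), e.g. one field of a [tree_spec()].
#' @param config A [training_config()].
#' @param backbone A backbone factory such as [texture_backbone()].
#' @param features Optional precomputed feature matrix aligned with `tiles`.
#' @return A `stage_classifier` wrapping the fitted backbone and the stage
#'   groups.
#' @export
fit_stage <- function(tiles, stage, config = training_config(),
                      backbone = texture_backbone(), features = NULL) {
  stopifnot(inherits(tiles, "tile_set"))
  lab <- tiles$info$label
  in0 <- lab %in% stage$g0
  in1 <- lab %in% stage$g1
  if (!any(in0) || !any(in1)) {
    missing <- if (any(in0)) .group_label(stage$g1) else .group_label(stage$g0)
    stop("stage '", stage$name, "': no training tiles for group ", missing)
  }
  keep <- which(in0 | in1)
  y <- as.integer(in1[keep])
  x <- if (is.null(features)) backbone$featurize(tiles$patches[keep])
       else features[keep, , drop = FALSE]
  bal <- balance_by_undersampling(x, y, seed = config$seed)
  model <- backbone$fit(bal$tiles, bal$labels, seed = config$seed)
  structure(list(stage = stage, model = model,
                 n_trained = length(bal$labels)),
            class = "stage_classifier")
}

#' @export
predict.stage_classifier <- function(object, newdata, ...) {
  stats::predict(object$model, newdata)
}

#' @rdname predict_score
#' @export
predict_score.stage_classifier <- function(object, tiles, ...) {
  predict_score(object$model, tiles)
}

# stage predictions as group label strings
#' @noRd
.stage_labels <- function(clf, x) {
  p <- stats::predict(clf$model, x)
  ifelse(p == 1L, .group_label(clf$stage$g1), .group_label(clf$stage$g0))
}
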