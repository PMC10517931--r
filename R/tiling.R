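#' Tiling configuration
#'
#' Geometry and background-removal settings for cutting raster images into
#' square tiles. Defaults follow routine practice for H&E whole-slide
#' analysis: 1000x1000 px source tiles downscaled to 112x112 for the
#' classifier, with tiles whose mean intensity exceeds 210 (near-white,
#' essentially tissue-free) discarded as background.
#'
#' @param tile_size_px Side length of square source tiles, in pixels.
#' @param model_input_px Side length after downscaling, in pixels.
#' @param background_mean_threshold Mean-intensity cutoff in `[0, 255]`; a
#'   tile is background iff its channel-averaged mean at source resolution is
#'   strictly greater than this value.
#' @return An object of class `tiling_config`.
#' @export
tiling_config <- function(tile_size_px = 1000L, model_input_px = 112L,
                          background_mean_threshold = 210) {
  tile_size_px <- as.integer(tile_size_px)
  model_input_px <- as.integer(model_input_px)
  if (model_input_px < 1L || tile_size_px < model_input_px)
    stop("need tile_size_px >= model_input_px >= 1")
  if (background_mean_threshold < 0 || background_mean_threshold > 255)
    stop("background_mean_threshold must lie in [0, 255]")
  structure(
    list(tile_size_px = tile_size_px, model_input_px = model_input_px,
         background_mean_threshold = background_mean_threshold),
    class = "tiling_config")
}

# row-major cell index
#' @noRd
.cell_idx <- function(r, c, n_cols) (r - 1L) * n_cols + c

#' Cut an image into a regular tile grid
#'
#' Tiles the image from its top-left corner into complete
#' `tile_size_px`-square tiles (partial border remainders are dropped), records
#' each tile's source-resolution mean intensity, downscales every tile to
#' `model_input_px` with area (anti-aliased) interpolation, and flags
#' background tiles per [mark_background()]. Color images are collapsed to
#' luminance by plain channel averaging.
#'
#' @param image Numeric matrix or `h x w x channels` array on the 0-255 scale.
#' @param config A [tiling_config()].
#' @return A `tile_grid`: list with `n_rows`, `n_cols`, the per-tile
#'   downscaled `patches` (row-major list of matrices), `tile_means`
#'   (`n_rows x n_cols`), and logical `background_mask`.
#' @export
tile_image <- function(image, config = tiling_config()) {
  gray <- .to_gray(image)
  ts <- config$tile_size_px
  h <- nrow(gray); w <- ncol(gray)
  if (h < ts || w < ts)
    stop("image too small: ", w, "x", h, " px cannot hold one ",
         ts, "x", ts, " tile")
  n_rows <- h %/% ts
  n_cols <- w %/% ts
  patches <- vector("list", n_rows * n_cols)
  tile_means <- matrix(NA_real_, n_rows, n_cols)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      tile <- gray[((r - 1L) * ts + 1L):(r * ts),
                   ((c - 1L) * ts + 1L):(c * ts), drop = FALSE]
      tile_means[r, c] <- mean(tile)
      patches[[.cell_idx(r, c, n_cols)]] <- .resize_area(tile, config$model_input_px)
    }
  }
  grid <- structure(
    list(n_rows = n_rows, n_cols = n_cols,
         tile_size_px = ts, model_input_px = config$model_input_px,
         patches = patches, tile_means = tile_means,
         background_mask = matrix(FALSE, n_rows, n_cols)),
    class = "tile_grid")
  mark_background(grid, config)
}

#' Flag empty background tiles
#'
#' A tile is background iff the mean over all pixel intensities of the
#' source-resolution tile (channel-averaged) is strictly greater than the
#' configured threshold. Background tiles are never sent to a classifier and
#' never vote.
#'
#' @param grid A `tile_grid`.
#' @param config A [tiling_config()].
#' @return The grid with `background_mask` recomputed.
#' @export
mark_background <- function(grid, config = tiling_config()) {
  stopifnot(inherits(grid, "tile_grid"))
  grid$background_mask <- grid$tile_means > config$background_mean_threshold
  grid
}

#' @export
print.tile_grid <- function(x, ...) {
  cat("tile_grid: ", x$n_rows, " x ", x$n_cols, " tiles (",
      x$tile_size_px, "px -> ", x$model_input_px, "px), ",
      sum(x$background_mask), " background\n", sep = "")
  invisible(x)
}

#' @noRd
.empty_tile_set <- function(model_input_px) {
  structure(
    list(patches = list(),
         info = data.frame(patient_id = character(), image = character(),
                           row = integer(), col = integer(),
                           label = character(), stringsAsFactors = FALSE),
         model_input_px = model_input_px),
    class = "tile_set")
}

#' @noRd
.bind_tile_sets <- function(a, b) {
  a$patches <- c(a$patches, b$patches)
  a$info <- rbind(a$info, b$info)
  a
}

#' @noRd
.subset_tile_set <- function(tiles, idx) {
  tiles$patches <- tiles$patches[idx]
  tiles$info <- tiles$info[idx, , drop = FALSE]
  rownames(tiles$info) <- NULL
  tiles
}

#' @export
print.tile_set <- function(x, ...) {
  cat("tile_set:", length(x$patches), "tiles,",
      length(unique(x$info$patient_id)), "patients\n")
  print(table(x$info$label))
  invisible(x)
}

#' Extract labelled training tiles from ROI annotations
#'
#' The training counterpart of whole-image tiling: each rectangular region of
#' interest (ROI), drawn by a pathologist over tissue that is homogeneous in
#' content, is independently cut into a regular grid of complete tiles
#' anchored at the ROI's top-left corner. Every emitted tile carries the
#' ROI's tissue label and its source patient id; tiles falling under the
#' background rule are discarded.
#'
#' @param images Named list of rasters (names are image ids).
#' @param annotations Data frame (or list coercible to one) with columns
#'   `image`, `x0`, `y0`, `x1`, `y1`, `label`. Coordinates are 0-based,
#'   half-open pixel intervals; `x` runs along columns, `y` along rows.
#'   Labels must come from the seven-category alphabet (four subtypes plus
#'   fiber, necrosis, normal_parenchyma).
#' @param config A [tiling_config()].
#' @param image_patients Optional named character vector mapping image id to
#'   patient id; defaults to using the image id as patient id.
#' @return A `tile_set` with `patches` and an `info` data frame
#'   (`patient_id`, `image`, `row`, `col`, `label`).
#' @export
extract_training_tiles <- function(images, annotations,
                                   config = tiling_config(),
                                   image_patients = NULL) {
  if (is.list(annotations) && !is.data.frame(annotations))
    annotations <- do.call(rbind, lapply(annotations, as.data.frame))
  known <- .all_tissue_labels()
  bad <- setdiff(unique(annotations$label), known)
  if (length(bad))
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
  ts <- config$tile_size_px
  out <- .empty_tile_set(config$model_input_px)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (!a$image %in% names(images))
      stop("annotation references unloaded image '", a$image, "'")
    img <- .to_gray(images[[a$image]])
    if (a$x0 < 0 || a$y0 < 0 || a$x1 > ncol(img) || a$y1 > nrow(img) ||
        a$x1 <= a$x0 || a$y1 <= a$y0)
      stop("ROI ", i, " out of bounds for image '", a$image, "'")
    roi <- img[(a$y0 + 1L):a$y1, (a$x0 + 1L):a$x1, drop = FALSE]
    nr <- nrow(roi) %/% ts
    nc <- ncol(roi) %/% ts
    if (nr == 0L || nc == 0L) {
      warning("ROI ", i, " (", a$label, ", image '", a$image,
              "') smaller than one tile; no tiles emitted")
      next
    }
    pid <- if (is.null(image_patients)) a$image else unname(image_patients[[a$image]])
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        tile <- roi[((r - 1L) * ts + 1L):(r * ts),
                    ((c - 1L) * ts + 1L):(c * ts), drop = FALSE]
        if (mean(tile) > config$background_mean_threshold) next
        out$patches[[length(out$patches) + 1L]] <-
          .resize_area(tile, config$model_input_px)
        out$info <- rbind(out$info, data.frame(
          patient_id = pid, image = a$image, row = r, col = c,
          label = a$label, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out$info) <- NULL
  out
}

#' Patient-level train/validation split
#'
#' Partitions patients (never tiles) into a training and a validation set so
#' that all regions from one subject land on the same side; the split is
#' reproducible under `seed`.
#'
#' @param tiles A `tile_set`.
#' @param fraction Fraction of patients assigned to training (default 0.75).
#' @param seed Integer seed.
#' @return List with `train` and `validation` tile sets.
#' @export
split_by_patient <- function(tiles, fraction = 0.75, seed = 1L) {
  stopifnot(inherits(tiles, "tile_set"))
  patients <- unique(tiles$info$patient_id)
  if (length(patients) < 2L)
    stop("patient-level split needs at least 2 patients, got ",
         length(patients))
  n_train <- round(fraction * length(patients))
  n_train <- min(max(n_train, 1L), length(patients) - 1L)
  shuffled <- .with_seed(seed, sample(patients))
  train_ids <- shuffled[seq_len(n_train)]
  in_train <- tiles$info$patient_id %in% train_ids
  list(train = .subset_tile_set(tiles, which(in_train)),
       validation = .subset_tile_set(tiles, which(!in_train)))
}
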