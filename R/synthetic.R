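#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic "whole-slide" generator. Each tissue
#' category is a band-limited random-field texture; the class layout in
#' feature space imposes the hierarchical separability the method assumes:
#' the (ccRCC, papRCC) and (chrRCC, ONCO) super-label pairs sit
#' `delta_between` apart on the mean-intensity axis (the easy split), while
#' the two members of each pair differ only by `delta_within` on the
#' texture-contrast axis (the hard differential diagnoses). Per-tile
#' contrast/mean jitter and per-pixel noise make single-tile calls fallible,
#' which is what Refine and patient voting exist to absorb.
#'
#' Defaults mirror a realistic small surgical cohort: 2.2 slides per patient
#' on average, roughly 70/30 tumor/not-tumor tissue within annotated areas,
#' near-white background margins, and a 60/40 patient-level train/test
#' split.
#'
#' @param n_per_subtype Patients per subtype.
#' @param slides_mean Mean slides per patient (truncated-geometric draw).
#' @param image_cells Image side length in tile cells (images are square,
#'   with a one-cell background margin ring).
#' @param tile_size_px,model_input_px Tile geometry (kept small for speed).
#' @param delta_between,delta_within Separability in `[0, 1]` of the
#'   between-pair and within-pair axes.
#' @param tumor_fraction Fraction of interior (tissue) cells covered by the
#'   tumor region.
#' @param background_margin_cells Width of the background ring, in cells.
#' @param noise_sd Per-pixel Gaussian noise (0-255 scale).
#' @param contrast_jitter_sd Per-tile log-normal contrast jitter.
#' @param mean_jitter_sd Per-tile Gaussian mean-intensity jitter.
#' @param train_fraction Patient-level training fraction.
#' @param seed Master seed.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_per_subtype = 10L, slides_mean = 2.2,
                          image_cells = 7L, tile_size_px = 64L,
                          model_input_px = 32L,
                          delta_between = 1.0, delta_within = 0.3,
                          tumor_fraction = 0.70,
                          background_margin_cells = 1L,
                          noise_sd = 15, contrast_jitter_sd = 0.25,
                          mean_jitter_sd = 6,
                          train_fraction = 0.6, seed = 1L) {
  fields <- as.list(environment())
  if (n_per_subtype < 1L) stop("need at least one patient per subtype")
  if (delta_between < 0 || delta_within < 0) stop("separabilities must be >= 0")
  if (any(c(tumor_fraction, train_fraction) < 0 |
          c(tumor_fraction, train_fraction) > 1))
    stop("fractions must lie in [0, 1]")
  if (image_cells - 2L * background_margin_cells < 2L)
    stop("impossible geometry: background margin leaves no interior tissue")
  structure(fields, class = "cohort_config")
}

#' @noRd
.tiling_from_cohort <- function(config) {
  tiling_config(tile_size_px = config$tile_size_px,
                model_input_px = config$model_input_px)
}

# class texture parameters: mean intensity encodes the between-pair axis,
# texture contrast the within-pair axis; not-tumor tissues sit apart from
# every tumor class.
#' @noRd
.texture_params <- function(label, delta_between, delta_within) {
  pair_lo <- c("ccRCC", "papRCC")   # darker pair
  pair_hi <- c("chrRCC", "ONCO")    # brighter pair
  if (label %in% c(pair_lo, pair_hi)) {
    m <- if (label %in% pair_lo) 150 - 25 * delta_between
         else 150 + 25 * delta_between
    c0 <- if (label %in% c("ccRCC", "chrRCC")) 25 * (1 - 0.6 * delta_within)
          else 25 * (1 + 0.6 * delta_within)
    return(list(mean = m, contrast = c0, grain_r = 3, grain_c = 3))
  }
  switch(label,
    fiber = list(mean = 195, contrast = 8, grain_r = 8, grain_c = 2),
    necrosis = list(mean = 60, contrast = 12, grain_r = 4, grain_c = 4),
    normal_parenchyma = list(mean = 200, contrast = 18, grain_r = 3, grain_c = 3),
    stop("unknown tissue label '", label, "'"))
}

# band-limited unit-variance random field via bilinear upsampling of a
# coarse Gaussian grid; grain_* set the correlation length per axis.
#' @noRd
.smooth_field <- function(size, grain_r, grain_c) {
  up <- function(n_coarse, n_out) {
    pos <- seq(1, n_coarse, length.out = n_out)
    i0 <- pmin(floor(pos), n_coarse - 1L)
    f <- pos - i0
    W <- matrix(0, n_out, n_coarse)
    W[cbind(seq_len(n_out), i0)] <- 1 - f
    W[cbind(seq_len(n_out), i0 + 1L)] <- f
    W
  }
  nr <- max(2L, ceiling(size / grain_r) + 1L)
  nc <- max(2L, ceiling(size / grain_c) + 1L)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- up(nr, size) %*% z %*% t(up(nc, size))
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

#' Procedural texture patch for a tissue class
#'
#' Draws one square patch from the class's texture distribution (see
#' [cohort_config()] for the parameterization). With `delta_within = 0` the
#' chrRCC and ONCO (and ccRCC/papRCC) patches are drawn from identical
#' distributions. Deterministic under `seed`.
#'
#' @param label One of the seven tissue labels.
#' @param delta_between,delta_within Separability parameters.
#' @param seed Integer seed.
#' @param size Patch side length in pixels.
#' @param noise_sd Per-pixel Gaussian noise.
#' @param contrast_jitter_sd,mean_jitter_sd Per-tile jitter.
#' @return `size x size` numeric matrix on the 0-255 scale.
#' @export
class_texture <- function(label, delta_between = 1.0, delta_within = 0.3,
                          seed = 1L, size = 64L, noise_sd = 15,
                          contrast_jitter_sd = 0.25, mean_jitter_sd = 6) {
  p <- .texture_params(label, delta_between, delta_within)
  .with_seed(seed, {
    mj <- stats::rnorm(1, 0, mean_jitter_sd)
    cj <- exp(stats::rnorm(1, 0, contrast_jitter_sd))
    field <- .smooth_field(size, p$grain_r, p$grain_c)
    img <- p$mean + mj + field * p$contrast * cj +
      matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
    pmin(pmax(img, 0), 255)
  })
}

# near-white empty background (> 240 by construction, so the 210 mean
# threshold separates it)
#' @noRd
.background_patch <- function(size, seed) {
  .with_seed(seed, {
    base <- stats::runif(1, 246, 252)
    pmin(pmax(base + matrix(stats::rnorm(size * size, 0, 1.5), size, size),
              241), 255)
  })
}

#' Generate one synthetic patient
#'
#' Builds the patient's images cell-by-cell: a background margin ring, a
#' rectangular tumor region of the patient's subtype texture covering about
#' `tumor_fraction` of the interior, and one not-tumor tissue filling the
#' rest. Ground-truth cell masks partition every image; rectangle ROI
#' annotations agreeing with the masks are emitted for training use.
#'
#' @param patient_id Character id.
#' @param subtype True subtype (one of [RCC_SUBTYPES]).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param tumor_fraction Override of the config's tumor fraction (0 gives a
#'   tumor-free patient).
#' @param tumor_mix Optional named proportion vector over subtype labels
#'   used to fill the tumor cells (for mixed-morphology patients); default
#'   is 100% the patient's subtype.
#' @param tumor_layout How a mixed tumor region is arranged: `"blocks"`
#'   (contiguous areas per label, emulating large coexisting morphologies)
#'   or `"random"` (i.i.d. per cell).
#' @return A `synthetic_patient`: id, subtype, named `images` (matrices),
#'   `cell_masks` (character matrices over background/tumor/not_tumor) and
#'   an `annotations` data frame.
#' @export
synth_patient <- function(patient_id, subtype, config = cohort_config(),
                          seed = 1L, tumor_fraction = config$tumor_fraction,
                          tumor_mix = NULL,
                          tumor_layout = c("blocks", "random")) {
  tumor_layout <- match.arg(tumor_layout)
  stopifnot(subtype %in% RCC_SUBTYPES)
  ts <- config$tile_size_px
  G <- config$image_cells
  mg <- config$background_margin_cells
  interior <- (mg + 1L):(G - mg)
  n_int <- length(interior)^2
  if (is.null(tumor_mix)) tumor_mix <- stats::setNames(1, subtype)
  .with_seed(seed, {
    n_slides <- min(1L + stats::rgeom(1L, 1 / config$slides_mean), 6L)
    images <- list(); masks <- list(); ann <- NULL
    for (s in seq_len(n_slides)) {
      img_id <- sprintf("%s_s%d", patient_id, s)
      nt_label <- sample(NOT_TUMOR_TISSUES, 1L)
      # tumor rectangle (in interior cell coordinates)
      target <- round(tumor_fraction * n_int)
      rect <- NULL
      if (target > 0L) {
        dims <- expand.grid(h = seq_along(interior), w = seq_along(interior))
        dims$err <- abs(dims$h * dims$w - target)
        best <- dims[dims$err == min(dims$err), , drop = FALSE]
        pick <- best[sample.int(nrow(best), 1L), ]
        r0 <- sample.int(length(interior) - pick$h + 1L, 1L) + mg
        c0 <- sample.int(length(interior) - pick$w + 1L, 1L) + mg
        rect <- c(r0 = r0, c0 = c0, r1 = r0 + pick$h - 1L,
                  c1 = c0 + pick$w - 1L)
      }
      cell_lab <- matrix("BG", G, G)
      cell_lab[interior, interior] <- nt_label
      if (!is.null(rect)) {
        n_cells <- (rect["r1"] - rect["r0"] + 1L) *
                   (rect["c1"] - rect["c0"] + 1L)
        tl <- if (tumor_layout == "random" || length(tumor_mix) == 1L) {
          sample(names(tumor_mix), size = n_cells, replace = TRUE,
                 prob = tumor_mix)
        } else {
          # contiguous bands, one per label, with areas matching the mix
          sizes <- round(tumor_mix / sum(tumor_mix) * n_cells)
          sizes[length(sizes)] <- n_cells - sum(sizes[-length(sizes)])
          rep(names(tumor_mix), times = sizes)
        }
        cell_lab[rect["r0"]:rect["r1"], rect["c0"]:rect["c1"]] <-
          matrix(tl, rect["r1"] - rect["r0"] + 1L,
                 rect["c1"] - rect["c0"] + 1L, byrow = TRUE)
      }
      img <- matrix(0, G * ts, G * ts)
      mask <- matrix("background", G, G)
      for (r in seq_len(G)) for (c in seq_len(G)) {
        cell_seed <- sample.int(2147483647L, 1L)
        lab <- cell_lab[r, c]
        patch <- if (lab == "BG") .background_patch(ts, cell_seed)
          else class_texture(lab, config$delta_between, config$delta_within,
                             seed = cell_seed, size = ts,
                             noise_sd = config$noise_sd,
                             contrast_jitter_sd = config$contrast_jitter_sd,
                             mean_jitter_sd = config$mean_jitter_sd)
        img[((r - 1L) * ts + 1L):(r * ts), ((c - 1L) * ts + 1L):(c * ts)] <- patch
        if (lab != "BG")
          mask[r, c] <- if (lab %in% RCC_SUBTYPES) "tumor" else "not_tumor"
      }
      # rectangle annotations: tumor block + decomposition of the rest of
      # the interior into bands, all in 0-based half-open pixel coordinates
      px <- function(r0, c0, r1, c1, label)
        data.frame(image = img_id, x0 = (c0 - 1L) * ts, y0 = (r0 - 1L) * ts,
                   x1 = c1 * ts, y1 = r1 * ts, label = label,
                   stringsAsFactors = FALSE)
      i0 <- interior[1]; i1 <- interior[length(interior)]
      a <- NULL
      if (!is.null(rect)) {
        a <- px(rect["r0"], rect["c0"], rect["r1"], rect["c1"], subtype)
        if (rect["r0"] > i0) a <- rbind(a, px(i0, i0, rect["r0"] - 1L, i1, nt_label))
        if (rect["r1"] < i1) a <- rbind(a, px(rect["r1"] + 1L, i0, i1, i1, nt_label))
        if (rect["c0"] > i0) a <- rbind(a, px(rect["r0"], i0, rect["r1"], rect["c0"] - 1L, nt_label))
        if (rect["c1"] < i1) a <- rbind(a, px(rect["r0"], rect["c1"] + 1L, rect["r1"], i1, nt_label))
      } else {
        a <- px(i0, i0, i1, i1, nt_label)
      }
      images[[img_id]] <- img
      masks[[img_id]] <- mask
      ann <- rbind(ann, a)
    }
    rownames(ann) <- NULL
    structure(list(patient_id = patient_id, subtype = subtype,
                   images = images, cell_masks = masks, annotations = ann),
              class = "synthetic_patient")
  })
}

#' Generate a synthetic train/test cohort
#'
#' Draws `n_per_subtype` patients for each subtype, splits them at patient
#' level into training and test sets (stratified by subtype at the
#' configured ratio) and generates every patient's images. All randomness
#' derives from the master seed; regeneration with the same seed is
#' byte-identical.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: lists `train` and `test` of
#'   `synthetic_patient`s plus the config.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_subtype
  ids <- sprintf("P%03d", seq_len(4L * n))
  subtypes <- rep(RCC_SUBTYPES, each = n)
  n_train <- round(config$train_fraction * n)
  n_train <- min(max(n_train, if (n > 1L) 1L else 0L), n - (n > 1L))
  assign_split <- .with_seed(.derive_seed(config$seed, 1L), {
    unlist(lapply(seq_len(4L), function(k) {
      perm <- sample.int(n)
      out <- rep("test", n)
      out[perm <= n_train] <- "train"
      out
    }))
  })
  patients <- lapply(seq_along(ids), function(i) {
    synth_patient(ids[i], subtypes[i], config,
                  seed = .derive_seed(config$seed, 100L + i))
  })
  structure(list(train = patients[assign_split == "train"],
                 test = patients[assign_split == "test"],
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$train), "train /", length(x$test),
      "test patients\n")
  invisible(x)
}

#' Generate a patient with mixed tumor morphology
#'
#' A patient whose tumor area mixes textures from the two super-label
#' groups (ccRCC from one, chrRCC from the other) in proportion
#' `balance` : `1 - balance`, exercising the node-pruning rule
#' deterministically: at `balance = 0.5` the super-label tile counts are
#' near-equal and selective pruning should fire; at `balance = 1` the
#' patient is single-texture.
#'
#' @param config A [cohort_config()].
#' @param balance Proportion of tumor cells drawn from the ccRCC texture.
#' @param seed Integer seed.
#' @return A `synthetic_patient`.
#' @export
make_ambiguous_patient <- function(config = cohort_config(), balance = 0.5,
                                   seed = 1L) {
  if (balance < 0 || balance > 1) stop("balance must lie in [0, 1]")
  mix <- c(ccRCC = balance, chrRCC = 1 - balance)
  mix <- mix[mix > 0]
  synth_patient("Pmix", "ccRCC", config, seed = seed, tumor_mix = mix)
}

# ---- bridging the generator to the pipeline --------------------------------

#' Training tiles from a synthetic cohort
#'
#' Pools the training patients' images and annotations and runs the
#' ROI-based tile extraction.
#'
#' @param cohort A `synthetic_cohort`.
#' @return A `tile_set`.
#' @export
cohort_tiles <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  images <- list(); ann <- NULL; owners <- character()
  for (p in cohort$train) {
    images <- c(images, p$images)
    ann <- rbind(ann, p$annotations)
    owners <- c(owners, stats::setNames(rep(p$patient_id, length(p$images)),
                                        names(p$images)))
  }
  extract_training_tiles(images, ann, .tiling_from_cohort(cohort$config),
                         image_patients = owners)
}

#' Tile grids for one patient's images
#'
#' @param patient A `synthetic_patient` (or any list with an `images` field).
#' @param config A [tiling_config()].
#' @return Named list of `tile_grid`s.
#' @export
patient_grids <- function(patient, config) {
  lapply(patient$images, tile_image, config = config)
}

#' Patient-level predictions over a set of patients
#'
#' @param tree A `fitted_tree`.
#' @param patients List of `synthetic_patient`s.
#' @param config A [tiling_config()].
#' @param policy A [pruning_policy()].
#' @param refine Apply Refine?
#' @return Data frame with `patient_id`, `truth`, `predicted`, `pruned`,
#'   `imbalance`.
#' @export
predict_cohort <- function(tree, patients, config,
                           policy = pruning_policy(), refine = TRUE) {
  rows <- lapply(patients, function(p) {
    res <- classify_patient(tree, patient_grids(p, config), policy, refine)
    data.frame(patient_id = p$patient_id, truth = p$subtype,
               predicted = res$subtype,
               pruned = res$diagnostics$pruned,
               imbalance = if (is.null(res$diagnostics$imbalance)) NA_real_
                           else res$diagnostics$imbalance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
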