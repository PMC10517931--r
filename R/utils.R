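#' Renal tumor subtype labels
#'
#' The four renal-cell neoplasm subtypes handled by the tree: clear cell
#' (ccRCC), papillary (papRCC) and chromophobe (chrRCC) carcinomas plus the
#' benign oncocytoma (ONCO). Order reflects decreasing prevalence and is the
#' fixed tie-break order for patient-level voting.
#'
#' @format Character vector of length 4.
#' @export
RCC_SUBTYPES <- c("ccRCC", "papRCC", "chrRCC", "ONCO")

#' Not-tumor tissue labels
#'
#' Tissue categories collapsed into the not-tumor (NT) super-class for the
#' root tumor/not-tumor classifier.
#'
#' @format Character vector of length 3.
#' @export
NOT_TUMOR_TISSUES <- c("fiber", "necrosis", "normal_parenchyma")

# sentinel cell states in tile label maps
.SENTINELS <- c("BACKGROUND", "OUT_OF_STAGE")

#' @noRd
.all_tissue_labels <- function() c(RCC_SUBTYPES, NOT_TUMOR_TISSUES)

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
#' @noRd
.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derivation; stays well below 2^31.
#' @noRd
.derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) + 0
  as.integer((s * 48271 + as.numeric(offset) * 9973 + 17) %% 2147483629)
}

# ---- raster handling --------------------------------------------------------

# Collapse an RGB(A) array to a single luminance channel by plain channel
# averaging (alpha dropped). Intensities are kept on the 0..255 scale.
#' @noRd
.to_gray <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  if (length(dim(image)) == 3L) {
    nch <- min(dim(image)[3L], 3L)
    out <- image[, , 1L]
    if (nch > 1L) for (k in 2:nch) out <- out + image[, , k]
    return(out / nch)
  }
  stop("raster must be a 2-D matrix or a 3-D (h, w, channels) array")
}

#' Read a raster image
#'
#' Reads an 8-bit PNG or TIFF image and returns it as a numeric array on the
#' 0-255 intensity scale (matrix for grayscale, `h x w x 3` array for RGB;
#' an alpha channel, if present, is dropped). This is the plain-raster
#' adapter boundary where a whole-slide reader could plug in.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix or 3-D array with values in `[0, 255]`.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' (expected png or tiff)")
  )
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]
  if (length(dim(img)) == 3L && dim(img)[3L] == 2L) img <- img[, , 1L]
  img * 255
}

#' @noRd
.write_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), target = path)
}

# ---- area (anti-aliased) resampling ----------------------------------------

# Interval-overlap weight matrix mapping n_src source pixels onto n_dst
# destination pixels: each destination pixel is the mean of the source
# interval it covers (exact area interpolation, anti-aliased for any ratio).
#' @noRd
.area_weights <- local({
  memo <- new.env(parent = emptyenv())
  function(n_src, n_dst) {
    key <- paste0(n_src, "_", n_dst)
    if (!is.null(memo[[key]])) return(memo[[key]])
    W <- matrix(0, n_dst, n_src)
    r <- n_src / n_dst
    for (d in seq_len(n_dst)) {
      lo <- (d - 1) * r
      hi <- d * r
      for (s in (floor(lo) + 1):min(ceiling(hi), n_src)) {
        ov <- min(hi, s) - max(lo, s - 1)
        if (ov > 0) W[d, s] <- ov
      }
    }
    W <- W / r
    memo[[key]] <- W
    W
  }
})

#' @noRd
.resize_area <- function(img, n_out) {
  if (nrow(img) == n_out && ncol(img) == n_out) return(img)
  Wr <- .area_weights(nrow(img), n_out)
  Wc <- .area_weights(ncol(img), n_out)
  Wr %*% img %*% t(Wc)
}
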