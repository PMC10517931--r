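#' Tile label maps
#'
#' Stage outputs are plain character matrices aligned with the source
#' `tile_grid`: each cell holds a label from the stage alphabet or one of the
#' sentinels `"BACKGROUND"` / `"OUT_OF_STAGE"`. Sentinel cells never vote and
#' are never relabelled.
#'
#' @param grid A `tile_grid`.
#' @param fill Label to place in non-background cells.
#' @return Character matrix of dimension `n_rows x n_cols`.
#' @export
empty_label_map <- function(grid, fill = "OUT_OF_STAGE") {
  m <- matrix(fill, grid$n_rows, grid$n_cols)
  m[grid$background_mask] <- "BACKGROUND"
  m
}

#' Labels voting in a tile's 9-connected neighborhood
#'
#' Returns the labels of the cells in the 3x3 window centered at
#' `(row, col)` -- the tiles touching an edge or corner of the center tile,
#' plus the tile itself -- restricted to cells that exist inside the grid and
#' are neither background nor out of the stage domain.
#'
#' @param map Character label matrix (see [empty_label_map()]).
#' @param row,col 1-based cell position; must hold a non-sentinel label.
#' @return Character vector of up to 9 labels.
#' @export
neighborhood_labels <- function(map, row, col) {
  if (map[row, col] %in% .SENTINELS)
    stop("cell (", row, ", ", col, ") is ", map[row, col],
         "; neighborhoods are defined for classified tiles only")
  rs <- max(1L, row - 1L):min(nrow(map), row + 1L)
  cs <- max(1L, col - 1L):min(ncol(map), col + 1L)
  labs <- as.vector(map[rs, cs])
  labs[!labs %in% .SENTINELS]
}

#' Refine: spatial majority-vote label smoothing
#'
#' Single-pass low-pass filter over a tile label map: every classified cell
#' is relabelled with the majority label of its 9-connected neighborhood
#' (self included), all votes being read synchronously from the input map.
#' Background and out-of-domain cells cast no vote and are returned
#' unchanged. When the maximal vote count is shared by several labels the
#' cell keeps its original label. Applied once downstream of each
#' classification stage, this removes isolated misclassified tiles without
#' reordering effects.
#'
#' @param map Character label matrix.
#' @param domain Stage alphabet over which votes are counted; labels outside
#'   it are treated as sentinels (frozen, non-voting). Defaults to every
#'   non-sentinel label present.
#' @return Relabelled map of the same dimension.
#' @export
refine_map <- function(map, domain = NULL) {
  stopifnot(is.matrix(map), is.character(map))
  if (is.null(domain)) domain <- setdiff(unique(as.vector(map)), .SENTINELS)
  k <- length(domain)
  if (k == 0L) return(map)
  nr <- nrow(map); nc <- ncol(map)
  active <- matrix(map %in% domain, nr, nc)
  if (!any(active)) return(map)
  lab_idx <- matrix(match(map, domain), nr, nc)  # NA outside domain
  counts <- array(0L, c(nr, nc, k))
  for (dr in -1L:1L) {
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    for (dc in -1L:1L) {
      cs <- max(1L, 1L - dc):min(nc, nc - dc)
      src <- lab_idx[rs + dr, cs + dc, drop = FALSE]
      ok <- !is.na(src)
      if (!any(ok)) next
      ridx <- rep.int(rs, length(cs))
      cidx <- rep(cs, each = length(rs))
      at <- cbind(ridx[ok], cidx[ok], as.vector(src)[ok])
      counts[at] <- counts[at] + 1L
    }
  }
  slices <- lapply(seq_len(k), function(j) counts[, , j])
  maxc <- Reduce(pmax, slices)
  n_at_max <- Reduce(`+`, lapply(slices, function(s) s == maxc))
  out <- map
  for (j in seq_len(k)) {
    sel <- active & slices[[j]] == maxc & n_at_max == 1L
    out[sel] <- domain[j]
  }
  out  # ties (n_at_max > 1) keep the original label
}
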