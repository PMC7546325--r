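#' Class codes used in per-pixel label masks
#'
#' Label masks are integer matrices: 0 = background, 1 = stomate, 2 = vein.
#' @return named integer vector mapping class name to code.
#' @export
class_codes <- function() c(background = 0L, stomate = 1L, vein = 2L)

# tile start offsets along one dimension: fixed stride, last tile shifted
# inward to end flush with the border (no padding pixels ever enter the
# classifier)
tile_starts <- function(extent, tile_size, overlap) {
  step <- tile_size - overlap
  s <- seq(0L, max(extent - tile_size, 0L), by = step)
  if (s[length(s)] + tile_size < extent) s <- c(s, extent - tile_size)
  as.integer(s)
}

#' Split a scan into overlapping tiles
#'
#' Whole-slide scans are too large to classify in one pass, so they are cut
#' into square tiles processed individually and reassembled afterwards.
#' Consecutive tiles share `overlap` pixels; the final tile in each direction
#' is shifted inward so it ends flush with the image border.
#'
#' @param image a [scan_image()].
#' @param tile_size tile side in pixels.
#' @param overlap shared pixels between consecutive tiles; must be smaller
#'   than `tile_size`. Use at least one detection window so stomata straddling
#'   a tile seam are seen whole by some tile.
#' @return list of tiles, each a list with `parent_id`, `row_offset`,
#'   `col_offset` (0-based) and `pixels`.
#' @export
tile_image <- function(image, tile_size = 2048, overlap = 128) {
  stopifnot(inherits(image, "scan_image"))
  d <- dim(image$pixels)
  if (overlap < 0 || overlap >= tile_size)
    stop("parameter error: need 0 <= overlap < tile_size")
  if (tile_size > max(d[1], d[2]))
    stop("parameter error: tile_size exceeds both image dimensions")
  ts_r <- min(tile_size, d[1]); ts_c <- min(tile_size, d[2])
  rows <- tile_starts(d[1], ts_r, min(overlap, ts_r - 1))
  cols <- tile_starts(d[2], ts_c, min(overlap, ts_c - 1))
  out <- vector("list", length(rows) * length(cols))
  k <- 1
  for (r0 in rows) for (c0 in cols) {
    px <- if (length(d) == 3)
      image$pixels[r0 + seq_len(ts_r), c0 + seq_len(ts_c), , drop = FALSE]
    else image$pixels[r0 + seq_len(ts_r), c0 + seq_len(ts_c), drop = FALSE]
    out[[k]] <- list(parent_id = image$source_id, row_offset = r0,
                     col_offset = c0, pixels = px)
    k <- k + 1
  }
  out
}

#' Reassemble per-tile label masks into a full-image mask
#'
#' Where tiles overlap, classes are merged conservatively: stomate beats
#' vein beats background, so a stomate found by any tile is never erased by
#' a neighbouring tile's background. Duplicate coverage is later merged by
#' connected components in [mask_to_boxes()].
#'
#' @param tile_masks list of lists with `row_offset`, `col_offset` (0-based)
#'   and `mask` (integer class grid, see [class_codes()]).
#' @param full_shape integer vector `c(height, width)`.
#' @return integer class grid of dimension `full_shape`.
#' @export
assemble_label_mask <- function(tile_masks, full_shape) {
  out <- matrix(0L, full_shape[1], full_shape[2])
  # priority rank: stomate (1) highest, then vein (2), then background (0)
  rank_of <- function(m) ifelse(m == 1L, 2L, ifelse(m == 2L, 1L, 0L))
  rank <- matrix(0L, full_shape[1], full_shape[2])
  for (tm in tile_masks) {
    m <- tm$mask
    r <- tm$row_offset + seq_len(nrow(m))
    c <- tm$col_offset + seq_len(ncol(m))
    if (min(r) < 1 || max(r) > full_shape[1] ||
        min(c) < 1 || max(c) > full_shape[2])
      stop("geometry error: tile mask outside full_shape")
    mr <- rank_of(m)
    win <- rank[r, c, drop = FALSE]
    take <- mr > win
    sub <- out[r, c, drop = FALSE]
    sub[take] <- m[take]
    out[r, c] <- sub
    win[take] <- mr[take]
    rank[r, c] <- win
  }
  out
}
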