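#' Sliding-window classification of a full image
#'
#' The classification window is slid across the image at the given stride
#' (the last position in each direction is shifted inward to end flush with
#' the border), each window is classified, and the window's central
#' stride-by-stride cell is painted with the predicted class. Painting only
#' the central cell keeps localisation crisp; set `paint = "window"` to
#' paint the full window instead (majority of stomate wins on overlap).
#' Border pixels not reachable by any window's central cell remain
#' background.
#'
#' @param image a [scan_image()] or grayscale matrix.
#' @param model a `stomate_classifier` from [train_classifier()].
#' @param window_size window side in px; defaults to the model's.
#' @param stride step between window positions, `1 <= stride <= window_size`.
#' @param paint `"center"` or `"window"`.
#' @return integer class grid (see [class_codes()]) of the image's size.
#' @export
sliding_window_classify <- function(image, model,
                                    window_size = model$window_size,
                                    stride = window_size %/% 2,
                                    paint = c("center", "window")) {
  paint <- match.arg(paint)
  g <- as_gray(image)
  h <- nrow(g); w <- ncol(g)
  if (window_size > h || window_size > w)
    stop("parameter error: window larger than image")
  if (stride < 1 || stride > window_size)
    stop("parameter error: need 1 <= stride <= window_size")
  rows <- tile_starts(h, window_size, window_size - stride)
  cols <- tile_starts(w, window_size, window_size - stride)
  ex <- model$extractor
  npos <- length(rows) * length(cols)
  feats <- matrix(0, npos, ex$length)
  k <- 1
  for (r0 in rows) for (c0 in cols) {
    feats[k, ] <- extract_features(ex,
      g[r0 + seq_len(window_size), c0 + seq_len(window_size)])
    k <- k + 1
  }
  pred <- predict_classes(model, feats)
  codes <- class_codes()
  out <- matrix(codes[["background"]], h, w)
  votes <- if (paint == "window") matrix(0L, h, w) else NULL
  off <- (window_size - stride) %/% 2
  k <- 1
  for (r0 in rows) for (c0 in cols) {
    code <- codes[[pred[k]]]
    if (paint == "center") {
      rr <- (r0 + off + 1):min(r0 + off + stride, h)
      cc <- (c0 + off + 1):min(c0 + off + stride, w)
      out[rr, cc] <- code
    } else {
      rr <- (r0 + 1):(r0 + window_size)
      cc <- (c0 + 1):(c0 + window_size)
      if (code == codes[["stomate"]]) {
        votes[rr, cc] <- votes[rr, cc] + 1L
      } else if (code == codes[["vein"]]) {
        sub <- out[rr, cc]; sub[sub == 0L] <- code; out[rr, cc] <- sub
      }
    }
    k <- k + 1
  }
  if (paint == "window") out[votes > 0L] <- codes[["stomate"]]
  out
}

#' Extract stomate bounding boxes from a class grid
#'
#' Each 8-connected "stomate" component with area at least `min_region_px`
#' becomes one box: the component's tight bounding rectangle dilated by
#' `padding` pixels and clipped to the image. The score is the fraction of
#' the final box covered by the component. Boxes are ordered by the
#' component's first pixel in row-major order, so output is reproducible.
#'
#' @param grid integer class grid from [sliding_window_classify()].
#' @param min_region_px minimum component area in pixels.
#' @param padding box dilation in pixels.
#' @return data frame `row0,col0,row1,col1,score` (0-based half-open boxes);
#'   zero rows when nothing qualifies.
#' @export
mask_to_boxes <- function(grid, min_region_px = 1000, padding = 8) {
  lab <- label_components(grid == class_codes()[["stomate"]])
  n <- max(lab)
  empty <- data.frame(row0 = integer(0), col0 = integer(0),
                      row1 = integer(0), col1 = integer(0),
                      score = numeric(0))
  if (n == 0) return(empty)
  h <- nrow(grid); w <- ncol(grid)
  rows <- lapply(seq_len(n), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_region_px) return(NULL)
    r0 <- max(min(idx[, 1]) - 1 - padding, 0)
    c0 <- max(min(idx[, 2]) - 1 - padding, 0)
    r1 <- min(max(idx[, 1]) + padding, h)
    c1 <- min(max(idx[, 2]) + padding, w)
    data.frame(row0 = r0, col0 = c0, row1 = r1, col1 = c1,
               score = nrow(idx) / ((r1 - r0) * (c1 - c0)))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Detect stomata in a scan
#'
#' Tiles the scan if it exceeds the configured tile size, classifies each
#' tile with the sliding window, reassembles the per-tile class masks
#' (stomate-wins on overlaps), and extracts bounding boxes.
#'
#' @param image a [scan_image()].
#' @param model a `stomate_classifier`.
#' @param config a [stoma_config()].
#' @return list with `boxes` (data frame) and `mask` (full class grid).
#' @export
detect_stomata <- function(image, model, config = stoma_config()) {
  d <- dim(image$pixels)[1:2]
  if (max(d) > config$tile_size) {
    tiles <- tile_image(image, config$tile_size, config$tile_overlap)
    tm <- lapply(tiles, function(tl) {
      sub <- scan_image(tl$pixels, image$pixel_scale, image$source_id)
      list(row_offset = tl$row_offset, col_offset = tl$col_offset,
           mask = sliding_window_classify(sub, model, config$window_size,
                                          config$stride, config$paint))
    })
    mask <- assemble_label_mask(tm, d)
  } else {
    mask <- sliding_window_classify(image, model, config$window_size,
                                    config$stride, config$paint)
  }
  list(boxes = mask_to_boxes(mask, config$min_region_px, config$box_padding),
       mask = mask)
}
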