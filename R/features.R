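#' Gradient-orientation-histogram feature extractor
#'
#' The default, weights-free patch descriptor: the window is divided into a
#' `cells x cells` grid, and each cell accumulates a magnitude-weighted
#' histogram of unsigned gradient orientations (`bins` bins over \[0, 180)
#' degrees). The concatenated vector is L2-normalised as a whole, so the
#' relative gradient energy between cells is preserved — a faint epidermal
#' outline must not weigh as much as a strong guard-cell edge. A window
#' with no gradient energy maps to the all-zero vector rather than dividing
#' by zero. The descriptor length is `cells^2 * bins` and the mapping is
#' fully deterministic.
#'
#' An external deep-feature backbone can be substituted by supplying any
#' object with the same contract (`id`, `window_size`, `length`, and a
#' `fun(window) -> numeric` field) to the training and detection functions.
#'
#' @param window_size expected square window side in pixels.
#' @param cells cell grid per side (default 8).
#' @param bins orientation bins (default 9).
#' @return object of class `feature_extractor`.
#' @export
hog_extractor <- function(window_size = 96, cells = 8, bins = 9) {
  structure(list(id = sprintf("hog-%dx%d-%db-w%d", cells, cells, bins,
                              window_size),
                 window_size = as.integer(window_size),
                 cells = as.integer(cells), bins = as.integer(bins),
                 length = as.integer(cells^2 * bins)),
            class = "feature_extractor")
}

#' Extract a feature vector from one window
#'
#' @param extractor a [hog_extractor()].
#' @param window square grayscale matrix of the extractor's window size
#'   (RGB arrays are converted via [as_gray()]).
#' @return numeric vector of length `extractor$length`.
#' @export
extract_features <- function(extractor, window) {
  window <- as_gray(window)
  w <- extractor$window_size
  if (nrow(window) != w || ncol(window) != w)
    stop(sprintf("shape error: extractor expects %dx%d window, got %dx%d",
                 w, w, nrow(window), ncol(window)))
  hog_descriptor(window, extractor$cells, extractor$bins)
}

# central-difference gradients with replicated edges, hard orientation
# binning, whole-vector L2 normalisation
hog_descriptor <- function(g, cells, bins) {
  h <- nrow(g); w <- ncol(g)
  gx <- (g[, c(2:w, w)] - g[, c(1, 1:(w - 1))]) / 2
  gy <- (g[c(2:h, h), ] - g[c(1, 1:(h - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                      # unsigned, [0, pi)
  bin <- pmin(floor(ang / pi * bins), bins - 1)   # 0-based
  cr <- floor((row(g) - 1) * cells / h)
  cc <- floor((col(g) - 1) * cells / w)
  idx <- (cr * cells + cc) * bins + bin + 1       # 1-based flat index
  v <- numeric(cells^2 * bins)
  acc <- rowsum(as.vector(mag), as.vector(idx))
  v[as.integer(rownames(acc))] <- acc[, 1]
  nrm <- sqrt(sum(v^2))
  if (nrm > 1e-12) v / nrm else v
}
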