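#' Construct a scan image
#'
#' The raster currency of the pipeline: an 8-bit intensity grid (grayscale
#' matrix or height x width x 3 RGB array) together with the physical pixel
#' scale. The default scale of 0.25 um/px matches 40x brightfield slide
#' scanners commonly used for leaf-imprint imaging.
#'
#' @param pixels numeric matrix (grayscale) or 3-plane array (RGB), values
#'   in \[0, 255\].
#' @param pixel_scale microns per pixel; must be positive.
#' @param source_id text identifier carried through to result tables.
#' @return an object of class `scan_image`.
#' @export
scan_image <- function(pixels, pixel_scale = 0.25, source_id = "image") {
  if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 1)
    pixels <- pixels[, , 1]
  stopifnot(is.numeric(pixels),
            length(dim(pixels)) %in% c(2, 3))
  if (length(dim(pixels)) == 3 && dim(pixels)[3] != 3)
    stop("RGB pixels must have exactly 3 planes")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("empty image")
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]")
  structure(list(pixels = pixels, pixel_scale = pixel_scale,
                 source_id = source_id),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 3) "RGB" else "grayscale"
  cat(sprintf("<scan_image> '%s' %dx%d %s, %.3g um/px\n",
              x$source_id, d[1], d[2], kind, x$pixel_scale))
  invisible(x)
}

#' @export
dim.scan_image <- function(x) dim(x$pixels)

#' Convert a scan image (or raw pixel array) to a grayscale matrix
#'
#' RGB is reduced with the Rec. 601 luminance weights 0.299/0.587/0.114.
#'
#' @param x `scan_image` or numeric matrix/array with values in \[0, 255\].
#' @return numeric matrix in \[0, 255\].
#' @export
as_gray <- function(x) {
  px <- if (inherits(x, "scan_image")) x$pixels else x
  if (length(dim(px)) == 3)
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  px
}

#' Load a PNG or TIFF micrograph
#'
#' 8-bit data is preserved exactly; 16-bit data is rescaled to 8 bits by a
#' linear min-max map (an all-zero image stays zero). An alpha channel, if
#' present, is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @inheritParams scan_image
#' @return a [scan_image()].
#' @export
load_image <- function(path, pixel_scale = 0.25,
                       source_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("input-format error: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- try(png::readPNG(path), silent = TRUE)
    if (inherits(raw, "try-error"))
      stop("input-format error: unreadable PNG: ", path)
    bits <- png_bit_depth(path)
    vals <- raw * (2^bits - 1)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- try(suppressWarnings(tiff::readTIFF(path, info = TRUE)),
               silent = TRUE)
    if (inherits(raw, "try-error"))
      stop("input-format error: unreadable TIFF: ", path)
    bits <- attr(raw, "bits.per.sample")[1]
    if (is.null(bits)) bits <- 8L
    vals <- raw * (2^bits - 1)
  } else {
    stop("input-format error: unsupported extension '", ext, "': ", path)
  }
  if (length(dim(vals)) == 3 && dim(vals)[3] %in% c(2, 4))  # drop alpha
    vals <- if (dim(vals)[3] == 2) vals[, , 1] else vals[, , 1:3]
  if (bits > 8) {
    rng <- range(vals)
    vals <- if (rng[2] > rng[1])
      (vals - rng[1]) / (rng[2] - rng[1]) * 255 else vals * 0
  }
  scan_image(round(vals), pixel_scale = pixel_scale, source_id = source_id)
}

# PNG bit depth from the IHDR chunk (byte 25 of the file)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25)
  as.integer(hdr[25])
}

#' Write a scan image to a PNG file
#' @param image a [scan_image()] or numeric pixel array in \[0, 255\].
#' @param path output path.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "scan_image")) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}
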