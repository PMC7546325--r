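#' Pipeline configuration
#'
#' All tunables of the pipeline in one flat list, overridable per call or
#' from a YAML file. Defaults (with units):
#'
#' * `pixel_scale` (um/px, 0.25): slide-scanner resolution.
#' * `tile_size` / `tile_overlap` (px, 2048 / 128): whole-scan tiling;
#'   the overlap covers at least one detection window.
#' * `window_size` (px, 96): classification window, about 24 um at the
#'   default scale — a typical stomate span.
#' * `stride` (px, 12): sliding-window step; also the side of the central
#'   cell painted with the window's class. Finer strides localise better at
#'   proportionally higher cost.
#' * `paint` (`"center"` or `"window"`): paint only the central
#'   stride-by-stride cell (crisp localisation, default) or the whole window.
#' * `min_region_px` (px^2, 432 = 3 stride cells): minimum stomate-class
#'   component area kept by [mask_to_boxes()]; isolated single-window fires
#'   (dust, vein fragments) fall below it.
#' * `box_padding` (px, 8): dilation of detection boxes before pore cropping.
#' * `clahe_clip` (2) and `clahe_tiles` (8): CLAHE contrast limit and tile
#'   grid for patch enhancement.
#' * `sharpen_radius` (px, 2) and `sharpen_amount` (0.5): unsharp mask.
#' * `min_area_px` (px^2, 50): binary regions no larger than this are
#'   discarded as dust/bubbles before stomate selection.
#' * `central_fraction` (0.5): the stomate region's centroid must fall in the
#'   central box of this fractional side — pore centres sit near the middle
#'   of a correct detection box.
#' * `smooth_window` (samples, 3) and `prominence_frac` (0.05): cross-section
#'   smoothing and the minimum extremum prominence as a fraction of the
#'   profile range.
#' * `tolerance_frac` (0.5): region-growing intensity tolerance as a
#'   fraction of the pore extremum's prominence; 0.5 is half-depth
#'   segmentation, robust to blurred pore edges.
#' * `patch_expand` (0.25): fractional margin added around a detection box
#'   when cropping the measurement patch.
#' * `cell_size` (px, 16): evaluation grid cell for mask comparison; it
#'   should resolve the smallest stomate of interest.
#'
#' @param ... name = value overrides of the defaults.
#' @return named list of class `stoma_config`.
#' @export
stoma_config <- function(...) {
  cfg <- list(
    pixel_scale = 0.25,
    tile_size = 2048, tile_overlap = 128,
    window_size = 96, stride = 12, paint = "center",
    min_region_px = 432, box_padding = 8,
    clahe_clip = 2, clahe_tiles = 8,
    sharpen_radius = 2, sharpen_amount = 0.5,
    min_area_px = 50, central_fraction = 0.5,
    smooth_window = 3, prominence_frac = 0.05,
    tolerance_frac = 0.5, patch_expand = 0.25,
    cell_size = 16)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = c("stoma_config", "list"))
}

#' Read a configuration from a YAML file
#'
#' Keys mirror [stoma_config()]; unknown keys are an error so typos fail
#' loudly.
#' @param path YAML file.
#' @return `stoma_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(stoma_config, vals)
}
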