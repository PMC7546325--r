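#' @title Stomatal pore area estimation
#'
#' @description The measurement pipeline run on each detected stomate:
#' enhance the patch, binarise it with Otsu's threshold, discard small
#' regions, select the stomate region near the patch centre, rotate it so
#' the major axis is horizontal, read the vertical intensity cross-section
#' through the region centroid, locate the extremum nearest the centroid
#' (a valley means a dark pore, a peak a light one), grow the pore region
#' from that centre by intensity similarity, and convert the pixel count to
#' square microns. Every failure path becomes a status, never an error.
#' @name pore_measure
NULL

# degenerate-input condition used by otsu_threshold / enhance
degenerate_input <- function(msg) {
  structure(class = c("stomapore_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Crop a measurement patch around a detection box
#'
#' @param image a [scan_image()].
#' @param box one-row data frame (`row0,col0,row1,col1`, 0-based half-open).
#' @param expand fractional margin added on each side of the box's larger
#'   dimension.
#' @return object of class `pore_patch`: grayscale `pixels`, the patch
#'   `center` (row, col), `pixel_scale`, and the patch's 0-based `offset` in
#'   the parent image.
#' @export
crop_patch <- function(image, box, expand = 0.25) {
  g <- as_gray(image)
  side <- round(max(box$row1 - box$row0, box$col1 - box$col0) *
                  (1 + 2 * expand))
  cr <- (box$row0 + box$row1) / 2
  cc <- (box$col0 + box$col1) / 2
  r0 <- max(round(cr - side / 2), 0)
  c0 <- max(round(cc - side / 2), 0)
  r1 <- min(r0 + side, nrow(g)); c0 <- min(c0, ncol(g) - 1)
  c1 <- min(c0 + side, ncol(g))
  px <- g[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  structure(list(pixels = px,
                 center = c(row = (nrow(px) + 1) / 2,
                            col = (ncol(px) + 1) / 2),
                 pixel_scale = image$pixel_scale,
                 offset = c(row = r0, col = c0)),
            class = "pore_patch")
}

#' Enhance a measurement patch
#'
#' Contrast-limited adaptive histogram equalisation on the luminance,
#' followed by a global linear stretch to \[0, 255\] and an unsharp mask.
#' A constant patch is returned unchanged (stretching a zero range is the
#' identity by convention); a 1-pixel patch is returned with a warning.
#'
#' @param patch a `pore_patch`, or a grayscale/RGB pixel array in \[0, 255\].
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tiles CLAHE tile grid per side (reduced automatically for
#'   small patches).
#' @param sharpen_radius unsharp-mask Gaussian sigma in px.
#' @param sharpen_amount unsharp-mask strength.
#' @return 8-bit grayscale matrix.
#' @export
enhance <- function(patch, clahe_clip = 2, clahe_tiles = 8,
                    sharpen_radius = 2, sharpen_amount = 0.5) {
  g <- as_gray(if (inherits(patch, "pore_patch")) patch$pixels else patch)
  if (length(g) == 1) {
    warning("degenerate 1-pixel patch returned unchanged")
    return(g)
  }
  if (max(g) == min(g)) return(round(g))
  h <- nrow(g); w <- ncol(g)
  # the tile grid is capped so each tile keeps at least 16 px of context;
  # smaller tiles over-amplify flat epidermal texture
  nx <- max(1, min(clahe_tiles, w %/% 16))
  ny <- max(1, min(clahe_tiles, h %/% 16))
  # CLAHE needs dimensions divisible by the tile grid: replicate-pad, crop
  ph <- ceiling(h / ny) * ny; pw <- ceiling(w / nx) * nx
  gp <- g[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w)),
          drop = FALSE]
  eq <- EBImage::clahe(EBImage::Image(t(gp) / 255), nx = nx, ny = ny,
                       limit = clahe_clip)
  g <- t(EBImage::imageData(eq))[seq_len(h), seq_len(w), drop = FALSE] * 255
  rng <- range(g)
  if (rng[2] > rng[1]) g <- (g - rng[1]) / (rng[2] - rng[1]) * 255
  if (sharpen_amount > 0 && min(h, w) > 4) {
    blur <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(g) / 255),
                                                sigma = sharpen_radius))) * 255
    g <- g + sharpen_amount * (g - blur)
  }
  round(pmin(pmax(g, 0), 255))
}

#' Otsu's threshold with a smallest-t tie-break
#'
#' Returns the integer threshold t in \[0, 255\] maximising the between-class
#' variance of the classes `{<= t}` and `{> t}`; among ties the smallest t
#' is returned so results are deterministic.
#'
#' @param g grayscale matrix with values in \[0, 255\].
#' @return integer threshold.
#' @export
otsu_threshold <- function(g) {
  v <- round(as.vector(g))
  if (length(unique(v)) < 2)
    stop(degenerate_input("otsu_threshold: constant image"))
  counts <- tabulate(v + 1L, 256)
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)                 # class {<= t}
  m0 <- cumsum(counts * levels)
  mu <- m0[256] / n
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / pmax(w0, 1)
  mu1 <- (m0[256] - m0) / pmax(w1, 1)
  sb <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  which.max(sb) - 1L                   # which.max takes the first maximum
}

#' Remove small binary regions
#'
#' Discards every 8-connected component whose area is no larger than
#' `min_area_px` — dust particles and air bubbles picked up by the
#' binarisation. Note the rule is strict: a component of exactly
#' `min_area_px` pixels is removed.
#'
#' @param mask logical matrix.
#' @param min_area_px area cutoff in pixels (default 50).
#' @return logical matrix, a subset of the input.
#' @export
filter_regions <- function(mask, min_area_px = 50) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0], max(lab))
  keep <- which(areas > min_area_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Select the stomate region near the patch centre
#'
#' Among components whose centroid falls inside the central box of side
#' `central_fraction` times the patch side, the largest by area wins; ties
#' go to the component nearest the centre. Two kinds of component are
#' excluded as "shapes at the edges" that cannot be the stomate of a
#' correct detection: those whose centroid falls outside the central
#' window, and those covering at least `max_border_frac` of the patch
#' border (epidermal-wall webs and other patch-spanning clutter pass
#' through the centre but always hug the border too).
#'
#' @param mask filtered logical matrix.
#' @param central_fraction side of the acceptance window as a fraction of
#'   the patch side.
#' @param max_border_frac components covering at least this fraction of the
#'   patch-border pixels are excluded.
#' @return a `region_mask` (see [region_stats()]), or NULL when no component
#'   qualifies (a no-detection, not an error).
#' @export
select_stomate_region <- function(mask, central_fraction = 0.5,
                                  max_border_frac = 0.25) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) return(NULL)
  h <- nrow(mask); w <- ncol(mask)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  half_h <- central_fraction * h / 2; half_w <- central_fraction * w / 2
  border_ids <- c(lab[1, ], lab[h, ], lab[, 1], lab[, w])
  best <- NULL; best_area <- -1; best_d <- Inf
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    cen <- colMeans(idx)
    if (abs(cen[1] - ctr[1]) > half_h || abs(cen[2] - ctr[2]) > half_w) next
    if (mean(border_ids == i) >= max_border_frac) next
    a <- nrow(idx)
    d <- sqrt(sum((cen - ctr)^2))
    if (a > best_area || (a == best_area && d < best_d)) {
      best <- i; best_area <- a; best_d <- d
    }
  }
  if (is.null(best)) return(NULL)
  region_stats(lab == best)
}

#' Rotate a patch so the stomate's major axis is horizontal
#'
#' Both the grayscale patch (bilinear) and the mask (nearest-neighbour) are
#' rotated by minus the mask's major-axis orientation, with canvas expansion
#' so nothing is cropped. Nearly circular masks (axis ratio below 1.05) have
#' no meaningful axis and are passed through unrotated. The grayscale
#' background fill is the patch mean, which is far from both pore
#' intensities and so cannot be absorbed into the grown pore region.
#'
#' @param gray grayscale matrix (typically the [enhance()] output).
#' @param region a `region_mask` from [select_stomate_region()].
#' @return list: `gray` and `region` in the rotated frame, `angle` (the
#'   orientation that was removed, degrees), and `transform` for mapping
#'   results back (NULL when rotation was skipped).
#' @export
align_to_major_axis <- function(gray, region) {
  if (region$axis_ratio < 1.05)
    return(list(gray = gray, region = region, angle = 0, transform = NULL))
  ang <- region$orientation
  rg <- rotate_raster(gray, -ang, filter = "bilinear", bg = mean(gray))
  rm <- rotate_raster(region$mask * 1, -ang, filter = "nearest", bg = 0)
  mask_rot <- rm$pixels > 0.5
  # nearest-neighbour rotation can nick a thin region apart; keep the core
  lab <- label_components(mask_rot)
  if (max(lab) > 1) {
    areas <- tabulate(lab[lab > 0], max(lab))
    mask_rot <- lab == which.max(areas)
  }
  list(gray = rg$pixels, region = region_stats(mask_rot), angle = ang,
       transform = rg$transform)
}

#' Vertical cross-section through the mask centroid
#'
#' Reads the intensity profile down the image column through the aligned
#' mask's centroid, clipped to the mask's vertical extent padded by 2 px.
#' The profile is smoothed with a centred moving average before strict local
#' extrema are detected; extrema must have topographic prominence of at
#' least `prominence_frac` of the smoothed profile's range.
#'
#' @param gray aligned grayscale matrix.
#' @param region aligned `region_mask`.
#' @param smooth_window moving-average window (odd, default 3).
#' @param prominence_frac minimum prominence as a fraction of profile range.
#' @return object of class `cross_section_profile` with fields `values`
#'   (raw), `smoothed`, `peaks`, `valleys`, `prominence` (named by index),
#'   `centroid_index`, `row_offset` and `col`; or NULL when the profile has
#'   fewer than 5 samples (a no-detection).
#' @export
cross_section <- function(gray, region, smooth_window = 3,
                          prominence_frac = 0.05) {
  cc <- round(region$centroid[["col"]])
  cc <- min(max(cc, 1), ncol(gray))
  rows_in <- which(apply(region$mask, 1, any))
  r0 <- max(min(rows_in) - 2, 1)
  r1 <- min(max(rows_in) + 2, nrow(gray))
  if (r1 - r0 + 1 < 5) return(NULL)
  v <- gray[r0:r1, cc]
  s <- moving_average(v, smooth_window)
  ex <- local_extrema(s, prominence_frac * (max(s) - min(s)))
  structure(list(values = v, smoothed = s,
                 peaks = ex$peaks, valleys = ex$valleys,
                 prominence = ex$prominence,
                 centroid_index = round(region$centroid[["row"]]) - r0 + 1,
                 row_offset = r0, col = cc),
            class = "cross_section_profile")
}

# centred moving average; ends use the samples available in the window
moving_average <- function(v, window = 3) {
  half <- window %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - half):min(n, i + half)]), numeric(1))
}

# local extrema with topographic prominence. Equal-value runs are compressed
# first so a flat-bottomed pore still registers: a run strictly above (below)
# both neighbouring runs is one peak (valley) at the run's centre sample.
# Prominence of a peak: walk out on each side until a strictly higher sample
# (or the end); the peak height above the higher of the two interval minima.
local_extrema <- function(s, min_prominence) {
  r <- rle(s)
  nr <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peaks <- integer(0); valleys <- integer(0)
  prom <- numeric(0); prom_idx <- integer(0)
  if (nr >= 3) {
    for (j in 2:(nr - 1)) {
      is_peak <- r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]
      is_valley <- r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1]
      if (!is_peak && !is_valley) next
      i <- floor((starts[j] + ends[j]) / 2)
      p <- prominence_at(s, i, peak = is_peak)
      if (p < min_prominence) next
      if (is_peak) peaks <- c(peaks, i) else valleys <- c(valleys, i)
      prom <- c(prom, p); prom_idx <- c(prom_idx, i)
    }
  }
  names(prom) <- as.character(prom_idx)
  list(peaks = peaks, valleys = valleys, prominence = prom)
}

prominence_at <- function(s, i, peak) {
  v <- if (peak) s else -s
  n <- length(v)
  left <- i; lmin <- v[i]
  while (left > 1 && v[left - 1] <= v[i]) {
    left <- left - 1; lmin <- min(lmin, v[left])
  }
  right <- i; rmin <- v[i]
  while (right < n && v[right + 1] <= v[i]) {
    right <- right + 1; rmin <- min(rmin, v[right])
  }
  v[i] - max(lmin, rmin)
}

#' Locate the pore centre on a cross-section profile
#'
#' The extremum nearest the mask centroid is the pore centre: a peak means
#' the pore is lighter than its surroundings, a valley that it is darker.
#' When a peak and a valley are equally close, the more prominent one wins;
#' if still tied, the valley (dark pores being the common case in focused
#' imprints).
#'
#' @param profile a `cross_section_profile`.
#' @return list with `index` (into the profile), `row` (absolute image row),
#'   `col`, and `polarity` (`"dark"` or `"light"`); or NULL when the profile
#'   has no extrema (a no-detection).
#' @export
find_pore_center <- function(profile) {
  if (is.null(profile)) return(NULL)
  cand <- rbind(
    if (length(profile$peaks))
      data.frame(index = profile$peaks, polarity = "light"),
    if (length(profile$valleys))
      data.frame(index = profile$valleys, polarity = "dark"))
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  cand$dist <- abs(cand$index - profile$centroid_index)
  cand$prom <- profile$prominence[as.character(cand$index)]
  cand <- cand[order(cand$dist, -cand$prom, cand$polarity != "dark"), ]
  best <- cand[1, ]
  list(index = best$index,
       row = profile$row_offset + best$index - 1,
       col = profile$col,
       polarity = best$polarity)
}

#' Grow the pore region from its centre
#'
#' Flood fill under 8-connectivity from the seed pixel, accepting a pixel
#' iff its intensity differs from the seed's by at most `tol_abs`. The
#' result is the single connected component containing the seed.
#'
#' @param gray grayscale matrix.
#' @param seed `c(row, col)` seed pixel.
#' @param tol_abs absolute intensity tolerance.
#' @return logical pore mask.
#' @export
grow_pore <- function(gray, seed, tol_abs) {
  stopifnot(seed[1] >= 1, seed[1] <= nrow(gray),
            seed[2] >= 1, seed[2] <= ncol(gray))
  cand <- abs(gray - gray[seed[1], seed[2]]) <= tol_abs
  lab <- label_components(cand)
  lab == lab[seed[1], seed[2]]
}

#' Estimate the pore area of one stomate patch
#'
#' Runs the full measurement chain (see [pore_measure]) and returns a
#' `pore_estimate`. A stage that cannot proceed (constant patch, no region
#' near the centre, no cross-section extrema, too-short profile) yields
#' status `"no_detection"`; a grown pore that fails a sanity check yields
#' `"rejected"` with a reason:
#' * `pore_touches_border` — the pore covers half or more of the patch
#'   border (region growing escaped the stomate);
#' * `pore_larger_than_stomate` — pore area exceeds the (hole-filled)
#'   stomate mask area;
#' * `pore_outside_stomate` — the pore centroid lies outside the hole-filled
#'   stomate mask. The filled mask is used because for a light pore the
#'   binarised stomate is the dark guard-cell annulus, which never contains
#'   the pore centre itself.
#'
#' @param patch a `pore_patch` from [crop_patch()], or a grayscale matrix
#'   (then `pixel_scale` is taken from `config`).
#' @param config a [stoma_config()].
#' @return object of class `pore_estimate`: `status` (accepted /
#'   no_detection / rejected), `pore_mask` in the original patch frame,
#'   `area_px`, `area_um2` (`= area_px * pixel_scale^2`), `polarity`,
#'   `orientation` (degrees), `reason`, and the diagnostic `profile`.
#' @export
estimate_pore <- function(patch, config = stoma_config()) {
  if (!inherits(patch, "pore_patch")) {
    px <- as_gray(patch)
    patch <- structure(list(pixels = px,
                            center = c(row = (nrow(px) + 1) / 2,
                                       col = (ncol(px) + 1) / 2),
                            pixel_scale = config$pixel_scale,
                            offset = c(row = 0, col = 0)),
                       class = "pore_patch")
  }
  scale2 <- patch$pixel_scale^2
  # brightfield imprints have a bright background; a majority-dark patch is
  # a negative. Canonicalise so processing is identical either way and map
  # the reported polarity back to the input's frame.
  inverted <- mean(patch$pixels) < 127.5
  if (inverted) patch$pixels <- 255 - patch$pixels
  flip_pol <- function(p) {
    if (!inverted || p %in% "none") p
    else if (p == "dark") "light" else "dark"
  }
  fail <- function(status, reason = NULL, polarity = "none", profile = NULL)
    structure(list(status = status, pore_mask = NULL, area_px = NA_real_,
                   area_um2 = NA_real_, polarity = flip_pol(polarity),
                   orientation = NA_real_, reason = reason,
                   profile = profile),
              class = "pore_estimate")

  g <- tryCatch(enhance(patch, config$clahe_clip, config$clahe_tiles,
                        config$sharpen_radius, config$sharpen_amount),
                stomapore_degenerate = function(e) NULL)
  if (is.null(g) || length(g) < 25) return(fail("no_detection", "degenerate_patch"))
  thr <- tryCatch(otsu_threshold(g),
                  stomapore_degenerate = function(e) NULL)
  if (is.null(thr)) return(fail("no_detection", "constant_patch"))
  # the stomate is a minority structure in its patch, so take whichever
  # Otsu class covers less area as foreground; this keeps the selection
  # symmetric under intensity inversion (dark and light pores alike)
  dark <- g <= thr
  binary <- if (sum(dark) <= length(dark) / 2) dark else !dark
  filtered <- filter_regions(binary, config$min_area_px)
  region <- select_stomate_region(filtered, config$central_fraction)
  if (is.null(region)) return(fail("no_detection", "no_central_region"))
  aligned <- align_to_major_axis(g, region)
  profile <- cross_section(aligned$gray, aligned$region,
                           config$smooth_window, config$prominence_frac)
  if (is.null(profile)) return(fail("no_detection", "profile_too_short"))
  center <- find_pore_center(profile)
  if (is.null(center)) return(fail("no_detection", "no_extrema",
                                   profile = profile))
  # tolerance scales with the chosen extremum's own prominence (its depth
  # against the guard-cell shoulders): at the 0.5 default this is half-depth
  # segmentation, which tracks the pore boundary even when blur turns the
  # pore edge into a gradient
  tol <- config$tolerance_frac *
    profile$prominence[[as.character(center$index)]]
  pore_rot <- grow_pore(aligned$gray, c(center$row, center$col), tol)

  # sanity checks in the rotated frame
  h <- nrow(pore_rot); w <- ncol(pore_rot)
  border <- c(pore_rot[1, ], pore_rot[h, ], pore_rot[, 1], pore_rot[, w])
  if (mean(border) >= 0.5)
    return(fail("rejected", "pore_touches_border", center$polarity, profile))
  stomate_filled <- fill_hull(aligned$region$mask)
  if (sum(pore_rot) > sum(stomate_filled))
    return(fail("rejected", "pore_larger_than_stomate", center$polarity,
                profile))
  pc <- round(colMeans(which(pore_rot, arr.ind = TRUE)))
  if (!stomate_filled[pc[1], pc[2]])
    return(fail("rejected", "pore_outside_stomate", center$polarity, profile))

  pore_mask <- if (is.null(aligned$transform)) pore_rot
               else unrotate_mask(pore_rot, aligned$transform)
  # back-rotation resamples; keep the seed's component
  lab <- label_components(pore_mask)
  if (max(lab) > 1) {
    areas <- tabulate(lab[lab > 0], max(lab))
    pore_mask <- lab == which.max(areas)
  }
  area_px <- sum(pore_mask)
  if (area_px < 1)
    return(fail("rejected", "empty_pore_after_back_rotation",
                center$polarity, profile))
  structure(list(status = "accepted", pore_mask = pore_mask,
                 area_px = area_px, area_um2 = area_px * scale2,
                 polarity = flip_pol(center$polarity),
                 orientation = aligned$angle,
                 reason = NULL, profile = profile),
            class = "pore_estimate")
}

#' @export
print.pore_estimate <- function(x, ...) {
  if (x$status == "accepted") {
    cat(sprintf("<pore_estimate> accepted: %s pore, %d px (%.2f um^2), orientation %.1f deg\n",
                x$polarity, x$area_px, x$area_um2, x$orientation))
  } else {
    cat(sprintf("<pore_estimate> %s (%s)\n", x$status,
                if (is.null(x$reason)) "" else x$reason))
  }
  invisible(x)
}

#' Measure the pores of all detected stomata in a scan
#'
#' @param image a [scan_image()].
#' @param boxes data frame of detection boxes from [detect_stomata()].
#' @param config a [stoma_config()].
#' @return list of `pore_estimate` objects, one per box.
#' @export
measure_pores <- function(image, boxes, config = stoma_config()) {
  lapply(seq_len(nrow(boxes)), function(i)
    estimate_pore(crop_patch(image, boxes[i, ], config$patch_expand), config))
}
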