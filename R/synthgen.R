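#' Specification for a synthetic micrograph scene
#'
#' Describes everything the generator randomises, so a scene is a pure
#' function of its spec (including the seed). The rendered phenomenology
#' mirrors brightfield leaf-imprint scans: elliptical stomata whose central
#' pore is darker or lighter than the guard cells depending on focus,
#' elongated dark veins, a low-contrast polygonal epidermal-cell background,
#' small dust/bubble artifacts, spatially varying blur and pixel noise.
#'
#' @param height,width canvas size in px.
#' @param n_stomata number of stomata to place (no overlap).
#' @param axis_len_range major-axis length range in px (full axis).
#' @param aspect_range minor/major axis ratio range.
#' @param polarity_mix fraction of stomata rendered with a light pore.
#' @param blur_sigma_range spatially varying Gaussian blur sigma range (px);
#'   `c(0, 0)` disables blur.
#' @param vein_density veins per megapixel.
#' @param artifact_rate dust/bubble blobs per megapixel.
#' @param background_cell_scale epidermal-cell size in px.
#' @param levels named list of intensity levels: `background`, `guard`,
#'   `inner` (guard-cell interior around the pore), `pore_dark`,
#'   `pore_light`.
#' @param pore_scale pore lens size as a fraction of the inner-ellipse axes.
#' @param noise_sd additive Gaussian pixel noise sigma (intensity levels).
#' @param pixel_scale microns per pixel.
#' @param seed integer RNG seed.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(height = 512, width = 512, n_stomata = 8,
                       axis_len_range = c(24, 56),
                       aspect_range = c(0.45, 0.65),
                       polarity_mix = 0.5,
                       blur_sigma_range = c(0.5, 1.5),
                       vein_density = 4, artifact_rate = 8,
                       background_cell_scale = 80,
                       levels = list(background = 180, guard = 140,
                                     inner = 165, pore_dark = 70,
                                     pore_light = 230),
                       pore_scale = 0.5, noise_sd = 3,
                       pixel_scale = 0.25, seed = 1) {
  stopifnot(height >= 32, width >= 32, n_stomata >= 0,
            axis_len_range[1] <= axis_len_range[2],
            aspect_range[1] <= aspect_range[2],
            polarity_mix >= 0, polarity_mix <= 1,
            blur_sigma_range[1] <= blur_sigma_range[2],
            pore_scale > 0, pore_scale < 1)
  structure(as.list(environment()), class = "scene_spec")
}

#' Generate a synthetic micrograph scene with ground truth
#'
#' Renders, in order: the epidermal-cell background, veins, artifacts, then
#' the stomata (each via [render_stomate()]); blur and noise are applied
#' last, after the ground-truth masks are recorded, so the masks stay exact.
#' Stomata are placed by rejection sampling with pairwise centre distances
#' of at least the larger of the two major-axis lengths.
#'
#' @param spec a [scene_spec()].
#' @return object of class `ground_truth_scene`: `image` (a [scan_image()]),
#'   `stomata` (per-stomate list: `center`, `axes`, `angle`, `polarity`,
#'   `bbox`, and `pore_mask` / `stomate_mask` cropped to `bbox`),
#'   `stomate_mask` and `vein_mask` (global logical matrices), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  h <- spec$height; w <- spec$width
  lv <- spec$levels
  canvas <- render_background(h, w, spec$background_cell_scale,
                              lv$background)
  vein_mask <- matrix(FALSE, h, w)
  n_veins <- round(spec$vein_density * h * w / 1e6)
  if (n_veins > 0) for (i in seq_len(n_veins)) {
    vm <- render_vein(h, w)
    canvas[vm] <- lv$background - 45
    vein_mask <- vein_mask | vm
  }
  n_art <- round(spec$artifact_rate * h * w / 1e6)
  if (n_art > 0) for (i in seq_len(n_art)) {
    am <- disk_mask(h, w, c(runif(1, 1, h), runif(1, 1, w)), runif(1, 2, 5))
    canvas[am] <- sample(c(60, 240), 1)
  }

  # place stomata by rejection sampling
  placed <- list()
  attempts <- 0; max_attempts <- 500 * max(spec$n_stomata, 1)
  while (length(placed) < spec$n_stomata) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("placement error: could not place ", spec$n_stomata,
           " stomata after ", max_attempts,
           " attempts; use a larger canvas or fewer stomata")
    major <- runif(1, spec$axis_len_range[1], spec$axis_len_range[2])
    minor <- major * runif(1, spec$aspect_range[1], spec$aspect_range[2])
    margin <- major / 2 + 6
    if (2 * margin >= min(h, w)) next
    ctr <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    ok <- TRUE
    for (p in placed) {
      min_sep <- max(major, p$axes[1])
      if (sqrt(sum((ctr - p$center)^2)) < min_sep) { ok <- FALSE; break }
    }
    if (!ok) next
    placed[[length(placed) + 1]] <- list(
      center = ctr, axes = c(major, minor),
      angle = runif(1, -90, 90),
      polarity = if (runif(1) < spec$polarity_mix) "light" else "dark")
  }

  stomate_mask <- matrix(FALSE, h, w)
  stomata <- vector("list", length(placed))
  for (i in seq_along(placed)) {
    p <- placed[[i]]
    r <- render_stomate(canvas, p$center, p$axes, p$angle, p$polarity,
                        lv, spec$pore_scale)
    canvas <- r$canvas
    stomate_mask <- stomate_mask | r$stomate_mask
    pad <- 2
    r0 <- max(floor(p$center[1] - p$axes[1] / 2) - pad, 0)
    c0 <- max(floor(p$center[2] - p$axes[1] / 2) - pad, 0)
    r1 <- min(ceiling(p$center[1] + p$axes[1] / 2) + pad, h)
    c1 <- min(ceiling(p$center[2] + p$axes[1] / 2) + pad, w)
    stomata[[i]] <- list(
      center = p$center, axes = p$axes, angle = p$angle,
      polarity = p$polarity, bbox = c(r0, c0, r1, c1),
      pore_mask = r$pore_mask[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE],
      stomate_mask = r$stomate_mask[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE])
  }
  vein_mask <- vein_mask & !stomate_mask

  canvas <- apply_spatial_blur(canvas, spec$blur_sigma_range)
  if (spec$noise_sd > 0)
    canvas <- canvas + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  canvas <- round(pmin(pmax(canvas, 0), 255))

  structure(list(
    image = scan_image(canvas, spec$pixel_scale,
                       sprintf("synthetic-seed%d", spec$seed)),
    stomata = stomata, stomate_mask = stomate_mask, vein_mask = vein_mask,
    spec = spec), class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("<ground_truth_scene> %dx%d, %d stomata, seed %d\n",
              x$spec$height, x$spec$width, length(x$stomata), x$spec$seed))
  invisible(x)
}

#' Render one stomate onto a canvas
#'
#' The guard-cell complex is a filled outer ellipse; the annulus between
#' the outer and an inner ellipse (80% axes) takes the guard intensity and
#' the inner-ellipse interior a slightly lighter tone. The pore is a
#' lens — the intersection of two circles offset along the minor axis —
#' sized `pore_scale` of the inner axes, rendered darker (dark polarity) or
#' lighter (light polarity) than the guard cells. Masks are returned
#' exactly as rasterised, before any blur or noise.
#'
#' @param canvas numeric matrix to draw on.
#' @param center `c(row, col)`.
#' @param axes `c(major, minor)` full axis lengths in px.
#' @param angle major-axis angle in degrees from horizontal.
#' @param polarity `"dark"` or `"light"`.
#' @param levels intensity levels (see [scene_spec()]).
#' @param pore_scale pore lens size as a fraction of the inner axes.
#' @return list: updated `canvas`, logical `pore_mask` and `stomate_mask`
#'   (full canvas size).
#' @export
render_stomate <- function(canvas, center, axes, angle, polarity, levels,
                           pore_scale = 0.5) {
  h <- nrow(canvas); w <- ncol(canvas)
  a <- axes[1] / 2; b <- axes[2] / 2
  rad <- a + 1
  if (center[1] - rad < 0 || center[1] + rad > h + 1 ||
      center[2] - rad < 0 || center[2] + rad > w + 1)
    stop("geometry error: stomate ellipse does not fit in canvas")
  r0 <- max(floor(center[1] - rad), 1); r1 <- min(ceiling(center[1] + rad), h)
  c0 <- max(floor(center[2] - rad), 1); c1 <- min(ceiling(center[2] + rad), w)
  rr <- r0:r1; cc <- c0:c1
  y <- matrix(rr - center[1], length(rr), length(cc))
  x <- matrix(cc - center[2], length(rr), length(cc), byrow = TRUE)
  th <- angle * pi / 180
  u <- cos(th) * x + sin(th) * y   # along major axis
  v <- -sin(th) * x + cos(th) * y  # along minor axis
  outer_e <- (u / a)^2 + (v / b)^2 <= 1
  a_in <- 0.8 * a; b_in <- 0.8 * b
  inner_e <- (u / a_in)^2 + (v / b_in)^2 <= 1
  wl <- pore_scale * a_in; hl <- pore_scale * b_in
  R <- (hl + wl^2 / hl) / 2; d <- R - hl
  lens <- (u^2 + (v - d)^2 <= R^2) & (u^2 + (v + d)^2 <= R^2)

  sub <- canvas[rr, cc]
  sub[outer_e & !inner_e] <- levels$guard
  sub[inner_e & !lens] <- levels$inner
  sub[lens] <- if (polarity == "dark") levels$pore_dark else levels$pore_light
  canvas[rr, cc] <- sub
  pore_mask <- matrix(FALSE, h, w); pore_mask[rr, cc] <- lens
  stomate_mask <- matrix(FALSE, h, w); stomate_mask[rr, cc] <- outer_e
  list(canvas = canvas, pore_mask = pore_mask, stomate_mask = stomate_mask)
}

# closed-form area of the pore lens used by render_stomate: intersection of
# two circles of radius R whose centres are 2d apart, with half-length
# wl = sqrt(R^2 - d^2) and half-height hl = R - d
lens_area <- function(wl, hl) {
  R <- (hl + wl^2 / hl) / 2; d <- R - hl
  2 * R^2 * acos(d / R) - 2 * d * wl
}

# low-contrast polygonal epidermal texture: jittered-grid Voronoi cells,
# darker borders where the two nearest seeds are nearly equidistant
render_background <- function(h, w, cell_scale, base_level) {
  s <- cell_scale
  gi <- seq(-1, ceiling(h / s)); gj <- seq(-1, ceiling(w / s))
  seeds_r <- outer(gi, gj * 0) * s + s / 2 +
    matrix(runif(length(gi) * length(gj), -s / 3, s / 3), length(gi))
  seeds_c <- outer(gi * 0, gj) * s + s / 2 +
    matrix(runif(length(gi) * length(gj), -s / 3, s / 3), length(gi))
  tone <- matrix(runif(length(gi) * length(gj), -5, 5), length(gi))
  out <- matrix(base_level, h, w)
  for (bi in seq_along(gi)) {
    if (gi[bi] < 0 || gi[bi] * s >= h) next
    for (bj in seq_along(gj)) {
      if (gj[bj] < 0 || gj[bj] * s >= w) next
      rr <- (gi[bi] * s + 1):min((gi[bi] + 1) * s, h)
      cc <- (gj[bj] * s + 1):min((gj[bj] + 1) * s, w)
      ni <- max(bi - 2, 1):min(bi + 2, length(gi))
      nj <- max(bj - 2, 1):min(bj + 2, length(gj))
      py <- matrix(rr, length(rr), length(cc))
      px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      d1 <- matrix(Inf, length(rr), length(cc))
      d2 <- d1; t1 <- matrix(0, length(rr), length(cc))
      for (i in ni) for (j in nj) {
        dd <- sqrt((py - seeds_r[i, j])^2 + (px - seeds_c[i, j])^2)
        closer <- dd < d1
        d2[closer] <- d1[closer]
        second <- !closer & dd < d2
        d2[second] <- dd[second]
        d1[closer] <- dd[closer]
        t1[closer] <- tone[i, j]
      }
      block <- base_level + t1
      # epidermal outlines are faint in brightfield imprints — much lighter
      # than guard cells, so they must not read as stomate-grade structure
      block[d2 - d1 < 1.6] <- base_level - 8
      out[rr, cc] <- block
    }
  }
  out
}

# one curved dark stroke: quadratic Bezier between two random border points
render_vein <- function(h, w) {
  side <- sample(1:4, 2)
  pt_on <- function(k) switch(k,
    c(1, runif(1, 1, w)), c(h, runif(1, 1, w)),
    c(runif(1, 1, h), 1), c(runif(1, 1, h), w))
  p0 <- pt_on(side[1]); p2 <- pt_on(side[2])
  p1 <- c(runif(1, h * 0.2, h * 0.8), runif(1, w * 0.2, w * 0.8))
  t <- seq(0, 1, length.out = round(1.5 * (h + w)))
  pr <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  pc <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  width <- runif(1, 2, 4)
  off <- expand.grid(dr = -ceiling(width):ceiling(width),
                     dc = -ceiling(width):ceiling(width))
  off <- off[off$dr^2 + off$dc^2 <= width^2, ]
  rr <- round(rep(pr, each = nrow(off)) + off$dr)
  cc <- round(rep(pc, each = nrow(off)) + off$dc)
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  m <- matrix(FALSE, h, w)
  m[cbind(rr[ok], cc[ok])] <- TRUE
  m
}

disk_mask <- function(h, w, center, radius) {
  r0 <- max(floor(center[1] - radius), 1)
  r1 <- min(ceiling(center[1] + radius), h)
  c0 <- max(floor(center[2] - radius), 1)
  c1 <- min(ceiling(center[2] + radius), w)
  m <- matrix(FALSE, h, w)
  if (r1 < r0 || c1 < c0) return(m)
  rr <- r0:r1; cc <- c0:c1
  y <- matrix(rr - center[1], length(rr), length(cc))
  x <- matrix(cc - center[2], length(rr), length(cc), byrow = TRUE)
  m[rr, cc] <- y^2 + x^2 <= radius^2
  m
}

# spatially varying blur: a smooth random sigma field (coarse 4x4 grid,
# bilinearly upsampled) blends two Gaussian-blurred anchors of the image
apply_spatial_blur <- function(canvas, sigma_range) {
  lo <- sigma_range[1]; hi <- sigma_range[2]
  if (hi <= 0.05) return(canvas)
  gb <- function(m, s) {
    if (s <= 0.05) return(m)
    t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m) / 255),
                                        sigma = s))) * 255
  }
  if (hi - lo < 0.05) return(gb(canvas, hi))
  h <- nrow(canvas); w <- ncol(canvas)
  coarse <- matrix(runif(16, lo, hi), 4, 4)
  field <- bilinear_upsample(coarse, h, w)
  tt <- (field - lo) / (hi - lo)
  (1 - tt) * gb(canvas, lo) + tt * gb(canvas, hi)
}

bilinear_upsample <- function(m, h, w) {
  ry <- seq(1, nrow(m), length.out = h)
  rx <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(ry), nrow(m) - 1); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(m) - 1); fx <- rx - x0
  m00 <- m[y0, x0]; m01 <- m[y0, x0 + 1]
  m10 <- m[y0 + 1, x0]; m11 <- m[y0 + 1, x0 + 1]
  fyM <- matrix(fy, h, w); fxM <- matrix(fx, h, w, byrow = TRUE)
  (1 - fyM) * ((1 - fxM) * m00 + fxM * m01) +
    fyM * ((1 - fxM) * m10 + fxM * m11)
}

#' Cut a ground-truth-aligned patch around one stomate
#'
#' Convenience for validation: crops a square patch of side `side` centred
#' on stomate `i` and returns the image pixels together with the true pore
#' and stomate masks in patch coordinates.
#'
#' @param scene a `ground_truth_scene`.
#' @param i stomate index.
#' @param side patch side in px. The default, twice the major axis plus
#'   8 px, matches the patches the pipeline itself cuts (a padded
#'   detection box expanded by its crop margin).
#' @return list with `patch` (a `pore_patch`), `true_pore`, `true_stomate`
#'   (logical matrices in patch frame) and `polarity`.
#' @export
scene_patch <- function(scene, i, side = NULL) {
  st <- scene$stomata[[i]]
  if (is.null(side)) side <- round(2 * st$axes[1]) + 8
  h <- nrow(scene$image$pixels); w <- ncol(scene$image$pixels)
  r0 <- max(round(st$center[1] - side / 2), 0)
  c0 <- max(round(st$center[2] - side / 2), 0)
  r1 <- min(r0 + side, h); c1 <- min(c0 + side, w)
  px <- as_gray(scene$image)[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  crop_from_bbox <- function(mask_cropped, bbox) {
    full <- matrix(FALSE, h, w)
    full[(bbox[1] + 1):bbox[3], (bbox[2] + 1):bbox[4]] <- mask_cropped
    full[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  }
  list(patch = structure(list(pixels = px,
                              center = c(row = (nrow(px) + 1) / 2,
                                         col = (ncol(px) + 1) / 2),
                              pixel_scale = scene$image$pixel_scale,
                              offset = c(row = r0, col = c0)),
                         class = "pore_patch"),
       true_pore = crop_from_bbox(st$pore_mask, st$bbox),
       true_stomate = crop_from_bbox(st$stomate_mask, st$bbox),
       polarity = st$polarity)
}

#' Sample labelled training patches from a scene
#'
#' Stomate patches are centred on ground-truth stomata (with a small random
#' jitter); vein patches on vein-mask pixels away from stomata. Background
#' patches contain no stomate pixels at all and keep their central
#' `center_clear` cell free of veins, but — deliberately — half of them are
#' centred a short distance off a vein so the vein clips the window
#' off-centre. These hard negatives teach the classifier that a structure
#' away from the window centre is not a detection, which is what makes
#' sliding-window localisation crisp. Sampling is seeded and returns exactly
#' `n_per_class` patches per class.
#'
#' @param scene a `ground_truth_scene`.
#' @param window_size patch side in px.
#' @param n_per_class patches per class.
#' @param seed RNG seed.
#' @param center_clear side of the central cell (px) that background windows
#'   keep free of vein pixels.
#' @return list of labelled patches: `pixels` (window-sized matrix),
#'   `label`, and `center` (row, col in the scene).
#' @export
make_training_patches <- function(scene, window_size = 96, n_per_class = 50,
                                  seed = 1, center_clear = 24) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  g <- as_gray(scene$image)
  h <- nrow(g); w <- ncol(g)
  half <- window_size / 2
  if (length(scene$stomata) == 0)
    stop("generation error: scene has no stomata")
  if (!any(scene$vein_mask))
    stop("generation error: scene has no veins")
  clamp <- function(v, lohi) pmin(pmax(v, lohi[1]), lohi[2])
  patch_at <- function(cr, cc, label) {
    r0 <- round(cr - half); c0 <- round(cc - half)
    list(pixels = g[(r0 + 1):(r0 + window_size),
                    (c0 + 1):(c0 + window_size)],
         label = label, center = c(row = cr, col = cc))
  }
  # stomate: centres + jitter, window kept inside the canvas
  ctrs <- t(vapply(scene$stomata, `[[`, numeric(2), "center"))
  pick <- sample(nrow(ctrs), n_per_class, replace = TRUE)
  jit <- matrix(runif(2 * n_per_class, -window_size / 8, window_size / 8),
                ncol = 2)
  sto <- lapply(seq_len(n_per_class), function(k)
    patch_at(clamp(ctrs[pick[k], 1] + jit[k, 1], c(half, h - half)),
             clamp(ctrs[pick[k], 2] + jit[k, 2], c(half, w - half)),
             "stomate"))
  # vein: vein pixels far enough from every stomate that the window is clean
  vidx_all <- which(scene$vein_mask, arr.ind = TRUE)
  vidx <- vidx_all[vidx_all[, 1] > half & vidx_all[, 1] <= h - half &
                   vidx_all[, 2] > half & vidx_all[, 2] <= w - half, ,
                   drop = FALSE]
  if (nrow(vidx) > 0) {
    clear <- rep(TRUE, nrow(vidx))
    for (st in scene$stomata) {
      dd <- sqrt((vidx[, 1] - st$center[1])^2 + (vidx[, 2] - st$center[2])^2)
      clear <- clear & dd > (half * sqrt(2) + st$axes[1] / 2)
    }
    vidx <- vidx[clear, , drop = FALSE]
  }
  if (nrow(vidx) < 1)
    stop("generation error: no vein pixels admit a clean window")
  vpick <- vidx[sample(nrow(vidx), n_per_class, replace = TRUE), ,
                drop = FALSE]
  vei <- lapply(seq_len(n_per_class), function(k)
    patch_at(vpick[k, 1], vpick[k, 2], "vein"))
  # background: zero stomate pixels, central cell clear of veins
  s_int <- integral_image(scene$stomate_mask)
  v_int <- integral_image(scene$vein_mask)
  q <- (window_size - center_clear) %/% 2
  valid_bg <- function(cr, cc) {
    r0 <- round(cr - half); c0 <- round(cc - half)
    cr >= half && cr <= h - half && cc >= half && cc <= w - half &&
      window_sum(s_int, r0, c0, window_size) == 0 &&
      window_sum(v_int, r0 + q, c0 + q, center_clear) == 0
  }
  bg <- list(); tries <- 0
  n_veinside <- n_per_class %/% 2
  while (length(bg) < n_veinside && tries < 400 * n_per_class) {
    tries <- tries + 1
    vp <- vidx_all[sample(nrow(vidx_all), 1), ]
    ang <- stats::runif(1, 0, 2 * pi)
    rr <- stats::runif(1, center_clear, half - 8)
    cr <- vp[1] + rr * sin(ang); cc <- vp[2] + rr * cos(ang)
    if (valid_bg(cr, cc))
      bg[[length(bg) + 1]] <- patch_at(cr, cc, "background")
  }
  tries <- 0
  while (length(bg) < n_per_class && tries < 400 * n_per_class) {
    tries <- tries + 1
    cr <- stats::runif(1, half, h - half)
    cc <- stats::runif(1, half, w - half)
    if (valid_bg(cr, cc))
      bg[[length(bg) + 1]] <- patch_at(cr, cc, "background")
  }
  if (length(bg) < n_per_class)
    stop("generation error: could not sample ", n_per_class,
         " clean background windows")
  c(sto, vei, bg)
}

integral_image <- function(mask) {
  apply(apply(mask * 1, 2, cumsum), 1, cumsum) |> t()
}

# sum of mask over rows r0+1..r0+n, cols c0+1..c0+n (0-based offsets)
window_sum <- function(int, r0, c0, n) {
  at <- function(r, c) if (r < 1 || c < 1) 0 else int[r, c]
  at(r0 + n, c0 + n) - at(r0, c0 + n) - at(r0 + n, c0) + at(r0, c0)
}
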