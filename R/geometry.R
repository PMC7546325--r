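#' @title Raster geometry helpers: rotation, labelling, region statistics
#' @name geometry
#' @keywords internal
NULL

# Rotation convention used throughout: angles are degrees measured from the
# horizontal (column) axis with rows increasing downwards, range (-90, 90].
# rotate_raster(m, a) moves image content so that a structure oriented at
# angle -a becomes horizontal; equivalently the major-axis angle of a region
# increases by a. Alignment therefore rotates by -orientation.

#' Rotate a raster about its centre with canvas expansion
#'
#' Inverse-mapping affine warp. The output canvas is enlarged so no pixel of
#' the input is cropped; pixels falling outside the input take value `bg`.
#'
#' @param m numeric matrix (rows x cols).
#' @param angle_deg rotation in degrees (see convention above).
#' @param filter `"bilinear"` for intensity images, `"nearest"` for masks.
#' @param bg fill value for out-of-canvas samples.
#' @return list with `pixels` (the rotated matrix) and `transform`, the
#'   information needed by [unrotate_coords()] / [unrotate_mask()].
#' @keywords internal
rotate_raster <- function(m, angle_deg, filter = c("bilinear", "nearest"),
                          bg = 0) {
  filter <- match.arg(filter)
  h <- nrow(m); w <- ncol(m)
  t_rad <- angle_deg * pi / 180
  ct <- cos(t_rad); st <- sin(t_rad)
  # extents of the rotated corner offsets
  hw <- (w - 1) / 2; hh <- (h - 1) / 2
  xs <- c(-hw, hw, -hw, hw); ys <- c(-hh, -hh, hh, hh)
  xr <- ct * xs - st * ys; yr <- st * xs + ct * ys
  W <- ceiling(2 * max(abs(xr))) + 1
  H <- ceiling(2 * max(abs(yr))) + 1
  cin <- c((h + 1) / 2, (w + 1) / 2)
  cout <- c((H + 1) / 2, (W + 1) / 2)

  # inverse map: output offset q -> input offset p = R(-angle) q
  yo <- rep(seq_len(H), times = W) - cout[1]
  xo <- rep(seq_len(W), each = H) - cout[2]
  xs <- ct * xo + st * yo + cin[2]
  ys <- -st * xo + ct * yo + cin[1]

  out <- if (filter == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    v <- rep(bg, H * W)
    v[ok] <- m[cbind(yi[ok], xi[ok])]
    v
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    v <- rep(as.numeric(bg), H * W)
    ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
    if (any(ok)) {
      y0k <- y0[ok]; x0k <- x0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
      v00 <- m[cbind(y0k, x0k)]
      v01 <- m[cbind(y0k, x0k + 1)]
      v10 <- m[cbind(y0k + 1, x0k)]
      v11 <- m[cbind(y0k + 1, x0k + 1)]
      v[ok] <- (1 - fyk) * ((1 - fxk) * v00 + fxk * v01) +
        fyk * ((1 - fxk) * v10 + fxk * v11)
    }
    # edge band: fall back to nearest so border pixels are preserved
    edge <- !ok & xs >= 0.5 & xs <= w + 0.5 & ys >= 0.5 & ys <= h + 0.5
    if (any(edge)) {
      xi <- pmin(pmax(round(xs[edge]), 1), w)
      yi <- pmin(pmax(round(ys[edge]), 1), h)
      v[edge] <- m[cbind(yi, xi)]
    }
    v
  }
  list(pixels = matrix(out, H, W),
       transform = list(angle_deg = angle_deg, cin = cin, cout = cout,
                        in_dim = c(h, w), out_dim = c(H, W)))
}

#' Map rotated-frame row/col coordinates back to the original frame
#' @keywords internal
unrotate_coords <- function(rc, transform) {
  t_rad <- transform$angle_deg * pi / 180
  ct <- cos(t_rad); st <- sin(t_rad)
  yo <- rc[, 1] - transform$cout[1]
  xo <- rc[, 2] - transform$cout[2]
  cbind(-st * xo + ct * yo + transform$cin[1],
        ct * xo + st * yo + transform$cin[2])
}

#' Resample a rotated-frame mask back onto the original canvas
#'
#' Nearest-neighbour sampling of the rotated mask at the forward-transformed
#' position of every original-frame pixel; the exact inverse of the warp
#' applied by [rotate_raster()].
#' @keywords internal
unrotate_mask <- function(mask_rot, transform) {
  h <- transform$in_dim[1]; w <- transform$in_dim[2]
  t_rad <- transform$angle_deg * pi / 180
  ct <- cos(t_rad); st <- sin(t_rad)
  yo <- rep(seq_len(h), times = w) - transform$cin[1]
  xo <- rep(seq_len(w), each = h) - transform$cin[2]
  # forward map into the rotated frame
  xr <- round(ct * xo - st * yo + transform$cout[2])
  yr <- round(st * xo + ct * yo + transform$cout[1])
  ok <- xr >= 1 & xr <= ncol(mask_rot) & yr >= 1 & yr <= nrow(mask_rot)
  v <- rep(FALSE, h * w)
  v[ok] <- mask_rot[cbind(yr[ok], xr[ok])]
  matrix(v, h, w)
}

#' Rotate a matrix by an exact quarter turn (no interpolation)
#' @keywords internal
rot90_raster <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

#' Label connected components under 8-connectivity
#'
#' `EBImage::bwlabel()` is 4-connected; diagonal-touching components are
#' merged afterwards with union-find. Labels are renumbered 1..n in order of
#' each component's first pixel in row-major scan order, so output is fully
#' deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n > 0 && connectivity == 8) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    merge_pairs <- function(a, b) {
      sel <- a > 0L & b > 0L & a != b
      for (k in which(sel)) {
        ra <- find(a[k]); rb <- find(b[k])
        if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
      }
    }
    h <- nrow(lab); w <- ncol(lab)
    if (h > 1 && w > 1) {
      merge_pairs(lab[-h, -w], lab[-1, -1])  # down-right diagonal
      merge_pairs(lab[-1, -w], lab[-h, -1])  # up-right diagonal
    }
    root <- vapply(seq_len(n), find, integer(1))
    lab[] <- c(0L, root)[lab + 1L]
  }
  # renumber by first occurrence in row-major order
  if (max(lab) > 0) {
    order_keys <- unique(as.integer(t(lab))[as.logical(t(lab != 0L))])
    remap <- integer(max(lab))
    remap[order_keys] <- seq_along(order_keys)
    lab[] <- ifelse(lab > 0L, remap[pmax(lab, 1L)], 0L)
  }
  lab
}

#' Second-moment statistics of a binary region
#'
#' @param mask logical matrix containing the region (TRUE pixels).
#' @return object of class `region_mask`: the mask plus `area_px`, `centroid`
#'   (row, col), `orientation` in degrees from horizontal in (-90, 90], and
#'   `axis_ratio` (major/minor, >= 1).
#' @export
region_stats <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("region_stats: empty mask")
  y <- idx[, 1]; x <- idx[, 2]
  mx <- mean(x); my <- mean(y)
  mxx <- mean((x - mx)^2) + 1 / 12  # pixel-footprint correction
  myy <- mean((y - my)^2) + 1 / 12
  mxy <- mean((x - mx) * (y - my))
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  common <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  structure(list(mask = mask, area_px = nrow(idx),
                 centroid = c(row = my, col = mx),
                 orientation = theta,
                 axis_ratio = sqrt(l1 / max(l2, 1e-9))),
            class = "region_mask")
}

#' Fill interior holes of a binary mask
#' @keywords internal
fill_hull <- function(mask) {
  f <- EBImage::fillHull(EBImage::Image(t(mask * 1)))
  t(EBImage::imageData(f)) > 0.5
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> area %d px, centroid (%.1f, %.1f), orientation %.1f deg, axis ratio %.2f\n",
              x$area_px, x$centroid[1], x$centroid[2], x$orientation,
              x$axis_ratio))
  invisible(x)
}
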