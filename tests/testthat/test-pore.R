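test_that("enhancement handles constant, RGB and low-contrast inputs", {
  # constant patch: stretch of a zero range is the identity
  expect_equal(enhance(matrix(90, 20, 20)), matrix(90, 20, 20))
  # RGB reduces via the 0.299/0.587/0.114 luminance weights (hand check)
  rgb <- array(0, c(1, 2, 3))
  rgb[1, 1, ] <- c(100, 50, 200); rgb[1, 2, ] <- c(0, 255, 0)
  expect_equal(as.vector(as_gray(rgb)),
               c(0.299 * 100 + 0.587 * 50 + 0.114 * 200, 0.587 * 255))
  # low-contrast ramp spans the full 8-bit range after the stretch
  ramp <- matrix(rep(seq(100, 140, length.out = 32), each = 32), 32, 32)
  out <- enhance(ramp, sharpen_amount = 0)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # a single pixel comes back unchanged with a warning
  expect_warning(out <- enhance(matrix(7, 1, 1)), "1-pixel")
  expect_equal(out, matrix(7, 1, 1))
})

test_that("Otsu threshold equals exhaustive search with smallest-t ties", {
  # 40 pixels at 10, 60 at 200: every t in [10, 199] separates the classes
  # equally well; the smallest wins
  g <- matrix(c(rep(10, 40), rep(200, 60)), 10, 10)
  expect_equal(otsu_threshold(g), 10)
  # two-valued {0, 255}
  expect_equal(otsu_threshold(matrix(c(0, 255), 4, 4)), 0)
  # oracle equivalence on 50 seeded random images
  set.seed(77)
  for (k in 1:50) {
    g <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_equal(otsu_threshold(g), otsu_oracle(g), info = paste("image", k))
  }
  expect_error(otsu_threshold(matrix(5, 3, 3)), "constant")
})

test_that("small-region filtering removes areas at or below the cutoff", {
  m <- matrix(FALSE, 30, 30); m[2:8, 2:8] <- TRUE  # 49 px
  expect_equal(sum(filter_regions(m, 50)), 0)
  m[2:8, 2:8] <- FALSE; m[2:18, 2:4] <- TRUE       # 51 px
  expect_equal(filter_regions(m, 50), m)
  # three blobs 10 / 50 / 80: the 50 is removed too ("no larger than")
  m <- matrix(FALSE, 40, 60)
  m[2:6, 2:3] <- TRUE                              # 10
  m[12:21, 10:14] <- TRUE                          # 50
  m[30:37, 30:39] <- TRUE                          # 80
  out <- filter_regions(m, 50)
  expect_equal(sum(out), 80)
  expect_true(all(out[30:37, 30:39]))
})

test_that("raising the area cutoff never increases surviving regions", {
  set.seed(15)
  m <- matrix(runif(80 * 80) < 0.35, 80, 80)
  prev <- Inf
  for (cutoff in c(0, 5, 20, 50, 120)) {
    n <- max(label_components(filter_regions(m, cutoff)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("stomate-region selection prefers large central components", {
  # one centred blob
  m <- ellipse_mask(60, 60, 30, 30, 12, 6)
  r <- select_stomate_region(m, 0.5)
  expect_equal(r$area_px, sum(m))
  # a big corner blob loses to a small central blob
  m <- ellipse_mask(100, 100, 50, 50, 8, 5) |
       ellipse_mask(100, 100, 6, 6, 6, 6)
  r <- select_stomate_region(m, 0.5)
  expect_lt(abs(r$centroid[["row"]] - 50), 2)
  # empty mask is a no-detection, not an error
  expect_null(select_stomate_region(matrix(FALSE, 10, 10), 0.5))
})

test_that("major-axis alignment recovers synthetic orientations within 2 degrees", {
  g <- matrix(128, 120, 120)
  # horizontal ellipse: nothing to do
  m0 <- ellipse_mask(120, 120, 60, 60, 30, 12, 0)
  al <- align_to_major_axis(g, region_stats(m0))
  expect_lt(abs(al$angle), 2)
  expect_lt(abs(al$region$orientation), 2)
  # 37-degree ellipse
  m37 <- ellipse_mask(120, 120, 60, 60, 30, 12, 37)
  al <- align_to_major_axis(g, region_stats(m37))
  expect_lt(abs(al$angle - 37), 2)
  expect_lt(abs(al$region$orientation), 2)
  # vertical ellipse rotates to horizontal
  m90 <- ellipse_mask(120, 120, 60, 60, 30, 12, 90)
  al <- align_to_major_axis(g, region_stats(m90))
  expect_lt(abs(al$region$orientation), 2)
  # a circle has no meaningful axis: rotation skipped
  circ <- ellipse_mask(60, 60, 30, 30, 10, 10)
  al <- align_to_major_axis(g[1:60, 1:60], region_stats(circ))
  expect_equal(al$angle, 0)
})

test_that("cross-section extrema match hand-computed smoothing", {
  # V-profile [200,150,80,150,200]; moving average (window 3, partial ends)
  # gives [175, 143.3, 126.7, 143.3, 175]: one valley at the centre
  g <- matrix(rep(c(200, 150, 80, 150, 200), 5), 5, 5)
  mask <- matrix(TRUE, 5, 5)
  prof <- cross_section(g, region_stats(mask))
  expect_equal(prof$valleys, 3)
  expect_length(prof$peaks, 0)
  expect_equal(prof$smoothed[3], mean(c(150, 80, 150)))
  # inverted profile: one peak by symmetry
  g2 <- matrix(rep(c(55, 105, 175, 105, 55), 5), 5, 5)
  prof <- cross_section(g2, region_stats(mask))
  expect_equal(prof$peaks, 3)
  expect_length(prof$valleys, 0)
  # monotone ramp: no extrema anywhere
  g3 <- matrix(rep(seq(10, 250, length.out = 9), 9), 9, 9)
  prof <- cross_section(g3, region_stats(matrix(TRUE, 9, 9)))
  expect_null(find_pore_center(prof))
  # profiles shorter than 5 samples signal no-detection
  tiny <- region_stats(matrix(TRUE, 2, 2))
  expect_null(cross_section(matrix(100, 2, 2), tiny))
})

test_that("a flat-bottomed pore profile still yields its central valley", {
  v <- c(230, 230, 180, 60, 0, 0, 0, 60, 180, 230, 230)
  g <- matrix(rep(v, 7), length(v), 7)
  prof <- cross_section(g, region_stats(matrix(TRUE, length(v), 7)))
  expect_length(prof$valleys, 1)
  expect_equal(prof$valleys, 6)  # centre of the zero run
})

test_that("pore-centre choice follows nearest-then-prominence-then-valley", {
  mk <- function(peaks, valleys, prom, centroid) {
    structure(list(values = rep(100, 40), smoothed = rep(100, 40),
                   peaks = peaks, valleys = valleys, prominence = prom,
                   centroid_index = centroid, row_offset = 1, col = 5),
              class = "cross_section_profile")
  }
  # single valley
  ctr <- find_pore_center(mk(integer(0), 10, c(`10` = 20), 12))
  expect_equal(ctr$index, 10); expect_equal(ctr$polarity, "dark")
  # nearest wins over type
  ctr <- find_pore_center(mk(30, 8, c(`8` = 20, `30` = 50), 12))
  expect_equal(ctr$index, 8); expect_equal(ctr$polarity, "dark")
  # equal distance: higher prominence wins
  ctr <- find_pore_center(mk(14, 10, c(`10` = 20, `14` = 40), 12))
  expect_equal(ctr$index, 14); expect_equal(ctr$polarity, "light")
  # equal distance and prominence: the valley wins
  ctr <- find_pore_center(mk(14, 10, c(`10` = 30, `14` = 30), 12))
  expect_equal(ctr$index, 10); expect_equal(ctr$polarity, "dark")
  expect_null(find_pore_center(mk(integer(0), integer(0), numeric(0), 5)))
})

test_that("region growing is tolerance-bounded and connectivity-bounded", {
  # flat image: everything is similar to the seed
  flat <- matrix(100, 20, 20)
  expect_true(all(grow_pore(flat, c(10, 10), 5)))
  # dark 5x5 square on a bright field, 10% tolerance of the 180 range
  g <- matrix(220, 20, 20); g[8:12, 8:12] <- 40
  pore <- grow_pore(g, c(10, 10), 0.10 * (220 - 40))
  expect_equal(sum(pore), 25)
  expect_true(all(pore[8:12, 8:12]))
  # a bright 1-px wall blocks the flood
  g <- matrix(220, 20, 20); g[8:12, 3:7] <- 40; g[8:12, 9:13] <- 40
  pore <- grow_pore(g, c(10, 5), 18)
  expect_true(all(pore[8:12, 3:7]))
  expect_equal(sum(pore), 25)
})

test_that("pore estimation recovers clean synthetic pores of both polarities", {
  cfg <- stoma_config()
  n_ok <- 0; n <- 0
  for (s in 1:4) {
    sc <- generate_scene(clean_spec(s))
    for (i in seq_along(sc$stomata)) {
      p <- scene_patch(sc, i)
      est <- estimate_pore(p$patch, cfg)
      n <- n + 1
      expect_equal(est$status, "accepted", info = sprintf("seed %d st %d", s, i))
      if (est$status != "accepted") next
      expect_equal(est$polarity, p$polarity,
                   info = sprintf("seed %d st %d", s, i))
      iou <- mask_iou(est$pore_mask, p$true_pore)
      if (est$polarity == p$polarity && iou >= 0.7) n_ok <- n_ok + 1
      # exact unit conversion
      expect_identical(est$area_um2, est$area_px * p$patch$pixel_scale^2)
    }
  }
  expect_gte(n_ok / n, 0.9)
})

test_that("a blank patch yields no_detection, not an error", {
  est <- estimate_pore(matrix(180, 80, 80), stoma_config())
  expect_equal(est$status, "no_detection")
  expect_equal(est$polarity, "none")
})

test_that("inverting intensities flips polarity and preserves the pore mask", {
  cfg <- stoma_config()
  checked <- 0
  for (s in 5:8) {
    sc <- generate_scene(clean_spec(s))
    for (i in seq_along(sc$stomata)) {
      p <- scene_patch(sc, i)
      est <- estimate_pore(p$patch, cfg)
      if (est$status != "accepted") next
      inv <- p$patch
      inv$pixels <- 255 - inv$pixels
      est2 <- estimate_pore(inv, cfg)
      expect_equal(est2$status, "accepted")
      expect_true(est2$polarity != est$polarity)
      expect_gte(mask_iou(est2$pore_mask, est$pore_mask), 0.9)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 4)
})

test_that("a quarter-turn of the patch changes pore area by at most 10%", {
  cfg <- stoma_config()
  checked <- 0
  for (s in 9:12) {
    sc <- generate_scene(clean_spec(s))
    for (i in seq_along(sc$stomata)) {
      p <- scene_patch(sc, i)
      est <- estimate_pore(p$patch, cfg)
      if (est$status != "accepted") next
      rot <- p$patch
      rot$pixels <- t(rot$pixels)[, rev(seq_len(nrow(rot$pixels))),
                                  drop = FALSE]
      est2 <- estimate_pore(rot, cfg)
      if (est2$status != "accepted") next
      expect_lte(abs(est2$area_px - est$area_px) / est$area_px, 0.10)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 4)
})

test_that("moderate blur still recovers most pores at IoU 0.5", {
  cfg <- stoma_config()
  ok <- 0; n <- 0
  for (s in 1:10) {
    sp <- scene_spec(height = 256, width = 256, n_stomata = 2,
                     blur_sigma_range = c(2, 2), noise_sd = 3,
                     vein_density = 4, artifact_rate = 0, seed = 400 + s)
    sc <- generate_scene(sp)
    for (i in seq_along(sc$stomata)) {
      p <- scene_patch(sc, i)
      est <- estimate_pore(p$patch, cfg)
      n <- n + 1
      if (est$status == "accepted" &&
          !is.na(mask_iou(est$pore_mask, p$true_pore)) &&
          mask_iou(est$pore_mask, p$true_pore) >= 0.5) ok <- ok + 1
    }
  }
  expect_gte(ok / n, 0.7)
})
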