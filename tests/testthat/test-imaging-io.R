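test_that("PNG and TIFF round trips preserve 8-bit data exactly", {
  # all-zero 2x2 PNG
  p <- tempfile(fileext = ".png")
  write_image(matrix(0, 2, 2), p)
  img <- load_image(p)
  expect_equal(dim(img$pixels), c(2, 2))
  expect_true(all(img$pixels == 0))

  # random grayscale PNG
  set.seed(3)
  g <- matrix(sample(0:255, 40 * 30, replace = TRUE), 40, 30)
  write_image(g, p)
  expect_equal(load_image(p)$pixels, g)

  # 8-bit RGB TIFF 100x80, values unchanged
  rgb <- array(sample(0:255, 100 * 80 * 3, replace = TRUE), c(100, 80, 3))
  tf <- tempfile(fileext = ".tif")
  tiff::writeTIFF(rgb / 255, tf, bits.per.sample = 8)
  img <- load_image(tf)
  expect_equal(dim(img$pixels), c(100, 80, 3))
  expect_equal(img$pixels, rgb, ignore_attr = TRUE)
})

test_that("16-bit input is rescaled to 8 bits by the linear min-max map", {
  tf <- tempfile(fileext = ".tif")
  vals <- matrix(c(0, 32768, 65535), 1, 3)
  tiff::writeTIFF(vals / 65535, tf, bits.per.sample = 16)
  img <- load_image(tf)
  # by hand: (v - 0) / 65535 * 255, rounded
  expect_equal(as.vector(img$pixels), round(c(0, 32768, 65535) / 65535 * 255))
  expect_equal(range(img$pixels), c(0, 255))
})

test_that("unreadable or unsupported files raise an input-format error", {
  expect_error(load_image("no-such-file.png"), "no such file")
  bad <- tempfile(fileext = ".txt")
  writeLines("x", bad)
  expect_error(load_image(bad), "unsupported")
})

test_that("scan_image enforces its invariants", {
  expect_error(scan_image(matrix(-1, 2, 2)), "\\[0, 255\\]")
  expect_error(scan_image(matrix(1, 2, 2), pixel_scale = 0), "pixel_scale")
  expect_error(scan_image(array(0, c(2, 2, 2))), "3 planes")
})

test_that("tiling covers the image with flush-shifted final tiles", {
  img <- scan_image(matrix(0, 100, 100))
  t1 <- tile_image(img, 50, 0)
  offs <- t(sapply(t1, function(x) c(x$row_offset, x$col_offset)))
  expect_equal(nrow(offs), 4)
  expect_setequal(paste(offs[, 1], offs[, 2]),
                  c("0 0", "0 50", "50 0", "50 50"))

  # tile_size equal to the image is the identity
  t2 <- tile_image(img, 100, 0)
  expect_length(t2, 1)
  expect_equal(t2[[1]]$pixels, img$pixels)

  # 60/10: offsets {0, 40} per direction, full coverage by brute force
  t3 <- tile_image(img, 60, 10)
  offs <- unique(sapply(t3, `[[`, "row_offset"))
  expect_equal(sort(offs), c(0, 40))
  cover <- matrix(0L, 100, 100)
  for (tl in t3)
    cover[tl$row_offset + 1:60, tl$col_offset + 1:60] <-
      cover[tl$row_offset + 1:60, tl$col_offset + 1:60] + 1L
  expect_equal(sum(cover > 0), 10000)

  expect_error(tile_image(img, 50, 50), "overlap")
})

test_that("any valid tiling covers every pixel at least once", {
  set.seed(9)
  for (k in 1:8) {
    h <- sample(40:160, 1); w <- sample(40:160, 1)
    ts <- sample(20:min(h, w), 1); ov <- sample(0:(ts - 1), 1)
    tiles <- tile_image(scan_image(matrix(0, h, w)), ts, ov)
    cover <- matrix(FALSE, h, w)
    for (tl in tiles) {
      d <- dim(tl$pixels)
      cover[tl$row_offset + seq_len(d[1]), tl$col_offset + seq_len(d[2])] <- TRUE
    }
    expect_true(all(cover), info = sprintf("h=%d w=%d ts=%d ov=%d", h, w, ts, ov))
  }
})

test_that("mask reassembly applies the stomate-wins rule and is exact for partitions", {
  codes <- class_codes()
  # single tile covering the whole image
  m <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  out <- assemble_label_mask(list(list(row_offset = 0, col_offset = 0,
                                       mask = m)), c(8, 8))
  expect_equal(out, m)

  # overlapping tiles: stomate beats background on the shared pixel
  t1 <- list(row_offset = 0, col_offset = 0,
             mask = matrix(codes[["stomate"]], 2, 2))
  t2 <- list(row_offset = 1, col_offset = 1,
             mask = matrix(codes[["background"]], 2, 2))
  out <- assemble_label_mask(list(t1, t2), c(3, 3))
  expect_equal(out[2, 2], codes[["stomate"]])
  out_rev <- assemble_label_mask(list(t2, t1), c(3, 3))
  expect_equal(out_rev[2, 2], codes[["stomate"]])

  # three overlapping tiles vs an independently enumerated union
  set.seed(4)
  tiles <- list(
    list(row_offset = 0, col_offset = 0,
         mask = matrix(sample(0:2, 3600, replace = TRUE), 60, 60)),
    list(row_offset = 30, col_offset = 20,
         mask = matrix(sample(0:2, 3600, replace = TRUE), 60, 60)),
    list(row_offset = 40, col_offset = 40,
         mask = matrix(sample(0:2, 3600, replace = TRUE), 60, 60)))
  out <- assemble_label_mask(tiles, c(100, 100))
  expected <- matrix(0L, 100, 100)
  rank_of <- function(v) ifelse(v == 1, 2L, ifelse(v == 2, 1L, 0L))
  for (r in 1:100) for (cl in 1:100) {
    vals <- integer(0)
    for (tl in tiles) {
      rr <- r - tl$row_offset; cc <- cl - tl$col_offset
      if (rr >= 1 && rr <= 60 && cc >= 1 && cc <= 60)
        vals <- c(vals, tl$mask[rr, cc])
    }
    if (length(vals)) expected[r, cl] <- vals[which.max(rank_of(vals))]
  }
  expect_equal(out, expected)

  # non-overlapping tiles cut from a mask reassemble it bit-exactly
  full <- matrix(sample(0:2, 10000, replace = TRUE), 100, 100)
  img <- scan_image(full)
  cut <- tile_image(img, 50, 0)
  tm <- lapply(cut, function(tl) list(row_offset = tl$row_offset,
                                      col_offset = tl$col_offset,
                                      mask = tl$pixels))
  expect_identical(assemble_label_mask(tm, c(100, 100)), full)

  # tile outside the canvas is a geometry error
  expect_error(assemble_label_mask(list(list(row_offset = 99, col_offset = 0,
                                             mask = matrix(0L, 2, 2))),
                                   c(100, 100)), "geometry")
})

test_that("annotation files round trip losslessly", {
  p <- tempfile(fileext = ".csv")
  # empty annotation file
  writeLines("row0,col0,row1,col1,label", p)
  ann <- read_annotations(p)
  expect_equal(nrow(ann$boxes), 0)

  # a single box
  writeLines(c("row0,col0,row1,col1,label", "10,10,50,60,stomate"), p)
  ann <- read_annotations(p)
  expect_equal(unlist(ann$boxes[1, 1:4]),
               c(row0 = 10, col0 = 10, row1 = 50, col1 = 60))

  # 25 random boxes, write then read
  set.seed(12)
  r0 <- sample(0:100, 25); c0 <- sample(0:100, 25)
  df <- data.frame(row0 = r0, col0 = c0,
                   row1 = r0 + sample(1:40, 25, replace = TRUE),
                   col1 = c0 + sample(1:40, 25, replace = TRUE),
                   label = sample(c("stomate", "vein"), 25, replace = TRUE))
  write_annotations(df, p)
  back <- read_annotations(p)
  expect_equal(back$boxes, df, ignore_attr = TRUE)

  # malformed rows are flagged with a line number
  writeLines(c("row0,col0,row1,col1,label", "5,5,5,9,stomate"), p)
  expect_error(read_annotations(p), "line 2")
})

test_that("per-stomate results round trip through CSV", {
  est <- list(
    structure(list(status = "accepted", area_px = 120, area_um2 = 7.5,
                   polarity = "dark", reason = NULL), class = "pore_estimate"),
    structure(list(status = "no_detection", area_px = NA_real_,
                   area_um2 = NA_real_, polarity = "none",
                   reason = "no_central_region"), class = "pore_estimate"))
  boxes <- data.frame(row0 = c(0, 50), col0 = c(0, 60),
                      row1 = c(40, 90), col1 = c(40, 100))
  p <- tempfile(fileext = ".csv")
  j <- tempfile(fileext = ".json")
  df <- write_results(est, boxes, "scanA", p, j)
  back <- read_results(p)
  expect_equal(back, df, ignore_attr = TRUE)
  run <- jsonlite::read_json(j)
  expect_equal(run$counts$accepted, 1)
  expect_equal(run$counts$no_detection, 1)
})
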