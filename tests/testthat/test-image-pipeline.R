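# Morphological image pipeline: segmentation, erosion contour, measurement.

test_that("crop_roi extracts the sub-image without touching grey levels", {
  px <- matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  fr <- sinter_frame(px, time_s = 3)
  expect_identical(crop_roi(fr, c(1, 100, 1, 100))$pixels, px)
  sub <- crop_roi(fr, c(11, 20, 31, 40))
  expect_identical(sub$pixels, px[11:20, 31:40])
  expect_equal(sub$time_s, 3)
  expect_error(crop_roi(fr, c(0, 10, 1, 10)), "outside")
  expect_error(crop_roi(fr, c(95, 105, 1, 10)), "outside")
  expect_error(crop_roi(fr, c(10, 5, 1, 10)), "roi")
})

test_that("segmentation yields one filled foreground object of the right size", {
  fr <- render_shape(B = 1, R0 = 60, noise = 0, blur = 0,
                     image_size = c(201L, 201L))
  mask <- segment(fr, threshold = 128)
  a <- a_constant_area(1, 60)
  expect_lt(abs(sum(mask) - pi * a^2) / (pi * a^2), 0.02)
  # uniform background: nothing to segment
  expect_error(segment(sinter_frame(matrix(220, 50, 50)), threshold = 128),
               "empty foreground")
  # two touching disks (a near-tangent lemniscate) stay one component
  fr2 <- render_shape(B = 0.05, R0 = 40, image_size = c(151L, 251L))
  mask2 <- segment(fr2, threshold = 128)
  lab <- EBImage::bwlabel(unclass(mask2))
  expect_equal(max(lab), 1)
  # idempotent on an already-binary image
  fr_bin <- sinter_frame(ifelse(unclass(mask) == 1, 0, 255))
  expect_equal(unclass(segment(fr_bin, threshold = 128)), unclass(mask),
               ignore_attr = TRUE)
})

test_that("segmentation keeps the largest component and fills holes", {
  px <- matrix(220, 60, 60)
  px[10:40, 10:40] <- 30          # main object
  px[20:25, 20:25] <- 220         # internal bright bubble -> must be filled
  px[50:52, 50:52] <- 30          # small spurious speck -> must be dropped
  mask <- segment(sinter_frame(px), threshold = 128)
  expect_equal(sum(mask), 31 * 31)
  expect_equal(unname(mask[22, 22]), 1)
  expect_equal(unname(mask[51, 51]), 0)
})

test_that("erosion contour matches the brute-force oracle exactly", {
  set.seed(4)
  for (k in 1:50) {
    nr <- sample(5:15, 1); nc <- sample(5:15, 1)
    mask <- matrix(0, nr, nc)
    mask[sample(nr * nc, size = sample(10:(nr * nc %/% 2), 1))] <- 1
    if (k %% 2 == 0) mask[2:min(6, nr), 2:min(6, nc)] <- 1  # solid block
    interior_oracle <- brute_erode3(mask)
    if (!any(interior_oracle == 1)) {
      expect_error(contour_pixels(mask), "erosion")
      next
    }
    ct <- contour_pixels(mask)
    edge_oracle <- which(mask - interior_oracle == 1, arr.ind = TRUE)
    got <- cbind(ct$rows, ct$cols)
    expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                     unname(edge_oracle[order(edge_oracle[, 1],
                                              edge_oracle[, 2]), ,
                                        drop = FALSE]))
    # conservation: contour + interior = mask
    expect_equal(length(ct$rows) + sum(ct$interior), sum(mask))
  }
})

test_that("erosion contour handles canonical shapes and degenerate input", {
  sq3 <- matrix(1, 3, 3)
  ct <- contour_pixels(sq3)
  expect_equal(length(ct$rows), 8)
  expect_equal(sum(ct$interior), 1)
  expect_error(contour_pixels(matrix(1, 1, 10)), "erosion")
  sq20 <- matrix(1, 20, 20)
  expect_equal(length(contour_pixels(sq20)$rows), 20^2 - 18^2)
})

test_that("base rows are excluded from the contour but conserved in the count", {
  mask <- matrix(0, 30, 30)
  mask[5:28, 5:25] <- 1
  ct <- contour_pixels(mask, base_rows_excluded = 4)
  expect_true(all(ct$rows <= 26))
  excluded_fg <- sum(mask[27:30, ]) - sum(ct$interior[27:30, ])
  expect_equal(length(ct$rows) + sum(ct$interior) + excluded_fg, sum(mask))
})

test_that("centroid is the mean of foreground pixel coordinates", {
  m <- matrix(0, 20, 20); m[5, 7] <- 1
  expect_equal(mask_centroid(m), c(row = 5, col = 7))
  m2 <- matrix(0, 20, 20); m2[9:11, 9:11] <- 1
  expect_equal(mask_centroid(m2), c(row = 10, col = 10))
  m3 <- matrix(0, 3, 3); m3[1, 1] <- m3[1, 2] <- m3[2, 1] <- 1
  expect_equal(mask_centroid(m3), c(row = 4 / 3, col = 4 / 3))
  expect_error(mask_centroid(matrix(0, 3, 3)), "empty")
})

test_that("maximum horizontal length spans extreme-to-extreme per row", {
  m <- matrix(0, 10, 10); m[3:5, 2:6] <- 1
  lm <- max_horizontal_length(m)
  expect_equal(lm$L_max, 5L)
  expect_equal(lm$row, 4L)            # tie broken toward the centroid row
  # gaps count: foreground only at columns 2 and 9
  m2 <- matrix(0, 5, 10); m2[3, c(2, 9)] <- 1
  expect_equal(max_horizontal_length(m2)$L_max, 8L)
  # rendered tangent circles, radius ~50 px each: width ~4 * radius
  fr <- render_shape(B = 1e-3, R0 = sqrt(2) * 50, image_size = c(151L, 301L))
  mask <- segment(fr, threshold = 128)
  expect_lt(abs(max_horizontal_length(mask)$L_max - 200), 2.5)
})

test_that("centering flips y upward and attaches exact polar coordinates", {
  ctr <- list(rows = c(10, 10, 9, 11), cols = c(20, 21, 20, 20))
  ps <- center_polarize(ctr, centroid_col = 20, row_of_L_max = 10)
  expect_equal(ps$x, c(0, 1, 0, 0))
  expect_equal(ps$y, c(0, 0, 1, -1))
  expect_equal(ps$r, c(0, 1, 1, 1))
  expect_equal(ps$phi, c(0, 0, pi / 2, -pi / 2))
  expect_equal(ps$r, sqrt(ps$x^2 + ps$y^2))
})

test_that("contour radii of a rendered shape follow the lemniscate closely", {
  for (B in c(0.3, 0.6)) {
    fr <- render_shape(B, R0 = 60, image_size = c(221L, 271L))
    ct <- frame_contour(fr, threshold = 128)
    a <- a_constant_area(B, 60)
    # outer-edge convention: boundary pixel centres sit ~half a pixel
    # inside the continuous silhouette (see fit_booth's edge_offset_px)
    dev <- abs(ct$r + 0.5 - booth_radius(a, ct$phi, B = B))
    expect_gt(mean(dev <= 1.5), 0.95)
  }
})

test_that("frame I/O round-trips PNG and TIFF and reads manifests", {
  px <- matrix(sample(0:255, 40 * 30, replace = TRUE), 40, 30)
  d <- withr::local_tempdir()
  png::writePNG(px / 255, file.path(d, "f1.png"))
  tiff::writeTIFF(px / 255, file.path(d, "f2.tif"))
  expect_equal(read_frame(file.path(d, "f1.png"))$pixels, px,
               ignore_attr = TRUE)
  expect_equal(read_frame(file.path(d, "f2.tif"))$pixels, px,
               ignore_attr = TRUE)
  write.csv(data.frame(filename = c("f1.png", "f2.tif"), time_s = c(5, 9)),
            file.path(d, "man.csv"), row.names = FALSE)
  seq2 <- read_sequence(file.path(d, "man.csv"))
  expect_equal(vapply(seq2, function(f) f$time_s, numeric(1)), c(5, 9))
  expect_error(read_frame(file.path(d, "missing.png")), "cannot read")
})
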