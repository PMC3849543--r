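test_that("image files round-trip through the reader", {
  dir <- withr::local_tempdir()
  arr <- array(sample(0:255, 12 * 10 * 3, replace = TRUE), c(10L, 12L, 3L))

  tif <- file.path(dir, "x.tiff")
  tiff::writeTIFF(arr / 255, tif, bits.per.sample = 8L)
  img <- load_image(tif)
  expect_s3_class(img, "raster_image")
  expect_equal(colour_model(img), "RGB")
  expect_equal(dim(unclass(img)), dim(arr))
  expect_equal(unclass(img), arr, ignore_attr = TRUE)

  # greyscale PNG is replicated to three identical channels
  png_path <- file.path(dir, "g.png")
  png::writePNG(arr[, , 1] / 255, png_path)
  g <- load_image(png_path)
  expect_equal(dim(unclass(g))[3], 3L)
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 1], arr[, , 1], ignore_attr = TRUE)

  # 16-bit TIFF rejected by default, rescaled on request
  t16 <- file.path(dir, "x16.tiff")
  tiff::writeTIFF(arr / 255, t16, bits.per.sample = 16L)
  expect_error(load_image(t16), "16-bit")
  img16 <- load_image(t16, allow_16bit = TRUE)
  expect_equal(unclass(img16), arr, ignore_attr = TRUE)

  expect_error(load_image(file.path(dir, "missing.png")), "no such file")
})

test_that("rgb_to_hsv matches the closed-form oracle", {
  # base R rgb2hsv as the independent closed form, mapped to the
  # 8-bit half-degree convention
  cols <- rbind(c(255, 0, 0), c(128, 128, 128), c(150, 90, 40),
                c(0, 0, 255), c(252, 252, 252), c(232, 213, 218))
  for (i in seq_len(nrow(cols))) {
    col <- cols[i, ]
    hsv <- rgb_to_hsv(flat_rgb(col, 2L, 2L))
    o <- grDevices::rgb2hsv(col[1], col[2], col[3], maxColorValue = 255)
    expect_equal(hsv[1, 1, 1], round(o[1] * 180) %% 180, tolerance = 1.01,
                 ignore_attr = TRUE)
    expect_equal(hsv[1, 1, 2], round(o[2] * 255), tolerance = 1.01,
                 ignore_attr = TRUE)
    expect_equal(hsv[1, 1, 3], round(o[3] * 255), tolerance = 1.01,
                 ignore_attr = TRUE)
  }
  # anchor points
  red <- rgb_to_hsv(flat_rgb(c(255, 0, 0)))
  expect_equal(red[1, 1, ], c(0, 255, 255), ignore_attr = TRUE)
  grey <- rgb_to_hsv(flat_rgb(c(128, 128, 128)))
  expect_equal(grey[1, 1, 2:3], c(0, 128), ignore_attr = TRUE)
  expect_error(rgb_to_hsv(extract_channel(red, 1L)), "RGB")
})

test_that("extract_channel selects planes and validates the index", {
  arr <- array(sample(0:255, 5 * 5 * 3, TRUE), c(5L, 5L, 3L))
  img <- raster_image(arr, "RGB")
  g <- extract_channel(img, 2L)
  expect_equal(colour_model(g), "GREY")
  expect_equal(unclass(g), arr[, , 2], ignore_attr = TRUE)
  expect_equal(unclass(extract_channel(g, 1L)), unclass(g),
               ignore_attr = TRUE)
  expect_error(extract_channel(img, 4L), "out of range")
})

test_that("threshold uses strict comparison and complements cleanly", {
  const <- function(v) raster_image(matrix(v, 4L, 4L), "GREY")
  expect_true(all(unclass(threshold(const(236), 236)) == 0L))
  expect_true(all(unclass(threshold(const(237), 236)) == 255L))
  withr::with_seed(7, {
    m <- raster_image(matrix(sample(0:255, 64, TRUE), 8L), "GREY")
    for (t in c(0, 30, 128, 255)) {
      a <- threshold(m, t, inverted = TRUE)
      b <- logical_not(threshold(m, t, inverted = FALSE))
      expect_identical(unclass(a), unclass(b))
    }
  })
})

test_that("mask logic is pixelwise boolean algebra", {
  withr::with_seed(11, {
    a <- random_mask(); b <- random_mask(); z <- binary_mask(matrix(FALSE, 16, 16))
    expect_identical(unclass(logical_or(z, a)), unclass(a))
    expect_identical(unclass(logical_not(logical_not(a))), unclass(a))
    expect_identical(unclass(logical_or(a, b)), unclass(logical_or(b, a)))
    expect_identical(unclass(logical_or(a, a)), unclass(a))
    # OR equals the pixel-loop maximum
    brute <- matrix(pmax(mask_int(a), mask_int(b)), 16L)
    expect_equal(unclass(logical_or(a, b)), brute, ignore_attr = TRUE)
    expect_error(logical_or(a, binary_mask(matrix(FALSE, 4, 4))), "differ")
  })
})

test_that("morphology agrees with the brute-force min/max oracle", {
  withr::with_seed(42, {
    for (i in 1:20) {
      m <- random_mask(12L, 14L, p = runif(1, 0.2, 0.7))
      for (op in c("erode", "dilate")) {
        iters <- sample(1:3, 1)
        expect_equal(unclass(morph(m, op, iters)),
                     oracle_morph(m, op, iters), ignore_attr = TRUE)
      }
    }
  })
})

test_that("morphology border policy and fixed points behave", {
  all_on <- binary_mask(matrix(TRUE, 6L, 6L))
  er <- unclass(morph(all_on, "erode", 1L))
  expect_true(all(er[2:5, 2:5] == 255L))
  expect_true(all(er[1, ] == 0L) && all(er[, 1] == 0L) &&
              all(er[6, ] == 0L) && all(er[, 6] == 0L))
  one <- matrix(FALSE, 7L, 7L); one[4, 4] <- TRUE
  di <- unclass(morph(binary_mask(one), "dilate", 1L))
  expect_equal(sum(di != 0L), 9L)
  expect_true(all(di[3:5, 3:5] == 255L))
  m <- random_mask(); expect_identical(unclass(morph(m, "erode", 0L)),
                                       unclass(m))
})

test_that("erosion and dilation preserve set inclusion", {
  withr::with_seed(5, {
    for (i in 1:10) {
      m <- random_mask(15L, 15L, 0.5)
      for (k in 0:3) {
        er <- unclass(morph(m, "erode", k))
        di <- unclass(morph(m, "dilate", k))
        expect_true(all(er <= unclass(m)))
        expect_true(all(unclass(m) <= di))
      }
    }
  })
})

test_that("hole filling honours the strict size bound", {
  # rectangular ring whose hole area is exactly controlled
  ring_with_hole <- function(hw, hh) {
    m <- matrix(FALSE, hh + 6L, hw + 6L)
    m[2:(hh + 5L), 2:(hw + 5L)] <- TRUE
    m[4:(hh + 3L), 4:(hw + 3L)] <- FALSE # hole of hw*hh px
    binary_mask(m)
  }
  r399 <- ring_with_hole(21L, 19L) # 399 px hole
  f399 <- fill_small_holes(r399, 400)
  expect_equal(sum(unclass(f399) != 0L), sum(unclass(r399) != 0L) + 399L)
  r400 <- ring_with_hole(20L, 20L) # 400 px hole
  expect_identical(unclass(fill_small_holes(r400, 400)), unclass(r400))
  withr::with_seed(3, {
    for (i in 1:20) {
      m <- random_mask(14L, 14L, 0.55)
      f <- fill_small_holes(m, sample(c(0, 3, 10, 400), 1))
      expect_true(all(unclass(f) >= unclass(m))) # never removes foreground
      expect_identical(unclass(fill_small_holes(f, 400)),
                       unclass(fill_small_holes(fill_small_holes(f, 400), 400)))
      expect_identical(unclass(fill_small_holes(m, 0)), unclass(m))
    }
  })
})

test_that("contour tracing recovers topology, hierarchy and orientation", {
  sq <- matrix(FALSE, 14L, 14L); sq[3:12, 3:12] <- TRUE
  ct <- find_contours(binary_mask(sq))
  expect_length(ct, 1L)
  expect_false(ct[[1]]$is_hole)
  expect_gt(contour_signed_area(ct[[1]]$points), 0)

  ann <- annulus_mask(10L, 5L)
  ct2 <- find_contours(ann)
  holes <- Filter(function(x) x$is_hole, ct2)
  outers <- Filter(function(x) !x$is_hole, ct2)
  expect_length(outers, 1L)
  expect_length(holes, 1L)
  expect_equal(holes[[1]]$parent, 1L)
  expect_lt(contour_signed_area(holes[[1]]$points), 0)
  # consecutive contour points are 8-connected
  for (cc in ct2) {
    d <- abs(cc$points - cc$points[c(2:nrow(cc$points), 1L), ])
    expect_true(all(d <= 1L))
  }
})

test_that("outer contour count equals the flood-fill component oracle", {
  withr::with_seed(99, {
    for (i in 1:20) {
      m <- random_mask(15L, 17L, runif(1, 0.25, 0.6))
      ct <- find_contours(m)
      n_outer <- sum(!vapply(ct, `[[`, TRUE, "is_hole"))
      expect_equal(n_outer, oracle_component_count(m, 8L))
    }
  })
  expect_length(find_contours(binary_mask(matrix(FALSE, 5, 5))), 0L)
})

test_that("tracing then rasterising reproduces each filled component", {
  withr::with_seed(17, {
    for (i in 1:20) {
      m <- random_mask(13L, 13L, runif(1, 0.3, 0.6))
      filled <- fill_small_holes(m, 13 * 13 + 1)
      ct <- find_contours(m)
      acc <- matrix(0L, 13L, 13L)
      for (cc in Filter(function(x) !x$is_hole, ct)) {
        r <- rasterise_contour(cc$points, 13L, 13L)
        acc <- pmax(acc, mask_int(r))
      }
      expect_equal(acc, mask_int(filled), ignore_attr = TRUE)
    }
  })
})

test_that("morphology and labeling agree with EBImage where conventions coincide", {
  skip_if_not_installed("EBImage")
  withr::with_seed(23, {
    kern <- EBImage::makeBrush(3, shape = "box")
    for (i in 1:5) {
      m <- random_mask(20L, 20L, 0.5)
      # compare on the interior (EBImage pads borders differently)
      ours <- unclass(morph(m, "dilate", 1L))[2:19, 2:19]
      eb <- EBImage::dilate(t(mask_int(m) / 255), kern)
      expect_equal(ours / 255, t(eb)[2:19, 2:19], ignore_attr = TRUE)
    }
  })
})
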