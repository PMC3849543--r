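test_that("closed forms hold for squares and rectangles", {
  sq <- vessel_contour(square_chain(10L))
  rec <- measure_vessel(sq, calibration(0.25))
  expect_equal(rec$area_px, 100)
  expect_equal(rec$aspect, 1)
  expect_equal(rec$roundness, 4 * pi * 100 / 40^2, tolerance = 1e-6) # 0.785
  expect_equal(rec$perimeter_ratio, 1, tolerance = 1e-6)
  expect_equal(rec$area_um2, 100 * 0.25^2)
  expect_equal(rec$width_um, 11 * 0.25) # tight bbox spans 11 px of chain

  # 40 x 10 rectangle chain
  r40 <- rbind(cbind(0:40, 0), cbind(40, 1:10), cbind(39:0, 10),
               cbind(0, 9:1))
  rc <- measure_vessel(vessel_contour(r40))
  expect_equal(rc$aspect, 41 / 11, tolerance = 1e-6)
  expect_equal(rc$perimeter_ratio, 1, tolerance = 1e-3)
  expect_error(measure_vessel(vessel_contour(rbind(c(0, 0), c(1, 1), c(2, 2))[1:2, ])),
               "degenerate")
})

test_that("digitised circles measure close to the continuous disc", {
  for (r in c(20L, 35L, 50L, 75L, 100L)) {
    ct <- find_contours(disc_mask(r))[[1]]$points
    rec <- measure_vessel(vessel_contour(ct))
    expect_gt(rec$roundness, 0.90)
    expect_lt(rec$roundness, 1.05)
    expect_equal(rec$area_px, pi * r^2, tolerance = 0.03)
    expect_gt(rec$perimeter_ratio, 0.95)
    expect_lt(rec$perimeter_ratio, 1.05)
  }
})

test_that("shape measures are translation invariant and aspect flips under 90 deg", {
  ct <- find_contours(disc_mask(20L))[[1]]$points
  a <- measure_vessel(vessel_contour(ct))
  b <- measure_vessel(vessel_contour(cbind(ct[, 1] + 57, ct[, 2] + 13)))
  for (f in c("area_px", "aspect", "roundness", "perimeter_ratio"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  # 90-degree rotation of a rectangle leaves aspect and roundness unchanged
  r40 <- rbind(cbind(0:40, 0), cbind(40, 1:10), cbind(39:0, 10), cbind(0, 9:1))
  rot <- cbind(r40[, 2], r40[, 1])
  ra <- measure_vessel(vessel_contour(r40))
  rb <- measure_vessel(vessel_contour(rot))
  expect_equal(ra$aspect, rb$aspect)
  expect_equal(ra$roundness, rb$roundness, tolerance = 1e-9)
})

test_that("the disc maximises roundness among equal-area shapes", {
  area_target <- pi * 40^2
  shapes <- list(
    disc = find_contours(disc_mask(40L))[[1]]$points,
    square = square_chain(round(sqrt(area_target))),
    rect = { s <- round(sqrt(area_target / 4))
             rbind(cbind(0:(4 * s), 0), cbind(4 * s, 1:s),
                   cbind((4 * s - 1):0, s), cbind(0, (s - 1):1)) },
    star = star_polygon(r = 40 / sqrt(1 + 0.3^2 / 2), depth = 0.3))
  rnd <- vapply(shapes, function(p)
    measure_vessel(vessel_contour(p))$roundness, 0)
  expect_true(all(rnd["disc"] + 0.05 >= rnd))
  expect_equal(max(rnd), rnd[["disc"]], tolerance = 0.05)
})

test_that("perimeter ratio strictly decreases with spike depth", {
  pr <- vapply(c(0.08, 0.16, 0.24, 0.32), function(d)
    measure_vessel(vessel_contour(star_polygon(depth = d)))$perimeter_ratio, 0)
  expect_true(all(diff(pr) < 0))
  expect_true(all(pr > 0 & pr <= 1 + 0.05))
})

test_that("inner-contour measures are reported for vessels with lumens", {
  vs <- extract_vessels(annulus_mask(30L, 18L))
  rec <- measure_vessel(vs[[1]], calibration(0.5), vessel_id = 7L)
  expect_equal(rec$vessel_id, 7L)
  expect_false(is.na(rec$inner_area_px))
  expect_lt(rec$inner_area_px, rec$area_px)
  expect_equal(rec$inner_area_um2, rec$inner_area_px * 0.25)
  expect_gt(rec$inner_roundness, 0.9)
})

test_that("vascular density aggregates counts and areas", {
  img <- flat_rgb(c(255, 255, 255), 100L, 100L)
  cal <- calibration(1) # 100 x 100 um image = 1e4 um2
  empty <- measure_vessel(vessel_contour(square_chain(10L)), cal)[0, ]
  d0 <- vascular_density(empty, img, cal)
  expect_equal(d0$vessel_count, 0L)
  expect_equal(d0$count_density, 0)
  expect_equal(d0$area_fraction, 0)

  one <- measure_vessel(vessel_contour(square_chain(10L)), cal) # 100 um2
  d1 <- vascular_density(one, img, cal)
  expect_equal(d1$area_fraction, 100 / 1e4)
  expect_equal(d1$count_density, 1 / (1e4 / 1e6)) # vessels per mm2
})

test_that("area fraction of random non-overlapping discs matches the generator", {
  withr::with_seed(8, {
    w <- 400L; h <- 400L
    radii <- sample(15:30, 6L)
    centres <- cbind(seq(40, 360, length.out = 6L),
                     rep(c(100, 300), 3L))
    m <- matrix(FALSE, h, w)
    for (i in 1:6) {
      d <- outer(0:(h - 1), 0:(w - 1), function(y, x)
        sqrt((x - centres[i, 1])^2 + (y - centres[i, 2])^2))
      m <- m | (d <= radii[i] + 0.5)
    }
    recs <- do.call(rbind, lapply(
      Filter(function(ct) !ct$is_hole, find_contours(binary_mask(m))),
      function(ct) measure_vessel(vessel_contour(ct$points), calibration(1))))
    dens <- vascular_density(recs, flat_rgb(c(0, 0, 0), w, h), calibration(1))
    expect_equal(dens$area_fraction, sum(pi * radii^2) / (w * h),
                 tolerance = 0.02)
    expect_equal(dens$vessel_count, 6L)
  })
})

test_that("the measurement table is written as CSV and XLSX is refused", {
  dir <- withr::local_tempdir()
  rec <- measure_vessel(vessel_contour(square_chain(10L)), vessel_id = 1L)
  p <- write_measurements(rec, file.path(dir, "m.csv"))
  lines <- readLines(p)
  expect_match(lines[1], "^# units:")
  back <- utils::read.csv(p, comment.char = "#")
  expect_equal(back$area_px, rec$area_px)
  expect_error(write_measurements(rec, file.path(dir, "m.csv"), xlsx = TRUE),
               "XLSX")
})
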