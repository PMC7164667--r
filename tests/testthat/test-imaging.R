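test_that("a clean disc segments to its analytic area", {
  for (polarity in c("dark", "bright")) {
    fr <- disc_frame(50, size = 200, polarity = polarity)
    seg <- segment_spheroid(fr, segmentation_config(polarity = polarity))
    expect_lt(abs(seg$area_px - pi * 50^2) / (pi * 50^2), 0.02)
    expect_equal(seg$equivalent_radius_um, sqrt(seg$area_px / pi))
  }
})

test_that("segmentation keeps one connected component and drops speckles", {
  fr <- disc_frame(30, size = 160, n_speckles = 20)
  seg <- segment_spheroid(fr)
  lab <- EBImage::bwlabel(EBImage::Image(t(seg$mask)))
  expect_equal(max(lab), 1)
  # speckles (single pixels) must not survive the opening
  expect_lt(abs(seg$area_px - pi * 30^2) / (pi * 30^2), 0.05)
})

test_that("contrast-free frames raise an empty-segmentation error", {
  blank <- frame_image(matrix(0, 64, 64), 1, day = 3)
  expect_error(segment_spheroid(blank), "empty segmentation")
  expect_error(segment_spheroid(frame_image(matrix(128, 64, 64), 1, day = 3.5)),
               "empty segmentation")
})

test_that("equivalent radius is invariant under rotation of the frame", {
  fr <- disc_frame(41, size = 160, noise_sd = 5, centre = c(70, 95))
  rot <- frame_image(t(fr$pixels)[, rev(seq_len(160))], 1, day = 2) # 90 deg
  r1 <- segment_spheroid(fr)$equivalent_radius_um
  r2 <- segment_spheroid(rot)$equivalent_radius_um
  expect_lt(abs(r1 - r2) / r1, 0.01)
})

test_that("equivalent_circle_radius follows pixel_size * sqrt(area/pi)", {
  expect_equal(equivalent_circle_radius(pi, 1), 1)
  expect_equal(equivalent_circle_radius(7854, 1), sqrt(7854 / pi))
  expect_equal(
    equivalent_circle_radius(7854, 0.65),
    0.65 * equivalent_circle_radius(7854, 1)
  )
  expect_error(equivalent_circle_radius(0, 1), "positive")
})

test_that("extract_growth_curve recovers counts and drops failing frames", {
  spec <- synthetic_spec(
    richards = c(A = 1, B = 0.9, C = 3000, M = 8, T = 1),
    day_start = 4, day_end = 12, frame_interval_h = 24,
    image_size_px = 280, noise_sd = 4, seed = 5
  )
  tl <- generate_timelapse(spec)
  curve <- extract_growth_curve(tl$frames, spec$cell_diameter_um)
  expect_s3_class(curve, "growth_curve")
  expect_identical(nrow(curve), length(tl$frames))
  # per-frame counts track the generating counts
  expect_true(all(abs(curve$cell_count - tl$counts) / tl$counts < 0.12))
  expect_false(is.unsorted(curve$cell_count))

  # a blank frame is dropped with a warning, shortening the curve by one
  frames2 <- tl$frames
  frames2[[3]] <- frame_image(matrix(128, 280, 280), spec$pixel_size_um,
                              day = frames2[[3]]$day)
  expect_warning(curve2 <- extract_growth_curve(frames2, spec$cell_diameter_um),
                 "dropped")
  expect_identical(nrow(curve2), length(tl$frames) - 1L)
})

test_that("two identical frames give two equal counts", {
  f1 <- disc_frame(30, size = 128, day = 2)
  f2 <- disc_frame(30, size = 128, day = 2.125)
  curve <- extract_growth_curve(list(f1, f2), cell_diameter_um = 10)
  expect_identical(curve$cell_count[1], curve$cell_count[2])
})

test_that("insufficient usable frames raise an error", {
  f1 <- disc_frame(30, size = 128, day = 2)
  blank <- frame_image(matrix(128, 128, 128), 1, day = 2.125)
  expect_error(
    suppressWarnings(extract_growth_curve(list(f1, blank), 10)),
    "insufficient series"
  )
})

test_that("single-cell size comes from one- and two-cell frames", {
  # one cell of diameter 10 um at 0.5 um/px -> radius 10 px
  f1 <- disc_frame(10, size = 128, pixel_size_um = 0.5)
  expect_lt(abs(estimate_single_cell_size(list(f1)) - 10) / 10, 0.02)

  # two touching equal discs flagged as two-cell: per-cell diameter of one disc
  size <- 160
  xi <- matrix(seq_len(size), size, size)
  yi <- t(xi)
  px <- matrix(200, size, size)
  px[(xi - 70)^2 + (yi - 80)^2 <= 100] <- 60
  px[(xi - 90)^2 + (yi - 80)^2 <= 100] <- 60
  f2 <- frame_image(px, 0.5, day = 2)
  est <- estimate_single_cell_size(list(f2), n_cells = 2L)
  expect_lt(abs(est - 10) / 10, 0.05)

  expect_error(estimate_single_cell_size(list()), "at least one frame")
  blank <- frame_image(matrix(128, 64, 64), 1)
  expect_error(estimate_single_cell_size(list(blank)), "empty segmentation")
})
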