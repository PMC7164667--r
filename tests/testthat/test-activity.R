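test_that("generation census counts every particle exactly once", {
  single <- make_state(matrix(0, 1, 3), generation = 0L)
  expect_equal(as.data.frame(generation_census(single)),
               data.frame(generation = 0L, count = 1L),
               ignore_attr = TRUE)
  after_division <- make_state(rbind(c(-2.5, 0, 0), c(2.5, 0, 0)),
                               generation = c(1L, 1L))
  expect_equal(as.data.frame(generation_census(after_division)),
               data.frame(generation = 1L, count = 2L),
               ignore_attr = TRUE)
  # totals equal the snapshot size on a simulated trajectory
  tr <- run_simulation(sim_config(total_days = 1.5, capacity = Inf, n0 = 12,
                                  Ke = 0.05, seed = 21))
  for (s in tr$snapshots) {
    expect_identical(sum(generation_census(s)$count), nrow(s$particles))
  }
})

test_that("activity cutoff is the last generation of the unchanged run", {
  # equal up to 13, decreased at 14-15, increased at 16-17
  d14 <- census_of(c(`10` = 50, `11` = 80, `12` = 120, `13` = 200,
                     `14` = 300, `15` = 250, `16` = 100, `17` = 10))
  d15 <- census_of(c(`10` = 50, `11` = 80, `12` = 120, `13` = 200,
                     `14` = 260, `15` = 200, `16` = 250, `17` = 90), day = 15)
  expect_identical(activity_cutoff(d14, d15), 13L)

  # decreased at 13, increased at 14: low up to generation 12
  a <- census_of(c(`11` = 40, `12` = 60, `13` = 90, `14` = 20))
  b <- census_of(c(`11` = 40, `12` = 60, `13` = 70, `14` = 60), day = 15)
  expect_identical(activity_cutoff(a, b), 12L)

  # identical censuses: all low, with a warning
  expect_warning(g <- activity_cutoff(d14, d14), "identical")
  expect_identical(g, 17L)

  # a change in the lowest generation puts the cutoff below the range
  x <- census_of(c(`5` = 10, `6` = 20))
  y <- census_of(c(`5` = 8, `6` = 26), day = 15)
  expect_identical(activity_cutoff(x, y), 4L)
})

test_that("cutoff ignores how generations above g*+1 change", {
  base <- census_of(c(`8` = 30, `9` = 40, `10` = 50, `11` = 60, `12` = 70))
  nxt1 <- census_of(c(`8` = 30, `9` = 40, `10` = 45, `11` = 80, `12` = 60), day = 15)
  nxt2 <- census_of(c(`8` = 30, `9` = 40, `10` = 45, `11` = 10, `12` = 999), day = 15)
  expect_identical(activity_cutoff(base, nxt1), 9L)
  expect_identical(activity_cutoff(base, nxt2), 9L)
})

test_that("low-activity ratio is the cumulative census share", {
  cen <- census_of(c(`10` = 100, `11` = 200, `12` = 300, `13` = 400, `14` = 500))
  expect_equal(low_activity_ratio(cen, 12L), 0.40)
  expect_equal(low_activity_ratio(cen, 14L), 1.0)
  expect_equal(low_activity_ratio(cen, 9L), 0.0)
  # monotone non-decreasing in g*
  ratios <- vapply(9:14, function(g) low_activity_ratio(cen, g), numeric(1))
  expect_true(all(diff(ratios) >= 0))
  expect_error(low_activity_ratio(census_of(c(`1` = 0)), 1L), "empty census")
})

test_that("particle labels are consistent with the ratio", {
  st <- make_state(hcp_cluster(60, 11.06),
                   generation = rep(10:15, each = 10))
  labels <- label_particles(st, 12L)
  expect_identical(sum(labels == "low") / length(labels),
                   low_activity_ratio(generation_census(st), 12L))
  expect_true(all(label_particles(st, 15L) == "low"))
})

test_that("cross sections slice slabs through the centroid", {
  single <- make_state(matrix(0, 1, 3))
  sec <- cross_sections(single)
  expect_identical(vapply(sec, nrow, integer(1)),
                   c(xy = 1L, xz = 1L, yz = 1L))
  # spherical fixture: the three sections have comparable occupancy
  set.seed(5)
  n <- 2000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 50 * runif(n)^(1 / 3)
  st <- make_state(u, generation = sample(1:5, n, TRUE))
  sec <- cross_sections(st)
  counts <- vapply(sec, nrow, integer(1))
  expect_lt(diff(range(counts)) / mean(counts), 0.2)
})

test_that("recent generations concentrate near the surface in a grown run", {
  tr <- run_simulation(sim_config(total_days = 3, capacity = 2e6, n0 = 80,
                                  Ke = 0.05, seed = 17))
  last <- tr$snapshots[[length(tr$snapshots)]]
  p <- last$particles
  pos <- as.matrix(p[, c("x_um", "y_um", "z_um")])
  r <- sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2))
  young <- p$generation >= max(p$generation) - 1
  old <- p$generation <= min(p$generation) + 1
  expect_gt(mean(r[young]), mean(r[old]))
})

test_that("cross sections render deterministically to PNG", {
  st <- make_state(hcp_cluster(80, 11.06), generation = rep(1:4, 20))
  sec <- cross_sections(st, colour_by = label_particles(st, 2L))
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  plot_cross_sections(sec, f1)
  plot_cross_sections(sec, f2)
  expect_true(file.exists(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("quiescent volume ratio is the cubed diameter ratio", {
  expect_equal(quiescent_volume_ratio(0, 100)$quiescent, 0)
  expect_equal(quiescent_volume_ratio(100, 100)$quiescent, 1)
  q <- quiescent_volume_ratio(80, 100)
  expect_equal(q$quiescent, 0.512)
  expect_equal(q$proliferation, 0.488)
  expect_error(quiescent_volume_ratio(120, 100), "inner diameter")
})

test_that("relative size ratios are taken against the largest spheroid", {
  expect_equal(relative_size_ratios(c(289, 291, 271, 237)),
               c(0.99, 1, 0.93, 0.81))
  expect_equal(relative_size_ratios(c(50, 100), reference = 1), c(1, 2))
})
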