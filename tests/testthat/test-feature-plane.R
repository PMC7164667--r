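test_that("normalization is a population z-score with stored record", {
  # each parameter alternates {0, 2}: mean 1, population SD 1 -> scores +/-1
  cohort <- as.data.frame(matrix(rep(c(0, 2), 10), nrow = 4,
    dimnames = list(NULL, c("A", "B", "C", "M", "T"))
  ))
  nz <- normalize_param_vectors(cohort)
  expect_true(all(abs(abs(nz$scores) - 1) < 1e-12))
  expect_equal(unname(colMeans(nz$scores)), rep(0, 5))
  expect_identical(nz$sd_convention, "population")
  expect_equal(unname(nz$scale), rep(1, 5))
})

test_that("zero-variance parameters are centred only, with a warning", {
  cohort <- data.frame(A = c(1, 1, 1), B = 1:3, C = 1:3, M = 1:3, T = 1:3)
  expect_warning(nz <- normalize_param_vectors(cohort), "zero variance.*A")
  expect_equal(unname(nz$scores[, "A"]), rep(0, 3))
})

test_that("identical cohorts are all zero after centering", {
  cohort <- data.frame(A = rep(1, 3), B = rep(2, 3), C = rep(3, 3),
                       M = rep(4, 3), T = rep(5, 3))
  expect_warning(nz <- normalize_param_vectors(cohort), "zero variance")
  expect_true(all(nz$scores == 0))
})

test_that("feature plane recovers a known dominant axis", {
  # diagonal Gaussian with variances (4, 1, 0.1, 0.1, 0.1) on (A, B, C, M, T):
  # eigenvalues equal the variances, so contributions are 4/5.3 and 1/5.3
  set.seed(42)
  n <- 500
  mat <- cbind(
    A = rnorm(n, 0, 2), B = rnorm(n, 0, 1), C = rnorm(n, 0, sqrt(0.1)),
    M = rnorm(n, 0, sqrt(0.1)), T = rnorm(n, 0, sqrt(0.1))
  )
  plane <- pca_feature_plane(mat)
  expect_equal(plane$contribution_pct[1], 100 * 4 / 5.3, tolerance = 0.08)
  expect_equal(plane$contribution_pct[2], 100 * 1 / 5.3, tolerance = 0.15)
  # first axis aligns with A
  expect_gt(abs(plane$rotation["A", "C1"]), 0.99)
  expect_equal(sum(plane$contribution_pct), 100)
  # scores are centred
  expect_equal(mean(plane$points$C1), 0, tolerance = 1e-9)
  expect_equal(mean(plane$points$C2), 0, tolerance = 1e-9)
})

test_that("collinear cohorts put all variance on the first component", {
  base <- c(A = 1, B = 2, C = 3, M = 4, T = 5)
  cohort <- t(sapply(c(0, 1, 2, 3), function(s) base * (1 + s)))
  plane <- pca_feature_plane(pca_norm <- normalize_param_vectors(cohort))
  expect_equal(plane$contribution_pct[1], 100, tolerance = 1e-6)
  expect_equal(plane$contribution_pct[2], 0, tolerance = 1e-6)
})

test_that("variance-free cohorts are rejected", {
  cohort <- data.frame(A = rep(1, 3), B = rep(2, 3), C = rep(3, 3),
                       M = rep(4, 3), T = rep(5, 3))
  expect_error(
    suppressWarnings(pca_feature_plane(normalize_param_vectors(cohort))),
    "rank"
  )
})

test_that("projection through the stored normalization reproduces scores", {
  coh <- generate_cohort(n = 12, seed = 3)
  fits <- do.call(rbind, lapply(coh$curves, function(cv) fit_richards(cv)$params))
  nz <- normalize_param_vectors(fits)
  plane <- pca_feature_plane(nz)
  proj <- project_onto_plane(plane, fits)
  expect_equal(proj$C1, plane$points$C1, tolerance = 1e-9)
  expect_equal(proj$C2, plane$points$C2, tolerance = 1e-9)
  expect_identical(proj$quadrant, plane$points$quadrant)
})

test_that("eigenvector orientation fixes the quadrant semantics", {
  coh <- generate_cohort(n = 18, seed = 9)
  # A is held at 1 cell across the cohort, so it centres with a warning
  plane <- pca_feature_plane(suppressWarnings(normalize_param_vectors(coh$truth)))
  expect_gte(plane$rotation["C", "C1"], 0)
  expect_gte(plane$rotation["B", "C2"], 0)
})

test_that("quadrants follow sign convention with lower-numbered tie-break", {
  expect_identical(quadrant_of(c(1, 1)), 1L)
  expect_identical(quadrant_of(c(-1, 1)), 2L)
  expect_identical(quadrant_of(c(-1, -1)), 3L)
  expect_identical(quadrant_of(c(1, -1)), 4L)
  expect_identical(quadrant_of(c(0, 1)), 1L)
  expect_identical(quadrant_of(c(-1, 0)), 2L)
  expect_identical(quadrant_of(c(0, -1)), 3L)
  expect_identical(quadrant_of(c(1, 0)), 1L)
  expect_identical(
    quadrant_of(rbind(c(2, 3), c(-2, 3), c(-2, -3), c(2, -3))),
    1:4
  )
})
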