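#' Centre and scale a cohort of Richards parameter vectors
#'
#' Each of the five parameters (`A`, `B`, `C`, `M`, `T`) is z-scored across
#' the cohort: centred on its mean and divided by its population standard
#' deviation (divisor `n`, not `n - 1`; the convention is stored in the
#' normalization record so projections round-trip exactly). A parameter with
#' zero variance is centred only, with a warning.
#'
#' @param cohort A matrix or data frame with columns `A`, `B`, `C`, `M`, `T`,
#'   one row per spheroid (>= 3 rows), or a list of named parameter vectors.
#' @return List with `scores` (normalized matrix), `center` and `scale`
#'   (named numeric vectors) and `sd_convention = "population"`.
#' @export
normalize_param_vectors <- function(cohort) {
  mat <- as_param_matrix(cohort)
  if (nrow(mat) < 3) stop("cohort must contain at least 3 parameter vectors")
  ctr <- colMeans(mat)
  n <- nrow(mat)
  scl <- sqrt(colMeans(sweep(mat, 2, ctr)^2)) # population SD
  zero <- scl <= .Machine$double.eps * pmax(abs(ctr), 1)
  if (any(zero)) {
    warning(
      "zero variance in parameter(s) ", paste(names(ctr)[zero], collapse = ", "),
      "; centred only"
    )
    scl[zero] <- 1
  }
  scores <- sweep(sweep(mat, 2, ctr), 2, scl, "/")
  list(scores = scores, center = ctr, scale = scl, sd_convention = "population")
}

as_param_matrix <- function(cohort) {
  if (is.list(cohort) && !is.data.frame(cohort)) {
    cohort <- do.call(rbind, lapply(cohort, function(p) unlist(p)[c("A", "B", "C", "M", "T")]))
  }
  mat <- as.matrix(as.data.frame(cohort)[, c("A", "B", "C", "M", "T")])
  storage.mode(mat) <- "double"
  mat
}

#' Principal-component feature plane of a growth-curve cohort
#'
#' Eigen-decomposes the covariance of the normalized five-parameter vectors
#' and keeps the first two components as a feature plane. Each spheroid gets
#' a score pair (C1, C2); contribution rates are eigenvalue shares in
#' percent. Eigenvector signs are fixed so that the loading of parameter `C`
#' on the first component and the loading of `B` on the second are
#' non-negative, giving reproducible quadrant labels.
#'
#' @param normalized Output of [normalize_param_vectors()], or a plain
#'   matrix (centred, but not rescaled, internally). A perfectly collinear
#'   cohort is valid (the second component then carries 0% of the
#'   variance); a cohort with no variance at all is rejected.
#' @return Object of class `feature_plane`: list with `rotation` (5 x 2
#'   loadings), `contribution_pct` (length 5, sums to 100), `points` (data
#'   frame `C1`, `C2`, `quadrant`), and the normalization record.
#' @export
pca_feature_plane <- function(normalized) {
  if (is.matrix(normalized)) {
    ctr <- colMeans(normalized)
    normalized <- list(
      scores = sweep(normalized, 2, ctr),
      center = ctr,
      scale = rep(1, ncol(normalized)),
      sd_convention = "population"
    )
  }
  x <- normalized$scores
  cv <- stats::cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  if (max(eg$values) <= 1e-12) {
    stop("cohort covariance has rank 0 (no parameter varies); ",
         "a feature plane is undefined")
  }
  contribution_pct <- 100 * eg$values / sum(eg$values)
  rot <- eg$vectors[, 1:2, drop = FALSE]
  rownames(rot) <- colnames(x)
  colnames(rot) <- c("C1", "C2")
  if (rot["C", "C1"] < 0) rot[, "C1"] <- -rot[, "C1"]
  if (rot["B", "C2"] < 0) rot[, "C2"] <- -rot[, "C2"]
  pts <- x %*% rot
  points <- data.frame(
    C1 = pts[, 1], C2 = pts[, 2],
    quadrant = quadrant_of(pts)
  )
  structure(
    list(
      rotation = rot,
      contribution_pct = contribution_pct,
      points = points,
      center = normalized$center,
      scale = normalized$scale,
      sd_convention = normalized$sd_convention
    ),
    class = "feature_plane"
  )
}

#' Project new Richards parameter vectors onto an existing feature plane
#'
#' @param plane A [pca_feature_plane()] result.
#' @param params Parameter vector(s): named vector, matrix or data frame with
#'   columns `A`, `B`, `C`, `M`, `T`.
#' @return Data frame with `C1`, `C2`, `quadrant`.
#' @export
project_onto_plane <- function(plane, params) {
  stopifnot(inherits(plane, "feature_plane"))
  if (is.numeric(params) && is.null(dim(params))) params <- t(params)
  mat <- as_param_matrix(params)
  z <- sweep(sweep(mat, 2, plane$center), 2, plane$scale, "/")
  pts <- z %*% plane$rotation
  data.frame(C1 = pts[, 1], C2 = pts[, 2], quadrant = quadrant_of(pts))
}

#' Quadrant of a point on the feature plane
#'
#' Standard quadrant numbering by sign of (C1, C2): 1 = (+,+), 2 = (-,+),
#' 3 = (-,-), 4 = (+,-). Points on an axis are assigned to the adjacent
#' lower-numbered quadrant, so (0, 1) is quadrant 1 and (-1, 0) is quadrant 2.
#'
#' @param points Two-column matrix or data frame of (C1, C2), or a length-2
#'   vector.
#' @return Integer vector of quadrants 1-4.
#' @export
quadrant_of <- function(points) {
  if (is.numeric(points) && is.null(dim(points))) points <- t(points)
  points <- as.matrix(points)
  c1 <- points[, 1]
  c2 <- points[, 2]
  q <- integer(length(c1))
  q[c1 >= 0 & c2 >= 0] <- 1L
  q[c1 < 0 & c2 >= 0] <- 2L
  q[c1 < 0 & c2 < 0] <- 3L
  q[c1 >= 0 & c2 < 0] <- 4L
  # axis tie-breaks toward the lower-numbered adjacent quadrant
  q[c1 == 0 & c2 < 0] <- 3L
  q[c2 == 0 & c1 < 0] <- 2L
  q
}

#' @export
print.feature_plane <- function(x, ...) {
  cat("PCA feature plane over Richards parameters (A, B, C, M, T)\n")
  cat(sprintf(
    "contribution rates: C1 %.2f%%, C2 %.2f%% (accumulated %.2f%%)\n",
    x$contribution_pct[1], x$contribution_pct[2],
    sum(x$contribution_pct[1:2])
  ))
  cat(sprintf("%d spheroids\n", nrow(x$points)))
  invisible(x)
}
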