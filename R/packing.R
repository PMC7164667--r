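#' Sphere-packing bounds on the number of cells in a spheroid
#'
#' A spheroid of diameter `spheroid_diameter_um` is treated as a sphere filled
#' with equal cellular spheres of diameter `cell_diameter_um`. The cell count
#' is bounded below by simple cubic packing (density pi/6) and above by
#' face-centred cubic packing (density pi/(3*sqrt(2))):
#' \deqn{n = \lfloor (D/d)^3 \, \rho \rfloor}
#' with \eqn{\rho} the packing density. Counts are floored to whole cells and
#' clamped to at least 1 (a spheroid at least one cell across contains a cell).
#'
#' @param spheroid_diameter_um Spheroid diameter in micrometres.
#' @param cell_diameter_um Single-cell diameter in micrometres.
#' @return A list with integer elements `lower` (simple cubic) and `upper`
#'   (face-centred cubic). Vector inputs give vector elements.
#' @examples
#' packing_count_bounds(100, 10) # list(lower = 523, upper = 740)
#' @seealso [estimate_cell_count()] for the FCC point estimate.
#' @export
packing_count_bounds <- function(spheroid_diameter_um, cell_diameter_um) {
  stopifnot(is.numeric(spheroid_diameter_um), is.numeric(cell_diameter_um))
  if (any(cell_diameter_um <= 0)) {
    stop("cell_diameter_um must be positive")
  }
  if (any(spheroid_diameter_um < cell_diameter_um)) {
    stop("spheroid smaller than a single cell: spheroid_diameter_um < cell_diameter_um")
  }
  ratio3 <- (spheroid_diameter_um / cell_diameter_um)^3
  lower <- pmax(1, floor(ratio3 * pi / 6))
  upper <- pmax(1, floor(ratio3 * pi / (3 * sqrt(2))))
  list(lower = as.integer(lower), upper = as.integer(upper))
}

#' Point estimate of the cell count in a spheroid
#'
#' The working estimate of the number of cells is the face-centred cubic
#' (upper) packing bound: spheroids are assumed densely packed, so the FCC
#' count is used as the point estimate `e(t)` on growth curves.
#'
#' @inheritParams packing_count_bounds
#' @return Integer cell count (FCC bound), vectorized over inputs.
#' @export
estimate_cell_count <- function(spheroid_diameter_um, cell_diameter_um) {
  packing_count_bounds(spheroid_diameter_um, cell_diameter_um)$upper
}

#' Invert the FCC count estimate back to a spheroid diameter
#'
#' Given a cell count, returns the diameter of the sphere whose FCC packing
#' holds that many cells of the given diameter (before flooring). Used by the
#' synthetic image generator so that analysis and generation are inverse maps.
#'
#' @param count Cell count (may be non-integer).
#' @param cell_diameter_um Single-cell diameter in micrometres.
#' @return Spheroid diameter in micrometres.
#' @export
diameter_from_count <- function(count, cell_diameter_um) {
  stopifnot(count > 0, cell_diameter_um > 0)
  cell_diameter_um * (count / (pi / (3 * sqrt(2))))^(1 / 3)
}

#' Generate a hexagonal close-packed cluster of particle centres
#'
#' Builds an HCP lattice with nearest-neighbour spacing `spacing_um`, keeps
#' the `n` sites closest to the lattice point nearest the cluster centroid,
#' and recentres. Interior sites of an HCP lattice have exactly 12 touching
#' neighbours (the kissing number in three dimensions), which makes the
#' cluster a reference fixture for density computations and the default
#' initial condition when a simulation starts from more than one particle.
#'
#' @param n Number of particles.
#' @param spacing_um Nearest-neighbour distance in micrometres.
#' @return A numeric matrix with `n` rows and columns `x`, `y`, `z` (um).
#' @export
hcp_cluster <- function(n, spacing_um = 10) {
  stopifnot(n >= 1, spacing_um > 0)
  side <- max(3L, ceiling((2 * n)^(1 / 3)) + 3L)
  idx <- expand.grid(i = 0:(side - 1), j = 0:(side - 1), k = 0:(side - 1))
  # HCP: A-B stacking of triangular layers (B above triangle centroids)
  x <- spacing_um * (idx$i + 0.5 * (idx$j %% 2) + 0.5 * (idx$k %% 2))
  y <- spacing_um * (sqrt(3) / 2) * (idx$j + (idx$k %% 2) / 3)
  z <- spacing_um * (sqrt(6) / 3) * idx$k
  pts <- cbind(x = x, y = y, z = z)
  ctr <- colMeans(pts)
  d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 + (pts[, 3] - ctr[3])^2
  near <- which.min(d2)
  d2c <- (pts[, 1] - pts[near, 1])^2 + (pts[, 2] - pts[near, 2])^2 +
    (pts[, 3] - pts[near, 3])^2
  keep <- order(d2c)[seq_len(n)]
  out <- pts[keep, , drop = FALSE]
  out <- sweep(out, 2, colMeans(out))
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Monte-Carlo random-close-packing count of spheres in a spherical container
#'
#' Independent packing estimate used to sanity-check the lattice bounds:
#' candidate spheres are inserted sequentially at random positions inside the
#' container, then iterative pairwise overlap relaxation pushes spheres apart
#' (and back inside the container) until no overlaps remain or the insertion
#' fails. The achieved count corresponds to a random close packing, whose
#' density (about 0.64) falls between simple cubic (0.524) and FCC (0.740).
#'
#' @param container_diameter_um Container sphere diameter (um).
#' @param sphere_diameter_um Packed sphere diameter (um).
#' @param seed Integer seed for the random insertions.
#' @param relax_iter Relaxation sweeps per insertion batch.
#' @return Integer: number of spheres packed without overlap.
#' @export
random_packing_count <- function(container_diameter_um, sphere_diameter_um,
                                 seed = 1L, relax_iter = 400L) {
  stopifnot(container_diameter_um >= sphere_diameter_um)
  cpp_random_packing(container_diameter_um, sphere_diameter_um,
                     as.integer(seed), as.integer(relax_iter))
}
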