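#' Specification of a synthetic spheroid acquisition
#'
#' Describes a simulated time-lapse experiment: a Richards curve driving the
#' spheroid's cell count, the acquisition schedule and optics, and the image
#' noise model. Every generator consuming the spec is deterministic given
#' `seed`.
#'
#' @param richards Named vector `A, B, C, M, T` of the driving curve.
#' @param day_start,day_end Acquisition window (days since seeding).
#' @param frame_interval_h Hours between frames (default 3).
#' @param pixel_size_um Micrometres per pixel (default 0.65, a typical 10x
#'   phase-contrast scale).
#' @param image_size_px Square frame side in pixels.
#' @param cell_diameter_um Single-cell diameter used in the packing
#'   inversion.
#' @param noise_sd Gaussian background noise SD on the 0..255 intensity
#'   scale.
#' @param count_noise_sd Lognormal sigma multiplying the curve's counts.
#' @param speckle_rate Fraction of pixels replaced by isolated salt/pepper
#'   speckles.
#' @param polarity `"dark"` object on bright background (default) or
#'   `"bright"`.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(richards = c(A = 1, B = 0.9, C = 4000, M = 8, T = 1),
                           day_start = 2, day_end = 15, frame_interval_h = 3,
                           pixel_size_um = 0.65, image_size_px = 512L,
                           cell_diameter_um = 10,
                           noise_sd = 6, count_noise_sd = 0,
                           speckle_rate = 0, polarity = c("dark", "bright"),
                           seed = 1L) {
  validate_richards(richards)
  stopifnot(
    day_end > day_start, frame_interval_h > 0, pixel_size_um > 0,
    image_size_px >= 64, cell_diameter_um > 0, noise_sd >= 0,
    count_noise_sd >= 0, speckle_rate >= 0, speckle_rate < 1
  )
  structure(
    list(
      richards = unlist(richards)[c("A", "B", "C", "M", "T")],
      day_start = day_start, day_end = day_end,
      frame_interval_h = frame_interval_h,
      pixel_size_um = pixel_size_um,
      image_size_px = as.integer(image_size_px),
      cell_diameter_um = cell_diameter_um,
      noise_sd = noise_sd, count_noise_sd = count_noise_sd,
      speckle_rate = speckle_rate,
      polarity = match.arg(polarity),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a noisy growth curve from a synthetic spec
#'
#' Samples the driving Richards curve on the acquisition grid, multiplies by
#' lognormal noise of sigma `count_noise_sd`, and rounds to integer counts
#' of at least 1. The ground-truth parameters ride along for round-trip
#' testing.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `curve` (a [growth_curve()]) and `truth` (the Richards
#'   parameters).
#' @export
generate_growth_curve <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  days <- seq(spec$day_start, spec$day_end, by = spec$frame_interval_h / 24)
  base <- richards_eval(spec$richards, days)
  withr_seed(spec$seed, {
    noise <- if (spec$count_noise_sd > 0) {
      exp(stats::rnorm(length(days), 0, spec$count_noise_sd))
    } else {
      rep(1, length(days))
    }
  })
  counts <- pmax(1, round(base * noise))
  list(
    curve = growth_curve(days, counts, cell_diameter_um = spec$cell_diameter_um),
    truth = spec$richards
  )
}

# evaluate expr with a local RNG state, restoring the caller's state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

#' Generate a synthetic time-lapse frame series
#'
#' For each acquisition time, the driving curve's count is inverted through
#' the FCC packing estimate to a spheroid diameter
#' (`D = d * (count / 0.74048)^(1/3)`), and a centred disc of that diameter
#' is drawn with the configured polarity, Gaussian background noise and
#' isolated speckles. The inversion mirrors the analysis direction, so
#' extract-then-count round-trips are self-consistent.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `frames` (list of [frame_image()]), `radii_px` (ground-
#'   truth disc radii) and `counts` (ground-truth counts).
#' @export
generate_timelapse <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gc <- generate_growth_curve(spec)
  counts <- gc$curve$cell_count
  days <- gc$curve$day
  # one- and two-cell stages show the cells themselves (projected area adds),
  # not a packed aggregate; from three cells on, invert the FCC estimate
  diam_um <- ifelse(
    counts <= 2,
    spec$cell_diameter_um * sqrt(counts),
    diameter_from_count(counts, spec$cell_diameter_um)
  )
  radii_px <- diam_um / 2 / spec$pixel_size_um
  sz <- spec$image_size_px
  if (any(2 * radii_px >= sz - 4)) {
    stop("synthetic disc exceeds the frame; enlarge image_size_px or shrink C")
  }
  bg <- if (spec$polarity == "dark") 200 else 40
  fg <- if (spec$polarity == "dark") 60 else 220
  ctr <- (sz + 1) / 2
  xi <- matrix(seq_len(sz), sz, sz)
  yi <- t(xi)
  d2 <- (xi - ctr)^2 + (yi - ctr)^2
  frames <- withr_seed(spec$seed + 1L, {
    lapply(seq_along(days), function(i) {
      px <- matrix(bg, sz, sz)
      px[d2 <= radii_px[i]^2] <- fg
      if (spec$noise_sd > 0) {
        px <- px + matrix(stats::rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
      }
      if (spec$speckle_rate > 0) {
        n_spk <- round(spec$speckle_rate * sz * sz)
        at <- sample.int(sz * sz, n_spk)
        px[at] <- ifelse(stats::runif(n_spk) < 0.5, 0, 255)
      }
      px[] <- pmin(255, pmax(0, px))
      frame_image(px, spec$pixel_size_um, day = days[i])
    })
  })
  list(frames = frames, radii_px = radii_px, counts = counts)
}

#' Generate a cohort of growth curves with varied Richards parameters
#'
#' Draws independent Richards parameters per spheroid (defaults: `A` fixed
#' at 1 cell, `B` and `C` and `T` lognormal, `M` normal) and generates a
#' noisy curve for each, emulating the spread of an 18-spheroid panel. The
#' defaults centre on a curve that rises from one cell to a few thousand
#' with maximum growth around day 8.
#'
#' @param n Number of spheroids (>= 3).
#' @param seed Integer seed.
#' @param B_meanlog,B_sdlog Lognormal parameters of the growth rate (1/day).
#' @param C_meanlog,C_sdlog Lognormal parameters of the asymptotic rise.
#' @param M_mean,M_sd Normal parameters of the time of maximum growth (day).
#' @param T_meanlog,T_sdlog Lognormal parameters of the shape parameter.
#' @param count_noise_sd Lognormal sigma on curve counts.
#' @param ... Further fields passed to [synthetic_spec()].
#' @return List with `curves` (list of [growth_curve()]) and `truth` (data
#'   frame of the generating parameters, one row per spheroid).
#' @export
generate_cohort <- function(n = 18, seed = 1L,
                            B_meanlog = log(0.9), B_sdlog = 0.25,
                            C_meanlog = log(4000), C_sdlog = 0.4,
                            M_mean = 8, M_sd = 1,
                            T_meanlog = 0, T_sdlog = 0.3,
                            count_noise_sd = 0.05, ...) {
  stopifnot(n >= 3)
  pars <- withr_seed(seed, {
    data.frame(
      A = rep(1, n),
      B = stats::rlnorm(n, B_meanlog, B_sdlog),
      C = stats::rlnorm(n, C_meanlog, C_sdlog),
      M = stats::rnorm(n, M_mean, M_sd),
      T = stats::rlnorm(n, T_meanlog, T_sdlog)
    )
  })
  curves <- lapply(seq_len(n), function(i) {
    spec <- synthetic_spec(
      richards = unlist(pars[i, ]),
      count_noise_sd = count_noise_sd,
      seed = seed + i, ...
    )
    generate_growth_curve(spec)$curve
  })
  list(curves = curves, truth = pars)
}
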