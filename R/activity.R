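#' Census of particle generations in a snapshot
#'
#' Counts the particles in each generation. Generation numbers record how
#' many divisions preceded a particle, so the census is the basis of the
#' virtual proliferative-activity labelling: generations whose counts stop
#' changing between consecutive days are no longer dividing.
#'
#' @param state A `spheroid_state` snapshot (or a data frame with a
#'   `generation` column).
#' @return Object of class `generation_census`: data frame with columns
#'   `generation` and `count`, plus attribute `day`.
#' @export
generation_census <- function(state) {
  gen <- if (inherits(state, "spheroid_state")) {
    state$particles$generation
  } else {
    state$generation
  }
  if (length(gen) < 1) stop("state contains no particles")
  tab <- table(factor(gen, levels = seq(min(gen), max(gen))))
  structure(
    data.frame(
      generation = as.integer(names(tab)),
      count = as.integer(tab)
    ),
    day = if (inherits(state, "spheroid_state")) state$day else NA_real_,
    class = c("generation_census", "data.frame")
  )
}

#' Highest generation with low virtual proliferative activity
#'
#' Compares the generation censuses of two consecutive days. A generation's
#' activity is low when its particle count is identical on both days (exact
#' integer equality: counts only change through division). The cutoff `g*`
#' is the largest generation such that every generation up to and including
#' it is unchanged — a single changed generation breaks the run, matching
#' the "low up to the Nth generation" reading. Generations above `g*` are
#' labelled high-activity.
#'
#' @param census_d [generation_census()] of the earlier day.
#' @param census_d1 [generation_census()] of the following day.
#' @return Integer cutoff generation `g*`. If the censuses are identical
#'   everywhere the maximum generation is returned with a warning (no
#'   division at all between the two days).
#' @export
activity_cutoff <- function(census_d, census_d1) {
  g_all <- sort(union(census_d$generation, census_d1$generation))
  c0 <- stats::setNames(rep(0L, length(g_all)), g_all)
  c1 <- c0
  c0[as.character(census_d$generation)] <- census_d$count
  c1[as.character(census_d1$generation)] <- census_d1$count
  same <- c0 == c1
  if (all(same)) {
    warning("censuses identical for every generation; no division between ",
            "the two days (all activity low)")
    return(max(g_all))
  }
  first_change <- which(!same)[1]
  if (first_change == 1) {
    return(min(g_all) - 1L)
  }
  g_all[first_change - 1L]
}

#' Fraction of particles with low virtual proliferative activity
#'
#' Share of the census total held by generations up to and including the
#' cutoff `g*`.
#'
#' @param census A [generation_census()].
#' @param g_star Cutoff generation from [activity_cutoff()].
#' @return Fraction in `[0, 1]`.
#' @export
low_activity_ratio <- function(census, g_star) {
  if (nrow(census) == 0 || sum(census$count) == 0) stop("empty census")
  sum(census$count[census$generation <= g_star]) / sum(census$count)
}

#' Label particles as low- or high-activity
#'
#' @param state A `spheroid_state` snapshot.
#' @param g_star Cutoff generation.
#' @return Character vector (`"low"` / `"high"`), one per particle.
#' @export
label_particles <- function(state, g_star) {
  gen <- if (inherits(state, "spheroid_state")) {
    state$particles$generation
  } else {
    state$generation
  }
  ifelse(gen <= g_star, "low", "high")
}

#' Three orthogonal cross sections through the spheroid centre
#'
#' Particles within half a slab thickness of each mid-plane (xy, xz, yz
#' planes through the centroid) are projected onto that plane. Use
#' [plot_cross_sections()] to render the result.
#'
#' @param state A `spheroid_state` snapshot.
#' @param colour_by Per-particle values to carry along (e.g. generation or
#'   activity labels); default the generation numbers.
#' @param slab_thickness_um Slab thickness (um); default one cell diameter.
#' @return List of three data frames (`xy`, `xz`, `yz`), each with `h_um`,
#'   `v_um`, `colour_by`.
#' @export
cross_sections <- function(state, colour_by = NULL, slab_thickness_um = NULL) {
  stopifnot(inherits(state, "spheroid_state"), nrow(state$particles) >= 1)
  if (is.null(slab_thickness_um)) slab_thickness_um <- state$cell_diameter_um
  if (is.null(colour_by)) colour_by <- state$particles$generation
  pos <- as_position_matrix(state)
  ctr <- colMeans(pos)
  rel <- sweep(pos, 2, ctr)
  half <- slab_thickness_um / 2
  section <- function(h, v, normal) {
    keep <- abs(rel[, normal]) <= half
    data.frame(
      h_um = rel[keep, h], v_um = rel[keep, v],
      colour_by = colour_by[keep]
    )
  }
  list(
    xy = section(1, 2, 3),
    xz = section(1, 3, 2),
    yz = section(2, 3, 1)
  )
}

#' Render cross sections to a PNG file
#'
#' Draws the three orthogonal sections side by side with particles coloured
#' by the `colour_by` values (viridis-like ramp for numeric values, light =
#' low / dark = high for activity labels). Layout is deterministic.
#'
#' @param sections Output of [cross_sections()].
#' @param file Output PNG path.
#' @param point_cex Point size.
#' @return `file`, invisibly.
#' @export
plot_cross_sections <- function(sections, file, point_cex = 0.6) {
  vals <- sections$xy$colour_by
  if (is.character(vals) || is.factor(vals)) {
    pal <- c(low = "#bfd8a8", high = "#215a2d")
    col_of <- function(v) unname(pal[as.character(v)])
  } else {
    rng <- range(unlist(lapply(sections, `[[`, "colour_by")))
    ramp <- grDevices::colorRampPalette(c("#440154", "#31688e", "#35b779", "#fde725"))(64)
    col_of <- function(v) {
      i <- if (diff(rng) == 0) 1 else 1 + round(63 * (v - rng[1]) / diff(rng))
      ramp[i]
    }
  }
  lim <- max(abs(unlist(lapply(sections, function(s) c(s$h_um, s$v_um)))), 1)
  grDevices::png(file, width = 1200, height = 420)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  for (nm in c("xy", "xz", "yz")) {
    s <- sections[[nm]]
    graphics::plot(s$h_um, s$v_um,
      pch = 19, cex = point_cex, col = col_of(s$colour_by),
      xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
      xlab = paste0(substr(nm, 1, 1), " [um]"),
      ylab = paste0(substr(nm, 2, 2), " [um]"),
      main = paste(nm, "section")
    )
  }
  invisible(file)
}

#' Quiescent-zone volume ratio from two concentric diameters
#'
#' Approximating the quiescent core and the whole spheroid as concentric
#' spheres of the given diameters, the quiescent volume fraction is
#' `(inner / outer)^3`; the complementary proliferation-zone fraction is one
#' minus that.
#'
#' @param inner_diameter_um Diameter of the inner (quiescent) sphere.
#' @param outer_diameter_um Diameter of the whole spheroid.
#' @return List with `quiescent` and `proliferation` fractions.
#' @export
quiescent_volume_ratio <- function(inner_diameter_um, outer_diameter_um) {
  stopifnot(outer_diameter_um > 0)
  if (any(inner_diameter_um < 0) || any(inner_diameter_um > outer_diameter_um)) {
    stop("inner diameter must lie in [0, outer diameter]")
  }
  q <- (inner_diameter_um / outer_diameter_um)^3
  list(quiescent = q, proliferation = 1 - q)
}

#' Relative day-15 size ratios of a spheroid panel
#'
#' Expresses each diameter as a ratio to a reference spheroid's diameter
#' (the panel's largest by default), rounded to two decimals — the standard
#' bookkeeping for comparing a panel of spheroids of one experiment.
#'
#' @param diameters_um Numeric vector of diameters.
#' @param reference Index of the reference spheroid; default the largest.
#' @param digits Rounding digits (default 2).
#' @return Numeric vector of ratios (reference ratio = 1).
#' @export
relative_size_ratios <- function(diameters_um, reference = which.max(diameters_um),
                                 digits = 2) {
  stopifnot(all(diameters_um > 0), reference >= 1,
            reference <= length(diameters_um))
  round(diameters_um / diameters_um[reference], digits)
}
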