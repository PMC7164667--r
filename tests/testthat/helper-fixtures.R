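# Shared fixtures, built in code at test time.

# A clean synthetic frame: disc of `radius_px` centred in a `size` x `size`
# 8-bit image, dark-on-bright by default, optional noise and speckles.
disc_frame <- function(radius_px, size = 128L, day = 2, pixel_size_um = 1,
                       polarity = "dark", noise_sd = 0, n_speckles = 0,
                       centre = NULL, seed = 1) {
  bg <- if (polarity == "dark") 200 else 40
  fg <- if (polarity == "dark") 60 else 220
  if (is.null(centre)) centre <- c((size + 1) / 2, (size + 1) / 2)
  xi <- matrix(seq_len(size), size, size)
  yi <- t(xi)
  px <- matrix(bg, size, size)
  px[(xi - centre[1])^2 + (yi - centre[2])^2 <= radius_px^2] <- fg
  set.seed(seed)
  if (noise_sd > 0) px <- px + matrix(rnorm(size^2, 0, noise_sd), size, size)
  if (n_speckles > 0) {
    # isolated single-pixel speckles away from the disc
    free <- which((xi - centre[1])^2 + (yi - centre[2])^2 > (radius_px + 10)^2)
    px[sample(free, n_speckles)] <- fg
  }
  px[] <- pmin(255, pmax(0, px))
  frame_image(px, pixel_size_um, day = day)
}

# Deterministic small particle table wrapped as a spheroid_state
make_state <- function(pos, generation = rep(0L, nrow(pos)), day = 14,
                       R_t = 1, cell_diameter_um = 10) {
  pos <- as.matrix(pos)
  structure(
    list(
      particles = data.frame(
        id = seq_len(nrow(pos)),
        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
        generation = as.integer(generation),
        cycle_age_min = 0, N = 1, density = 0, mobility = 1
      ),
      time_min = day * 1440, day = day, R_t = R_t,
      diameter_um = 2 * (max(sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2))) +
                           cell_diameter_um / 2),
      cell_diameter_um = cell_diameter_um
    ),
    class = "spheroid_state"
  )
}

# Census from a named vector, e.g. census_of(c(`10` = 100, `11` = 200), day = 14)
census_of <- function(counts, day = 14) {
  structure(
    data.frame(
      generation = as.integer(names(counts)),
      count = as.integer(counts)
    ),
    day = day,
    class = c("generation_census", "data.frame")
  )
}
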