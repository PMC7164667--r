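#' Simulation configuration with standard defaults
#'
#' Bundles every tunable of the lattice-free cellular-particle simulator.
#' Force constants (`k = 0.005`, `R = 1.106`, `G = 1.5`) balance attraction
#' and repulsion so that relaxed clusters settle near hexagonal close
#' packing; the equilibrium pair distance is `R * cell_diameter_um`
#' (11.06 um) and interaction ceases beyond `G * cell_diameter_um` (15 um).
#' Growth sources diffuse at most `max_depth_um` = 200 um below the surface
#' with consumption-to-diffusion ratio `alpha_over_D` = 20 per mm^2.
#'
#' @param total_days Simulated duration in days.
#' @param dt_min Time step in minutes (the model is stepped every minute).
#' @param cell_diameter_um Cellular-particle diameter (um); also the base
#'   distance of the force law.
#' @param k,R,G Force constant, repulsion constant and attraction constant.
#'   Requires `0 < R < G`.
#' @param max_depth_um Maximum depth below the surface that growth sources
#'   reach (um).
#' @param alpha_over_D Particle consumption over diffusion coefficient, per
#'   square millimetre.
#' @param shell_width_um Radial discretization of the diffusion profile (um).
#' @param min_cycle_h Minimum cell-cycle time in hours; its reciprocal is the
#'   specific maximum growth rate.
#' @param Kc Relaxation coefficient for growth sources (dimensionless).
#' @param Ke Relaxation coefficient for the environment (dimensionless).
#' @param capacity Initial growth-source budget in particle-minutes of
#'   supply (`Q0 / c`); `Inf` means unlimited.
#' @param n0 Initial particle count (1 = start from a single cell; larger
#'   values start from a relaxed HCP cluster).
#' @param g0 Initial generation number; default `ceiling(log2(n0))` so that
#'   generations approximate divisions since seeding.
#' @param start_day Day of culture corresponding to simulated time zero.
#' @param eta Overdamped mobility constant (um displacement per unit force
#'   per minute).
#' @param max_step_frac Displacement cap per step, as a fraction of
#'   `cell_diameter_um`.
#' @param eps_mobility Lower clamp on the mobility ratio (guards the central
#'   particle against division by zero).
#' @param max_particles Carrying-capacity guard: divisions are suspended
#'   while the particle count is at or above this value (default `Inf`).
#'   Used to bound the cost of exploratory runs during bridging.
#' @param desync_ages If `TRUE` (default) initial cycle ages are drawn
#'   uniformly from one minimum cycle so the founding cohort does not divide
#'   in lockstep.
#' @param snapshot_every_h Interval between recorded snapshots, hours.
#' @param seed Integer seed governing all stochastic choices (division
#'   directions, initial ages, jitter).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(total_days = 20, dt_min = 1, cell_diameter_um = 10,
                       k = 0.005, R = 1.106, G = 1.5,
                       max_depth_um = 200, alpha_over_D = 20,
                       shell_width_um = 10,
                       min_cycle_h = 18, Kc = 1, Ke = 1,
                       capacity = 2.5e7,
                       n0 = 1L, g0 = NULL, start_day = 0,
                       eta = 2000, max_step_frac = 0.2, eps_mobility = 1e-3,
                       max_particles = Inf, desync_ages = TRUE,
                       snapshot_every_h = 3, seed = 1L) {
  cfg <- list(
    total_days = total_days, dt_min = dt_min,
    cell_diameter_um = cell_diameter_um,
    k = k, R = R, G = G,
    max_depth_um = max_depth_um, alpha_over_D = alpha_over_D,
    shell_width_um = shell_width_um,
    min_cycle_h = min_cycle_h, Kc = Kc, Ke = Ke, capacity = capacity,
    n0 = as.integer(n0),
    g0 = if (is.null(g0)) as.integer(ceiling(log2(max(1, n0)))) else as.integer(g0),
    start_day = start_day,
    eta = eta, max_step_frac = max_step_frac, eps_mobility = eps_mobility,
    max_particles = max_particles, desync_ages = isTRUE(desync_ages),
    snapshot_every_h = snapshot_every_h, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(cfg$total_days >= 0, "total_days must be >= 0")
  chk(cfg$dt_min > 0, "dt_min must be positive")
  chk(cfg$cell_diameter_um > 0, "cell_diameter_um must be positive")
  chk(cfg$k > 0, "k must be positive")
  chk(cfg$R > 0, "R must be positive")
  chk(cfg$R < cfg$G, "repulsion constant R must be smaller than attraction constant G")
  chk(cfg$max_depth_um > 0, "max_depth_um must be positive")
  chk(cfg$alpha_over_D > 0, "alpha_over_D must be positive")
  chk(cfg$shell_width_um > 0, "shell_width_um must be positive")
  chk(cfg$min_cycle_h > 0, "min_cycle_h must be positive")
  chk(cfg$Kc > 0, "Kc must be positive")
  chk(cfg$Ke > 0, "Ke must be positive")
  chk(is.infinite(cfg$capacity) || cfg$capacity >= 0, "capacity must be >= 0")
  chk(cfg$n0 >= 1, "n0 must be >= 1")
  chk(cfg$max_particles >= 1, "max_particles must be >= 1")
  chk(cfg$eta > 0, "eta must be positive")
  chk(cfg$max_step_frac > 0, "max_step_frac must be positive")
  chk(cfg$snapshot_every_h > 0, "snapshot_every_h must be positive")
  if (length(problems)) {
    stop("invalid simulation config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' Signed force between two cellular particles
#'
#' \deqn{F(r) = k \left(1 - \frac{r}{R r_0}\right)\left(1 - \frac{r}{G r_0}\right)}
#' for `r < G * r0`, and 0 beyond the attraction range (`G` bounds the
#' interaction; the polynomial's unphysical re-growth past `G r0` is cut
#' off). Positive values are repulsive along the line joining the particles,
#' negative attractive. The force vanishes at `r = R * r0` (the equilibrium
#' spacing) and at `r = G * r0`.
#'
#' @param r Pair distance(s), um, > 0.
#' @param config A [sim_config()] supplying `k`, `R`, `G`, `cell_diameter_um`.
#' @return Signed force magnitude(s).
#' @export
pair_force <- function(r, config = sim_config()) {
  if (any(r <= 0)) stop("coincident particles: pair distance must be positive")
  r0 <- config$cell_diameter_um
  ifelse(r >= config$G * r0, 0,
    config$k * (1 - r / (config$R * r0)) * (1 - r / (config$G * r0))
  )
}

#' Residual growth-source index
#'
#' The fraction of the initial growth-source budget remaining after the
#' recorded consumption: `R_t = max(0, 1 - sum(consumed) / Q0)`, clamped at
#' zero once the budget is exhausted.
#'
#' @param consumed Numeric vector of per-step consumption `C_k` (same units
#'   as `Q0`).
#' @param Q0 Initial growth-source amount, > 0.
#' @return `R_t` in `[0, 1]`.
#' @export
residual_source_index <- function(consumed, Q0) {
  stopifnot(Q0 > 0)
  max(0, 1 - sum(consumed) / Q0)
}

#' Radial growth-source profile by finite differences
#'
#' Steady-state of the depth-wise diffusion-consumption balance
#' `D d2R/dx2 = alpha` on `n_shells` nodes of width `shell_width_um`, with
#' the residual index `R_s` imposed at the surface node, zero flux at the
#' innermost node, consumption only in occupied shells, and the profile
#' clamped at zero (the clamp realizes the free boundary where the source
#' runs out). Depth is measured in millimetres where `alpha_over_D` (per
#' mm^2) enters.
#'
#' @param R_s Source index at the spheroid surface (the current residual
#'   budget index).
#' @param n_shells Number of depth nodes.
#' @param shell_width_um Node spacing (um).
#' @param alpha_over_D Consumption-to-diffusion ratio (per mm^2).
#' @param occupied Logical vector (length `n_shells`): which shells contain
#'   particles and hence consume. Default all.
#' @return Numeric vector of source index per node, non-increasing with
#'   depth.
#' @export
diffusion_profile <- function(R_s, n_shells, shell_width_um,
                              alpha_over_D = 20,
                              occupied = rep(TRUE, n_shells)) {
  stopifnot(R_s >= 0, n_shells >= 1, shell_width_um > 0, alpha_over_D > 0)
  cpp_shell_profile(R_s, as.integer(n_shells), shell_width_um, alpha_over_D,
                    as.logical(occupied))
}

#' Neighbour-count density of each particle
#'
#' Number of other particles with centre distance below the attraction range
#' `G * cell_diameter_um` — the first coordination shell in near-HCP packing,
#' so interior particles of a relaxed cluster approach the kissing number 12.
#'
#' @param positions Numeric matrix (n x 3) of particle centres (um), or a
#'   `spheroid_state`.
#' @param config A [sim_config()] supplying the cutoff.
#' @param method `"grid"` (spatial-hash, default) or `"bruteforce"` (all
#'   pairs); both give identical counts.
#' @return Integer vector of neighbour counts.
#' @export
compute_density <- function(positions, config = sim_config(),
                            method = c("grid", "bruteforce")) {
  method <- match.arg(method)
  pos <- as_position_matrix(positions)
  cutoff <- config$G * config$cell_diameter_um
  if (method == "grid") {
    cpp_density_grid(pos, cutoff)
  } else {
    cpp_density_bruteforce(pos, cutoff)
  }
}

as_position_matrix <- function(positions) {
  if (inherits(positions, "spheroid_state")) {
    positions <- positions$particles[, c("x_um", "y_um", "z_um")]
  }
  pos <- as.matrix(positions)
  stopifnot(ncol(pos) == 3)
  storage.mode(pos) <- "double"
  pos
}

#' Mobility of each particle
#'
#' Ratio of the particle's distance from the spheroid centroid to the
#' spheroid radius (the centre distance of the outermost particle), clamped
#' below at `eps_mobility` so the central particle keeps a finite cycle
#' time. Ranges over `[eps, 1]`, reaching exactly 1 at the outermost
#' particle and increasing toward the surface.
#'
#' @inheritParams compute_density
#' @return Numeric vector in `[eps_mobility, 1]`.
#' @export
compute_mobility <- function(positions, config = sim_config()) {
  pos <- as_position_matrix(positions)
  ctr <- colMeans(pos)
  d <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  rmax <- max(d)
  if (rmax == 0) {
    return(rep(config$eps_mobility, nrow(pos)))
  }
  pmax(config$eps_mobility, d / rmax)
}

#' Cell-cycle time of a particle under Monod-type control
#'
#' \deqn{T_z = \frac{1}{\mu_{max}} \cdot
#'   \frac{1 + (K_c / N_z)^2}{1 + K_c^2} \cdot
#'   \left(1 + K_e \frac{D_z}{P_z}\right)}
#' The supply factor equals 1 at full supply (`N_z = 1`), so the cycle
#' attains its minimum `1 / mu_max` for a fully supplied, isolated particle;
#' starved particles (`N_z = 0`) never divide (`T_z = Inf`). Crowding
#' (density `D_z`) lengthens the cycle, mobility `P_z` (surface proximity)
#' shortens it.
#'
#' @param N_z Supplied growth-source index in `[0, 1]`.
#' @param D_z Neighbour-count density.
#' @param P_z Mobility in `[eps, 1]`.
#' @param config A [sim_config()] supplying `min_cycle_h`, `Kc`, `Ke`.
#' @return Cycle time(s) in minutes (possibly `Inf`).
#' @export
cell_cycle_time <- function(N_z, D_z, P_z, config = sim_config()) {
  stopifnot(all(N_z >= 0), all(N_z <= 1), all(P_z > 0))
  Tmin <- config$min_cycle_h * 60
  supply <- (1 + (config$Kc / N_z)^2) / (1 + config$Kc^2)
  out <- Tmin * supply * (1 + config$Ke * D_z / P_z)
  out[N_z == 0] <- Inf
  out
}

#' Divide one cellular particle into two daughters
#'
#' The parent is replaced by two daughters placed at the parent position
#' plus and minus `(r0 / 4) u` for a uniformly random unit vector `u`
#' (daughter separation `r0 / 2`). Both daughters carry generation
#' `parent + 1` and cycle age zero. Randomness comes from R's RNG, so a
#' fixed seed gives identical division directions.
#'
#' @param position Length-3 numeric parent position (um).
#' @param generation Parent generation (integer >= 0).
#' @param cell_diameter_um Particle diameter `r0` (um).
#' @return List of two daughters, each `list(position, generation, cycle_age_min)`.
#' @export
divide_particle <- function(position, generation, cell_diameter_um = 10) {
  stopifnot(length(position) == 3)
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  off <- cell_diameter_um / 4
  lapply(c(-1, 1), function(s) {
    list(
      position = position + s * off * u,
      generation = as.integer(generation) + 1L,
      cycle_age_min = 0
    )
  })
}

#' Run the lattice-free spheroid growth simulation
#'
#' Steps the particle system in `dt_min` increments. Each step: (1) updates
#' the residual source index and diffuses growth sources over depth shells,
#' (2) advances cycle ages and divides particles whose age has reached their
#' cycle time, (3) relaxes positions by overdamped displacement under the
#' pairwise force law (displacement capped at `max_step_frac * r0` per
#' step). Consumption accrues one budget unit per supplied particle per
#' minute. Deterministic for a fixed `seed`.
#'
#' @param config A [sim_config()].
#' @param init Optional n x 3 matrix of initial positions (um); default a
#'   relaxed HCP cluster of `config$n0` particles at the equilibrium spacing
#'   (or a single particle at the origin).
#' @return Object of class `spheroid_trajectory`: list with `index` (data
#'   frame `day`, `n_particles`, `diameter_um`, `R_t` per snapshot),
#'   `snapshots` (list of `spheroid_state`), and `config`. Days in `index`
#'   are days of culture (`start_day` + simulated time).
#' @export
run_simulation <- function(config = sim_config(), init = NULL) {
  validate_sim_config(config)
  n0 <- config$n0
  if (is.null(init)) {
    init <- if (n0 == 1) {
      matrix(0, 1, 3, dimnames = list(NULL, c("x", "y", "z")))
    } else {
      hcp_cluster(n0, spacing_um = config$R * config$cell_diameter_um)
    }
  }
  init <- as_position_matrix(init)
  n0 <- nrow(init)
  gen0 <- rep(config$g0, n0)
  Tmin <- config$min_cycle_h * 60
  if (config$desync_ages && n0 > 1) {
    # seeded independently of the C++ stream; founding cohort spread over one cycle
    rs <- .lcg_runif(n0, config$seed)
    age0 <- rs * Tmin
  } else {
    age0 <- rep(0, n0)
  }
  par <- config
  par$total_min <- config$total_days * 1440
  par$snapshot_every_min <- config$snapshot_every_h * 60
  raw <- cpp_run_simulation(init, as.integer(gen0), age0, par)
  snapshots <- lapply(raw$snapshots, function(s) {
    particles <- data.frame(
      id = seq_along(s$x_um),
      x_um = s$x_um, y_um = s$y_um, z_um = s$z_um,
      generation = s$generation,
      cycle_age_min = s$cycle_age_min,
      N = s$N, density = s$density, mobility = s$mobility
    )
    structure(
      list(
        particles = particles,
        time_min = s$time_min,
        day = config$start_day + s$time_min / 1440,
        R_t = s$R_t,
        diameter_um = s$diameter_um,
        cell_diameter_um = config$cell_diameter_um
      ),
      class = "spheroid_state"
    )
  })
  index <- raw$index
  index$day <- index$day + config$start_day
  structure(
    list(index = index, snapshots = snapshots, config = config,
         consumed = raw$consumed),
    class = "spheroid_trajectory"
  )
}

# Minimal deterministic uniform generator for initial-age desynchronization;
# independent of both R's RNG state and the simulator's C++ stream.
.lcg_runif <- function(n, seed) {
  state <- (as.numeric(seed) + 1) %% 2147483647
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (16807 * state) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

#' Growth curve of a simulated trajectory
#'
#' @param trajectory A [run_simulation()] result.
#' @return A [growth_curve()] with the particle count per snapshot.
#' @export
trajectory_growth_curve <- function(trajectory) {
  stopifnot(inherits(trajectory, "spheroid_trajectory"))
  growth_curve(trajectory$index$day, trajectory$index$n_particles,
    equiv_diameter_um = trajectory$index$diameter_um,
    cell_diameter_um = trajectory$config$cell_diameter_um
  )
}

#' Radial density and source profiles of a snapshot
#'
#' Partitions the spheroid into concentric shells whose width defaults to
#' the attraction range `G * r0` (the region over which the attractive force
#' acts). A particle contributes to every shell its body overlaps, so a
#' shell's cell density — the mean number of particles overlapping the
#' attraction neighbourhood (the particle itself plus its neighbours) — can
#' exceed the kissing number 12. The source profile is the diffusion grid
#' evaluated at the shell's depth.
#'
#' @param state A `spheroid_state` snapshot.
#' @param shell_width_um Shell width (um); default the attraction range.
#' @param config A [sim_config()]; defaults taken from the snapshot's cell
#'   diameter.
#' @return Data frame with `r_inner_um`, `r_outer_um`, `n_particles`
#'   (particles overlapping the shell), `cell_density` (mean attraction-
#'   neighbourhood count of those particles), `source_index`.
#' @export
radial_profiles <- function(state, shell_width_um = NULL, config = NULL) {
  stopifnot(inherits(state, "spheroid_state"), nrow(state$particles) >= 1)
  if (is.null(config)) config <- sim_config(cell_diameter_um = state$cell_diameter_um)
  if (is.null(shell_width_um)) {
    shell_width_um <- config$G * config$cell_diameter_um
  }
  pos <- as_position_matrix(state)
  r0 <- config$cell_diameter_um
  ctr <- colMeans(pos)
  d <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  radius <- max(d) + r0 / 2
  dens <- compute_density(pos, config) + 1 # neighbourhood includes the particle
  n_shell <- max(1L, ceiling(radius / shell_width_um))
  edges <- shell_width_um * (0:n_shell)
  lo <- d - r0 / 2
  hi <- d + r0 / 2
  res <- lapply(seq_len(n_shell), function(s) {
    inside <- hi > edges[s] & lo < edges[s + 1]
    c(
      n = sum(inside),
      dens = if (any(inside)) mean(dens[inside]) else 0
    )
  })
  res <- do.call(rbind, res)
  depth <- pmax(0, radius - (edges[-1] + edges[-length(edges)]) / 2)
  m <- max(1L, ceiling(min(radius, config$max_depth_um) / config$shell_width_um))
  prof <- diffusion_profile(state$R_t, m, config$shell_width_um,
                            config$alpha_over_D)
  src_shell <- pmin(m, floor(depth / config$shell_width_um) + 1)
  src <- ifelse(depth > config$max_depth_um, 0, prof[src_shell])
  data.frame(
    r_inner_um = edges[-length(edges)],
    r_outer_um = edges[-1],
    n_particles = res[, "n"],
    cell_density = res[, "dens"],
    source_index = src
  )
}

#' @export
print.spheroid_trajectory <- function(x, ...) {
  idx <- x$index
  cat(sprintf(
    "spheroid trajectory: %d snapshots, day %.2f-%.2f, %d -> %d particles\n",
    nrow(idx), min(idx$day), max(idx$day),
    idx$n_particles[1], idx$n_particles[nrow(idx)]
  ))
  cat(sprintf(
    "final diameter %.1f um, residual source index %.3f\n",
    idx$diameter_um[nrow(idx)], idx$R_t[nrow(idx)]
  ))
  invisible(x)
}

#' @export
print.spheroid_state <- function(x, ...) {
  cat(sprintf(
    "spheroid state at day %.2f: %d particles, diameter %.1f um, R_t %.3f\n",
    x$day, nrow(x$particles), x$diameter_um, x$R_t
  ))
  invisible(x)
}
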