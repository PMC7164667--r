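test_that("pair force has roots at R*r0 and G*r0 with the right signs", {
  cfg <- sim_config()
  expect_equal(pair_force(11.06, cfg), 0)
  expect_equal(pair_force(15, cfg), 0)
  expect_equal(pair_force(10, cfg), 0.005 * (1 - 10 / 11.06) * (1 - 10 / 15),
               tolerance = 1e-12)
  r <- seq(0.5, 25, by = 0.01)
  f <- pair_force(r, cfg)
  expect_true(all(f[r < 11.06] > 0)) # repulsive inside equilibrium
  expect_true(all(f[r > 11.06 + 1e-9 & r < 15] < 0)) # attractive in range
  expect_true(all(f[r >= 15] == 0)) # cut off beyond attraction range
  expect_error(pair_force(0, cfg), "coincident")
})

test_that("residual source index tracks cumulative consumption", {
  expect_equal(residual_source_index(numeric(0), 1000), 1)
  expect_equal(residual_source_index(rep(100, 3), 1000), 0.7)
  expect_equal(residual_source_index(rep(500, 2), 1000), 0)
  expect_equal(residual_source_index(rep(500, 3), 1000), 0) # clamped
})

test_that("diffusion profile matches the closed-form steady state", {
  # alpha/D = 50 per mm^2 puts the penetration depth L = sqrt(2/50) mm at
  # exactly 200 um, the span of 200 shells of 1 um
  prof <- diffusion_profile(1, 200, 1, alpha_over_D = 50)
  x <- (0:199) / 1000 # depth, mm
  L <- sqrt(2 * 1 / 50)
  closed <- pmax(0, 1 - (50 / 2) * x * (2 * L - x))
  expect_lt(max(abs(prof - closed)), 0.02)
  expect_true(all(diff(prof) <= 1e-12)) # non-increasing with depth
})

test_that("diffusion profile degenerate cases", {
  expect_equal(diffusion_profile(1, 1, 10), 1) # single (surface) shell
  expect_equal(diffusion_profile(0, 50, 10), rep(0, 50)) # exhausted budget
  # unoccupied shells do not consume: with no occupancy the profile is flat
  prof <- diffusion_profile(0.8, 30, 10, occupied = rep(FALSE, 30))
  expect_equal(prof, rep(0.8, 30))
})

test_that("density counts the first coordination shell only", {
  cfg <- sim_config()
  expect_identical(compute_density(matrix(0, 1, 3), cfg), 0L)
  # interior particles of a perfect HCP cluster at the equilibrium spacing
  # see exactly the kissing number 12; the second shell at sqrt(2)*11.06 =
  # 15.64 um lies beyond the attraction range 15 um
  pts <- hcp_cluster(300, spacing_um = cfg$R * cfg$cell_diameter_um)
  dens <- compute_density(pts, cfg)
  expect_identical(max(dens), 12L)
  d0 <- sqrt(rowSums(pts^2))
  expect_true(all(dens[d0 < 15] == 12L))
})

test_that("grid and brute-force neighbour counts agree", {
  cfg <- sim_config()
  set.seed(8)
  for (i in 1:5) {
    pts <- matrix(runif(3 * 400, 0, 80), ncol = 3)
    expect_identical(
      compute_density(pts, cfg, method = "grid"),
      compute_density(pts, cfg, method = "bruteforce")
    )
  }
})

test_that("mobility is the centre-distance ratio with central clamp", {
  cfg <- sim_config()
  pts <- cbind(x = c(-8, -4, 0, 4, 8), y = 0, z = 0)
  expect_equal(compute_mobility(pts, cfg), c(1, 0.5, cfg$eps_mobility, 0.5, 1))
  expect_equal(compute_mobility(matrix(0, 1, 3), cfg), cfg$eps_mobility)
})

test_that("cell cycle time follows the Monod-type reconstruction", {
  cfg <- sim_config() # Kc = Ke = 1, 18 h minimum
  expect_equal(cell_cycle_time(1, 0, 1, cfg), 18 * 60)
  expect_equal(cell_cycle_time(0.5, 0, 1, cfg), 2.5 * 18 * 60) # (1+4)/(1+1)
  expect_identical(cell_cycle_time(0, 5, 0.5, cfg), Inf) # starvation
  # never shorter than the minimum cycle
  set.seed(2)
  tz <- cell_cycle_time(runif(100, 0.01, 1), sample(0:12, 100, TRUE),
                        runif(100, 1e-3, 1), cfg)
  expect_true(all(tz >= 18 * 60 - 1e-9))
  # monotone: less supply, more crowding, less mobility all lengthen the cycle
  expect_gt(cell_cycle_time(0.3, 0, 1, cfg), cell_cycle_time(0.6, 0, 1, cfg))
  expect_gt(cell_cycle_time(1, 8, 1, cfg), cell_cycle_time(1, 2, 1, cfg))
  expect_gt(cell_cycle_time(1, 6, 0.2, cfg), cell_cycle_time(1, 6, 0.9, cfg))
})

test_that("division replaces the parent by two offset daughters", {
  set.seed(33)
  daughters <- divide_particle(c(1, 2, 3), generation = 5L, cell_diameter_um = 10)
  expect_length(daughters, 2)
  sep <- sqrt(sum((daughters[[1]]$position - daughters[[2]]$position)^2))
  expect_equal(sep, 5) # r0 / 2
  expect_identical(daughters[[1]]$generation, 6L)
  expect_identical(daughters[[2]]$generation, 6L)
  expect_equal((daughters[[1]]$position + daughters[[2]]$position) / 2, c(1, 2, 3))
  # same seed, same directions
  set.seed(33)
  again <- divide_particle(c(1, 2, 3), 5L, 10)
  expect_identical(daughters, again)
})

test_that("a lone supplied particle divides at exactly the minimum cycle", {
  cfg <- sim_config(total_days = 1, capacity = Inf, n0 = 1,
                    snapshot_every_h = 0.25, seed = 2)
  tr <- run_simulation(cfg)
  first2 <- tr$index$day[which(tr$index$n_particles >= 2)[1]]
  expect_equal(first2, 0.75) # 18 h
})

test_that("an exhausted budget freezes the population", {
  tr <- run_simulation(sim_config(total_days = 1.5, capacity = 0, n0 = 5, seed = 4))
  expect_true(all(tr$index$n_particles == 5))
  expect_true(all(tr$index$R_t == 0))
})

test_that("simulation is reproducible and monotone in particle count", {
  cfg <- sim_config(total_days = 2, capacity = Inf, n0 = 20, Ke = 0.05, seed = 31)
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$index, tr2$index)
  last1 <- tr1$snapshots[[length(tr1$snapshots)]]$particles
  last2 <- tr2$snapshots[[length(tr2$snapshots)]]$particles
  expect_identical(last1, last2)
  expect_false(is.unsorted(tr1$index$n_particles))
  # generations form a contiguous range from g0
  gens <- sort(unique(last1$generation))
  expect_identical(gens, seq(min(gens), max(gens)))
  expect_gte(min(gens), cfg$g0)
})

test_that("overlapping particles are pushed apart by relaxation", {
  init <- rbind(c(0, 0, 0), c(8, 0, 0)) # r = 0.8 r0, inside repulsion zone
  cfg <- sim_config(total_days = 1 / 1440, capacity = Inf, n0 = 2,
                    desync_ages = FALSE, seed = 1)
  tr <- run_simulation(cfg, init = init)
  last <- tr$snapshots[[length(tr$snapshots)]]$particles
  expect_gt(abs(last$x_um[1] - last$x_um[2]), 8)
})

test_that("relaxation restores near-equilibrium neighbour spacing", {
  cfg <- sim_config(total_days = 100 / 1440, capacity = 0, n0 = 150, seed = 6)
  set.seed(6)
  init <- hcp_cluster(150, spacing_um = cfg$R * cfg$cell_diameter_um) +
    matrix(runif(450, -0.8, 0.8), ncol = 3)
  tr <- run_simulation(cfg, init = init)
  last <- tr$snapshots[[length(tr$snapshots)]]$particles
  pos <- as.matrix(last[, c("x_um", "y_um", "z_um")])
  dd <- as.matrix(dist(pos))
  diag(dd) <- Inf
  nn <- apply(dd, 1, min)
  eq <- cfg$R * cfg$cell_diameter_um
  expect_true(mean(abs(nn - eq) / eq < 0.05) > 0.95)
})

test_that("supply is non-increasing with depth in every snapshot", {
  tr <- run_simulation(sim_config(total_days = 2, capacity = 4e5, n0 = 80,
                                  Ke = 0.05, snapshot_every_h = 12, seed = 12))
  for (s in tr$snapshots) {
    p <- s$particles
    pos <- as.matrix(p[, c("x_um", "y_um", "z_um")])
    depth <- (s$diameter_um / 2) -
      sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2))
    expect_true(all(diff(p$N[order(depth)]) <= 1e-9))
  }
  expect_true(all(diff(tr$index$R_t) <= 1e-12))
})

test_that("the carrying-capacity guard suspends divisions", {
  tr <- run_simulation(sim_config(total_days = 2, capacity = Inf, n0 = 30,
                                  Ke = 0.01, max_particles = 40, seed = 3))
  expect_true(all(tr$index$n_particles <= 40))
  expect_equal(max(tr$index$n_particles), 40)
})

test_that("radial profiles summarize shells of the attraction range", {
  single <- make_state(matrix(0, 1, 3))
  prof1 <- radial_profiles(single)
  expect_identical(nrow(prof1), 1L)
  expect_equal(prof1$n_particles, 1)
  expect_equal(prof1$cell_density, 1) # the particle itself

  cfg <- sim_config()
  pts <- hcp_cluster(400, spacing_um = cfg$R * cfg$cell_diameter_um)
  st <- make_state(pts, R_t = 1)
  prof <- radial_profiles(st, config = cfg)
  # interior shells sit near the kissing number + self; density drops at the
  # surface shell
  expect_gt(prof$cell_density[1], 11)
  expect_lt(prof$cell_density[nrow(prof)], prof$cell_density[1])
  # the source profile decreases from surface to centre (increasing r)
  expect_true(all(diff(prof$source_index) >= -1e-12))
})

test_that("invalid configurations report all problems at once", {
  err <- tryCatch(sim_config(R = 2, G = 1.5, Kc = -1, dt_min = 0),
                  error = function(e) conditionMessage(e))
  expect_match(err, "R must be smaller")
  expect_match(err, "Kc must be positive")
  expect_match(err, "dt_min must be positive")
})
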