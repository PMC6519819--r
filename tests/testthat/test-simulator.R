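# Electron-stream Monte Carlo building blocks: Compton sampling, CSDA
# transport, helical flight, and the assembled simulation.

test_that("Compton kinematics reproduce the closed forms", {
  expect_equal(compton_electron_energy(1.25, 1), 0)  # forward scatter
  # Compton edge of the mean Co-60 line
  alpha <- 1.25 / 0.511
  expect_equal(compton_edge(1.25), 1.25 * 2 * alpha / (1 + 2 * alpha))
  expect_equal(compton_edge(1.25), 1.0380, tolerance = 1e-3)
  expect_equal(compton_electron_energy(1.25, -1), compton_edge(1.25))
  # electron angle: backscattered photon -> forward electron
  expect_equal(compton_electron_angle(1.25, -1), 0, tolerance = 1e-12)
})

test_that("sampled scattering angles follow the Klein-Nishina law", {
  set.seed(31)
  n <- 1e5
  cs <- sample_compton(rep(1.25, n))
  expect_true(all(cs$electron_kinetic_mev >= 0))
  expect_true(all(cs$electron_kinetic_mev <= compton_edge(1.25) + 1e-12))
  # numeric CDF of the Klein-Nishina density in cos(theta)
  grid <- seq(-1, 1, length.out = 4001)
  dens <- estreamlab:::kn_density(grid, 1.25 / 0.511)
  cdf <- cumsum(dens) - dens / 2 - dens[1] / 2
  cdf <- cdf / cdf[length(cdf)]
  emp <- ecdf(cs$cos_theta)
  ks <- max(abs(emp(grid) - cdf))
  expect_lt(ks, 1.63 / sqrt(n))  # 1% critical value
})

test_that("the relativistic gyroradius matches the closed form", {
  pc <- electron_momentum_mev(1)
  expect_equal(pc, sqrt(1.511^2 - 0.511^2), tolerance = 1e-12)
  r <- gyroradius_cm(pc, 0.35)
  # r = pc[MeV] * 1e6 / (c * B), in cm
  expect_equal(r, pc * 1e6 / (2.99792458e8 * 0.35) * 100, tolerance = 1e-12)
  expect_equal(r, 1.3552, tolerance = 1e-4)
  expect_true(is.infinite(gyroradius_cm(pc, 0)))
})

test_that("photon sampling covers the field square with the line spectrum", {
  set.seed(17)
  ph <- sample_photon(beam_setup(0, 6.3), physics_config(), 1e5)
  frac_low <- mean(ph$energy_mev == 1.17)
  expect_lt(abs(frac_low - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_true(all(abs(ph$target) <= 3.15))
  expect_lt(abs(mean(ph$target[, 1])), 3 * (6.3 / sqrt(12)) / sqrt(1e5))
  expect_lt(abs(mean(ph$target[, 2])), 3 * (6.3 / sqrt(12)) / sqrt(1e5))
  expect_equal(rowSums(ph$direction^2), rep(1, 1e5), tolerance = 1e-9)
})

test_that("interaction sampling matches the exponential chord law", {
  phantom <- phantom_setup(0)
  n <- 4e4
  dirs <- matrix(rep(c(0, 0, -1), n), n, 3, byrow = TRUE)
  # vertical rays through the flat phantom: chord length exactly 10 cm
  mu <- 0.0756
  phys <- physics_config(photon_lines = cbind(1.17, 1),
                         phantom_attenuation = c("1.17" = mu))
  set.seed(23)
  ia <- sample_interaction(c(0, 0, 105), dirs, rep(1.17, n), phantom, phys)
  p_expect <- 1 - exp(-mu * 10)
  expect_lt(abs(mean(ia$interacts) - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / n))
  pts <- ia$point[ia$interacts, ]
  expect_true(all(abs(pts[, 3]) <= 5 + 1e-9))
  expect_true(all(pts[, 1] == 0 & pts[, 2] == 0))
  # vanishing attenuation -> always pass through
  phys0 <- physics_config(photon_lines = cbind(1.17, 1),
                          phantom_attenuation = c("1.17" = 1e-12))
  set.seed(23)
  ia0 <- sample_interaction(c(0, 0, 105), dirs[1:2000, ], rep(1.17, 2000),
                            phantom, phys0)
  expect_false(any(ia0$interacts))
})

test_that("the support plate adds a second material block", {
  phantom <- phantom_setup(0)
  sup <- support_setup(thickness = 1, extent = c(20, 20))
  n <- 4e4
  dirs <- matrix(rep(c(0, 0, -1), n), n, 3, byrow = TRUE)
  mu <- 0.0756
  phys <- physics_config(photon_lines = cbind(1.17, 1),
                         phantom_attenuation = c("1.17" = mu))
  set.seed(29)
  ia <- sample_interaction(c(0, 0, 105), dirs, rep(1.17, n), phantom, phys,
                           support = sup)
  p_expect <- 1 - exp(-mu * 11)  # 10 cm phantom + 1 cm plate
  expect_lt(abs(mean(ia$interacts) - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / n))
  expect_true(any(ia$point[ia$interacts, 3] < -5))  # some land in the plate
})

test_that("straight-line CSDA escape follows the range table", {
  phantom <- phantom_setup(0)
  phys <- physics_config()
  # born on the surface moving outward: escapes with (almost) full energy
  esc <- propagate_electron_to_surface(matrix(c(0, 0, 4.9999), 1),
                                       matrix(c(0, 0, 1), 1), 1.0,
                                       phantom, phys)
  expect_true(esc$escapes)
  expect_equal(esc$exit_energy_mev, 1.0, tolerance = 1e-2)
  # deeper than the range: absorbed
  esc2 <- propagate_electron_to_surface(matrix(c(0, 0, 0), 1),
                                        matrix(c(0, 0, 1), 1), 1.0,
                                        phantom, phys)
  expect_false(esc2$escapes)

  # two-point range table: hand log-log interpolation of the exit energy
  tab <- data.frame(energy_mev = c(0.1, 1), range_gcm2 = c(0.02, 0.5))
  phys2 <- physics_config(csda_table = tab, phantom_density = 1)
  start <- matrix(c(0, 0, 4.8), 1)
  esc3 <- propagate_electron_to_surface(start, matrix(c(0, 0, 1), 1), 1.0,
                                        phantom, phys2)
  residual <- 0.5 - 0.2  # range(1 MeV) minus 0.2 cm depth, density 1
  slope <- log(1 / 0.1) / log(0.5 / 0.02)
  e_hand <- exp(log(0.1) + slope * (log(residual) - log(0.02)))
  expect_true(esc3$escapes)
  expect_equal(esc3$exit_energy_mev, e_hand, tolerance = 1e-12)
})

test_that("helical transport crosses the right panel at the right place", {
  pos <- matrix(c(1, 0, -2), 1)
  # pure +y motion: no gyration, crossing at the launch (x, z)
  hx <- helix_to_panel(pos, matrix(c(0, 1, 0), 1), 0.5, 0.35, 10,
                       floor_z = NULL)
  expect_true(hx$hits)
  expect_equal(c(hx$u, hx$v), c(1, -2))
  # no field-axis velocity: a miss, not an error
  expect_false(helix_to_panel(pos, matrix(c(1, 0, 0), 1), 0.5, 0.35, 10,
                              floor_z = NULL)$hits)
  # wrong side: heading -y cannot reach the +y panel
  expect_false(helix_to_panel(pos, matrix(c(0, -1, 0), 1), 0.5, 0.35, 10,
                              floor_z = NULL)$hits)
  # zero field: straight-line crossing
  hx0 <- helix_to_panel(pos, matrix(c(0.6, 0.8, 0), 1), 0.5, 0, 10,
                        floor_z = NULL)
  expect_equal(c(hx0$u, hx0$v), c(1 + 0.6 / 0.8 * 10, -2))
})

test_that("hit centroids stay within a gyroradius of the launch patch", {
  set.seed(37)
  n <- 1e4
  pos <- cbind(runif(n, -1, 1), 0, runif(n, -1, 1))
  # random directions with a guaranteed +y component
  d <- cbind(rnorm(n, 0, 0.4), runif(n, 0.3, 1), rnorm(n, 0, 0.4))
  d <- d / sqrt(rowSums(d^2))
  T <- rep(1, n)
  hx <- helix_to_panel(pos, d, T, 0.35, 10, floor_z = NULL)
  expect_true(all(hx$hits))
  r_max <- gyroradius_cm(electron_momentum_mev(1), 0.35)
  expect_lt(abs(mean(hx$u) - mean(pos[, 1])), r_max)
  expect_lt(abs(mean(hx$v) - mean(pos[, 3])), r_max)
  # every landing point is within two gyroradii of its own field line
  expect_true(all(sqrt((hx$u - pos[, 1])^2 + (hx$v - pos[, 3])^2)
                  <= 2 * r_max + 1e-9))
})

test_that("the re-entry cull removes electrons curling into the assembly", {
  phantom <- phantom_setup(30)
  # launched just under the exit face with mostly-transverse velocity: the
  # first gyration arc climbs back through the surface
  pos <- matrix(c(0, -2.51, -4.35), 1)
  d <- matrix(c(0, -0.05, -1), 1)
  d <- d / sqrt(sum(d^2))
  culled <- helix_to_panel(pos, d, 0.5, 0.35, -10, phantom = phantom,
                           reentry_check = TRUE, floor_z = NULL)
  free <- helix_to_panel(pos, d, 0.5, 0.35, -10, phantom = phantom,
                         reentry_check = FALSE, floor_z = NULL)
  expect_true(free$hits)
  expect_false(culled$hits)
})

test_that("simulation is reproducible and conserves energy", {
  cond <- tiny_condition()
  s1 <- simulate_condition(cond, n_photons = 3e4, seed = 11)
  s2 <- simulate_condition(cond, n_photons = 3e4, seed = 11)
  expect_identical(s1$front_map$values, s2$front_map$values)
  expect_identical(s1$end_map$values, s2$end_map$values)
  expect_identical(s1$escaped_count, s2$escaped_count)
  s3 <- simulate_condition(cond, n_photons = 3e4, seed = 12)
  expect_false(identical(s1$end_map$values, s3$end_map$values))

  # scored kinetic energy cannot exceed the total Compton energy released,
  # which is itself below the total photon energy
  scored_mev <- (sum(s1$front_map$values) + sum(s1$end_map$values)) /
    s1$normalization
  expect_lt(scored_mev, 3e4 * 1.33)
  expect_gt(s1$isocenter_score, 0)
})

test_that("glance reports the panel summary of a simulation", {
  s <- simulate_condition(tiny_condition(), n_photons = 3e4, seed = 11)
  g <- glance(s)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_photons, 3e4)
  expect_gte(g$end_dr1_cGy, 0)
  expect_true(g$hits_front >= 0 && g$hits_end >= 0)
})
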