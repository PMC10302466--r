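test_that("init_configuration respects spacing, composition and determinism", {
  # 500 atoms in a (7.5 sigma)^3 box, equimolar binary mixture
  snap <- init_configuration(500, c(7.5, 7.5, 7.5),
                             species_fractions = c(0.5, 0.5), seed = 42)
  expect_equal(as.numeric(sort(table(snap$species))), c(250, 250))
  # all-pairs scan with independent minimum-image arithmetic
  expect_gte(min(all_pair_distances(snap$positions, snap$box)), 0.85)
  expect_true(all(snap$positions >= 0 & snap$positions <
                    rep(snap$box, each = 500)))

  snap2 <- init_configuration(500, c(7.5, 7.5, 7.5),
                              species_fractions = c(0.5, 0.5), seed = 42)
  expect_identical(snap, snap2)

  two <- init_configuration(2, c(20, 20, 20), seed = 1)
  expect_gte(min_image_dist(two$positions, 1, 2, two$box), 0.85)
  expect_identical(two$species, c(0L, 0L))

  expect_error(init_configuration(1000, c(3, 3, 3), seed = 1),
               "box too small")
})

test_that("drawn velocities have zero momentum, exact temperature and the right spread", {
  v <- draw_velocities(10000, temperature = 1.0, masses = 1, seed = 9)
  expect_lt(max(abs(colSums(v))), 1e-10)
  expect_equal(sum(v^2) / (3 * 10000), 1.0, tolerance = 1e-12)
  # per-component spread matches kT/m within 3% at this sample size
  expect_equal(unname(apply(v, 2, var)), rep(1, 3), tolerance = 0.03)

  # heavier atoms move slower: variance scales as 1/m
  vm <- draw_velocities(10000, temperature = 1.0, masses = 4, seed = 9)
  expect_equal(mean(vm^2) * 4, 1.0, tolerance = 1e-12)
})

test_that("forces vanish at the pair minimum and obey Newton's third law", {
  pos <- rbind(c(5, 5, 5), c(5 + 2^(1 / 6), 5, 5))
  snap <- snapshot(pos, NULL, c(0, 0), c(20, 20, 20))
  f <- compute_forces(snap)
  expect_lt(max(abs(f$forces)), 1e-12)

  snap <- random_snapshot(80, c(6, 6, 6), seed = 2)
  f <- compute_forces(snap)
  # zero to round-off relative to the force scale (random overlaps make
  # individual forces huge)
  expect_lt(max(abs(colSums(f$forces))), 1e-12 * max(abs(f$forces)))
})

test_that("forces are the exact negative gradient of the pair energy", {
  params <- lj_params(epsilon = c(1, 0.7), sigma = c(1, 0.88),
                      mass = c(1, 0.8))
  snap <- cached_fixture("fd_snap", function() {
    s <- init_configuration(50, c(5.5, 5.5, 5.5), species_fractions = c(0.5, 0.5),
                            params = lj_params(epsilon = c(1, 0.7),
                                               sigma = c(1, 0.88),
                                               mass = c(1, 0.8)),
                            seed = 13)
    step_nvt(s, params = lj_params(epsilon = c(1, 0.7), sigma = c(1, 0.88),
                                   mass = c(1, 0.8)),
             n_steps = 100)  # off-lattice, well inside the liquid
  })
  f <- compute_forces(snap, params)
  h <- 1e-6
  energy_at <- function(pos) {
    pointrdf:::lj_forces_cpp(pos, snap$species, snap$box, params$eps_mat,
                  params$sig_mat, params$cutoff)$epot
  }
  fd <- matrix(0, 10, 3)
  for (i in 1:10) for (k in 1:3) {
    pp <- snap$positions; pp[i, k] <- pp[i, k] + h
    pm <- snap$positions; pm[i, k] <- pm[i, k] - h
    fd[i, k] <- -(energy_at(pp) - energy_at(pm)) / (2 * h)
  }
  scale <- max(abs(f$forces[1:10, ]))
  expect_lt(max(abs(f$forces[1:10, ] - fd)) / scale, 1e-5)
})

test_that("overlapping atoms raise a numerical-overlap error", {
  pos <- rbind(c(1, 1, 1), c(1.1, 1, 1))
  snap <- snapshot(pos, NULL, c(0, 0), c(20, 20, 20))
  expect_error(compute_forces(snap), "overlap")
})

test_that("NVE dynamics conserves energy and momentum; fixed points stay put", {
  # thermalize a small liquid, then switch the thermostat off
  snap <- cached_fixture("nve_snap", function() {
    s <- init_configuration(100, c(5.2, 5.2, 5.2), temperature = 1.0,
                            seed = 21)
    step_nvt(s, n_steps = 500, thermostat_coupling = 0.1, temperature = 1.0)
  })
  total_energy <- function(s) {
    compute_forces(s)$epot + 1.5 * nrow(s$positions) * kinetic_temperature(s)
  }
  e0 <- total_energy(snap)
  s <- snap
  drift <- 0
  for (chunk in 1:10) {
    s <- step_nvt(s, dt = 0.002, thermostat_coupling = 0, n_steps = 100)
    drift <- max(drift, abs(total_energy(s) - e0))
  }
  expect_lt(drift / abs(e0), 1e-3)
  p <- colSums(s$velocities)
  expect_lt(max(abs(p)), 1e-8)

  # two atoms at the pair minimum with zero velocities do not move
  pos <- rbind(c(5, 5, 5), c(5 + 2^(1 / 6), 5, 5))
  still <- snapshot(pos, matrix(0, 2, 3), c(0, 0), c(20, 20, 20))
  moved <- step_nvt(still, dt = 0.002, thermostat_coupling = 0, n_steps = 50)
  expect_lt(max(abs(moved$positions - still$positions)), 1e-12)
})

test_that("the thermostat holds the kinetic temperature near its target", {
  traj <- liquid_trajectory()
  temps <- vapply(traj$snapshots, kinetic_temperature, numeric(1))
  expect_equal(mean(temps), traj$condition$temperature, tolerance = 0.02)
})

test_that("run_condition counts frames, reproduces from the seed and labels conditions", {
  cond <- condition(1.0, 0.75)
  tr <- run_condition(cond, n_atoms = 120, n_equil_steps = 100,
                      n_prod_steps = 2000, sample_interval = 100, seed = 5)
  expect_length(tr$snapshots, 20)
  expect_true(all(vapply(tr$snapshots, function(s)
    identical(s$condition$condition_id, cond$condition_id), logical(1))))
  expect_error(run_condition(cond, n_prod_steps = 100, sample_interval = 33),
               "divide")

  tr2 <- run_condition(cond, n_atoms = 120, n_equil_steps = 100,
                       n_prod_steps = 2000, sample_interval = 100, seed = 5)
  expect_identical(lapply(tr$snapshots, `[[`, "positions"),
                   lapply(tr2$snapshots, `[[`, "positions"))
})

test_that("a long liquid run shows liquid structure: tall first peak, flat tail", {
  g <- trajectory_rdf(liquid_trajectory())[["0-0"]]
  expect_gt(max(g$g), 1)
  tail_bins <- g$g[g$r > 0.75 * max(g$r)]
  expect_lt(abs(mean(tail_bins) - 1), 0.05)
})

test_that("generate_grid is deterministic, and hotter liquids have lower first peaks", {
  trajs <- tiny_grid_trajectories()
  expect_length(trajs, 6)
  expect_length(unique(names(trajs)), 6)

  # same master seed, byte-identical archive
  conds <- condition_grid(c(0.9, 1.1), c(0.70, 0.75, 0.80))
  rerun <- generate_grid(conds, seed = 3, n_atoms = 120, n_equil_steps = 300,
                         n_prod_steps = 300, sample_interval = 10)
  f1 <- tempfile(); f2 <- tempfile()
  save_archive(trajs, f1); save_archive(rerun, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # physical monotonicity at fixed density, averaged over the trajectory
  peak <- function(tr) max(trajectory_rdf(tr)[["0-0"]]$g)
  expect_gt(peak(trajs[["T0.9_rho0.75"]]), peak(trajs[["T1.1_rho0.75"]]))
})

test_that("with epsilon = 0 the engine samples ideal-gas structure", {
  params <- lj_params(epsilon = 0)
  # wide sampling interval so free-flight frames decorrelate between samples
  tr <- run_condition(condition(1.0, 0.4), params = params, n_atoms = 300,
                      n_equil_steps = 50, n_prod_steps = 3000,
                      sample_interval = 60, seed = 17)
  grid <- radial_grid(r_max = 0.45 * min(tr$snapshots[[1]]$box), n_bins = 30)
  g <- average_rdf(lapply(tr$snapshots, snapshot_rdf, pair = c(0, 0),
                          grid = grid))
  # 3 Poisson standard errors on the per-bin mean over 50 frames
  n <- 300
  v_shell <- 4 / 3 * pi * diff(grid$edges^3)
  lambda <- n * (n - 1) * v_shell / prod(tr$snapshots[[1]]$box) *
    length(tr$snapshots)
  se <- sqrt(2 / lambda)  # ordered-pair counts come in correlated twos
  expect_true(all(abs(g$g - 1) <= 3 * se))
})
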