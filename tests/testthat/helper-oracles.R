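# Independent oracles and small fixtures shared across test files.
# Everything here is deliberately naive plain R so it cannot share a bug
# with the package's C++ paths.

# Brute-force minimum-image distance between rows i and j.
min_image_dist <- function(pos, i, j, box) {
  d <- pos[i, ] - pos[j, ]
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# All minimum-image pair distances (i < j) by explicit double loop.
all_pair_distances <- function(pos, box) {
  n <- nrow(pos)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out <- c(out, min_image_dist(pos, i, j, box))
  out
}

# Brute-force partial RDF: explicit O(N^2) double loop, half-open bins,
# ordered (a, b) pair counting, exact shell volumes.
brute_force_rdf <- function(snap, pair, grid) {
  pair <- sort(pair)
  counts <- integer(grid$n_bins)
  n <- nrow(snap$positions)
  for (i in seq_len(n)) {
    if (snap$species[i] != pair[1]) next
    for (j in seq_len(n)) {
      if (j == i || snap$species[j] != pair[2]) next
      r <- min_image_dist(snap$positions, i, j, snap$box)
      if (r < grid$r_max) {
        k <- floor(r / grid$dr) + 1
        counts[k] <- counts[k] + 1
      }
    }
  }
  n_a <- sum(snap$species == pair[1])
  n_b <- sum(snap$species == pair[2])
  n_b_eff <- if (pair[1] == pair[2]) n_b - 1 else n_b
  v_shell <- 4 / 3 * pi * diff(grid$edges^3)
  counts / (n_a * n_b_eff * v_shell / prod(snap$box))
}

# Uniform ideal-gas snapshot.
random_snapshot <- function(n, box, n_species = 1, seed = 1) {
  withr::with_seed(seed, {
    pos <- matrix(runif(3 * n, 0, rep(box, each = n)), n, 3)
    species <- if (n_species > 1) sample(0:(n_species - 1), n, TRUE)
               else integer(n)
    snapshot(pos, NULL, species, box)
  })
}

# Equilibrated LJ liquid trajectories are expensive; simulate once per test
# run and share.
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, fun) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fun()
  .fixture_env[[name]]
}

liquid_trajectory <- function() {
  cached_fixture("liquid_traj", function() {
    run_condition(condition(1.0, 0.75), n_atoms = 400, seed = 11)
  })
}

small_trajectory <- function(n_frames = 20) {
  cached_fixture("small_traj", function() {
    run_condition(condition(1.0, 0.75), n_atoms = 120, n_equil_steps = 300,
                  n_prod_steps = n_frames * 10, sample_interval = 10,
                  seed = 7)
  })
}

small_binary_trajectory <- function() {
  cached_fixture("small_binary_traj", function() {
    run_condition(condition(1.0, 0.75), params = system_params("binary"),
                  n_atoms = 120, n_equil_steps = 300, n_prod_steps = 200,
                  sample_interval = 10, species_fractions = c(0.5, 0.5),
                  seed = 8)
  })
}

# Small condition grids for pipeline tests: 6 conditions, few atoms/frames.
tiny_grid_trajectories <- function() {
  cached_fixture("tiny_grid", function() {
    conds <- condition_grid(c(0.9, 1.1), c(0.70, 0.75, 0.80))
    generate_grid(conds, seed = 3, n_atoms = 120, n_equil_steps = 300,
                  n_prod_steps = 300, sample_interval = 10)
  })
}
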