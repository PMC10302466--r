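#' Initialize a liquid configuration
#'
#' Places atoms on a simple cubic lattice perturbed by small uniform noise so
#' that no minimum-image pair is closer than `0.85 * sigma`, assigns species
#' by the requested fractions, and draws thermal velocities. Plays the role a
#' packing tool plays ahead of a production simulation.
#'
#' @param n_atoms Number of atoms (>= 2).
#' @param box Length-3 box edges.
#' @param species_fractions Probability vector over species; must sum to 1.
#' @param temperature Target temperature for the initial velocities.
#' @param params [lj_params()]; sigma sets the minimum-spacing scale.
#' @param seed Integer seed; the same seed reproduces the snapshot bitwise.
#' @return A [snapshot()].
#' @export
init_configuration <- function(n_atoms, box, species_fractions = 1,
                               temperature = 1, params = lj_params(),
                               seed = 1L) {
  stopifnot(n_atoms >= 2L)
  box <- as.numeric(box)
  if (abs(sum(species_fractions) - 1) > 1e-8)
    stop("species_fractions must sum to 1")
  sig_min <- min(params$sigma)
  n_cells <- ceiling(n_atoms^(1 / 3))
  spacing <- min(box) / n_cells
  if (spacing < 0.85 * sig_min)
    stop(sprintf(
      "box too small: lattice spacing %.3g below minimum separation %.3g",
      spacing, 0.85 * sig_min))

  withr::with_seed(seed, {
    # all lattice sites, keep the first n_atoms of a seeded shuffle
    grid <- as.matrix(expand.grid(seq_len(n_cells), seq_len(n_cells),
                                  seq_len(n_cells)))
    sites <- grid[sample(nrow(grid), n_atoms), , drop = FALSE]
    pos <- sweep(sites - 0.5, 2, box / n_cells, `*`)
    # noise bounded so perturbed neighbours stay >= 0.85 sigma apart
    amp <- max(0, (spacing - 0.85 * sig_min) / 2) * 0.95
    pos <- pos + matrix(stats::runif(3 * n_atoms, -amp, amp), n_atoms, 3)

    counts <- round(species_fractions * n_atoms)
    counts[1] <- counts[1] + (n_atoms - sum(counts))
    species <- sample(rep.int(seq_along(counts) - 1L, counts))
    masses <- rep_len(params$mass, length(counts))[species + 1L]
    vel <- draw_velocities(n_atoms, temperature, masses, seed = NULL)
  })
  snap <- snapshot(pos, vel, species, box, time = 0)
  dmin <- min_pair_distance_cpp(snap$positions, snap$box)
  if (dmin < 0.85 * sig_min)
    stop("internal: initial configuration violates minimum spacing")
  snap
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each component is Gaussian with variance `kT/m`; the aggregate linear
#' momentum is removed and the instantaneous kinetic temperature is rescaled
#' to the target exactly.
#'
#' @param n_atoms Number of atoms.
#' @param temperature Target temperature (> 0).
#' @param masses Per-atom masses (recycled).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return N x 3 velocity matrix.
#' @export
draw_velocities <- function(n_atoms, temperature, masses = 1, seed = 1L) {
  stopifnot(temperature > 0)
  masses <- rep_len(masses, n_atoms)
  draw <- function() {
    v <- matrix(stats::rnorm(3 * n_atoms, sd = sqrt(temperature)), n_atoms, 3)
    v <- v / sqrt(masses)
    # remove aggregate linear momentum
    pmean <- colSums(v * masses) / sum(masses)
    v <- sweep(v, 2, pmean, `-`)
    t_inst <- sum(masses * v^2) / (3 * n_atoms)
    v * sqrt(temperature / t_inst)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Lennard-Jones forces and potential energy
#'
#' Truncated-and-shifted pair potential under the minimum image convention;
#' forces are the exact negative gradient of the shifted energy.
#'
#' @param snap A [snapshot()].
#' @param params [lj_params()]; the cutoff must be below half the smallest
#'   box edge.
#' @return List with `forces` (N x 3) and `epot` (scalar).
#' @export
compute_forces <- function(snap, params = lj_params()) {
  check_cutoff(params, snap$box)
  lj_forces_cpp(snap$positions, snap$species, snap$box,
                params$eps_mat, params$sig_mat, params$cutoff)
}

#' Advance a snapshot by molecular-dynamics steps
#'
#' Velocity-Verlet integration with a Berendsen-style velocity-rescaling
#' thermostat. `thermostat_coupling = 0` gives plain NVE dynamics. Positions
#' are re-wrapped into the box after every step.
#'
#' @param snap A [snapshot()].
#' @param params [lj_params()].
#' @param dt Time step (> 0).
#' @param thermostat_coupling Dimensionless rescaling strength per step in
#'   `[0, 1]`; 0 disables the thermostat.
#' @param temperature Thermostat target; defaults to the snapshot's condition
#'   temperature.
#' @param n_steps Number of steps to advance.
#' @return The advanced [snapshot()].
#' @export
step_nvt <- function(snap, params = lj_params(), dt = 0.005,
                     thermostat_coupling = 0.1, temperature = NULL,
                     n_steps = 1L) {
  stopifnot(dt > 0)
  check_cutoff(params, snap$box)
  if (is.null(temperature)) {
    temperature <- if (!is.null(snap$condition)) snap$condition$temperature else 1
  }
  out <- run_md_cpp(snap$positions, snap$velocities, snap$species, snap$box,
                    params$eps_mat, params$sig_mat, params$cutoff,
                    params$mass[snap$species + 1L], dt, thermostat_coupling,
                    temperature, as.integer(n_steps), 0L)
  snapshot(out$pos, out$vel, snap$species, snap$box,
           time = snap$time + n_steps * dt, condition = snap$condition,
           units = snap$units)
}

#' Run one thermodynamic condition end to end
#'
#' Builds an initial configuration at the condition's density, equilibrates
#' under the thermostat, then runs production sampling every
#' `sample_interval` steps. The condition is annotated with the mean virial
#' pressure measured over the production samples.
#'
#' @param cond A [condition()].
#' @param params [lj_params()].
#' @param n_atoms Atoms in the (cubic) box; the edge follows from the
#'   condition's density.
#' @param n_equil_steps,n_prod_steps Equilibration / production step counts;
#'   `sample_interval` must divide `n_prod_steps`.
#' @param sample_interval Steps between stored frames.
#' @param dt Time step.
#' @param thermostat_coupling Per-step velocity-rescaling strength.
#' @param species_fractions Species composition.
#' @param seed Integer seed; the full trajectory is reproducible from it.
#' @return A [trajectory()] of `n_prod_steps / sample_interval` frames.
#' @export
run_condition <- function(cond, params = lj_params(), n_atoms = 400,
                          n_equil_steps = 1200, n_prod_steps = 1500,
                          sample_interval = 10, dt = 0.005,
                          thermostat_coupling = 0.1,
                          species_fractions = 1, seed = 1L) {
  if (n_prod_steps %% sample_interval != 0)
    stop("sample_interval must divide n_prod_steps")
  edge <- (n_atoms / cond$density)^(1 / 3)
  box <- rep(edge, 3)
  check_cutoff(params, box)
  snap <- init_configuration(n_atoms, box, species_fractions,
                             temperature = cond$temperature, params = params,
                             seed = seed)
  masses <- params$mass[snap$species + 1L]
  eq <- tryCatch(
    run_md_cpp(snap$positions, snap$velocities, snap$species, box,
               params$eps_mat, params$sig_mat, params$cutoff, masses, dt,
               thermostat_coupling, cond$temperature,
               as.integer(n_equil_steps), 0L),
    error = function(e) stop(sprintf("condition %s (equilibration): %s",
                                     cond$condition_id, conditionMessage(e)),
                             call. = FALSE))
  pr <- tryCatch(
    run_md_cpp(eq$pos, eq$vel, snap$species, box,
               params$eps_mat, params$sig_mat, params$cutoff, masses, dt,
               thermostat_coupling, cond$temperature,
               as.integer(n_prod_steps), as.integer(sample_interval)),
    error = function(e) stop(sprintf("condition %s (production): %s",
                                     cond$condition_id, conditionMessage(e)),
                             call. = FALSE))
  cond$pressure <- mean(pr$samples_pressure)
  n <- n_atoms
  frames <- lapply(seq_len(pr$n_samples), function(i) {
    off <- (i - 1) * n * 3
    pos <- matrix(pr$samples_pos[off + seq_len(n * 3)], n, 3)
    vel <- matrix(pr$samples_vel[off + seq_len(n * 3)], n, 3)
    snapshot(pos, vel, snap$species, box,
             time = (n_equil_steps + pr$samples_step[i]) * dt,
             condition = cond)
  })
  trajectory(cond, frames, sample_interval = sample_interval * dt)
}

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + k * 1000003) %% 2147483629)
}

#' Simulate a grid of thermodynamic conditions
#'
#' One trajectory per condition; per-condition seeds are derived
#' deterministically from the master seed, so the whole grid is reproducible
#' from one integer.
#'
#' @param conditions List of [condition()] objects (>= 5 so a condition-level
#'   80/10/10 split is non-degenerate).
#' @param params [lj_params()].
#' @param seed Master integer seed.
#' @param ... Engine settings forwarded to [run_condition()].
#' @return Named list of [trajectory()] objects keyed by `condition_id`.
#' @export
generate_grid <- function(conditions, params = lj_params(), seed = 1L, ...) {
  if (length(conditions) < 5L)
    stop("need at least 5 conditions for a non-degenerate condition split")
  ids <- vapply(conditions, function(c) c$condition_id, character(1))
  if (anyDuplicated(ids)) stop("condition_ids must be unique")
  trajs <- lapply(seq_along(conditions), function(i) {
    run_condition(conditions[[i]], params = params,
                  seed = derive_seed(seed, i), ...)
  })
  names(trajs) <- ids
  trajs
}

#' Regular (temperature, density) condition grid
#'
#' @param temperatures,densities Vectors of state values; the grid is their
#'   Cartesian product.
#' @return List of [condition()] objects.
#' @export
condition_grid <- function(temperatures, densities) {
  grid <- expand.grid(temperature = temperatures, density = densities)
  lapply(seq_len(nrow(grid)), function(i) {
    condition(grid$temperature[i], grid$density[i])
  })
}
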