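#' Thermodynamic condition label
#'
#' A condition labels one simulation: a thermostat target temperature plus a
#' second state variable. The bundled engine runs constant-volume dynamics, so
#' the second variable is the number density; a measured pressure can be
#' attached later as metadata so each condition still carries a (P, T) label.
#'
#' @param temperature Thermostat target (reduced units by default). Must be
#'   positive.
#' @param density Number density N/V (reduced units).
#' @param condition_id Unique identifier string; generated from the state
#'   point when omitted.
#' @param pressure Optional measured pressure label.
#' @return A `condition` object.
#' @export
condition <- function(temperature, density, condition_id = NULL,
                      pressure = NA_real_) {
  stopifnot(is.numeric(temperature), temperature > 0, density > 0)
  if (is.null(condition_id)) {
    condition_id <- sprintf("T%.4g_rho%.4g", temperature, density)
  }
  structure(
    list(temperature = temperature, density = density,
         pressure = pressure, condition_id = condition_id),
    class = "md_condition"
  )
}

#' @export
print.md_condition <- function(x, ...) {
  cat(sprintf("<condition %s: T = %g, rho = %g, P = %s>\n", x$condition_id,
              x$temperature, x$density,
              if (is.na(x$pressure)) "unmeasured" else format(x$pressure)))
  invisible(x)
}

#' Single molecular configuration
#'
#' One frame of a trajectory: wrapped positions, velocities, integer species
#' labels, an orthorhombic box and a time stamp, optionally tied to the
#' thermodynamic condition it was sampled from.
#'
#' @param positions N x 3 numeric matrix; wrapped into `[0, box)` on
#'   construction.
#' @param velocities N x 3 numeric matrix, or `NULL` for a velocity-free
#'   snapshot (stored as zeros and flagged).
#' @param species Integer vector of dense 0-based species labels.
#' @param box Length-3 positive edge lengths.
#' @param time Simulation time stamp.
#' @param condition Optional [condition()].
#' @param units Unit-system tag, `"reduced"` (default) or `"real"`.
#' @return A `snapshot` object.
#' @export
snapshot <- function(positions, velocities = NULL, species = NULL,
                     box, time = 0, condition = NULL, units = "reduced") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  n <- nrow(positions)
  if (n < 2L) stop("a snapshot needs at least 2 atoms")
  if (ncol(positions) != 3L) stop("positions must be N x 3")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  has_velocities <- !is.null(velocities)
  if (!has_velocities) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  storage.mode(velocities) <- "double"
  dimnames(velocities) <- NULL
  if (!all(dim(velocities) == c(n, 3L)))
    stop("velocities must match positions in shape")
  if (is.null(species)) species <- integer(n)
  species <- as.integer(species)
  if (length(species) != n) stop("species must have one label per atom")
  if (any(species < 0L)) stop("species labels must be >= 0")
  # wrap into [0, L)
  positions <- wrap_positions(positions, box)
  if (any(!is.finite(positions)) || any(!is.finite(velocities)))
    stop("non-finite coordinates or velocities")
  structure(
    list(positions = positions, velocities = velocities, species = species,
         box = box, time = time, condition = condition,
         has_velocities = has_velocities, units = units),
    class = "snapshot"
  )
}

wrap_positions <- function(positions, box) {
  for (k in 1:3) {
    positions[, k] <- positions[, k] - box[k] * floor(positions[, k] / box[k])
  }
  positions
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot: %d atoms, %d species, box (%s), t = %g>\n",
              nrow(x$positions), length(unique(x$species)),
              paste(signif(x$box, 5), collapse = ", "), x$time))
  invisible(x)
}

#' @rdname snapshot
#' @param x A `snapshot`.
#' @param ... Unused.
#' @return `as_tibble()`: one row per atom with columns `atom`, `species`,
#'   `x`, `y`, `z`, `vx`, `vy`, `vz`.
#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.snapshot <- function(x, ...) {
  tibble::tibble(
    atom = seq_len(nrow(x$positions)), species = x$species,
    x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3],
    vx = x$velocities[, 1], vy = x$velocities[, 2], vz = x$velocities[, 3]
  )
}

#' Time-ordered collection of snapshots from one condition
#'
#' @param condition The [condition()] the snapshots were sampled from.
#' @param snapshots List of [snapshot()] objects with strictly increasing
#'   times, identical N, species and box.
#' @param sample_interval Time between stored snapshots.
#' @return A `trajectory` object.
#' @export
trajectory <- function(condition, snapshots, sample_interval = NA_real_) {
  stopifnot(length(snapshots) >= 1L)
  times <- vapply(snapshots, function(s) s$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("snapshot times must be strictly increasing")
  n <- vapply(snapshots, function(s) nrow(s$positions), integer(1))
  if (length(unique(n)) != 1L) stop("all snapshots must share N")
  box0 <- snapshots[[1]]$box
  same_box <- vapply(snapshots, function(s) isTRUE(all.equal(s$box, box0)),
                     logical(1))
  if (!all(same_box)) stop("all snapshots must share the box")
  structure(
    list(condition = condition, snapshots = snapshots,
         sample_interval = sample_interval),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  id <- if (is.null(x$condition)) "<unlabelled>" else x$condition$condition_id
  cat(sprintf("<trajectory %s: %d frames of %d atoms>\n",
              id, length(x$snapshots), nrow(x$snapshots[[1]]$positions)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$snapshots)

#' Lennard-Jones interaction parameters
#'
#' Per-species epsilon, sigma and mass; cross terms follow Lorentz-Berthelot
#' mixing (arithmetic sigma, geometric epsilon). Reduced units
#' (sigma = epsilon = mass = kB = 1) are the default.
#'
#' @param epsilon Per-species well depths.
#' @param sigma Per-species diameters.
#' @param mass Per-species masses.
#' @param cutoff Interaction cutoff radius (same length unit as sigma).
#' @return An `lj_params` object with dense pair matrices `eps_mat`,
#'   `sig_mat`.
#' @export
lj_params <- function(epsilon = 1, sigma = 1, mass = 1, cutoff = 2.5) {
  # epsilon = 0 is allowed: the ideal-gas limit of the engine
  stopifnot(all(epsilon >= 0), all(sigma > 0), all(mass > 0), cutoff > 0)
  ns <- max(length(epsilon), length(sigma), length(mass))
  epsilon <- rep_len(epsilon, ns); sigma <- rep_len(sigma, ns)
  mass <- rep_len(mass, ns)
  sig_mat <- outer(sigma, sigma, function(a, b) (a + b) / 2)
  eps_mat <- outer(epsilon, epsilon, function(a, b) sqrt(a * b))
  structure(
    list(epsilon = epsilon, sigma = sigma, mass = mass, cutoff = cutoff,
         n_species = ns, eps_mat = eps_mat, sig_mat = sig_mat),
    class = "lj_params"
  )
}

check_cutoff <- function(params, box) {
  if (params$cutoff >= min(box) / 2)
    stop("cutoff must be below half the smallest box edge")
  invisible(TRUE)
}

#' Instantaneous kinetic temperature of a snapshot
#'
#' Defined as `sum(m v^2) / (3 N)` in units with kB = 1.
#'
#' @param snap A [snapshot()].
#' @param params An [lj_params()] supplying per-species masses.
#' @return Scalar temperature.
#' @export
kinetic_temperature <- function(snap, params = lj_params()) {
  m <- params$mass[snap$species + 1L]
  sum(m * snap$velocities^2) / (3 * nrow(snap$positions))
}
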