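#' Uniform radial grid for RDF estimation
#'
#' Half-open bins `[k dr, (k+1) dr)` with `dr = r_max / n_bins`; a distance
#' exactly equal to `r_max` is discarded. Bin centers sit at the midpoints.
#'
#' @param r_max Largest distance covered; must not exceed half the smallest
#'   box edge of any snapshot the grid is applied to.
#' @param n_bins Number of bins (>= 2).
#' @return A `radial_grid` object with `edges` and `centers`.
#' @export
radial_grid <- function(r_max = 4, n_bins = 100) {
  stopifnot(r_max > 0, n_bins >= 2)
  dr <- r_max / n_bins
  structure(
    list(r_max = r_max, n_bins = as.integer(n_bins), dr = dr,
         edges = seq(0, r_max, length.out = n_bins + 1),
         centers = (seq_len(n_bins) - 0.5) * dr),
    class = "radial_grid"
  )
}

#' Default grid for a set of trajectories
#'
#' `r_max` is the smaller of 4 sigma and half the smallest box edge across
#' the trajectories, so one fixed-length grid is valid for every condition.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param n_bins Number of bins.
#' @param sigma Length scale (reduced units: 1).
#' @return A [radial_grid()].
#' @export
default_grid <- function(trajectories, n_bins = 100, sigma = 1) {
  half_box <- min(vapply(trajectories,
                         function(tr) min(tr$snapshots[[1]]$box) / 2,
                         numeric(1)))
  radial_grid(r_max = min(4 * sigma, half_box), n_bins = n_bins)
}

same_grid <- function(a, b, tol = 1e-12) {
  abs(a$r_max - b$r_max) <= tol && a$n_bins == b$n_bins
}

new_rdf_curve <- function(grid, g, pair, n_frames = 1L) {
  out <- tibble::tibble(r = grid$centers, g = as.numeric(g))
  structure(out, pair = as.integer(pair), grid = grid,
            n_frames_averaged = as.integer(n_frames),
            class = c("rdf_curve", class(out)))
}

#' Single-snapshot partial radial distribution function
#'
#' Histograms minimum-image pair distances for one ordered species pair and
#' normalizes by the ideal-gas expectation: `g_k = C_k / (N_a N_b'
#' V_shell_k / V_box)` where `C_k` counts ordered (a, b) pairs in bin `k`
#' (self-pairs excluded), and `N_b' = N_b - 1` when `a == b`.
#'
#' @param snap A [snapshot()].
#' @param pair Length-2 species pair (dense 0-based labels); order is
#'   irrelevant.
#' @param grid A [radial_grid()]; `r_max` must be at most half the smallest
#'   box edge.
#' @return An `rdf_curve`: a tibble with columns `r`, `g` plus `pair`,
#'   `grid`, `n_frames_averaged` attributes.
#' @export
snapshot_rdf <- function(snap, pair = c(0, 0), grid = radial_grid()) {
  pair <- sort(as.integer(pair))
  if (grid$r_max > min(snap$box) / 2 + 1e-12)
    stop("grid r_max exceeds half the smallest box edge")
  n_a <- sum(snap$species == pair[1])
  n_b <- sum(snap$species == pair[2])
  if (n_a == 0L || n_b == 0L)
    stop(sprintf("species pair (%d, %d) not present in snapshot",
                 pair[1], pair[2]))
  counts <- pair_histogram_cpp(snap$positions, snap$species, snap$box,
                               pair[1], pair[2], grid$r_max, grid$n_bins)
  v_shell <- 4 / 3 * pi * diff(grid$edges^3)
  v_box <- prod(snap$box)
  n_b_eff <- if (pair[1] == pair[2]) n_b - 1 else n_b
  ideal <- n_a * n_b_eff * v_shell / v_box
  new_rdf_curve(grid, counts / ideal, pair, n_frames = 1L)
}

#' Average RDF curves sharing one pair and grid
#'
#' The temporal ground truth: the per-bin arithmetic mean of single-snapshot
#' curves, with `n_frames_averaged` accumulated.
#'
#' @param curves Non-empty list of `rdf_curve` objects with identical pair
#'   and grid.
#' @return The averaged `rdf_curve`.
#' @export
average_rdf <- function(curves) {
  if (length(curves) == 0L) stop("no curves to average")
  p0 <- attr(curves[[1]], "pair"); g0 <- attr(curves[[1]], "grid")
  for (cv in curves) {
    if (!identical(attr(cv, "pair"), p0) || !same_grid(attr(cv, "grid"), g0))
      stop("curves must share one species pair and one grid")
  }
  gmat <- vapply(curves, function(cv) cv$g, numeric(g0$n_bins))
  n <- sum(vapply(curves, function(cv) attr(cv, "n_frames_averaged"),
                  integer(1)))
  new_rdf_curve(g0, rowMeans(gmat), p0, n_frames = n)
}

check_matching_curves <- function(g_pred, g_ref) {
  if (!same_grid(attr(g_pred, "grid"), attr(g_ref, "grid")))
    stop("curves are on different radial grids")
}

#' Mean squared RDF error
#'
#' The per-bin mean squared deviation between a predicted and a reference
#' curve, the same quantity the network's training loss minimizes; zero iff
#' the curves are identical.
#'
#' @param g_pred,g_ref `rdf_curve` objects on one grid.
#' @return Non-negative scalar.
#' @export
rdf_error <- function(g_pred, g_ref) {
  check_matching_curves(g_pred, g_ref)
  mean((g_pred$g - g_ref$g)^2)
}

#' Coefficient of determination between RDF curves
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the reference curve over bins. Identical curves give exactly 1; a
#' constant reference is rejected (zero total variance).
#'
#' @inheritParams rdf_error
#' @return Scalar, at most 1.
#' @export
r2_score <- function(g_pred, g_ref) {
  check_matching_curves(g_pred, g_ref)
  ss_tot <- sum((g_ref$g - mean(g_ref$g))^2)
  if (ss_tot == 0) stop("reference curve is constant; R^2 undefined")
  1 - sum((g_pred$g - g_ref$g)^2) / ss_tot
}

#' L1 relative error between RDF curves
#'
#' `sum |g_pred - g_ref| / sum |g_ref|`; zero iff identical.
#'
#' @inheritParams rdf_error
#' @return Non-negative scalar.
#' @export
relative_error <- function(g_pred, g_ref) {
  check_matching_curves(g_pred, g_ref)
  sum(abs(g_pred$g - g_ref$g)) / sum(abs(g_ref$g))
}

#' All unordered species pairs of a system
#'
#' @param n_species Number of species.
#' @return List of sorted pairs in lexicographic order: (0,0), (0,1), (1,1),
#'   ...
#' @export
species_pairs <- function(n_species) {
  out <- list()
  for (a in 0:(n_species - 1)) for (b in a:(n_species - 1))
    out[[length(out) + 1L]] <- c(a, b)
  out
}

pair_key <- function(pair) paste(pair, collapse = "-")

#' Temporally averaged partial RDFs of a trajectory
#'
#' The reference ("ground truth") curves: single-snapshot RDFs averaged over
#' every frame, one curve per species pair in lexicographic order.
#'
#' @param traj A [trajectory()].
#' @param grid A [radial_grid()].
#' @param pairs List of species pairs; defaults to every pair present.
#' @return An `rdf_set`: named list of `rdf_curve`s with a `condition`
#'   attribute.
#' @export
trajectory_rdf <- function(traj, grid = NULL, pairs = NULL) {
  if (is.null(grid)) grid <- default_grid(list(traj))
  if (is.null(pairs))
    pairs <- species_pairs(length(unique(traj$snapshots[[1]]$species)))
  curves <- lapply(pairs, function(p) {
    average_rdf(lapply(traj$snapshots, snapshot_rdf, pair = p, grid = grid))
  })
  names(curves) <- vapply(pairs, pair_key, character(1))
  structure(curves, condition = traj$condition, class = "rdf_set")
}

#' @export
print.rdf_set <- function(x, ...) {
  cat(sprintf("<rdf_set: pairs %s, %d bins>\n",
              paste(names(x), collapse = ", "),
              attr(x[[1]], "grid")$n_bins))
  invisible(x)
}

#' Single-snapshot RDF errors of direct MD estimation
#'
#' For every frame and pair, the error of that frame's RDF against the
#' full-trajectory average: the accuracy a practitioner gets from one
#' snapshot of direct simulation, the baseline the surrogate is compared to.
#'
#' @param traj A [trajectory()].
#' @param grid A [radial_grid()].
#' @param pairs Species pairs (default: all present).
#' @param reference Optional precomputed `rdf_set` to compare against;
#'   defaults to the average over `traj` itself.
#' @return Tibble with columns `frame`, `time`, `pair`, `error`, `r2`,
#'   `rel_error`. Per-pair mean/sd via [summary()] or `dplyr::summarise()`.
#' @export
baseline_snapshot_errors <- function(traj, grid = NULL, pairs = NULL,
                                     reference = NULL) {
  if (is.null(grid)) grid <- default_grid(list(traj))
  if (is.null(pairs))
    pairs <- species_pairs(length(unique(traj$snapshots[[1]]$species)))
  if (is.null(reference)) reference <- trajectory_rdf(traj, grid, pairs)
  rows <- purrr::map_dfr(seq_along(traj$snapshots), function(i) {
    snap <- traj$snapshots[[i]]
    purrr::map_dfr(pairs, function(p) {
      cur <- snapshot_rdf(snap, p, grid)
      ref <- reference[[pair_key(p)]]
      tibble::tibble(frame = i, time = snap$time, pair = pair_key(p),
                     error = rdf_error(cur, ref),
                     r2 = r2_score(cur, ref),
                     rel_error = relative_error(cur, ref))
    })
  })
  class(rows) <- c("baseline_errors", class(rows))
  rows
}

#' @export
summary.baseline_errors <- function(object, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(object), .data$pair),
                   mean_error = mean(.data$error),
                   sd_error = stats::sd(.data$error),
                   mean_r2 = mean(.data$r2),
                   mean_rel_error = mean(.data$rel_error),
                   n_frames = dplyr::n(), .groups = "drop")
}

#' Tidy an RDF set into one long tibble
#'
#' @param x An `rdf_set`.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `r`, `g`, `n_frames_averaged`.
#' @export
tidy.rdf_set <- function(x, ...) {
  purrr::map_dfr(names(x), function(k) {
    tibble::tibble(pair = k, r = x[[k]]$r, g = x[[k]]$g,
                   n_frames_averaged = attr(x[[k]], "n_frames_averaged"))
  })
}

#' Plot an RDF set
#'
#' @param object An `rdf_set`.
#' @param ... Unused.
#' @return A ggplot: g(r) per species pair.
#' @export
autoplot.rdf_set <- function(object, ...) {
  ggplot2::ggplot(tidy.rdf_set(object),
                  ggplot2::aes(x = .data$r, y = .data$g,
                               colour = .data$pair)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r", y = "g(r)", colour = "pair") +
    ggplot2::theme_minimal()
}

#' Write an RDF set to CSV with a JSON metadata sidecar
#'
#' @param x An `rdf_set`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_rdf_csv <- function(x, path) {
  utils::write.csv(tidy.rdf_set(x), path, row.names = FALSE)
  g0 <- attr(x[[1]], "grid")
  meta <- list(
    r_max = g0$r_max, n_bins = g0$n_bins, pair_order = names(x),
    n_frames_averaged = vapply(x, function(cv)
      attr(cv, "n_frames_averaged"), integer(1)),
    condition_id = if (!is.null(attr(x, "condition")))
      attr(x, "condition")$condition_id else NULL
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
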