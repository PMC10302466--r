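#' Default desk-scale condition grid
#'
#' Twelve (temperature, density) state points spanning the Lennard-Jones
#' liquid region in reduced units: T in {0.85, 0.95, 1.10, 1.25} crossed
#' with rho in {0.70, 0.75, 0.80}.
#'
#' @return List of 12 [condition()] objects.
#' @export
default_conditions <- function() {
  condition_grid(temperatures = c(0.85, 0.95, 1.10, 1.25),
                 densities = c(0.70, 0.75, 0.80))
}

#' Interaction parameters for the bundled systems
#'
#' `"mono"` is a single Lennard-Jones species (an argon analogue in reduced
#' units); `"binary"` is an equimolar two-species mixture with
#' Lorentz-Berthelot cross terms, mildly asymmetric so the three partial
#' RDFs differ.
#'
#' @param system `"mono"` or `"binary"`.
#' @return An [lj_params()].
#' @export
system_params <- function(system = c("mono", "binary")) {
  system <- match.arg(system)
  if (system == "mono") lj_params()
  else lj_params(epsilon = c(1, 0.7), sigma = c(1, 0.88),
                 mass = c(1, 0.8), cutoff = 2.5)
}

#' Run the end-to-end single-snapshot RDF experiment at desk scale
#'
#' The full pipeline in miniature: simulate a grid of Lennard-Jones liquid
#' conditions, build a dataset whose inputs come from the leading fifth of
#' each trajectory and whose labels are the full-run averaged RDFs, split by
#' condition (80/10/10), train the point-cloud network (Adam, learning rate
#' 0.001, MSE loss, early stopping) and score the held-out condition against
#' both the ground truth and the direct-MD single-snapshot baseline.
#'
#' @param seed Seed for the split, weight initialization and training
#'   shuffles.
#' @param system `"mono"` (one species, one RDF) or `"binary"` (two species,
#'   three partial RDFs predicted simultaneously).
#' @param sim_seed Seed for the simulations (defaults to `seed`); pass the
#'   same value with different `seed`s to rerun training on one dataset.
#' @param trajectories Optional pre-simulated named trajectory list (e.g.
#'   from a previous run's `$trajectories`); skips the MD stage.
#' @param n_atoms Atoms per condition.
#' @param n_equil_steps,n_prod_steps,sample_interval,dt Engine settings;
#'   defaults give 150 production frames per condition.
#' @param max_epochs,patience,batch_size Training-loop settings.
#' @param n_bins Radial bins per pair.
#' @param input_window Leading fraction of each trajectory used as inputs.
#' @return An `rdf_experiment`: trajectories, dataset, split, trained model,
#'   evaluation report and a one-row `summary` tibble with the held-out
#'   mean R^2, model and baseline errors and their ratio.
#' @export
run_rdf_experiment <- function(seed = 1L, system = c("mono", "binary"),
                               sim_seed = seed, trajectories = NULL,
                               n_atoms = 400, n_equil_steps = 1200,
                               n_prod_steps = 1500, sample_interval = 10,
                               dt = 0.005, max_epochs = 2000, patience = 300,
                               batch_size = 8, n_bins = 100,
                               input_window = 0.2) {
  system <- match.arg(system)
  params <- system_params(system)
  fractions <- if (system == "mono") 1 else c(0.5, 0.5)
  if (is.null(trajectories)) {
    trajectories <- generate_grid(default_conditions(), params = params,
                                  seed = sim_seed, n_atoms = n_atoms,
                                  n_equil_steps = n_equil_steps,
                                  n_prod_steps = n_prod_steps,
                                  sample_interval = sample_interval,
                                  dt = dt, species_fractions = fractions)
  }
  grid <- default_grid(trajectories, n_bins = n_bins)
  dataset <- build_dataset(trajectories, grid = grid,
                           input_window = input_window)
  split <- split_conditions(names(trajectories), seed = seed)
  model <- build_model(spec_for_dataset(dataset), seed = seed)
  config <- train_config(max_epochs = max_epochs, patience = patience,
                         batch_size = batch_size, seed = seed)
  fit <- train_pointnet(model, dataset, split, config)
  report <- evaluate_model(fit, trajectories, dataset)
  ov <- report$overall
  summary <- tibble::tibble(
    system = system, seed = seed,
    n_conditions = length(trajectories),
    n_train = length(split$train), n_validation = length(split$validation),
    n_test = length(split$test),
    epochs_run = max(fit$history$epoch), best_epoch = fit$best_epoch,
    heldout_mean_r2 = ov$mean_r2[ov$method == "model"],
    model_mean_error = ov$mean_error[ov$method == "model"],
    baseline_mean_error = ov$mean_error[ov$method == "md_baseline"],
    error_ratio = ov$mean_error[ov$method == "model"] /
      ov$mean_error[ov$method == "md_baseline"],
    model_mu_re = ov$mu_re[ov$method == "model"],
    model_sigma_re = ov$sigma_re[ov$method == "model"]
  )
  structure(list(trajectories = trajectories, dataset = dataset,
                 split = split, model = fit, report = report,
                 summary = summary, system = system, seed = seed),
            class = "rdf_experiment")
}

#' @export
print.rdf_experiment <- function(x, ...) {
  cat(sprintf("<rdf_experiment (%s, seed %d)>\n", x$system, x$seed))
  print(as.data.frame(x$summary))
  invisible(x)
}

#' @export
glance.rdf_experiment <- function(x, ...) x$summary
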