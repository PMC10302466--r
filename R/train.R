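#' Split conditions into train/validation/test sets
#'
#' Conditions (not frames) are shuffled by the seed and partitioned, so every
#' frame of a condition inherits its subset and no frame-level leakage is
#' possible. Validation and test sizes are `round(fraction * n)` (half away
#' from zero) with the remainder assigned to training, which reproduces an
#' 80/10/10 split of 400 conditions as (320, 40, 40) and of 200 as
#' (160, 20, 20).
#'
#' @param condition_ids Character vector of unique ids (>= 5).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return A `condition_split` with `train`, `validation`, `test` id sets.
#' @export
split_conditions <- function(condition_ids, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L) {
  n <- length(condition_ids)
  if (n < 5L) stop("need at least 5 conditions to split")
  if (anyDuplicated(condition_ids)) stop("condition_ids must be unique")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  round_half_up <- function(x) floor(x + 0.5)
  n_val <- round_half_up(fractions[2] * n)
  n_test <- round_half_up(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L)
    stop("every subset must be non-empty")
  shuffled <- withr::with_seed(seed, sample(condition_ids))
  structure(
    list(train = shuffled[seq_len(n_train)],
         validation = shuffled[n_train + seq_len(n_val)],
         test = shuffled[n_train + n_val + seq_len(n_test)],
         fractions = fractions, seed = seed),
    class = "condition_split"
  )
}

#' @export
print.condition_split <- function(x, ...) {
  cat(sprintf("<condition_split: %d train / %d validation / %d test>\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs Upper bound on epochs; early stopping usually ends
#'   training sooner.
#' @param patience Epochs without validation-MSE improvement before stopping;
#'   the best-validation parameters are restored.
#' @param batch_size Minibatch size.
#' @param seed Seed for shuffling and weight initialization.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 1000,
                         patience = 50, batch_size = 8, seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 1, max_epochs >= 1,
            batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble a training dataset from trajectories
#'
#' Inputs are drawn only from the leading window of each trajectory (the
#' short-time data the surrogate sees), while every sample's target is the
#' condition's full-trajectory averaged RDF — the long-time structure the
#' model is asked to recover. Per-pair target curves are concatenated in
#' lexicographic pair order.
#'
#' @param trajectories Named list of [trajectory()] objects.
#' @param grid [radial_grid()]; defaults to [default_grid()] of the set.
#' @param input_window Fraction of each trajectory whose leading frames
#'   become inputs (default 0.2).
#' @param stride Keep every `stride`-th frame of the window.
#' @param include_velocities Append the velocity block to the point features.
#' @return An `rdf_dataset`: a samples tibble (list-columns `features`,
#'   `state`), per-condition ground-truth `rdf_set`s, the grid, pair list
#'   and feature metadata.
#' @export
build_dataset <- function(trajectories, grid = NULL, input_window = 0.2,
                          stride = 1, include_velocities = TRUE) {
  stopifnot(length(trajectories) >= 1, input_window > 0, input_window <= 1)
  if (is.null(grid)) grid <- default_grid(trajectories)
  n_species <- max(vapply(trajectories, function(tr)
    max(tr$snapshots[[1]]$species), integer(1))) + 1L
  pairs <- species_pairs(n_species)
  ground_truth <- lapply(trajectories, trajectory_rdf, grid = grid,
                         pairs = pairs)
  targets <- lapply(ground_truth, function(gt)
    unlist(lapply(gt, function(cv) cv$g), use.names = FALSE))

  samples <- purrr::map_dfr(names(trajectories), function(id) {
    tr <- trajectories[[id]]
    nf <- length(tr$snapshots)
    nw <- max(1L, floor(nf * input_window))
    idx <- seq(1L, nw, by = stride)
    purrr::map_dfr(idx, function(i) {
      snap <- tr$snapshots[[i]]
      tibble::tibble(
        condition_id = id, frame = i, time = snap$time,
        features = list(snapshot_features(snap, n_species,
                                          include_velocities)),
        state = list(c(tr$condition$density, tr$condition$temperature))
      )
    })
  })
  structure(
    list(samples = samples, targets = targets, ground_truth = ground_truth,
         grid = grid, pairs = pairs, n_species = n_species,
         n_points = nrow(trajectories[[1]]$snapshots[[1]]$positions),
         include_velocities = include_velocities,
         input_window = input_window, stride = stride),
    class = "rdf_dataset"
  )
}

#' @export
print.rdf_dataset <- function(x, ...) {
  cat(sprintf(
    "<rdf_dataset: %d samples from %d conditions, %d species, %d-bin grid>\n",
    nrow(x$samples), length(x$targets), x$n_species, x$grid$n_bins))
  invisible(x)
}

#' Default model spec matching a dataset
#'
#' @param dataset An `rdf_dataset`.
#' @param ... Overrides passed to [model_spec()].
#' @return A [model_spec()] with matching feature and output dimensions.
#' @export
spec_for_dataset <- function(dataset, ...) {
  n_feat <- 3L + (if (dataset$include_velocities) 3L else 0L) +
    (if (dataset$n_species > 1L) dataset$n_species else 0L)
  model_spec(n_point_features = n_feat,
             n_output_pairs = length(dataset$pairs),
             n_bins_per_pair = dataset$grid$n_bins, ...)
}

# Stack a subset of samples into dense arrays for batched passes.
stack_samples <- function(dataset, idx, normalizer) {
  n <- dataset$n_points
  feats <- lapply(dataset$samples$features[idx], function(f) {
    if (normalizer$include_velocities) f[, 4:6] <- f[, 4:6] / normalizer$v_rms
    f
  })
  states <- t(vapply(dataset$samples$state[idx],
                     function(s) (s - normalizer$s_mean) / normalizer$s_sd,
                     numeric(2)))
  y <- t(vapply(dataset$samples$condition_id[idx],
                function(id) dataset$targets[[id]],
                numeric(length(dataset$targets[[1]]))))
  list(points = do.call(rbind, feats), states = states, y = y,
       n_points = n, b = length(idx))
}

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

# One Adam update over the nested parameter list (in place via recursion).
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(p$W)) {
      for (nm in c("W", "b")) {
        s[[nm]]$m <- beta1 * s[[nm]]$m + (1 - beta1) * g[[nm]]
        s[[nm]]$v <- beta2 * s[[nm]]$v + (1 - beta2) * g[[nm]]^2
        mhat <- s[[nm]]$m / (1 - beta1^t)
        vhat <- s[[nm]]$v / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      return(list(p = p, s = s))
    }
    for (i in seq_along(p)) {
      r <- walk(p[[i]], g[[i]], s[[i]])
      p[[i]] <- r$p; s[[i]] <- r$s
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

batch_loss <- function(params, stacked, chunk = 64L) {
  idx <- seq_len(stacked$b)
  total <- 0
  for (part in split(idx, ceiling(idx / chunk))) {
    rows <- as.vector(outer(seq_len(stacked$n_points),
                            (part - 1) * stacked$n_points, `+`))
    out <- forward_batch(params, stacked$points[rows, , drop = FALSE],
                         stacked$n_points,
                         stacked$states[part, , drop = FALSE])
    total <- total + sum((out$pred - stacked$y[part, , drop = FALSE])^2)
  }
  total / (stacked$b * ncol(stacked$y))
}

#' Train the point-cloud RDF network
#'
#' Adam on the mean squared error between predicted and long-run averaged
#' RDF vectors, with condition-level train/validation separation, per-epoch
#' validation monitoring and early stopping that restores the best
#' parameters. Fully reproducible from the config seed.
#'
#' @param model A `pointnet` from [build_model()] (or `NULL` to build one
#'   from the dataset with defaults).
#' @param dataset An `rdf_dataset` from [build_dataset()].
#' @param split A `condition_split`; training and validation sets must be
#'   non-empty.
#' @param config A [train_config()].
#' @return A trained `pointnet_md`: the network plus normalizer, grid, pair
#'   order and a per-epoch `history` tibble.
#' @export
train_pointnet <- function(model, dataset, split, config = train_config()) {
  if (is.null(model))
    model <- build_model(spec_for_dataset(dataset), seed = config$seed)
  stopifnot(length(split$train) >= 1, length(split$validation) >= 1)
  stopifnot(length(intersect(split$train, split$validation)) == 0,
            length(intersect(split$train, split$test)) == 0,
            length(intersect(split$validation, split$test)) == 0)

  tr_idx <- which(dataset$samples$condition_id %in% split$train)
  va_idx <- which(dataset$samples$condition_id %in% split$validation)
  if (length(tr_idx) == 0 || length(va_idx) == 0)
    stop("training and validation sets must contain samples")

  # normalizer statistics from the training samples only
  v_rms <- if (dataset$include_velocities) {
    sqrt(mean(unlist(lapply(dataset$samples$features[tr_idx],
                            function(f) f[, 4:6]^2))))
  } else NA_real_
  smat <- t(vapply(dataset$samples$state[tr_idx], identity, numeric(2)))
  s_sd <- apply(smat, 2, stats::sd)
  s_sd[!is.finite(s_sd) | s_sd == 0] <- 1
  normalizer <- list(v_rms = v_rms, s_mean = colMeans(smat), s_sd = s_sd,
                     include_velocities = dataset$include_velocities)

  tr <- stack_samples(dataset, tr_idx, normalizer)
  va <- stack_samples(dataset, va_idx, normalizer)

  params <- model$params
  astate <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- vector("list", config$max_epochs)
  t_adam <- 0L
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(tr$b)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        rows <- as.vector(outer(seq_len(tr$n_points),
                                (bt - 1) * tr$n_points, `+`))
        step <- fwdbwd_batch(params, tr$points[rows, , drop = FALSE],
                             tr$n_points, tr$states[bt, , drop = FALSE],
                             tr$y[bt, , drop = FALSE])
        if (!is.finite(step$loss))
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        t_adam <- t_adam + 1L
        upd <- adam_update(params, step$grads, astate,
                           config$learning_rate, t_adam)
        params <- upd$p; astate <- upd$s
        ep_loss <- ep_loss + step$loss * length(bt)
      }
      val_loss <- batch_loss(params, va)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / tr$b, val_loss = val_loss)
      if (val_loss < best$loss)
        best <- list(loss = val_loss, params = params, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
  })

  structure(
    list(spec = model$spec, params = best$params, normalizer = normalizer,
         grid = dataset$grid, pairs = dataset$pairs,
         n_species = dataset$n_species,
         include_velocities = dataset$include_velocities,
         split = split, config = config,
         best_val_loss = best$loss, best_epoch = best$epoch,
         history = dplyr::bind_rows(history[!vapply(history, is.null,
                                                    logical(1))])),
    class = c("pointnet_md", "pointnet")
  )
}

#' @export
print.pointnet_md <- function(x, ...) {
  cat(sprintf(
    "<trained pointnet_md: %d pairs x %d bins, best val MSE %.3g at epoch %d/%d>\n",
    length(x$pairs), x$spec$n_bins_per_pair, x$best_val_loss, x$best_epoch,
    max(x$history$epoch)))
  invisible(x)
}

#' Evaluate a trained model on held-out conditions
#'
#' For every window frame of the requested conditions the model predicts the
#' full-trajectory RDF from that single snapshot; the same frame's direct MD
#' single-snapshot RDF provides the baseline. Both are scored against the
#' condition's long-run averaged ground truth with the mean squared error,
#' the coefficient of determination and the L1 relative error, per pair and
#' for the concatenated all-pair curve (`pair == "all"`).
#'
#' @param model A trained `pointnet_md`.
#' @param trajectories Named list of [trajectory()] objects containing the
#'   conditions to score.
#' @param dataset The `rdf_dataset` the model was trained from (supplies the
#'   ground truth, window and stride).
#' @param condition_ids Conditions to evaluate; default: the split's test
#'   set.
#' @return An `eval_report`: per-frame tibble plus per-condition and overall
#'   aggregates for model and baseline.
#' @export
evaluate_model <- function(model, trajectories, dataset,
                           condition_ids = model$split$test) {
  stopifnot(length(condition_ids) >= 1)
  score <- function(pred_vec, ref_vec, nb) {
    # per-pair rows then the concatenated curve
    p <- length(pred_vec) / nb
    rows <- lapply(seq_len(p), function(i) {
      sl <- (i - 1) * nb + seq_len(nb)
      tibble::tibble(pair = pair_key(model$pairs[[i]]),
                     error = mean((pred_vec[sl] - ref_vec[sl])^2),
                     r2 = 1 - sum((pred_vec[sl] - ref_vec[sl])^2) /
                       sum((ref_vec[sl] - mean(ref_vec[sl]))^2),
                     rel_error = sum(abs(pred_vec[sl] - ref_vec[sl])) /
                       sum(abs(ref_vec[sl])))
    })
    all_row <- tibble::tibble(
      pair = "all", error = mean((pred_vec - ref_vec)^2),
      r2 = 1 - sum((pred_vec - ref_vec)^2) /
        sum((ref_vec - mean(ref_vec))^2),
      rel_error = sum(abs(pred_vec - ref_vec)) / sum(abs(ref_vec)))
    dplyr::bind_rows(rows, all_row)
  }
  nb <- model$grid$n_bins
  per_frame <- purrr::map_dfr(condition_ids, function(id) {
    tr <- trajectories[[id]]
    if (is.null(tr)) stop(sprintf("condition %s has no trajectory", id))
    gt_vec <- dataset$targets[[id]]
    nf <- length(tr$snapshots)
    idx <- seq(1L, max(1L, floor(nf * dataset$input_window)),
               by = dataset$stride)
    purrr::map_dfr(idx, function(i) {
      snap <- tr$snapshots[[i]]
      pred <- suppressMessages(predict_rdfset(model, snap, tr$condition))
      pred_vec <- unlist(lapply(pred, function(cv) cv$g), use.names = FALSE)
      base_vec <- unlist(lapply(model$pairs, function(p)
        snapshot_rdf(snap, p, model$grid)$g), use.names = FALSE)
      dplyr::bind_rows(
        dplyr::mutate(score(pred_vec, gt_vec, nb), method = "model"),
        dplyr::mutate(score(base_vec, gt_vec, nb), method = "md_baseline")
      ) |> dplyr::mutate(condition_id = id, frame = i, time = snap$time)
    })
  })
  per_condition <- per_frame |>
    dplyr::group_by(.data$condition_id, .data$method, .data$pair) |>
    dplyr::summarise(mean_error = mean(.data$error),
                     sd_error = stats::sd(.data$error),
                     mean_r2 = mean(.data$r2),
                     mu_re = mean(.data$rel_error),
                     sigma_re = stats::sd(.data$rel_error),
                     n_frames = dplyr::n(), .groups = "drop")
  overall <- per_frame |>
    dplyr::filter(.data$pair == "all") |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_error = mean(.data$error),
                     sd_error = stats::sd(.data$error),
                     mean_r2 = mean(.data$r2),
                     mu_re = mean(.data$rel_error),
                     sigma_re = stats::sd(.data$rel_error),
                     n_frames = dplyr::n(), .groups = "drop")
  structure(list(per_frame = per_frame, per_condition = per_condition,
                 overall = overall, condition_ids = condition_ids),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d conditions>\n", length(x$condition_ids)))
  print(x$overall)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_condition

#' @export
glance.eval_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$overall[, c("method", "mean_error", "mean_r2", "mu_re", "sigma_re")],
    names_from = "method",
    values_from = c("mean_error", "mean_r2", "mu_re", "sigma_re"))
  dplyr::mutate(wide, error_ratio =
                  .data$mean_error_model / .data$mean_error_md_baseline)
}

#' @export
tidy.pointnet_md <- function(x, ...) x$history

#' @export
glance.pointnet_md <- function(x, ...) {
  tibble::tibble(n_parameters = n_parameters(x$spec),
                 epochs_run = max(x$history$epoch),
                 best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss)
}

#' Plot training history
#'
#' @param object A trained `pointnet_md`.
#' @param ... Unused.
#' @return A ggplot of train/validation MSE per epoch (log scale).
#' @export
autoplot.pointnet_md <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE") +
    ggplot2::theme_minimal()
}

#' Plot a model/baseline error comparison
#'
#' Bar chart of mean single-snapshot RDF error per held-out condition for
#' the surrogate and the direct-MD baseline (log scale).
#'
#' @param report An `eval_report`.
#' @return A ggplot.
#' @export
plot_error_comparison <- function(report) {
  dat <- dplyr::filter(report$per_condition, .data$pair == "all")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$condition_id,
                                    y = .data$mean_error,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mean RDF error (MSE)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
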