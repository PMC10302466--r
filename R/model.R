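#' Architecture of the point-cloud RDF network
#'
#' A shared multilayer perceptron is applied to every atom (point)
#' independently, a per-feature maximum over atoms pools the point features
#' into one global descriptor, the two thermodynamic state scalars are
#' concatenated to it, and a fully connected head maps the result to one
#' fixed-length g(r) vector per species pair.
#'
#' @param n_point_features Per-point input width, 3 + M (positions plus
#'   optional velocity and one-hot species blocks).
#' @param pointwise_widths Widths of the shared per-point layers. The
#'   defaults are a compact CPU-trainable stack; widen (e.g.
#'   `c(64, 64, 128, 256)`) for larger datasets.
#' @param n_state_scalars Number of state scalars fused after pooling
#'   (default 2: the condition's two state variables).
#' @param head_widths Hidden widths of the fully connected head.
#' @param n_output_pairs Number of species pairs predicted simultaneously.
#' @param n_bins_per_pair Radial bins per pair; output length is
#'   `n_output_pairs * n_bins_per_pair`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(n_point_features, pointwise_widths = c(16, 16, 32),
                       n_state_scalars = 2, head_widths = c(32, 32),
                       n_output_pairs = 1, n_bins_per_pair = 100) {
  stopifnot(n_point_features >= 3, all(pointwise_widths > 0),
            all(head_widths > 0), n_output_pairs >= 1, n_bins_per_pair >= 2)
  structure(
    list(n_point_features = as.integer(n_point_features),
         pointwise_widths = as.integer(pointwise_widths),
         n_state_scalars = as.integer(n_state_scalars),
         head_widths = as.integer(head_widths),
         n_output_pairs = as.integer(n_output_pairs),
         n_bins_per_pair = as.integer(n_bins_per_pair),
         activation = "relu"),
    class = "model_spec"
  )
}

output_length <- function(spec) spec$n_output_pairs * spec$n_bins_per_pair

layer_dims <- function(spec) {
  shared_in <- c(spec$n_point_features,
                 spec$pointwise_widths[-length(spec$pointwise_widths)])
  pooled <- spec$pointwise_widths[length(spec$pointwise_widths)]
  head_widths <- c(spec$head_widths, output_length(spec))
  head_in <- c(pooled + spec$n_state_scalars,
               head_widths[-length(head_widths)])
  list(shared = cbind(inp = shared_in, out = spec$pointwise_widths),
       head = cbind(inp = head_in, out = head_widths))
}

#' Number of trainable parameters of a spec
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count (weights + biases).
#' @export
n_parameters <- function(spec) {
  d <- layer_dims(spec)
  sum(d$shared[, 1] * d$shared[, 2] + d$shared[, 2]) +
    sum(d$head[, 1] * d$head[, 2] + d$head[, 2])
}

#' One-hot encode species labels
#'
#' Row i carries a single 1 in the column of atom i's species. Columns follow
#' dense label order reversed, so label 0 maps to the last column: in a
#' two-species system the second species encodes as `[1, 0]` and the first
#' as `[0, 1]`.
#'
#' @param species Dense 0-based labels.
#' @param n_species Number of species (> all labels).
#' @return N x n_species 0/1 matrix.
#' @export
encode_species <- function(species, n_species) {
  species <- as.integer(species)
  if (any(species < 0L | species >= n_species))
    stop("species label outside [0, n_species)")
  out <- matrix(0, length(species), n_species)
  out[cbind(seq_along(species), n_species - species)] <- 1
  out
}

#' Build a network with seed-deterministic initialization
#'
#' He-normal weights (sd `sqrt(2 / fan_in)`), zero biases.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return A `pointnet` object holding the spec and a flat parameter list.
#' @export
build_model <- function(spec, seed = 1L) {
  d <- layer_dims(spec)
  init_layer <- function(inp, out)
    list(W = matrix(stats::rnorm(inp * out, sd = sqrt(2 / inp)), inp, out),
         b = numeric(out))
  params <- withr::with_seed(seed, list(
    shared = lapply(seq_len(nrow(d$shared)), function(l)
      init_layer(d$shared[l, 1], d$shared[l, 2])),
    head = lapply(seq_len(nrow(d$head)), function(l)
      init_layer(d$head[l, 1], d$head[l, 2]))
  ))
  structure(list(spec = spec, params = params, seed = seed),
            class = "pointnet")
}

#' @export
print.pointnet <- function(x, ...) {
  cat(sprintf(
    "<pointnet: %d-wide points -> (%s) -> max pool -> +%d scalars -> (%s); %d parameters>\n",
    x$spec$n_point_features,
    paste(x$spec$pointwise_widths, collapse = ", "),
    x$spec$n_state_scalars,
    paste(c(x$spec$head_widths, output_length(x$spec)), collapse = ", "),
    n_parameters(x$spec)))
  invisible(x)
}

# Split a nested parameter list into the flat W/b lists the compiled
# kernels take.
param_lists <- function(params) {
  list(sW = lapply(params$shared, `[[`, "W"),
       sb = lapply(params$shared, `[[`, "b"),
       hW = lapply(params$head, `[[`, "W"),
       hb = lapply(params$head, `[[`, "b"))
}

# Batched forward pass. `points` stacks the B samples' point matrices
# sample-major: rows (b-1)*N + 1:N belong to sample b (all samples share N).
# Returns predictions (B x D) plus the pooled global features and the
# post-shared per-point features.
forward_batch <- function(params, points, n_points, states) {
  b <- nrow(states)
  stopifnot(nrow(points) == b * n_points)
  p <- param_lists(params)
  nn_forward_cpp(p$sW, p$sb, p$hW, p$hb, points, as.integer(n_points),
                 states)
}

# Loss and gradient of the mean squared error in one fused compiled pass.
# Returns loss, predictions and a gradient list shaped like `params`.
fwdbwd_batch <- function(params, points, n_points, states, targets) {
  p <- param_lists(params)
  out <- nn_fwdbwd_cpp(p$sW, p$sb, p$hW, p$hb, points,
                       as.integer(n_points), states, targets)
  grads <- list(
    shared = lapply(seq_along(params$shared), function(l)
      list(W = out$gW_shared[[l]], b = as.numeric(out$gb_shared[[l]]))),
    head = lapply(seq_along(params$head), function(l)
      list(W = out$gW_head[[l]], b = as.numeric(out$gb_head[[l]]))))
  list(loss = out$loss, pred = out$pred, grads = grads)
}

#' Forward pass of the network
#'
#' Applies the shared layers to every point independently, max-pools over
#' points, concatenates the state scalars and maps through the head. Exactly
#' permutation-invariant in the points.
#'
#' @param model A `pointnet` or trained `pointnet_md`.
#' @param point_features N x (3+M) feature matrix (already normalized).
#' @param state_scalars Length-`n_state_scalars` vector (already
#'   standardized).
#' @return Numeric prediction of length `n_output_pairs * n_bins_per_pair`.
#' @export
forward <- function(model, point_features, state_scalars) {
  spec <- model$spec
  point_features <- as.matrix(point_features)
  if (ncol(point_features) != spec$n_point_features)
    stop("point feature width does not match the model spec")
  if (length(state_scalars) != spec$n_state_scalars)
    stop("state scalar count does not match the model spec")
  out <- forward_batch(model$params, point_features, nrow(point_features),
                       matrix(state_scalars, 1))
  as.numeric(out$pred)
}

# Assemble the raw (un-normalized beyond fractional positions) per-point
# feature matrix of a snapshot: fractional positions, then velocities, then
# the one-hot species block.
snapshot_features <- function(snap, n_species, include_velocities = TRUE) {
  pos <- sweep(snap$positions, 2, snap$box, `/`)
  blocks <- list(pos)
  if (include_velocities) blocks <- c(blocks, list(snap$velocities))
  if (n_species > 1L)
    blocks <- c(blocks, list(encode_species(snap$species, n_species)))
  do.call(cbind, blocks)
}

# Apply a trained normalizer: scale the velocity block by its training-set
# rms and standardize the state scalars.
normalize_features <- function(features, state, normalizer) {
  if (normalizer$include_velocities) {
    vcols <- 4:6
    features[, vcols] <- features[, vcols] / normalizer$v_rms
  }
  list(features = features,
       state = (state - normalizer$s_mean) / normalizer$s_sd)
}

#' Predict all partial RDFs from one configuration
#'
#' Assembles the point features of a snapshot with the model's trained
#' normalizer, runs the network once and splits the output into per-pair
#' curves in lexicographic pair order. Negative predicted g values are
#' clamped to zero at this interface (never during training), with a message
#' reporting the count.
#'
#' @param model A trained `pointnet_md` (from [train_pointnet()]).
#' @param snap A [snapshot()].
#' @param cond Condition supplying the state scalars; defaults to the
#'   snapshot's own condition.
#' @return An `rdf_set` of predicted curves.
#' @export
predict_rdfset <- function(model, snap, cond = NULL) {
  if (is.null(cond)) cond <- snap$condition
  if (is.null(cond)) stop("no condition supplied for the state scalars")
  if (any(snap$species >= model$n_species))
    stop("snapshot contains species unknown to the trained model")
  feats <- snapshot_features(snap, model$n_species,
                             model$normalizer$include_velocities)
  nf <- normalize_features(feats, c(cond$density, cond$temperature),
                           model$normalizer)
  pred <- forward(model, nf$features, nf$state)
  n_clamped <- sum(pred < 0)
  if (n_clamped > 0)
    message(sprintf("clamped %d negative predicted g values to 0", n_clamped))
  pred[pred < 0] <- 0
  nb <- model$spec$n_bins_per_pair
  curves <- lapply(seq_along(model$pairs), function(i) {
    new_rdf_curve(model$grid, pred[(i - 1) * nb + seq_len(nb)],
                  model$pairs[[i]], n_frames = 1L)
  })
  names(curves) <- vapply(model$pairs, pair_key, character(1))
  structure(curves, condition = cond, class = "rdf_set")
}

#' Save / load a trained model checkpoint
#'
#' The parameter blob is written as RDS next to a JSON sidecar holding the
#' spec, normalizer statistics, pair order and radial grid — enough to reload
#' and predict with no other context.
#'
#' @param model A trained `pointnet_md`.
#' @param path Checkpoint path (RDS); the sidecar goes to `<path>.json`.
#' @return `path` invisibly (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    spec = unclass(model$spec),
    normalizer = model$normalizer,
    pairs = lapply(model$pairs, identity),
    grid = list(r_max = model$grid$r_max, n_bins = model$grid$n_bins),
    n_species = model$n_species,
    n_parameters = n_parameters(model$spec)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
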