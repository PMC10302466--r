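test_that("condition splits reproduce the published sizes and stay disjoint", {
  ids400 <- sprintf("c%03d", 1:400)
  s <- split_conditions(ids400, seed = 1)
  expect_identical(lengths(s[c("train", "validation", "test")]),
                   c(train = 320L, validation = 40L, test = 40L))

  s200 <- split_conditions(sprintf("c%03d", 1:200), seed = 2)
  expect_identical(lengths(s200[c("train", "validation", "test")]),
                   c(train = 160L, validation = 20L, test = 20L))

  s5 <- split_conditions(letters[1:5], seed = 3)
  expect_identical(lengths(s5[c("train", "validation", "test")]),
                   c(train = 3L, validation = 1L, test = 1L))

  all_ids <- c(s$train, s$validation, s$test)
  expect_identical(sort(all_ids), sort(ids400))
  expect_length(intersect(s$train, s$test), 0)
  expect_length(intersect(s$train, s$validation), 0)
  expect_length(intersect(s$validation, s$test), 0)

  expect_identical(split_conditions(ids400, seed = 7),
                   split_conditions(ids400, seed = 7))
  expect_error(split_conditions(ids400, fractions = c(0.8, 0.1, 0.2)),
               "sum")
  expect_error(split_conditions(letters[1:4]), "at least 5")
})

test_that("datasets window the inputs and label every sample with the full-run average", {
  trajs <- tiny_grid_trajectories()
  grid <- radial_grid(r_max = 2, n_bins = 25)
  ds <- build_dataset(trajs, grid = grid, input_window = 0.2, stride = 1)
  # 30 frames per condition -> 6 window samples each
  expect_identical(nrow(ds$samples), 6L * 6L)
  expect_true(all(ds$samples$frame <= 6))

  ds2 <- build_dataset(trajs, grid = grid, input_window = 0.2, stride = 2)
  expect_identical(nrow(ds2$samples), 3L * 6L)

  # target equals the independently recomputed temporal average
  id <- names(trajs)[4]
  ref <- average_rdf(lapply(trajs[[id]]$snapshots, snapshot_rdf,
                            pair = c(0, 0), grid = grid))
  expect_equal(ds$targets[[id]], ref$g, tolerance = 1e-12)

  # feature block layout: fractional positions, velocities
  f <- ds$samples$features[[1]]
  expect_identical(ncol(f), 6L)
  expect_true(all(f[, 1:3] >= 0 & f[, 1:3] < 1))
})

test_that("training is seed-reproducible, early-stops and keeps the best weights", {
  trajs <- tiny_grid_trajectories()
  ds <- build_dataset(trajs, grid = radial_grid(2, 25), input_window = 0.2)
  split <- split_conditions(names(trajs), seed = 4)
  spec <- spec_for_dataset(ds, pointwise_widths = c(8, 8),
                           head_widths = c(16))
  cfg <- train_config(max_epochs = 15, patience = 5, batch_size = 8,
                      seed = 4)
  fit1 <- train_pointnet(build_model(spec, seed = 4), ds, split, cfg)
  fit2 <- train_pointnet(build_model(spec, seed = 4), ds, split, cfg)
  expect_identical(fit1$best_val_loss, fit2$best_val_loss)
  expect_identical(fit1$params, fit2$params)

  h <- fit1$history
  expect_identical(min(h$val_loss), fit1$best_val_loss)
  # stopped within `patience` epochs of the best epoch
  expect_lte(max(h$epoch) - fit1$best_epoch, cfg$patience)
  # best-so-far validation loss is non-increasing
  expect_true(all(diff(cummin(h$val_loss)) <= 0))
  expect_identical(glance(fit1)$best_epoch, fit1$best_epoch)
  expect_s3_class(autoplot(fit1), "ggplot")
})

test_that("an oracle predictor scores perfectly and beats any baseline", {
  trajs <- tiny_grid_trajectories()
  ds <- build_dataset(trajs, grid = radial_grid(2, 25), input_window = 0.2)
  split <- split_conditions(names(trajs), seed = 4)
  spec <- spec_for_dataset(ds, pointwise_widths = c(4, 4), head_widths = c(4))
  model <- build_model(spec, seed = 1)
  # zero the last head layer and plant the held-out ground truth in its bias:
  # the network then emits exactly the reference curve for every frame
  nl <- length(model$params$head)
  model$params$head[[nl]]$W[] <- 0
  model$params$head[[nl]]$b <- ds$targets[[split$test]]
  oracle <- structure(
    c(model, list(normalizer = list(v_rms = 1, s_mean = c(0, 0),
                                    s_sd = c(1, 1),
                                    include_velocities = TRUE),
                  grid = ds$grid, pairs = ds$pairs,
                  n_species = ds$n_species, split = split,
                  include_velocities = TRUE)),
    class = c("pointnet_md", "pointnet"))
  rep <- evaluate_model(oracle, trajs, ds)
  model_rows <- dplyr::filter(rep$per_frame, method == "model")
  expect_equal(model_rows$error, rep(0, nrow(model_rows)), tolerance = 1e-20)
  expect_equal(model_rows$r2, rep(1, nrow(model_rows)))
  expect_equal(model_rows$rel_error, rep(0, nrow(model_rows)))
  base_rows <- dplyr::filter(rep$per_frame, method == "md_baseline")
  expect_true(all(base_rows$error > 0))
  gl <- glance(rep)
  expect_identical(gl$error_ratio, 0)
  expect_s3_class(plot_error_comparison(rep), "ggplot")
})

test_that("prediction refuses species the model never saw", {
  trajs <- tiny_grid_trajectories()
  ds <- build_dataset(trajs, grid = radial_grid(2, 25))
  split <- split_conditions(names(trajs), seed = 4)
  spec <- spec_for_dataset(ds, pointwise_widths = c(4, 4), head_widths = c(4))
  fit <- structure(
    c(build_model(spec, seed = 1),
      list(normalizer = list(v_rms = 1, s_mean = c(0, 0), s_sd = c(1, 1),
                             include_velocities = TRUE),
           grid = ds$grid, pairs = ds$pairs, n_species = ds$n_species,
           split = split)),
    class = c("pointnet_md", "pointnet"))
  snap <- trajs[[1]]$snapshots[[1]]
  alien <- snapshot(snap$positions, snap$velocities,
                    rep(c(0L, 1L), length.out = nrow(snap$positions)),
                    snap$box, condition = snap$condition)
  expect_error(predict_rdfset(fit, alien), "unknown")
})
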