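test_that("a single pair lands in exactly one bin", {
  d <- 1.37
  pos <- rbind(c(1, 1, 1), c(1 + d, 1, 1))
  snap <- snapshot(pos, NULL, c(0, 0), c(20, 20, 20))
  grid <- radial_grid(r_max = 4, n_bins = 40)
  g <- snapshot_rdf(snap, c(0, 0), grid)
  hit <- which(g$g > 0)
  expect_length(hit, 1)
  expect_identical(hit, as.integer(floor(d / grid$dr) + 1))
})

test_that("snapshot_rdf matches the brute-force double loop bin for bin", {
  grid <- radial_grid(r_max = 2.5, n_bins = 25)
  for (seed in 1:12) {
    n_species <- 1 + seed %% 2
    snap <- random_snapshot(60, c(6, 7, 8), n_species = n_species,
                            seed = seed)
    for (p in species_pairs(n_species)) {
      expect_equal(snapshot_rdf(snap, p, grid)$g,
                   brute_force_rdf(snap, p, grid), tolerance = 1e-12)
    }
  }
})

test_that("RDF is symmetric in the species pair and errors on bad input", {
  snap <- random_snapshot(80, c(6, 6, 6), n_species = 2, seed = 4)
  grid <- radial_grid(r_max = 2.5, n_bins = 20)
  expect_identical(snapshot_rdf(snap, c(0, 1), grid)$g,
                   snapshot_rdf(snap, c(1, 0), grid)$g)
  expect_error(snapshot_rdf(snap, c(0, 0), radial_grid(r_max = 4)),
               "half")
  expect_error(snapshot_rdf(snap, c(0, 5), grid), "not present")
})

test_that("ideal-gas configurations give g = 1 within Poisson noise", {
  grid <- radial_grid(r_max = 4.5, n_bins = 30)
  curves <- lapply(1:50, function(s)
    snapshot_rdf(random_snapshot(1000, c(10, 10, 10), seed = 100 + s),
                 c(0, 0), grid))
  g <- average_rdf(curves)
  expect_identical(attr(g, "n_frames_averaged"), 50L)
  v_shell <- 4 / 3 * pi * diff(grid$edges^3)
  lambda <- 1000 * 999 * v_shell / 1000 * 50   # expected ordered-pair counts
  se <- sqrt(2 / lambda)
  expect_true(all(abs(g$g - 1) <= 3 * se))
})

test_that("average_rdf is an identity on one curve and linear in its inputs", {
  snap <- random_snapshot(50, c(6, 6, 6), seed = 1)
  grid <- radial_grid(r_max = 2.5, n_bins = 20)
  g <- snapshot_rdf(snap, c(0, 0), grid)
  expect_equal(average_rdf(list(g))$g, g$g)

  mirror <- g
  mirror$g <- 2 - g$g
  expect_equal(average_rdf(list(g, mirror))$g, rep(1, 20))

  other <- snapshot_rdf(snap, c(0, 0), radial_grid(r_max = 2, n_bins = 20))
  expect_error(average_rdf(list(g, other)), "share")
})

test_that("frame-wise averaging equals one-pass accumulation over all distances", {
  traj <- small_trajectory()
  grid <- radial_grid(r_max = 2, n_bins = 40)
  by_frames <- average_rdf(lapply(traj$snapshots, snapshot_rdf,
                                  pair = c(0, 0), grid = grid))
  # independent route: accumulate raw counts over every frame, normalize once
  total <- Reduce(`+`, lapply(traj$snapshots, function(s)
    pointrdf:::pair_histogram_cpp(s$positions, s$species, s$box, 0L, 0L,
                       grid$r_max, grid$n_bins)))
  n <- nrow(traj$snapshots[[1]]$positions)
  v_shell <- 4 / 3 * pi * diff(grid$edges^3)
  ideal <- n * (n - 1) * v_shell / prod(traj$snapshots[[1]]$box)
  expect_equal(by_frames$g, total / (ideal * length(traj$snapshots)),
               tolerance = 1e-12)
})

test_that("error metrics match closed forms and independent re-implementations", {
  grid <- radial_grid(r_max = 2.5, n_bins = 50)
  snap <- random_snapshot(200, c(6, 6, 6), seed = 31)
  a <- snapshot_rdf(snap, c(0, 0), grid)
  b <- snapshot_rdf(random_snapshot(200, c(6, 6, 6), seed = 32),
                    c(0, 0), grid)

  expect_identical(rdf_error(a, a), 0)
  expect_equal(r2_score(a, a), 1)
  expect_identical(relative_error(a, a), 0)

  shifted <- a; shifted$g <- a$g + 0.1
  expect_equal(rdf_error(shifted, a), 0.01, tolerance = 1e-12)
  scaled <- a; scaled$g <- 1.01 * a$g
  expect_equal(relative_error(scaled, a), 0.01, tolerance = 1e-12)

  # independent textbook formulas
  expect_equal(rdf_error(b, a), sum((b$g - a$g)^2) / length(a$g),
               tolerance = 1e-12)
  expect_equal(r2_score(b, a),
               1 - sum((b$g - a$g)^2) / sum((a$g - mean(a$g))^2),
               tolerance = 1e-12)
  expect_equal(relative_error(b, a), sum(abs(b$g - a$g)) / sum(abs(a$g)),
               tolerance = 1e-12)

  # predicting the reference mean scores exactly zero
  flat <- a; flat$g <- rep(mean(a$g), length(a$g))
  expect_equal(r2_score(flat, a), 0, tolerance = 1e-12)

  const <- a; const$g <- rep(1, length(a$g))
  expect_error(r2_score(a, const), "constant")
  expect_error(rdf_error(a, snapshot_rdf(snap, c(0, 0),
                                         radial_grid(2.5, 25))),
               "grid")
})

test_that("the liquid RDF has an empty core below 0.8 sigma", {
  g <- trajectory_rdf(liquid_trajectory())[["0-0"]]
  expect_identical(max(g$g[g$r < 0.8]), 0)
})

test_that("single-snapshot baseline errors behave like sampling noise", {
  traj <- small_trajectory()
  grid <- radial_grid(r_max = 2, n_bins = 30)
  one <- trajectory(traj$condition, traj$snapshots[1])
  errs1 <- baseline_snapshot_errors(one, grid)
  expect_equal(errs1$error, 0)

  errs <- baseline_snapshot_errors(traj, grid)
  expect_true(all(errs$error > 0))
  expect_identical(nrow(errs), length(traj$snapshots))
  s <- summary(errs)
  expect_true(all(s$sd_error >= 0))

  # block-averaging 10 frames per "snapshot" must cut the mean error
  ref <- trajectory_rdf(traj, grid)[["0-0"]]
  blocks <- split(seq_along(traj$snapshots),
                  (seq_along(traj$snapshots) - 1) %/% 10)
  block_err <- vapply(blocks, function(ix) {
    rdf_error(average_rdf(lapply(traj$snapshots[ix], snapshot_rdf,
                                 pair = c(0, 0), grid = grid)), ref)
  }, numeric(1))
  expect_lt(mean(block_err), mean(errs$error))
})

test_that("rdf sets tidy, plot and export cleanly", {
  traj <- small_binary_trajectory()
  rs <- trajectory_rdf(traj, radial_grid(r_max = 2, n_bins = 20))
  expect_named(rs, c("0-0", "0-1", "1-1"))
  td <- tidy(rs)
  expect_identical(nrow(td), 60L)
  expect_s3_class(autoplot(rs), "ggplot")
  path <- tempfile(fileext = ".csv")
  write_rdf_csv(rs, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(unlist(meta$pair_order), c("0-0", "0-1", "1-1"))
})
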