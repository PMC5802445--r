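test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(n_neurons = 1), "n_neurons")
  expect_error(sim_params(n_frames = 1), "n_frames")
  expect_error(sim_params(offspring_mean = -0.1), "offspring_mean")
  expect_error(sim_params(persist_prob = 1), "persist_prob")
  expect_error(sim_params(drive_rate = -1), "drive_rate")
  expect_error(sim_params(lambda_amplitude = list(dist = "gamma", mean = 1)))
})

test_that("no drive means no activity; no propagation means one-frame clusters", {
  r0 <- simulate_branching_raster(sim_params(n_neurons = 20, n_frames = 200,
                                             drive_rate = 0, seed = 1))
  expect_equal(nrow(r0$events), 0L)
  expect_equal(nrow(extract_clusters(r0)$clusters), 0L)

  # without offspring or persistence, all activity is seed activations:
  # no neuron is ever active on consecutive frames, and population clusters
  # longer than one frame can only arise from independent seeds colliding
  # on adjacent frames
  r1 <- simulate_branching_raster(sim_params(n_neurons = 20, n_frames = 2000,
                                             offspring_mean = 0, persist_prob = 0,
                                             drive_rate = 0.5, seed = 2))
  cs <- extract_clusters(r1)
  expect_gt(nrow(cs$clusters), 0L)
  expect_equal(sum(cs$clusters$size_count), nrow(r1$events))
  # at low drive adjacent-frame collisions vanish and durations collapse to 1
  r2 <- simulate_branching_raster(sim_params(n_neurons = 20, n_frames = 2000,
                                             offspring_mean = 0, persist_prob = 0,
                                             drive_rate = 0.02, seed = 2))
  expect_true(mean(extract_clusters(r2)$clusters$duration) < 1.2)
})

test_that("identical seeds give bit-identical rasters, ROI maps, and cohorts", {
  p <- sal_params(n_neurons = 30, n_frames = 500, seed = 7)
  expect_identical(simulate_branching_raster(p), simulate_branching_raster(p))
  expect_identical(generate_roi_map(15, seed = 3), generate_roi_map(15, seed = 3))
  expect_identical(make_cohort(movies_per_group = 2, seed = 5),
                   make_cohort(movies_per_group = 2, seed = 5))
})

test_that("ROI maps stay inside the imaging field", {
  roi <- generate_roi_map(80, field_size = 557, seed = 11)
  expect_equal(nrow(roi), 80L)
  expect_true(all(roi$x_um >= 0 & roi$x_um <= 557))
  expect_true(all(roi$y_um >= 0 & roi$y_um <= 557))
  expect_equal(nrow(generate_roi_map(1, seed = 1)), 1L)
})

test_that("pooled temporal branching matches the Galton-Watson total-progeny law", {
  # closed form: descendants per seed average m/(1-m); checked first against
  # a brute-force tree ensemble, then against the raster pipeline
  m <- 0.4
  trees <- gw_trees(20000, m, seed = 99)
  expect_equal(mean(trees[, "desc"]), m / (1 - m), tolerance = 0.03)

  p <- sim_params(n_neurons = 150, n_frames = 6e5, offspring_mean = m,
                  persist_prob = 0, drive_rate = 0.003, seed = 301)
  sig <- temporal_branching(extract_clusters(simulate_branching_raster(p)))$sigma
  expect_equal(sig, m / (1 - m), tolerance = 0.05 / (m / (1 - m)))
})

test_that("higher persistence yields more multi-frame bursts in the cohort", {
  co <- make_cohort(sal_params(n_frames = 3000), pcp_params(n_frames = 3000),
                    movies_per_group = 3, seed = 13)
  grp <- vapply(co, `[[`, character(1), "group")
  fmf <- vapply(co, function(mv)
    burst_length_stats(extract_bursts(mv$raster))$fraction_multiframe, numeric(1))
  expect_gt(mean(fmf[grp == "PCP"]), mean(fmf[grp == "SAL"]))
  expect_length(co, 6L)
})

test_that("exponential amplitude mode draws positive per-activation lambdas", {
  p <- sim_params(n_neurons = 30, n_frames = 2000, seed = 21,
                  lambda_amplitude = list(dist = "exponential", mean = 2))
  r <- simulate_branching_raster(p)
  expect_true(all(r$events$lam > 0))
  # per-event lambda averages the configured per-activation mean
  expect_equal(mean(r$events$lam), 2, tolerance = 0.25)
})

test_that("forward model produces the AR(1) kernel exactly", {
  lam <- matrix(0, 1, 40)
  lam[1, 10] <- 1
  r <- toy_raster(lam)
  tr <- spikes_to_fluorescence(r, decay_tau = 1, noise_sd = 0)
  g <- exp(-1 / 15)
  expect_equal(tr$values[1, 10:40], g^(0:30), tolerance = 1e-12)
  expect_true(all(tr$values[1, 1:9] == 0))
  expect_error(spikes_to_fluorescence(r, decay_tau = 0), "decay_tau")
})
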