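test_that("cluster extraction follows the silent-frame delimitation rule", {
  lam <- matrix(0, 3, 10)
  lam[1, 3] <- 1; lam[2, 4] <- 0.5; lam[1, 5] <- 2   # frames 3-5 active
  lam[3, 8] <- 1                                     # frame 8 active
  cs <- extract_clusters(toy_raster(lam))
  expect_equal(nrow(cs$clusters), 2L)
  expect_equal(cs$clusters$duration, c(3L, 1L))
  expect_equal(cs$clusters$start_frame, c(3L, 8L))
  expect_equal(cs$clusters$size_count, c(3L, 1L))
  expect_equal(cs$clusters$size_lambda, c(3.5, 1))
  expect_false(any(cs$clusters$edge_flag))

  # empty raster -> empty set
  expect_equal(nrow(extract_clusters(toy_raster(matrix(0, 3, 10)))$clusters), 0L)

  # every frame active -> a single edge-touching movie-spanning cluster
  cs2 <- extract_clusters(toy_raster(matrix(1, 2, 10)))
  expect_equal(nrow(cs2$clusters), 1L)
  expect_equal(cs2$clusters$duration, 10L)
  expect_true(cs2$clusters$edge_flag)
})

test_that("clustering conserves activity and counts silent-to-active transitions", {
  r <- simulate_branching_raster(pcp_params(n_neurons = 40, n_frames = 2000, seed = 12))
  cs <- extract_clusters(r)
  expect_equal(sum(cs$clusters$size_lambda), sum(r$events$lam))
  expect_equal(sum(cs$clusters$size_count), nrow(r$events))
  act <- colSums(activity_mask(r)) > 0
  transitions <- sum(diff(c(FALSE, act)) == 1)
  expect_equal(nrow(cs$clusters), transitions)
  expect_true(all(cs$clusters$size_count >= cs$clusters$duration))
})

test_that("size distributions are normalized densities on geometric bins", {
  lam <- matrix(0, 2, 12)
  lam[1, c(2, 4, 6, 8, 10)] <- 1                # five isolated size-1 clusters
  d <- size_distribution(extract_clusters(toy_raster(lam)))
  expect_equal(sum(d$density * diff(d$edges)), 1)
  expect_equal(d$counts[1], d$n_clusters)       # all mass in the first bin
  expect_equal(d$centers[1], 1)

  sizes <- sample_power_law(20000, 1.5, 500, seed = 31)
  d2 <- size_distribution(sizes)
  expect_equal(sum(d2$density * diff(d2$edges)), 1)
  expect_error(size_distribution(extract_clusters(toy_raster(matrix(0, 2, 5)))),
               "no clusters")
})

test_that("log-binned least squares recovers known exponents within 0.05", {
  for (tau in c(1.2, 1.5, 2.0)) {
    sizes <- sample_power_law(1e5, tau, 1000, seed = round(100 * tau))
    fit <- fit_power_law(size_distribution(sizes), cutoff = 1000)
    expect_equal(fit$exponent, tau, tolerance = 0.05 / tau)
    # the MLE cross-check mode agrees
    fit_m <- fit_power_law(size_distribution(sizes), cutoff = 1000, method = "mle")
    expect_equal(fit_m$exponent, tau, tolerance = 0.05 / tau)
  }
})

test_that("KS distance separates power-law from exponential size data", {
  sizes_pl <- sample_power_law(20000, 1.5, 300, seed = 7)
  set.seed(8)
  sizes_ex <- pmax(1, round(rexp(20000, rate = 1 / 4)))
  sizes_ex <- sizes_ex[sizes_ex <= 300]
  f_pl <- fit_power_law(size_distribution(sizes_pl), cutoff = 300)
  f_ex <- fit_power_law(size_distribution(sizes_ex), cutoff = 300)
  expect_lt(f_pl$ks_distance, 0.1)
  expect_gt(f_ex$ks_distance, f_pl$ks_distance)
  expect_true(f_pl$ks_distance >= 0 && f_pl$ks_distance <= 1)
})

test_that("power-law fitting needs at least three occupied bins", {
  expect_error(fit_power_law(size_distribution(rep(1L, 50)), cutoff = 100),
               "occupied bins")
})

test_that("size-duration scaling recovers exact and degenerate cases", {
  # s = T^2 exactly -> chi = 2 exactly
  tab <- data.frame(duration = rep(1:6, each = 12))
  tab$size <- tab$duration^2
  sc <- size_duration_scaling(tab, min_per_duration = 10)
  expect_equal(sc$chi, 2, tolerance = 1e-12)

  # all clusters duration 1 -> fit error
  tab1 <- data.frame(duration = rep(1L, 100), size = rep(2, 100))
  expect_error(size_duration_scaling(tab1), "durations")
})

test_that("averaging per-movie distributions preserves normalization and pools sizes", {
  rs <- lapply(1:3, function(s)
    simulate_branching_raster(sal_params(n_neurons = 30, n_frames = 1500, seed = s)))
  ds <- lapply(rs, function(r) size_distribution(extract_clusters(r)))
  avg <- average_size_distributions(ds)
  expect_equal(sum(avg$density * diff(avg$edges)), 1, tolerance = 1e-9)
  expect_equal(avg$n_clusters, sum(vapply(ds, `[[`, numeric(1), "n_clusters")))
  expect_equal(sum(avg$counts), avg$n_clusters)
})
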