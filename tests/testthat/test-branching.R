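test_that("temporal branching matches hand-computed cluster ratios", {
  # one cluster with per-frame lambda sums 2, 1, 1 -> (1+1)/2 = 1
  lam <- matrix(0, 3, 7)
  lam[1, 2] <- 1; lam[2, 2] <- 1    # frame 2: total 2
  lam[1, 3] <- 1                    # frame 3: total 1
  lam[3, 4] <- 1                    # frame 4: total 1
  cs <- extract_clusters(toy_raster(lam))
  expect_equal(temporal_branching(cs, "pooled")$sigma, 1)
  expect_equal(temporal_branching(cs, "per_cluster_mean")$sigma, 1)

  # adding a single-frame cluster leaves the pooled ratio 2/3 and halves the mean
  lam[2, 6] <- 1
  cs2 <- extract_clusters(toy_raster(lam))
  expect_equal(temporal_branching(cs2, "pooled")$sigma, 2 / 3)
  expect_equal(temporal_branching(cs2, "per_cluster_mean")$sigma, 0.5)
})

test_that("spatial branching decomposes into new and repeat exactly", {
  # frames: {A, B} then {A, C}: total 2/2 = 1, new (C) 0.5, repeat (A) 0.5
  lam <- matrix(0, 3, 5)
  lam[1, 2] <- 1; lam[2, 2] <- 1
  lam[1, 3] <- 1; lam[3, 3] <- 1
  bs <- spatial_branching(extract_clusters(toy_raster(lam)))
  expect_equal(bs$sigma_total, 1)
  expect_equal(bs$sigma_new, 0.5)
  expect_equal(bs$sigma_repeat, 0.5)

  # duration-1 clusters only: all components zero in per-cluster mean
  lam1 <- matrix(0, 3, 9); lam1[1, c(2, 5)] <- 1; lam1[2, 7] <- 1
  bs1 <- spatial_branching(extract_clusters(toy_raster(lam1)), "per_cluster_mean")
  expect_equal(bs1$sigma_total, 0)
  expect_equal(bs1$sigma_new + bs1$sigma_repeat, 0)
})

test_that("new + repeat equals total on random rasters in both modes", {
  for (k in 1:60) {
    r <- random_raster(10, 60, density = 0.08, seed = 700 + k)
    if (nrow(r$events) == 0) next
    cs <- extract_clusters(r)
    if (!nrow(cs$clusters)) next
    for (mode in c("pooled", "per_cluster_mean")) {
      bs <- spatial_branching(cs, mode)
      expect_identical(bs$sigma_new + bs$sigma_repeat, bs$sigma_total)
    }
  }
})

test_that("burst extraction finds maximal consecutive runs", {
  lam <- matrix(0, 2, 12)
  lam[1, c(1, 2, 3, 7)] <- 1
  bs <- extract_bursts(toy_raster(lam))
  expect_equal(bs$bursts$length, c(3L, 1L))
  expect_equal(bs$bursts$start_frame, c(1L, 7L))
  expect_equal(unique(bs$bursts$neuron), 1L)        # silent neuron: no bursts
  expect_equal(sum(bs$bursts$length), nrow(toy_raster(lam)$events))
})

test_that("burst-length statistics match closed forms", {
  lam <- matrix(0, 2, 30); lam[1, c(2, 6, 10)] <- 1
  st <- burst_length_stats(extract_bursts(toy_raster(lam)))
  expect_equal(st$fraction_multiframe, 0)
  expect_true(is.na(st$beta))                       # < 3 occupied lengths

  # geometric lengths: fraction of multi-frame bursts is the continuation prob
  p_cont <- 0.35
  set.seed(40)
  lens <- rgeom(20000, prob = 1 - p_cont) + 1L
  bset <- structure(list(bursts = data.frame(neuron = 1L, start_frame = 1L,
                                             length = lens),
                         n_neurons = 1L, n_frames = 1L), class = "burst_set")
  st2 <- burst_length_stats(bset)
  expect_equal(st2$fraction_multiframe, p_cont, tolerance = 0.03)
  # geometric P(L) ~ p^L: log-log slope exists and is positive
  expect_false(is.na(st2$beta))
  expect_gt(st2$beta, 0)
})

test_that("higher persistence flattens the burst-length distribution", {
  beta_at <- function(pp, seed) {
    r <- simulate_branching_raster(sim_params(persist_prob = pp, seed = seed))
    burst_length_stats(extract_bursts(r))$beta
  }
  expect_gt(beta_at(0.05, 51), beta_at(0.3, 52))
})

test_that("burst removal truncates the requested fraction and nothing else", {
  r <- simulate_branching_raster(pcp_params(n_neurons = 40, n_frames = 1500, seed = 61))
  expect_identical(remove_persistent_bursts(r, 0, seed = 1), r)

  r_all <- remove_persistent_bursts(r, 1, seed = 1)
  st <- burst_length_stats(extract_bursts(r_all))
  expect_equal(st$fraction_multiframe, 0)

  b0 <- extract_bursts(r)$bursts
  m0 <- sum(b0$length > 1L)
  r3 <- remove_persistent_bursts(r, 1 / 3, seed = 2)
  b3 <- extract_bursts(r3)$bursts
  # exactly round(m0/3) bursts truncated; first frames all preserved
  expect_equal(m0 - sum(b3$length > 1L), floor(m0 / 3 + 0.5))
  expect_true(all(b0$start_frame %in% b3$start_frame))
  expect_lt(nrow(r3$events), nrow(r$events))        # never creates activity
  expect_identical(remove_persistent_bursts(r, 1 / 3, seed = 2), r3)

  # nearest-integer, ties-up rule: 9 multi-frame bursts at 1/3 -> exactly 3
  lam <- matrix(0, 9, 40)
  for (i in 1:9) lam[i, (4 * i):(4 * i + 1)] <- 1
  rt <- toy_raster(lam)
  rr <- remove_persistent_bursts(rt, 1 / 3, seed = 3)
  expect_equal(sum(extract_bursts(rr)$bursts$length > 1L), 6L)
  expect_equal(nrow(rt$events) - nrow(rr$events), 3L)
})

test_that("persistence sweep raises repeat branching but not new branching", {
  # low drive keeps clusters well separated so persistence-driven merging
  # does not confound the new-activation component
  reps <- vapply(c(0, 0.15, 0.3), function(pp) {
    r <- simulate_branching_raster(sim_params(n_neurons = 60, n_frames = 8000,
                                              drive_rate = 0.1,
                                              persist_prob = pp, seed = 71))
    bs <- spatial_branching(extract_clusters(r))
    c(bs$sigma_new, bs$sigma_repeat)
  }, numeric(2))
  expect_true(all(diff(reps[2, ]) > 0))          # repeat strictly increases
  expect_lt(max(reps[1, ]) - min(reps[1, ]), 0.15)  # new stays flat-ish
})
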