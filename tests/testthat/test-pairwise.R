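test_that("zero-lag correlation handles perfect, anti-phase, and degenerate pairs", {
  lam <- rbind(c(1, 0, 2, 0, 1, 0),
               c(1, 0, 2, 0, 1, 0),
               c(0, 1, 0, 1, 0, 1),
               rep(0.5, 6))
  pm <- zero_lag_correlation(toy_raster(lam))
  expect_equal(pm$values[1, 2], 1)
  expect_equal(sign(pm$values[1, 3]), -1)
  expect_equal(pm$values[3, 3], NA_real_)      # diagonal undefined
  expect_true(all(is.na(pm$values[4, -4])))    # zero variance -> undefined
  # x = [1,0,1,0] vs y = [0,1,0,1] is exactly -1
  pm2 <- zero_lag_correlation(toy_raster(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))))
  expect_equal(pm2$values[1, 2], -1)
  expect_error(zero_lag_correlation(toy_raster(matrix(1, 1, 4))), "2 neurons")
})

test_that("pair matrices are symmetric and Q depends only on the mask", {
  r <- simulate_branching_raster(sal_params(n_neurons = 25, n_frames = 800, seed = 5))
  pr <- zero_lag_correlation(r)
  expect_equal(pr$values, t(pr$values))
  q1 <- event_synchronization(r)
  expect_equal(q1$values, t(q1$values))
  # rescaling lambda amplitudes leaves Q untouched
  r2 <- r; r2$events$lam <- r2$events$lam * 7.3
  expect_equal(event_synchronization(r2)$values, q1$values)
  expect_true(all(pair_values(q1) >= 0 & pair_values(q1) <= 1))
})

test_that("event synchronization is 1 for identical trains and 0 for distant ones", {
  lam <- matrix(0, 3, 80)
  lam[1, c(10, 25, 40, 60)] <- 1
  lam[2, c(10, 25, 40, 60)] <- 1
  lam[3, c(5, 50, 75)] <- 1
  q <- event_synchronization(toy_raster(lam))
  expect_equal(q$values[1, 2], 1)
  expect_equal(q$values[1, 3], 0)
})

test_that("shuffle correction zeroes independent trains and keeps true coupling", {
  set.seed(42)
  lam <- matrix(rbinom(30 * 1200, 1, 0.05), 30, 1200)  # independent Poisson-like
  r <- toy_raster(lam)
  rc <- shuffle_correct(r, "correlation", n_shuffles = 10, seed = 1)
  v <- pair_values(rc)
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))

  qc <- shuffle_correct(r, "synchronization", n_shuffles = 5, seed = 2)
  vq <- pair_values(qc)
  expect_lt(abs(mean(vq)), 4 * sd(vq) / sqrt(length(vq)))

  # duplicated neuron: correction keeps the genuine dependence
  lam2 <- lam; lam2[2, ] <- lam2[1, ]
  rc2 <- shuffle_correct(toy_raster(lam2), "correlation", n_shuffles = 10, seed = 3)
  expect_gt(rc2$values[1, 2], 0.5)

  # more shuffles estimate the same correction with less spread
  est <- function(n_sh, seeds) vapply(seeds, function(s)
    shuffle_correct(toy_raster(lam[1:8, 1:400]), "correlation",
                    n_shuffles = n_sh, seed = s)$values[1, 2], numeric(1))
  e1 <- est(1, 1:12); e20 <- est(20, 1:12)
  expect_equal(mean(e1), mean(e20), tolerance = 0.1)
  expect_lt(sd(e20), sd(e1))
})

test_that("metric distributions normalize and distance bins behave", {
  r <- simulate_branching_raster(sal_params(n_neurons = 20, n_frames = 600, seed = 9))
  pm <- zero_lag_correlation(r)
  md <- metric_distribution(pm)
  expect_equal(sum(md$prob), 1)
  expect_equal(md$cdf[length(md$cdf)], 1)
  expect_length(md$prob, length(md$breaks) - 1L)

  # constant metric: every occupied distance bin has that mean
  vals <- matrix(0.25, 20, 20)
  pmc <- structure(list(values = vals, metric = "correlation", n_neurons = 20),
                   class = "pair_matrix")
  diag(pmc$values) <- NA
  roi <- generate_roi_map(20, seed = 14)
  db <- distance_binned_means(pmc, roi)
  occ <- db$n_pairs > 0
  expect_true(all(abs(db$mean[occ] - 0.25) < 1e-12))
  expect_equal(sum(db$n_pairs), 20 * 19 / 2)

  # all neurons at one point: a single occupied bin
  roi0 <- roi; roi0$x_um <- 10; roi0$y_um <- 10
  db0 <- distance_binned_means(pmc, roi0)
  expect_equal(sum(db0$n_pairs > 0), 1L)
  expect_error(metric_distribution(pmc, bin_edges = c(5, 6)), "inside the bin range")
})

test_that("coupling without spatial structure shows no distance trend", {
  r <- simulate_branching_raster(sal_params(n_neurons = 40, n_frames = 4000, seed = 16))
  roi <- generate_roi_map(40, seed = 17)
  pm <- zero_lag_correlation(r)
  dm <- as.matrix(dist(cbind(roi$x_um, roi$y_um)))
  ut <- upper.tri(dm)
  fit <- lm(pm$values[ut] ~ dm[ut])
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)   # slope CI straddles zero
})
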