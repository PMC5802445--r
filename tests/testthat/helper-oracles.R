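# Independent oracles used to freeze expected values. These never call the
# package's generator or estimators.

# Brute-force Galton-Watson trees with Poisson(m) offspring: per tree, the
# number of descendants of the seed and the generation count (duration).
gw_trees <- function(n_trees, m, seed, max_size = 1e5) {
  set.seed(seed)
  t(vapply(seq_len(n_trees), function(i) {
    a <- 1L; desc <- 0L; dur <- 1L
    while (a > 0L && desc < max_size) {
      a <- sum(rpois(a, m))
      if (a > 0L) {
        desc <- desc + a
        dur <- dur + 1L
      }
    }
    c(desc = desc, dur = dur)
  }, c(desc = 0L, dur = 0L)))
}

# Inverse-CDF sampler for the discrete power law p(s) ~ s^-tau on 1..smax.
sample_power_law <- function(n, tau, smax, seed) {
  set.seed(seed)
  s <- seq_len(smax)
  sample(s, n, replace = TRUE, prob = s^(-tau))
}

# Small raster from an explicit lambda matrix.
toy_raster <- function(lam, frame_rate = 15) {
  spike_raster(lam, frame_rate = frame_rate)
}

# Random sparse raster for property tests.
random_raster <- function(n_neurons, n_frames, density, seed) {
  set.seed(seed)
  lam <- matrix(0, n_neurons, n_frames)
  k <- rbinom(1, n_neurons * n_frames, density)
  if (k > 0) lam[sample(n_neurons * n_frames, k)] <- runif(k, 0.5, 2)
  spike_raster(lam, frame_rate = 15)
}

# Circular inter-event-interval multiset of a sorted event-frame vector.
circular_isi <- function(frames, n_frames) {
  if (length(frames) < 1) return(integer(0))
  sort(diff(c(frames, frames[1] + n_frames)))
}
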