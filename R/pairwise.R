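## Pairwise synchrony: zero-lag correlation of lambda time series and
## rate-independent event synchronization, both with shuffle correction.

new_pair_matrix <- function(values, metric) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  diag(values) <- NA_real_
  structure(list(values = values, metric = metric,
                 n_neurons = nrow(values)), class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  v <- pair_values(x)
  cat(sprintf("pair_matrix [%s]: %d neurons, %d defined pairs, mean %.4f\n",
              x$metric, x$n_neurons, length(v), mean(v)))
  invisible(x)
}

#' Defined upper-triangle values of a pair matrix
#'
#' @param x a `pair_matrix`.
#' @return numeric vector of the defined (non-`NA`) pairwise values.
#' @export
pair_values <- function(x) {
  stopifnot(inherits(x, "pair_matrix"))
  v <- x$values[upper.tri(x$values)]
  v[!is.na(v)]
}

#' Zero-lag pairwise cross-correlation
#'
#' Pearson correlation of the lambda time series of every neuron pair at lag
#' zero. Pairs involving a zero-variance series are undefined (`NA`) and are
#' excluded from downstream distributions.
#'
#' @param raster a [spike_raster] with >= 2 neurons and >= 2 frames.
#' @return A `pair_matrix` with metric `"correlation"`.
#' @export
zero_lag_correlation <- function(raster) {
  assert_raster(raster)
  if (raster$n_neurons < 2L) stop("need >= 2 neurons")
  if (raster$n_frames < 2L) stop("need >= 2 frames")
  v <- suppressWarnings(stats::cor(t(lam_matrix(raster))))
  new_pair_matrix(v, "correlation")
}

#' Event synchronization
#'
#' Rate-normalized count of near-coincident event pairs:
#' `Q(i,j) = (c(i|j) + c(j|i)) / sqrt(m_i * m_j)`, where `c(i|j)` counts
#' events of neuron i that fall within an adaptive window tau after an event
#' of neuron j. For an event pair, tau is half the minimum of the four
#' neighbouring inter-event intervals, capped at `tau_cap` frames; events in
#' the same frame count 1/2 towards each direction. Pairs where either
#' neuron has no events are undefined.
#'
#' @param raster a [spike_raster].
#' @param tau_cap maximum coincidence window in frames (default 2; at 15 Hz
#'   longer windows would conflate separate transients).
#' @return A `pair_matrix` with metric `"synchronization"`, values in
#'   `[0, 1]`.
#' @export
event_synchronization <- function(raster, tau_cap = 2) {
  assert_raster(raster)
  n <- raster$n_neurons
  tr <- event_frames_by_roi(raster)
  ## per-event minimum of the two adjacent ISIs (Inf at single events/ends)
  loc <- lapply(tr, function(f) {
    m <- length(f)
    if (m == 0L) return(numeric(0))
    if (m == 1L) return(Inf)
    isi <- diff(f)
    pmin(c(Inf, isi), c(isi, Inf))
  })
  q <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    ti <- tr[[i]]; li <- loc[[i]]; mi <- length(ti)
    if (mi == 0L) next
    for (j in seq.int(i + 1L, n)) {
      tj <- tr[[j]]; mj <- length(tj)
      if (mj == 0L) next
      lj <- loc[[j]]
      ## candidate partners of each i-event within +/- tau_cap frames
      lo <- findInterval(ti - tau_cap - 0.5, tj)
      hi <- findInterval(ti + tau_cap + 0.5, tj)
      cij <- 0; cji <- 0
      for (l in seq_len(mi)) {
        if (hi[l] <= lo[l]) next
        ks <- seq.int(lo[l] + 1L, hi[l])
        d <- ti[l] - tj[ks]
        tau <- pmin(tau_cap, 0.5 * pmin(li[l], lj[ks]))
        cij <- cij + sum(d > 0 & d <= tau) + 0.5 * sum(d == 0)
        cji <- cji + sum(d < 0 & -d <= tau) + 0.5 * sum(d == 0)
      }
      q[i, j] <- q[j, i] <- (cij + cji) / sqrt(mi * as.numeric(mj))
    }
  }
  new_pair_matrix(q, "synchronization")
}

#' Shuffle-corrected pairwise metric
#'
#' Computes the observed pair matrix and subtracts, per pair, its mean over
#' `n_shuffles` independently ISI-shuffled surrogate rasters
#' ([shuffle_raster]). With `method = "zscore"` the difference is divided by
#' the per-pair SD across shuffles instead.
#'
#' @param raster a [spike_raster].
#' @param metric `"correlation"` or `"synchronization"`.
#' @param n_shuffles number of surrogate rasters (>= 1, default 20).
#' @param seed RNG seed for the surrogates.
#' @param method `"subtract"` (default) or `"zscore"`.
#' @return A `pair_matrix` with metric tagged `"<metric>_corrected"`.
#' @export
shuffle_correct <- function(raster, metric = c("correlation", "synchronization"),
                            n_shuffles = 20, seed = NULL,
                            method = c("subtract", "zscore")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  fun <- switch(metric, correlation = zero_lag_correlation,
                synchronization = event_synchronization)
  obs <- fun(raster)
  with_seed(seed, {
    acc <- 0; acc2 <- 0
    for (k in seq_len(n_shuffles)) {
      s <- fun(shuffle_raster(raster))$values
      acc <- acc + s
      acc2 <- acc2 + s^2
    }
    mu <- acc / n_shuffles
    corrected <- if (method == "subtract") obs$values - mu else {
      sdv <- sqrt(pmax(acc2 / n_shuffles - mu^2, 0)) * sqrt(n_shuffles / max(n_shuffles - 1L, 1L))
      (obs$values - mu) / sdv
    }
    out <- new_pair_matrix(corrected, paste0(metric, "_corrected"))
    attr(out, "n_shuffles") <- n_shuffles
    out
  })
}

#' Pairwise metric vs inter-neuron distance
#'
#' Bins pairwise Euclidean centroid distances and reports the mean and SEM
#' of the metric per bin. Empty bins yield `NA` entries, not errors.
#'
#' @param pm a `pair_matrix`.
#' @param rois a `roi_map` covering the same neurons.
#' @param bin_edges distance bin edges in micrometres.
#' @return data.frame with `bin_lo`, `bin_hi`, `n_pairs`, `mean`, `sem`.
#' @export
distance_binned_means <- function(pm, rois, bin_edges = seq(0, 800, by = 100)) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (nrow(rois) != pm$n_neurons)
    stop("roi map and pair matrix cover different neuron counts")
  dm <- as.matrix(stats::dist(cbind(rois$x_um, rois$y_um)))
  ut <- upper.tri(dm)
  d <- dm[ut]; v <- pm$values[ut]
  ok <- !is.na(v)
  b <- findInterval(d[ok], bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  res <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L],
                    n_pairs = 0L, mean = NA_real_, sem = NA_real_)
  for (k in seq_len(nb)) {
    vk <- v[ok][b == k]
    res$n_pairs[k] <- length(vk)
    if (length(vk)) {
      res$mean[k] <- mean(vk)
      res$sem[k] <- if (length(vk) > 1L) stats::sd(vk) / sqrt(length(vk)) else NA_real_
    }
  }
  res
}

#' Histogram and CDF of a pairwise metric
#'
#' Normalized histogram of the defined pairwise values over the supplied bin
#' edges, with its cumulative distribution. Values outside the bin range are
#' dropped. Per-movie distributions are averaged across movies at the
#' pipeline level, mirroring the per-movie-then-average convention.
#'
#' @param pm a `pair_matrix` with at least one defined pair.
#' @param bin_edges histogram bin edges (default width 0.01 on -0.2..0.6).
#' @return list of class `metric_distribution`: `breaks`, `mids`, `prob`
#'   (sums to 1), `cdf` (ends at 1), `n_pairs`.
#' @export
metric_distribution <- function(pm, bin_edges = seq(-0.2, 0.6, by = 0.01)) {
  stopifnot(inherits(pm, "pair_matrix"))
  v <- pair_values(pm)
  if (!length(v)) stop("all pairs undefined; no distribution")
  v <- v[v >= bin_edges[1L] & v <= bin_edges[length(bin_edges)]]
  if (!length(v)) stop("no pairwise values inside the bin range")
  h <- graphics::hist(v, breaks = bin_edges, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  structure(list(breaks = bin_edges, mids = h$mids, prob = prob,
                 cdf = cumsum(prob), n_pairs = length(v)),
            class = "metric_distribution")
}
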