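## From fluorescence to thresholded spike-rate rasters, plus the
## ISI-preserving surrogate used for shuffle correction and shuffle controls.

#' Deconvolution parameters
#'
#' @param decay_tau indicator decay time constant in seconds; the AR(1)
#'   coefficient is `gamma = exp(-1 / (frame_rate * decay_tau))`.
#' @param threshold_k threshold in multiples of the estimated per-neuron
#'   noise SD; deconvolved rates below `threshold_k * sd` are zeroed. The
#'   default 5 keeps the expected number of noise-induced events per movie
#'   (hundreds of thousands of ROI-frames) in the tens: the noise on the
#'   deconvolved rate is `sqrt(1 + gamma^2)` times the trace noise SD that
#'   the estimator reports, so 5 corresponds to an effective ~3.7 sigma test.
#' @param noise_estimator only `"mad_diff"` is implemented: 1.4826 x median
#'   absolute deviation of the first difference of the trace, divided by
#'   sqrt(2). Robust to sparse transients.
#' @return list of class `deconv_params`.
#' @export
deconv_params <- function(decay_tau = 1, threshold_k = 5,
                          noise_estimator = "mad_diff") {
  if (decay_tau <= 0) stop("decay_tau must be > 0")
  if (threshold_k < 0) stop("threshold_k must be >= 0")
  noise_estimator <- match.arg(noise_estimator, "mad_diff")
  structure(list(decay_tau = decay_tau, threshold_k = threshold_k,
                 noise_estimator = noise_estimator), class = "deconv_params")
}

#' Compute dF/F from raw fluorescence
#'
#' `dF/F = (F - F0) / F0` with `F0` the per-neuron static baseline
#' percentile.
#'
#' @param raw_f positive numeric matrix, neurons x frames.
#' @param baseline_percentile baseline percentile (default 20).
#' @param frame_rate Hz.
#' @return A [fluorescence_traces] object.
#' @export
compute_dff <- function(raw_f, baseline_percentile = 20, frame_rate = 15) {
  if (!is.matrix(raw_f) || any(raw_f <= 0))
    stop("raw fluorescence must be a matrix of positive values")
  f0 <- apply(raw_f, 1L, stats::quantile, probs = baseline_percentile / 100,
              names = FALSE)
  if (any(f0 <= 0)) stop("nonpositive baseline F0")
  fluorescence_traces((raw_f - f0) / f0, frame_rate)
}

## per-neuron noise SD of the dF/F trace
estimate_noise_sd <- function(values) {
  apply(values, 1L, function(x) stats::mad(diff(x))) / sqrt(2)
}

#' Deconvolve dF/F traces to a spike-rate raster
#'
#' First-order AR inversion with nonnegativity and SD thresholding:
#' `lambda(t) = max(0, F(t) - gamma * F(t-1))` (and `lambda(1) = max(0, F(1))`),
#' after which rates below `threshold_k` times the per-neuron noise SD are
#' set to zero. This inverts [spikes_to_fluorescence] exactly on noiseless
#' traces.
#'
#' @param traces a [fluorescence_traces] object.
#' @param params a [deconv_params] object.
#' @return A [spike_raster].
#' @export
deconvolve <- function(traces, params = deconv_params()) {
  if (!inherits(traces, "fluorescence_traces"))
    stop("`traces` must be a fluorescence_traces object")
  if (!inherits(params, "deconv_params"))
    stop("`params` must come from deconv_params()")
  f <- traces$values
  if (ncol(f) < 2L) stop("need at least two frames to deconvolve")
  ## anchor each trace at its minimum: removes any DC offset in the dF/F
  ## baseline (a constant trace must deconvolve to silence) and is exact on
  ## traces whose baseline already touches zero
  f <- f - apply(f, 1L, min)
  g <- exp(-1 / (traces$frame_rate * params$decay_tau))
  lam <- cbind(pmax(f[, 1L, drop = FALSE], 0),
               pmax(f[, -1L, drop = FALSE] - g * f[, -ncol(f), drop = FALSE], 0))
  if (params$threshold_k > 0) {
    thr <- params$threshold_k * estimate_noise_sd(f)
    lam[lam < thr] <- 0   # per-neuron threshold recycles down columns
  }
  spike_raster(lam, traces$frame_rate)
}

#' ISI-preserving surrogate raster
#'
#' Per neuron, the recording is treated as a ring: the circular inter-event
#' gaps are randomly permuted and re-laid starting from a uniformly random
#' frame. Event count, firing rate, and the circular inter-spike-interval
#' multiset are preserved exactly; cross-neuron timing is destroyed. Lambda
#' amplitudes travel with their events. Neurons with fewer than two events
#' are circularly shifted only.
#'
#' @param raster a [spike_raster].
#' @param seed RNG seed (`NULL` = current stream).
#' @return A [spike_raster] with identical per-neuron rates.
#' @export
shuffle_raster <- function(raster, seed = NULL) {
  assert_raster(raster)
  nt <- raster$n_frames
  ev <- raster$events
  with_seed(seed, {
    if (!nrow(ev))
      return(new_spike_raster(ev, raster$n_neurons, nt, raster$frame_rate))
    o <- order(ev$roi, ev$frame)
    roi_s <- ev$roi[o]; frame_s <- ev$frame[o]; lam_s <- ev$lam[o]
    idx <- split(seq_along(roi_s), roi_s)
    new_frame <- integer(length(frame_s))
    for (ii in idx) {
      f <- frame_s[ii]                  # already sorted within neuron
      m <- length(f)
      gaps <- diff(c(f, f[1L] + nt))    # m circular gaps summing to n_frames
      if (m > 1L) gaps <- gaps[sample.int(m)]
      start <- sample.int(nt, 1L)
      new_frame[ii] <- (start + cumsum(c(0L, gaps[-m])) - 1L) %% nt + 1L
    }
    out <- data.frame(roi = roi_s, frame = new_frame, lam = lam_s)
    out <- out[order(out$frame, out$roi), , drop = FALSE]
    new_spike_raster(out, raster$n_neurons, nt, raster$frame_rate)
  })
}
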