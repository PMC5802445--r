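## Synthetic branching-process rasters.
##
## The generator produces population activity with three mechanisms:
##   (i)  Poisson drive: each frame receives Poisson(drive_rate) spontaneous
##        seed activations on uniformly chosen neurons;
##   (ii) cascade propagation: every cascade-activated neuron (seed or
##        offspring target) at frame t activates Poisson(offspring_mean)
##        uniformly chosen neurons (with replacement, self-targeting
##        allowed) at frame t+1;
##   (iii) burst persistence: every active neuron independently stays active
##        at t+1 with probability persist_prob. Persistence-only activity is
##        superimposed on the cascade: a neuron active purely because it is
##        persisting emits no offspring, so burst tails ride on top of the
##        propagating cascade without feeding back into it.
## A neuron counts once per frame in the activity mask regardless of how many
## activations it received; lambda amplitudes sum over activations.

## run RNG-dependent code under a seed without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation parameters for the branching-process generator
#'
#' Defaults reproduce the geometry of the emulated recordings (80 neurons,
#' 5000 frames at 15 Hz in a 557 um field) with subcritical cascade
#' propagation. `sal_params()` and `pcp_params()` are presets for the two
#' phenotypes: identical cascade strength, differing only in per-neuron burst
#' persistence. `critical_params()` configures the near-critical benchmark
#' used to check the avalanche statistics against mean-field theory.
#'
#' @param n_neurons number of neurons (>= 2).
#' @param n_frames number of frames (>= 2).
#' @param frame_rate sampling rate, Hz.
#' @param offspring_mean expected number of next-frame descendants per active
#'   neuron (the branching ratio of the cascade mechanism, >= 0).
#' @param drive_rate expected spontaneous seed activations per frame (>= 0).
#' @param persist_prob probability an active neuron stays active in the next
#'   frame, in `[0, 1)`.
#' @param lambda_amplitude per-activation lambda amplitude model: a list with
#'   `dist` (`"constant"` or `"exponential"`) and `mean`. The default
#'   (constant 1) makes lambda-based and count-based avalanche sizes coincide.
#' @param seed RNG seed carried with the parameters; `NULL` uses the current
#'   RNG state.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_neurons = 80, n_frames = 5000, frame_rate = 15,
                       offspring_mean = 0.42, drive_rate = 0.3,
                       persist_prob = 0.05,
                       lambda_amplitude = list(dist = "constant", mean = 1),
                       seed = NULL) {
  p <- list(n_neurons = as.integer(n_neurons), n_frames = as.integer(n_frames),
            frame_rate = frame_rate, offspring_mean = offspring_mean,
            drive_rate = drive_rate, persist_prob = persist_prob,
            lambda_amplitude = lambda_amplitude, seed = seed)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_neurons < 2L) stop("n_neurons must be >= 2")
  if (p$n_frames < 2L) stop("n_frames must be >= 2")
  if (!is.numeric(p$frame_rate) || p$frame_rate <= 0) stop("frame_rate must be > 0")
  if (p$offspring_mean < 0) stop("offspring_mean must be >= 0")
  if (p$drive_rate < 0) stop("drive_rate must be >= 0")
  if (p$persist_prob < 0 || p$persist_prob >= 1)
    stop("persist_prob must be in [0, 1)")
  la <- p$lambda_amplitude
  if (!is.list(la) || !la$dist %in% c("constant", "exponential") ||
      !is.numeric(la$mean) || la$mean <= 0)
    stop("lambda_amplitude must be list(dist = 'constant'|'exponential', mean > 0)")
  invisible(p)
}

#' @rdname sim_params
#' @param ... overrides passed to [sim_params].
#' @export
sal_params <- function(...) {
  do.call(sim_params, utils::modifyList(list(persist_prob = 0.05), list(...)))
}

#' @rdname sim_params
#' @export
pcp_params <- function(...) {
  do.call(sim_params, utils::modifyList(list(persist_prob = 0.25), list(...)))
}

#' @rdname sim_params
#' @export
critical_params <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(n_neurons = 2000, n_frames = 5e6, offspring_mean = 1,
         persist_prob = 0, drive_rate = 0.015), list(...)))
}

#' Simulate a branching-process spike raster
#'
#' Runs the seeded cascade/persistence process described in [sim_params] and
#' returns the resulting raster. The run is reproducible: the same `seed`
#' gives a bit-identical raster.
#'
#' @param params a [sim_params] object.
#' @return A [spike_raster].
#' @examples
#' r <- simulate_branching_raster(sal_params(n_frames = 500, seed = 1))
#' r
#' @export
simulate_branching_raster <- function(params) {
  if (!inherits(params, "sim_params")) stop("`params` must come from sim_params()")
  validate_sim_params(params)
  with_seed(params$seed, {
    n <- params$n_neurons
    nt <- params$n_frames
    m <- params$offspring_mean
    pp <- params$persist_prob
    d <- params$drive_rate
    la <- params$lambda_amplitude
    const_amp <- la$dist == "constant"

    roi_t <- vector("list", nt)   # unique active neurons per frame
    lam_t <- vector("list", nt)   # their summed lambda amplitudes
    prev <- integer(0)            # all active at t-1
    casc <- integer(0)            # cascade-activated (seed/offspring) at t-1
    for (t in seq_len(nt)) {
      ns <- stats::rpois(1L, d)
      tg <- if (ns > 0L) sample.int(n, ns, replace = TRUE) else integer(0)
      if (length(casc)) {
        noff <- sum(stats::rpois(length(casc), m))
        if (noff > 0L) tg <- c(tg, sample.int(n, noff, replace = TRUE))
      }
      casc <- if (length(tg)) unique.default(tg) else integer(0)
      if (pp > 0 && length(prev))
        tg <- c(tg, prev[stats::runif(length(prev)) < pp])
      if (length(tg)) {
        s <- sort.int(tg)
        r <- rle(s)
        roi_t[[t]] <- r$values
        lam_t[[t]] <- if (const_amp) r$lengths * la$mean else
          as.numeric(rowsum(stats::rexp(length(s), rate = 1 / la$mean), s))
        prev <- r$values
      } else {
        prev <- integer(0)
      }
    }
    nact <- lengths(roi_t)
    events <- data.frame(
      roi = as.integer(unlist(roi_t, use.names = FALSE)),
      frame = rep.int(seq_len(nt), nact),
      lam = as.numeric(unlist(lam_t, use.names = FALSE)))
    ## events are frame-major; order within frame ascending by roi already
    if (is.null(events$roi)) events <- data.frame(roi = integer(0),
                                                  frame = integer(0),
                                                  lam = numeric(0))
    new_spike_raster(events, n, nt, params$frame_rate)
  })
}

#' Uniform ROI centroid map
#'
#' Draws `n` centroids uniformly in a square imaging field.
#'
#' @param n number of ROIs (>= 1).
#' @param field_size side of the field in micrometres (default the 557 um
#'   field of the emulated recordings).
#' @param seed RNG seed (`NULL` = current stream).
#' @return A data.frame of class `roi_map` with columns `roi_id`, `x_um`,
#'   `y_um` and attribute `field_size`.
#' @export
generate_roi_map <- function(n, field_size = 557, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  with_seed(seed, {
    d <- data.frame(roi_id = seq_len(n),
                    x_um = stats::runif(n, 0, field_size),
                    y_um = stats::runif(n, 0, field_size))
    structure(d, class = c("roi_map", "data.frame"), field_size = field_size)
  })
}

#' Fluorescence traces container
#'
#' @param values numeric matrix of dF/F values, neurons x frames.
#' @param frame_rate Hz.
#' @export
fluorescence_traces <- function(values, frame_rate) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stop("`values` must be a finite numeric matrix")
  structure(list(values = values, frame_rate = frame_rate),
            class = "fluorescence_traces")
}

#' @export
print.fluorescence_traces <- function(x, ...) {
  cat(sprintf("fluorescence_traces: %d neurons x %d frames @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' Forward model: spikes to fluorescence
#'
#' Convolves the raster with a one-frame-recursion calcium kernel,
#' `F(t) = gamma * F(t-1) + lambda(t)` with `gamma = exp(-1 / (frame_rate *
#' decay_tau))` and `F(1) = lambda(1)`, then adds independent Gaussian
#' measurement noise to every sample. This is the exact inverse of
#' [deconvolve] at `noise_sd = 0`.
#'
#' @param raster a [spike_raster].
#' @param decay_tau indicator decay time constant in seconds (> 0).
#' @param noise_sd standard deviation of the additive dF/F noise (>= 0).
#' @param seed RNG seed for the noise.
#' @return A [fluorescence_traces] object.
#' @export
spikes_to_fluorescence <- function(raster, decay_tau = 1, noise_sd = 0.05,
                                   seed = NULL) {
  assert_raster(raster)
  if (decay_tau <= 0) stop("decay_tau must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lam <- lam_matrix(raster)
  g <- exp(-1 / (raster$frame_rate * decay_tau))
  f <- lam
  for (t in seq_len(ncol(f))[-1L]) f[, t] <- g * f[, t - 1L] + lam[, t]
  with_seed(seed, {
    if (noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, noise_sd), nrow(f), ncol(f))
    fluorescence_traces(f, raster$frame_rate)
  })
}

#' Generate a two-group synthetic cohort
#'
#' Produces labelled per-movie rasters (and optionally forward-modelled
#' fluorescence traces and ROI maps) for a SAL-like and a PCP-like group,
#' with distinct reproducible sub-seeds per movie.
#'
#' @param sal_params,pcp_params [sim_params] for the two groups.
#' @param movies_per_group movies per group (default 15, the per-group movie
#'   count of the emulated design).
#' @param seed master seed; movie sub-seeds are drawn from it.
#' @param include_traces if `TRUE`, attach forward-modelled traces.
#' @param decay_tau,noise_sd forward-model settings when `include_traces`.
#' @return A list of class `cohort`; each element has `raster`, `group`
#'   (`"SAL"` or `"PCP"`), `movie_id`, `seed`, `roi_map`, and optionally
#'   `traces`.
#' @export
make_cohort <- function(sal_params = avalanchr::sal_params(),
                        pcp_params = avalanchr::pcp_params(),
                        movies_per_group = 15, seed = 1,
                        include_traces = FALSE, decay_tau = 1,
                        noise_sd = 0.05) {
  if (movies_per_group < 1L) stop("movies_per_group must be >= 1")
  n_mov <- 2L * as.integer(movies_per_group)
  with_seed(seed, {
    sub <- sample.int(.Machine$integer.max - 1L, 3L * n_mov)
    movies <- vector("list", n_mov)
    k <- 0L
    for (g in c("SAL", "PCP")) {
      par0 <- if (g == "SAL") sal_params else pcp_params
      for (i in seq_len(movies_per_group)) {
        k <- k + 1L
        par <- par0
        par$seed <- sub[3L * k - 2L]
        raster <- simulate_branching_raster(par)
        movie <- list(
          raster = raster, group = g, movie_id = sprintf("%s_%02d", g, i),
          seed = par$seed,
          roi_map = generate_roi_map(par$n_neurons, seed = sub[3L * k - 1L]))
        if (include_traces)
          movie$traces <- spikes_to_fluorescence(raster, decay_tau = decay_tau,
                                                 noise_sd = noise_sd,
                                                 seed = sub[3L * k])
        movies[[k]] <- movie
      }
    }
    structure(movies, class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("cohort: %d movies (%s)\n", length(x),
              paste(sprintf("%s n=%d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}
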