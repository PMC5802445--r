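## Branching parameters, single-neuron burst statistics, and the
## persistent-burst-removal intervention.

#' Temporal (lambda-based) branching parameter
#'
#' Ratio of descendant to ancestor activity within clusters: total lambda in
#' all frames after the first frame of a cluster divided by total lambda in
#' that first frame. `mode = "pooled"` pools the sums over all clusters
#' before dividing; `mode = "per_cluster_mean"` averages the per-cluster
#' ratios (duration-1 clusters contribute 0). A branching parameter of 1
#' marks the critical point.
#'
#' @param clusters a `cluster_set` with >= 1 cluster.
#' @param mode `"pooled"` (default) or `"per_cluster_mean"`.
#' @return list of class `branching_estimate` with `sigma`, `kind =
#'   "temporal"`, `mode`, `n_clusters`.
#' @export
temporal_branching <- function(clusters, mode = c("pooled", "per_cluster_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(clusters, "cluster_set"))
  if (!nrow(clusters$clusters)) stop("no clusters: branching undefined")
  a <- clusters$activations
  first <- a$frame == clusters$clusters$start_frame[a$cluster_id]
  nb <- nrow(clusters$clusters)
  anc <- as.numeric(rowsum(a$lam * first, a$cluster_id, reorder = TRUE))
  desc <- as.numeric(rowsum(a$lam * !first, a$cluster_id, reorder = TRUE))
  if (any(anc <= 0)) stop("cluster with empty first frame: invalid cluster set")
  sigma <- if (mode == "pooled") sum(desc) / sum(anc) else mean(desc / anc)
  structure(list(sigma = sigma, kind = "temporal", mode = mode,
                 n_clusters = nb), class = "branching_estimate")
}

#' Spatial branching parameter with new/repeat decomposition
#'
#' Count-based branching: the number of ROI-frame activations after the
#' first frame of a cluster divided by the number of active ROIs in that
#' first frame. Every downstream activation is labelled `repeat` if that ROI
#' was already active in an earlier frame of the same cluster, otherwise
#' `new`; first-frame activations form the denominator and are themselves
#' neither. The decomposition is exact: `sigma_new + sigma_repeat =
#' sigma_total` in both modes.
#'
#' @inheritParams temporal_branching
#' @return list of class `branching_estimate` with `sigma_total`,
#'   `sigma_new`, `sigma_repeat`, `kind = "spatial"`, `mode`, `n_clusters`.
#' @export
spatial_branching <- function(clusters, mode = c("pooled", "per_cluster_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(clusters, "cluster_set"))
  if (!nrow(clusters$clusters)) stop("no clusters: branching undefined")
  a <- clusters$activations
  first <- a$frame == clusters$clusters$start_frame[a$cluster_id]
  ## activations are frame-sorted, so the first occurrence of (cluster, roi)
  ## is its earliest frame; later occurrences are repeats
  key <- a$cluster_id * (clusters$n_neurons + 1) + a$roi
  rep_act <- duplicated(key) & !first
  new_act <- !duplicated(key) & !first
  cid <- a$cluster_id
  anc <- as.numeric(rowsum(as.numeric(first), cid, reorder = TRUE))
  if (any(anc <= 0)) stop("cluster with empty first frame: invalid cluster set")
  newc <- as.numeric(rowsum(as.numeric(new_act), cid, reorder = TRUE))
  repc <- as.numeric(rowsum(as.numeric(rep_act), cid, reorder = TRUE))
  if (mode == "pooled") {
    s_new <- sum(newc) / sum(anc)
    s_rep <- sum(repc) / sum(anc)
  } else {
    s_new <- mean(newc / anc)
    s_rep <- mean(repc / anc)
  }
  structure(list(sigma_total = s_new + s_rep, sigma_new = s_new,
                 sigma_repeat = s_rep, kind = "spatial", mode = mode,
                 n_clusters = nrow(clusters$clusters)),
            class = "branching_estimate")
}

#' @export
print.branching_estimate <- function(x, ...) {
  if (x$kind == "temporal") {
    cat(sprintf("branching_estimate (temporal, %s): sigma = %.4f [%d clusters]\n",
                x$mode, x$sigma, x$n_clusters))
  } else {
    cat(sprintf("branching_estimate (spatial, %s): total %.4f = new %.4f + repeat %.4f [%d clusters]\n",
                x$mode, x$sigma_total, x$sigma_new, x$sigma_repeat, x$n_clusters))
  }
  invisible(x)
}

#' Extract single-neuron bursts
#'
#' A burst is a maximal run of consecutive active frames of one neuron.
#'
#' @param raster a [spike_raster].
#' @return list of class `burst_set`: `bursts` (data.frame `neuron`,
#'   `start_frame`, `length`), `n_neurons`, `n_frames`.
#' @export
extract_bursts <- function(raster) {
  assert_raster(raster)
  tr <- event_frames_by_roi(raster)
  res <- lapply(seq_along(tr), function(i) {
    f <- tr[[i]]
    if (!length(f)) return(NULL)
    brk <- cumsum(c(1L, as.integer(diff(f) > 1L)))
    len <- tabulate(brk)
    data.frame(neuron = i, start_frame = f[!duplicated(brk)], length = len)
  })
  bursts <- do.call(rbind, res)
  if (is.null(bursts))
    bursts <- data.frame(neuron = integer(0), start_frame = integer(0),
                         length = integer(0))
  structure(list(bursts = bursts, n_neurons = raster$n_neurons,
                 n_frames = raster$n_frames), class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("burst_set: %d bursts, fraction multi-frame %.3f\n",
              nrow(x$bursts),
              if (nrow(x$bursts)) mean(x$bursts$length > 1L) else NA_real_))
  invisible(x)
}

#' Burst-length distribution statistics
#'
#' Pools all bursts, fits `P(L) ~ L^-beta` by least squares on log length
#' vs log probability over the occupied lengths inside `fit_range`, and
#' reports the fraction of bursts longer than one frame. With fewer than
#' three occupied lengths the slope is undefined (`NA`) but the fraction is
#' still returned.
#'
#' @param bursts a `burst_set` with >= 1 burst.
#' @param fit_range length range (frames) entering the slope fit.
#' @return list of class `burst_slope_fit`: `beta`, `fraction_multiframe`,
#'   `length_table` (data.frame `length`, `n`, `prob`), `n_bursts`.
#' @export
burst_length_stats <- function(bursts, fit_range = c(1, Inf)) {
  stopifnot(inherits(bursts, "burst_set"))
  len <- bursts$bursts$length
  if (!length(len)) stop("no bursts")
  tab <- table(len)
  lt <- data.frame(length = as.integer(names(tab)), n = as.integer(tab))
  lt$prob <- lt$n / sum(lt$n)
  use <- lt$length >= fit_range[1L] & lt$length <= fit_range[2L]
  beta <- if (sum(use) >= 3L) {
    -as.numeric(stats::coef(stats::lm(log(prob) ~ log(length),
                                      data = lt[use, ]))[2L])
  } else NA_real_
  structure(list(beta = beta, fraction_multiframe = mean(len > 1L),
                 length_table = lt, n_bursts = length(len),
                 fit_range = fit_range),
            class = "burst_slope_fit")
}

#' @export
print.burst_slope_fit <- function(x, ...) {
  cat(sprintf("burst_slope_fit: beta = %s, fraction multi-frame = %.3f (%d bursts)\n",
              if (is.na(x$beta)) "NA" else sprintf("%.3f", x$beta),
              x$fraction_multiframe, x$n_bursts))
  invisible(x)
}

#' Remove persistent bursts (intervention)
#'
#' Randomly selects `round(fraction * count)` of the bursts longer than one
#' frame (nearest integer, ties up) and deletes all activity of each
#' selected burst after its first frame. No activity is created, first
#' frames are untouched, and the operation is reproducible given `seed`.
#'
#' @param raster a [spike_raster].
#' @param fraction proportion of multi-frame bursts to truncate, in
#'   `[0, 1]` (the intervention of interest uses 1/3).
#' @param seed RNG seed for the selection.
#' @return A [spike_raster] with the selected bursts truncated to length 1.
#' @export
remove_persistent_bursts <- function(raster, fraction = 1 / 3, seed = NULL) {
  assert_raster(raster)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  b <- extract_bursts(raster)$bursts
  multi <- b[b$length > 1L, , drop = FALSE]
  m <- nrow(multi)
  k <- as.integer(floor(fraction * m + 0.5))   # nearest integer, ties up
  if (k == 0L || m == 0L) return(raster)
  with_seed(seed, {
    sel <- multi[sample.int(m, k), , drop = FALSE]
    drop_roi <- rep.int(sel$neuron, sel$length - 1L)
    drop_frame <- unlist(lapply(seq_len(k), function(i)
      seq.int(sel$start_frame[i] + 1L, sel$start_frame[i] + sel$length[i] - 1L)))
    nt <- raster$n_frames
    drop_key <- as.numeric(drop_roi) * (nt + 1) + drop_frame
    ev <- raster$events
    keep <- !(as.numeric(ev$roi) * (nt + 1) + ev$frame) %in% drop_key
    new_spike_raster(ev[keep, , drop = FALSE], raster$n_neurons, nt,
                     raster$frame_rate)
  })
}
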