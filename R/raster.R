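#' @keywords internal
"_PACKAGE"

## Central container: a spike-rate raster stored sparsely as events.
## An event is one (neuron, frame) with lambda > 0; the binary activity mask
## is exactly the support of lambda, so it is never stored separately.

#' Construct a spike-rate raster
#'
#' A `spike_raster` holds nonnegative per-neuron, per-frame spike-rate
#' estimates (lambda) together with the sampling rate. Internally the raster
#' is stored as a table of events (neuron, frame, lambda) so that long
#' sparse recordings stay cheap; the binary activity mask is the support of
#' lambda (`mask(i, t) = 1` iff `lambda(i, t) > 0`).
#'
#' @param lam numeric matrix, neurons x frames, finite and nonnegative.
#' @param frame_rate sampling rate in Hz.
#' @return An object of class `spike_raster` with fields `events`
#'   (data.frame `roi`, `frame`, `lam`), `n_neurons`, `n_frames`,
#'   `frame_rate`.
#' @examples
#' r <- spike_raster(matrix(c(0, 1, 0, 0, 0, 2), nrow = 2), frame_rate = 15)
#' lam_matrix(r)
#' @export
spike_raster <- function(lam, frame_rate) {
  if (!is.matrix(lam) || !is.numeric(lam))
    stop("`lam` must be a numeric matrix (neurons x frames)")
  if (!all(is.finite(lam)))
    stop("`lam` must be finite")
  if (any(lam < 0))
    stop("`lam` must be nonnegative")
  idx <- which(lam > 0, arr.ind = TRUE)
  events <- data.frame(roi = as.integer(idx[, 1L]),
                       frame = as.integer(idx[, 2L]),
                       lam = lam[idx])
  events <- events[order(events$frame, events$roi), , drop = FALSE]
  new_spike_raster(events, nrow(lam), ncol(lam), frame_rate)
}

## internal constructor; `events` assumed sorted by frame then roi
new_spike_raster <- function(events, n_neurons, n_frames, frame_rate) {
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1L, frame_rate > 0)
  rownames(events) <- NULL
  structure(list(events = events,
                 n_neurons = as.integer(n_neurons),
                 n_frames = as.integer(n_frames),
                 frame_rate = as.numeric(frame_rate)),
            class = "spike_raster")
}

is_spike_raster <- function(x) inherits(x, "spike_raster")

assert_raster <- function(x) {
  if (!is_spike_raster(x)) stop("expected a `spike_raster` object")
  invisible(x)
}

#' Dense lambda matrix of a raster
#'
#' @param x a [spike_raster].
#' @return numeric matrix, neurons x frames.
#' @export
lam_matrix <- function(x) {
  assert_raster(x)
  m <- matrix(0, x$n_neurons, x$n_frames)
  if (nrow(x$events)) m[cbind(x$events$roi, x$events$frame)] <- x$events$lam
  m
}

#' Binary activity mask of a raster
#'
#' @param x a [spike_raster].
#' @return logical matrix, `TRUE` where lambda > 0.
#' @export
activity_mask <- function(x) lam_matrix(x) > 0

## sorted event frames per neuron, as a list of integer vectors
event_frames_by_roi <- function(x) {
  out <- vector("list", x$n_neurons)
  if (nrow(x$events)) {
    sp <- split(x$events$frame, factor(x$events$roi, levels = seq_len(x$n_neurons)))
    out <- lapply(sp, function(f) sort.int(f))
  } else {
    out <- rep(list(integer(0)), x$n_neurons)
  }
  out
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons x %d frames @ %g Hz, %d events (%.4f events/neuron/frame)\n",
              x$n_neurons, x$n_frames, x$frame_rate, nrow(x$events),
              nrow(x$events) / (x$n_neurons * as.numeric(x$n_frames))))
  invisible(x)
}

#' Per-neuron coefficient of variation of the inter-spike interval
#'
#' Inter-spike intervals are measured in frames between successive active
#' frames of the same neuron. Neurons with fewer than three events (fewer
#' than two intervals) are returned as `NA`.
#'
#' @param x a [spike_raster].
#' @return numeric vector of length `n_neurons`.
#' @export
cv_isi <- function(x) {
  assert_raster(x)
  unname(vapply(event_frames_by_roi(x), function(f) {
    if (length(f) < 3L) return(NA_real_)
    isi <- diff(f)
    stats::sd(isi) / mean(isi)
  }, numeric(1)))
}

## ---- delimited-text interchange -------------------------------------------

#' Write / read a raster as delimited text
#'
#' Layout: a comment line `# frame_rate=<Hz>`, a header row of frame indices,
#' then one row per neuron with the lambda values. Intended for movie-scale
#' rasters; the dense layout is the interchange format, the in-memory
#' representation stays sparse.
#'
#' @param x a [spike_raster].
#' @param path file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   [spike_raster].
#' @export
write_raster <- function(x, path) {
  assert_raster(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%.10g", x$frame_rate), con)
  m <- lam_matrix(x)
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# frame_rate=", first))
    stop("not a raster file: missing '# frame_rate=' header in ", path)
  fr <- as.numeric(sub("^# frame_rate=", "", first))
  m <- as.matrix(utils::read.csv(path, skip = 1L, header = TRUE))
  dimnames(m) <- NULL
  spike_raster(m, frame_rate = fr)
}

#' Write / read fluorescence traces as delimited text
#'
#' Same layout as [write_raster] but holding dF/F values, which may be
#' negative.
#'
#' @param x a [fluorescence_traces] object.
#' @param path file path.
#' @export
write_traces <- function(x, path) {
  stopifnot(inherits(x, "fluorescence_traces"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%.10g", x$frame_rate), con)
  m <- x$values
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# frame_rate=", first))
    stop("not a traces file: missing '# frame_rate=' header in ", path)
  fr <- as.numeric(sub("^# frame_rate=", "", first))
  m <- as.matrix(utils::read.csv(path, skip = 1L, header = TRUE))
  dimnames(m) <- NULL
  fluorescence_traces(m, frame_rate = fr)
}

#' Write / read an ROI centroid map as CSV
#'
#' Columns `roi_id,x_um,y_um`; the field size (um) is kept as a `field_size`
#' attribute and stored in a comment line.
#'
#' @param x a `roi_map` data.frame from [generate_roi_map].
#' @param path file path.
#' @export
write_roi_map <- function(x, path) {
  stopifnot(inherits(x, "roi_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_size=%.10g", attr(x, "field_size")), con)
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_map
#' @export
read_roi_map <- function(path) {
  first <- readLines(path, n = 1L)
  fs <- if (grepl("^# field_size=", first))
    as.numeric(sub("^# field_size=", "", first)) else NA_real_
  d <- utils::read.csv(path, skip = if (is.na(fs)) 0L else 1L)
  structure(d, class = c("roi_map", "data.frame"), field_size = fs)
}
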