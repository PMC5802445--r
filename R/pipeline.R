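## Orchestration: per-movie analysis, cohort aggregation, normality-gated
## statistics, and reporting.

#' Analysis configuration
#'
#' One place for every tunable of the per-movie pipeline, so a config plus
#' the seeds fully determines every number in a report.
#'
#' @param decay_tau,threshold_k deconvolution settings (see [deconv_params]);
#'   used only when the input is fluorescence.
#' @param lambda_min clustering threshold on lambda (0 on already-thresholded
#'   rasters).
#' @param n_shuffles surrogates for shuffle correction.
#' @param compute_sync also compute shuffle-corrected event synchronization
#'   (slower; the correlation is always computed).
#' @param r_bin_edges histogram bins for the corrected-correlation
#'   distribution.
#' @param size_mode,bin_factor,s_min avalanche size distribution settings.
#' @param cutoff power-law fit cutoff; `NULL` uses the system-size
#'   prediction (number of neurons, scaled by the mean single-activation
#'   lambda for `size_mode = "lambda"`).
#' @param min_per_duration,scaling_fit_range size-duration scaling settings.
#' @param burst_fit_range burst-length slope fit range.
#' @param branching_mode `"pooled"` or `"per_cluster_mean"`; both are
#'   reported, this selects the headline one.
#' @param alpha significance level for the statistics layer.
#' @param seed seed for the shuffle correction.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(decay_tau = 1, threshold_k = 5, lambda_min = 0,
                            n_shuffles = 20, compute_sync = FALSE,
                            r_bin_edges = seq(-0.2, 0.6, by = 0.01),
                            size_mode = "count", bin_factor = 2, s_min = 1,
                            cutoff = NULL, min_per_duration = 10,
                            scaling_fit_range = c(1, Inf),
                            burst_fit_range = c(1, Inf),
                            branching_mode = "pooled",
                            alpha = 0.05, seed = 1) {
  structure(list(decay_tau = decay_tau, threshold_k = threshold_k,
                 lambda_min = lambda_min, n_shuffles = n_shuffles,
                 compute_sync = compute_sync, r_bin_edges = r_bin_edges,
                 size_mode = size_mode, bin_factor = bin_factor,
                 s_min = s_min, cutoff = cutoff,
                 min_per_duration = min_per_duration,
                 scaling_fit_range = scaling_fit_range,
                 burst_fit_range = burst_fit_range,
                 branching_mode = branching_mode,
                 alpha = alpha, seed = seed),
            class = "analysis_config")
}

na_or <- function(expr) tryCatch(expr, error = function(e) NA)

#' Run the full per-movie analysis
#'
#' Accepts either fluorescence traces (deconvolved first) or a spike-rate
#' raster, and computes the complete movie summary: rate and irregularity
#' statistics, the shuffle-corrected pairwise correlation distribution
#' (optionally event synchronization), avalanche power-law and scaling
#' fits, temporal and spatial branching with new/repeat decomposition, and
#' burst statistics. Fit failures (e.g. an all-silent raster) are flagged
#' as `NA` rather than aborting the movie.
#'
#' @param x a [spike_raster] or [fluorescence_traces].
#' @param config an [analysis_config].
#' @param label input label carried into the provenance block.
#' @return list of class `movie_summary`.
#' @export
run_movie_analysis <- function(x, config = analysis_config(), label = "movie") {
  if (inherits(x, "fluorescence_traces")) {
    raster <- deconvolve(x, deconv_params(decay_tau = config$decay_tau,
                                          threshold_k = config$threshold_k))
  } else if (is_spike_raster(x)) {
    raster <- x
  } else stop("input must be a spike_raster or fluorescence_traces; got ",
              paste(class(x), collapse = "/"))

  n_ev <- nrow(raster$events)
  rate_frame <- n_ev / (raster$n_neurons * as.numeric(raster$n_frames))
  cv <- cv_isi(raster)

  rc <- na_or(shuffle_correct(raster, "correlation",
                              n_shuffles = config$n_shuffles,
                              seed = config$seed))
  r_dist <- if (inherits(rc, "pair_matrix")) na_or(metric_distribution(rc, config$r_bin_edges)) else NA
  q_mean <- NA_real_
  q_dist <- NULL
  if (isTRUE(config$compute_sync)) {
    qc <- na_or(shuffle_correct(raster, "synchronization",
                                n_shuffles = config$n_shuffles,
                                seed = config$seed + 1L))
    if (inherits(qc, "pair_matrix")) {
      q_mean <- mean(pair_values(qc))
      q_dist <- na_or(metric_distribution(qc, config$r_bin_edges))
    }
  }

  cs <- extract_clusters(raster, lambda_min = config$lambda_min)
  cutoff <- config$cutoff
  if (is.null(cutoff)) {
    cutoff <- raster$n_neurons
    if (config$size_mode == "lambda" && n_ev > 0)
      cutoff <- cutoff * mean(raster$events$lam)
  }
  sd_ <- na_or(size_distribution(cs, size_mode = config$size_mode,
                                 bin_factor = config$bin_factor,
                                 s_min = config$s_min))
  fit <- if (inherits(sd_, "size_distribution"))
    na_or(fit_power_law(sd_, cutoff = cutoff)) else NA
  sc <- na_or(size_duration_scaling(cs, size_mode = config$size_mode,
                                    min_per_duration = config$min_per_duration,
                                    fit_range = config$scaling_fit_range))
  bt_pool <- na_or(temporal_branching(cs, "pooled"))
  bt_mean <- na_or(temporal_branching(cs, "per_cluster_mean"))
  bs <- na_or(spatial_branching(cs, config$branching_mode))
  bursts <- extract_bursts(raster)
  bl <- na_or(burst_length_stats(bursts, fit_range = config$burst_fit_range))

  structure(list(
    label = label,
    n_neurons = raster$n_neurons, n_frames = raster$n_frames,
    frame_rate = raster$frame_rate,
    mean_rate_frame = rate_frame,
    mean_rate_hz = rate_frame * raster$frame_rate,
    cv_isi_median = stats::median(cv, na.rm = TRUE),
    cv_isi = cv,
    r_corrected_mean = if (inherits(rc, "pair_matrix")) mean(pair_values(rc)) else NA_real_,
    r_distribution = if (inherits(r_dist, "metric_distribution")) r_dist else NULL,
    q_corrected_mean = q_mean,
    q_distribution = q_dist,
    n_clusters = nrow(cs$clusters),
    exponent = if (inherits(fit, "power_law_fit")) fit$exponent else NA_real_,
    ks_distance = if (inherits(fit, "power_law_fit")) fit$ks_distance else NA_real_,
    chi = if (inherits(sc, "scaling_fit")) sc$chi else NA_real_,
    sigma_temporal = if (inherits(bt_pool, "branching_estimate")) bt_pool$sigma else NA_real_,
    sigma_temporal_mean = if (inherits(bt_mean, "branching_estimate")) bt_mean$sigma else NA_real_,
    sigma_spatial_total = if (inherits(bs, "branching_estimate")) bs$sigma_total else NA_real_,
    sigma_spatial_new = if (inherits(bs, "branching_estimate")) bs$sigma_new else NA_real_,
    sigma_spatial_repeat = if (inherits(bs, "branching_estimate")) bs$sigma_repeat else NA_real_,
    beta = if (inherits(bl, "burst_slope_fit")) bl$beta else NA_real_,
    fraction_multiframe = if (inherits(bl, "burst_slope_fit")) bl$fraction_multiframe else NA_real_,
    n_bursts = nrow(bursts$bursts),
    provenance = list(label = label, config = unclass(config),
                      seed = config$seed)),
    class = "movie_summary")
}

#' @export
print.movie_summary <- function(x, ...) {
  cat(sprintf("movie_summary '%s': %d neurons, %d clusters\n", x$label,
              x$n_neurons, x$n_clusters))
  cat(sprintf("  rate %.4f ev/frame (%.3f Hz), median CV(ISI) %.3f\n",
              x$mean_rate_frame, x$mean_rate_hz, x$cv_isi_median))
  cat(sprintf("  exponent %.3f, KS %.4f, chi %.3f, sigma_t %.3f, sigma_s %.3f (new %.3f + rep %.3f)\n",
              x$exponent, x$ks_distance, x$chi, x$sigma_temporal,
              x$sigma_spatial_total, x$sigma_spatial_new, x$sigma_spatial_repeat))
  cat(sprintf("  beta %.3f, fraction multi-frame %.3f, corrected r mean %.4f\n",
              x$beta, x$fraction_multiframe, x$r_corrected_mean))
  invisible(x)
}

summary_scalar_fields <- c(
  "mean_rate_frame", "mean_rate_hz", "cv_isi_median", "r_corrected_mean",
  "q_corrected_mean", "n_clusters", "exponent", "ks_distance", "chi",
  "sigma_temporal", "sigma_temporal_mean", "sigma_spatial_total",
  "sigma_spatial_new", "sigma_spatial_repeat", "beta",
  "fraction_multiframe", "n_bursts")

#' Analyze every movie of a cohort
#'
#' @param cohort a `cohort` from [make_cohort] (or any list of elements with
#'   `raster`/`traces`, `group`, `movie_id`).
#' @param config an [analysis_config].
#' @param use_traces analyze the forward-modelled traces (through
#'   deconvolution) instead of the ground-truth rasters.
#' @return list of class `cohort_summary`: `summaries` (per movie) and
#'   `table` (one row of scalar statistics per movie, with `group`).
#' @export
analyze_cohort <- function(cohort, config = analysis_config(),
                           use_traces = FALSE) {
  summaries <- lapply(cohort, function(mv) {
    x <- if (use_traces) mv$traces else mv$raster
    s <- run_movie_analysis(x, config, label = mv$movie_id)
    s$group <- mv$group
    s
  })
  tab <- do.call(rbind, lapply(summaries, function(s) {
    row <- as.data.frame(s[summary_scalar_fields])
    cbind(data.frame(movie_id = s$label, group = s$group), row)
  }))
  structure(list(summaries = summaries, table = tab),
            class = "cohort_summary")
}

## ---- normality-gated statistics -------------------------------------------

shapiro_normal <- function(x, alpha) {
  ## constant or too-short samples cannot pass a normality test
  if (length(x) < 3L || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

extract_field <- function(x, field) {
  if (is.numeric(x)) return(x)
  if (inherits(x, "cohort_summary")) x <- x$summaries
  vapply(x, function(s) as.numeric(s[[field]]), numeric(1))
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group at level `alpha`; if both pass, Student's
#' two-tailed t-test with Welch's correction (paired t-test when `paired`),
#' otherwise Wilcoxon's rank-sum test (sign-rank when `paired`).
#'
#' @param a,b numeric vectors (n >= 3 each), or lists of `movie_summary` /
#'   `cohort_summary` objects with `field` naming the statistic to extract.
#' @param field summary field when `a`/`b` are summaries.
#' @param paired paired comparison (requires equal n).
#' @param alpha significance level of the normality gate (and reported
#'   level), default 0.05.
#' @return list of class `group_comparison`: `test`, `statistic`, `p_value`,
#'   `normal_a`, `normal_b`, `paired`, `n_a`, `n_b`.
#' @export
compare_two <- function(a, b, field = NULL, paired = FALSE, alpha = 0.05) {
  x <- extract_field(a, field); y <- extract_field(b, field)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) stop("need n >= 3 per group")
  if (paired && length(x) != length(y))
    stop("paired comparison requires equal group sizes")
  norm_a <- shapiro_normal(x, alpha)
  norm_b <- shapiro_normal(y, alpha)
  if (norm_a && norm_b) {
    ht <- if (paired) stats::t.test(x, y, paired = TRUE)
          else stats::t.test(x, y)            # Welch by default
    test <- if (paired) "paired t" else "Welch t"
  } else {
    ht <- suppressWarnings(
      if (paired) stats::wilcox.test(x, y, paired = TRUE)
      else stats::wilcox.test(x, y))
    test <- if (paired) "Wilcoxon sign-rank" else "Wilcoxon rank-sum"
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, normal_a = norm_a, normal_b = norm_b,
                 paired = paired, alpha = alpha,
                 n_a = length(x), n_b = length(y)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s, statistic %.4g, p = %.4g (n = %d/%d; normality %s/%s)\n",
              x$test, x$statistic, x$p_value, x$n_a, x$n_b,
              x$normal_a, x$normal_b))
  invisible(x)
}

#' Normality-gated multi-group comparison
#'
#' One-way ANOVA followed by Tukey's honest significant differences when
#' every group passes Shapiro-Wilk at `alpha`; otherwise the Kruskal-Wallis
#' test (no post hoc).
#'
#' @param groups named list of >= 3 numeric vectors (n >= 3 each), or of
#'   summary lists with `field`.
#' @param field summary field when `groups` hold summaries.
#' @param alpha significance level of the gate.
#' @return list of class `multi_group_comparison`: `test`, `statistic`,
#'   `p_value`, `normal` (per group), `posthoc` (Tukey data.frame or
#'   `NULL`).
#' @export
compare_multi <- function(groups, field = NULL, alpha = 0.05) {
  if (length(groups) < 3L) stop("need >= 3 groups")
  vals <- lapply(groups, extract_field, field = field)
  if (any(lengths(vals) < 3L)) stop("need n >= 3 per group")
  if (is.null(names(vals)) || any(names(vals) == ""))
    names(vals) <- paste0("g", seq_along(vals))
  normal <- vapply(vals, shapiro_normal, logical(1), alpha = alpha)
  y <- unlist(vals, use.names = FALSE)
  g <- factor(rep(names(vals), lengths(vals)), levels = names(vals))
  if (all(normal)) {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1L]]
    tk <- as.data.frame(stats::TukeyHSD(fit)$g)
    tk$pair <- rownames(tk); rownames(tk) <- NULL
    out <- list(test = "one-way ANOVA + Tukey",
                statistic = an[["F value"]][1L],
                p_value = an[["Pr(>F)"]][1L], posthoc = tk)
  } else {
    ht <- stats::kruskal.test(y, g)
    out <- list(test = "Kruskal-Wallis", statistic = unname(ht$statistic),
                p_value = ht$p.value, posthoc = NULL)
  }
  structure(c(out, list(normal = normal, alpha = alpha)),
            class = "multi_group_comparison")
}

#' @export
print.multi_group_comparison <- function(x, ...) {
  cat(sprintf("multi_group_comparison: %s, statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  invisible(x)
}

#' Per-bin comparison of two sets of per-movie distributions
#'
#' For each histogram bin, compares the per-movie probabilities between the
#' two groups with Wilcoxon's rank-sum test (sign-rank when `paired`) at
#' level `alpha`, uncorrected. Also reports the maximum absolute difference
#' between the group-averaged CDFs, and, when the underlying pooled pair
#' values are supplied, a two-sample Kolmogorov-Smirnov test on them.
#'
#' @param a,b matrices of per-movie bin probabilities (movies x bins, same
#'   bins), or lists of `metric_distribution` objects.
#' @param paired use the sign-rank test per bin.
#' @param alpha per-bin significance level (uncorrected).
#' @param values_a,values_b optional pooled raw pair values for the KS test.
#' @return list of class `bin_test`: `p_values`, `significant` (logical mask,
#'   one per bin), `d_mean_cdf`, `ks` (htest or `NULL`), `alpha`.
#' @export
per_bin_distribution_test <- function(a, b, paired = FALSE, alpha = 0.05,
                                      values_a = NULL, values_b = NULL) {
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, function(d) d$prob))
  }
  ma <- as_mat(a); mb <- as_mat(b)
  if (ncol(ma) != ncol(mb)) stop("mismatched bins between groups")
  p <- vapply(seq_len(ncol(ma)), function(k) {
    xa <- ma[, k]; xb <- mb[, k]
    if (stats::sd(c(xa, xb)) == 0) return(1)
    suppressWarnings(
      if (paired) stats::wilcox.test(xa, xb, paired = TRUE)$p.value
      else stats::wilcox.test(xa, xb)$p.value)
  }, numeric(1))
  cdf_a <- cumsum(colMeans(ma)); cdf_b <- cumsum(colMeans(mb))
  ks <- if (!is.null(values_a) && !is.null(values_b))
    suppressWarnings(stats::ks.test(values_a, values_b)) else NULL
  structure(list(p_values = p, significant = p < alpha,
                 d_mean_cdf = max(abs(cdf_a - cdf_b)), ks = ks,
                 alpha = alpha, corrected = FALSE),
            class = "bin_test")
}

## ---- reporting -------------------------------------------------------------

#' Write summaries and comparisons to disk
#'
#' Writes the scalar per-movie table as CSV and the full summaries plus any
#' comparisons as JSON. The JSON round-trips: reading it back reproduces the
#' scalar content.
#'
#' @param summaries a `cohort_summary`, or a list of `movie_summary`.
#' @param comparisons optional named list of comparison objects.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
report <- function(summaries, comparisons = NULL, outdir) {
  if (inherits(summaries, "cohort_summary")) {
    tab <- summaries$table
    sums <- summaries$summaries
  } else {
    if (!length(summaries)) stop("empty summary list")
    sums <- summaries
    tab <- do.call(rbind, lapply(sums, function(s)
      cbind(data.frame(movie_id = s$label,
                       group = if (is.null(s$group)) NA_character_ else s$group),
            as.data.frame(s[summary_scalar_fields]))))
  }
  if (!nrow(tab)) stop("empty summary list")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  csv_path <- file.path(outdir, "movie_summaries.csv")
  json_path <- file.path(outdir, "report.json")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  strip <- function(s) {
    s <- unclass(s)
    s$r_distribution <- if (!is.null(s$r_distribution)) unclass(s$r_distribution)
    s$q_distribution <- if (!is.null(s$q_distribution)) unclass(s$q_distribution)
    s
  }
  payload <- list(summaries = lapply(sums, strip),
                  comparisons = lapply(comparisons, unclass))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv_path, json = json_path))
}
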