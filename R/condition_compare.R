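#' Pearson correlation between two PSTH matrices
#'
#' Correlates the two conditions' smoothed PSTHs pooled over all directions
#' and time bins; the standard consistency check between a stimulus condition
#' and its control (e.g. fixation vs total darkness). Cells missing in either
#' matrix are excluded pairwise.
#'
#' @param psth_a,psth_b `psth_matrix` objects of identical shape.
#' @param smoothed Correlate smoothed (default) or raw matrices.
#' @return One-row tibble: `r`, `p`, `n`, `defined`.
#' @export
psth_correlation <- function(psth_a, psth_b, smoothed = TRUE) {
  a <- if (smoothed) psth_a$smoothed else psth_a$rates
  b <- if (smoothed) psth_b$smoothed else psth_b$rates
  if (!all(dim(a) == dim(b)))
    stop("PSTH matrices must have identical shape")
  x <- as.vector(a); y <- as.vector(b)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x),
                          defined = FALSE))
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 defined = TRUE)
}

#' Maximal firing rate of a neuron
#'
#' The maximum over directions and analysis windows of the trial-mean
#' windowed rate; the response-strength metric used for cross-condition
#' comparisons.
#'
#' @param windowed A [sliding_window_rates()] array.
#' @return Spikes/s.
#' @export
max_firing_rate <- function(windowed) {
  max(rowMeans(windowed, dims = 2))
}

#' Paired population comparison of a metric across two conditions
#'
#' Pearson correlation plus a two-sided paired t-test between per-neuron
#' metric values measured in two conditions (e.g. DDI under fixation vs
#' darkness).
#'
#' @param metric_a,metric_b Equal-length numeric vectors (>= 3 pairs).
#' @return One-row tibble: `pearson_r`, `pearson_p`, `paired_p`,
#'   `mean_diff`, `n`. Degenerate inputs (zero variance of the differences or
#'   of either vector) yield `NA` for the affected statistic.
#' @export
paired_population_comparison <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("metric vectors must have equal length")
  ok <- is.finite(metric_a) & is.finite(metric_b)
  a <- metric_a[ok]; b <- metric_b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  r <- p_r <- p_t <- NA_real_
  if (stats::sd(a) > 0 && stats::sd(b) > 0) {
    ct <- stats::cor.test(a, b)
    r <- unname(ct$estimate); p_r <- ct$p.value
  }
  if (stats::sd(a - b) > 0) {
    p_t <- stats::t.test(a, b, paired = TRUE)$p.value
  }
  tibble::tibble(pearson_r = r, pearson_p = p_r, paired_p = p_t,
                 mean_diff = mean(a - b), n = length(a))
}

#' Compare one neuron across two recording conditions
#'
#' Computes the full pairwise comparison used for control analyses: PSTH
#' correlation, per-condition DDI, and per-condition maximal firing rate.
#'
#' @param rec_a,rec_b [neuron_recording()] objects for the two conditions.
#' @param bin_width,smooth_width PSTH parameters (see [build_psth()]).
#' @param window,step Analysis-window parameters
#'   (see [sliding_window_rates()]).
#' @return One-row tibble: `neuron_id`, `condition_a`, `condition_b`,
#'   `psth_r`, `psth_p`, `ddi_a`, `ddi_b`, `maxfr_a`, `maxfr_b`.
#' @export
compare_conditions <- function(rec_a, rec_b, bin_width = 0.025,
                               smooth_width = 0.3, window = 0.3,
                               step = 0.025) {
  pa <- build_psth(rec_a, bin_width, smooth_width)
  pb <- build_psth(rec_b, bin_width, smooth_width)
  wa <- sliding_window_rates(rec_a, window, step)
  wb <- sliding_window_rates(rec_b, window, step)
  pr <- psth_correlation(pa, pb)
  tibble::tibble(
    neuron_id = rec_a$neuron_id,
    condition_a = rec_a$condition, condition_b = rec_b$condition,
    psth_r = pr$r, psth_p = pr$p,
    ddi_a = compute_ddi(wa)$ddi, ddi_b = compute_ddi(wb)$ddi,
    maxfr_a = max_firing_rate(wa), maxfr_b = max_firing_rate(wb)
  )
}
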