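#' Run the full tuning screen on one neuron
#'
#' Applies, in order: the temporal-tuning rank-sum run criterion, the
#' per-window ANOVA across directions with peak counting, the DDI with its
#' permutation test, and the vector-sum preferred direction (first peak
#' window). Mirrors the per-neuron characterization pipeline used for
#' population summaries.
#'
#' @param rec A [neuron_recording()].
#' @param grid Direction grid.
#' @param alpha Significance level for the rank-sum and ANOVA screens
#'   (default 0.01).
#' @param min_run Consecutive-window requirement (default 5).
#' @param n_perm DDI permutations (default 1000).
#' @param seed Seed for the permutation test.
#' @param window,step Analysis-window parameters.
#' @return One-row tibble: `neuron_id`, `condition`, `temporally_tuned`,
#'   `spatially_tuned`, `n_peaks`, `ddi`, `ddi_p`, `pref_azimuth_deg`,
#'   `pref_elevation_deg`, `pref_magnitude`, `max_firing_rate`. The
#'   preferred direction is reported only for spatially tuned neurons with a
#'   nonzero resultant; otherwise `NA`.
#' @export
screen_neuron <- function(rec, grid, alpha = 0.01, min_run = 5,
                          n_perm = 1000, seed = 1, window = 0.3,
                          step = 0.025) {
  windowed <- sliding_window_rates(rec, window, step)
  spont <- spontaneous_rates(rec)
  tt <- temporal_tuning_test(windowed, spont, grid, alpha = alpha,
                             min_run = min_run)
  ap <- spatial_anova(windowed)
  pk <- count_peaks(windowed, ap, alpha = alpha)
  spatially_tuned <- pk$n_peaks > 0
  dd <- compute_ddi(windowed)
  dp <- ddi_permutation_test(windowed, n_perm = n_perm, seed = seed)
  pref <- tibble::tibble(azimuth_deg = NA_real_, elevation_deg = NA_real_,
                         magnitude = NA_real_)
  if (spatially_tuned) {
    pd <- preferred_direction(windowed, grid, pk$peak_windows)
    if (pd$defined) pref <- pd[c("azimuth_deg", "elevation_deg", "magnitude")]
  }
  tibble::tibble(
    neuron_id = rec$neuron_id, condition = rec$condition,
    temporally_tuned = tt$tuned,
    spatially_tuned = spatially_tuned,
    n_peaks = pk$n_peaks,
    ddi = dd$ddi, ddi_p = dp$p,
    pref_azimuth_deg = pref$azimuth_deg,
    pref_elevation_deg = pref$elevation_deg,
    pref_magnitude = pref$magnitude,
    max_firing_rate = max_firing_rate(windowed)
  )
}

#' Screen a population of recordings
#'
#' @param recordings List of [neuron_recording()] objects.
#' @param grid Direction grid.
#' @param seed Master seed; per-neuron permutation seeds are derived from it.
#' @param ... Passed to [screen_neuron()].
#' @return Tibble with one row per recording (see [screen_neuron()]).
#' @export
screen_population <- function(recordings, grid, seed = 1, ...) {
  seeds <- derive_seeds(seed, length(recordings))
  purrr::list_rbind(purrr::imap(
    recordings,
    function(rec, i) screen_neuron(rec, grid, seed = seeds[i], ...)
  ))
}
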