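#' Peristimulus time histogram (PSTH) matrix
#'
#' Bins each direction's trial-pooled spikes over the stimulus epoch
#' `[0, duration)` into `bin_width` bins (default 25 ms), converts to
#' trial-averaged spikes/s, and smooths each direction's trace with a
#' Gaussian filter of total width `smooth_width` (default 300 ms: kernel
#' truncated at +/- 150 ms, SD = `smooth_width / 6` = 50 ms, renormalized to
#' unit sum inside the data range so edge rates are unbiased).
#'
#' @param rec A [neuron_recording()].
#' @param bin_width Bin width, seconds; must divide the epoch duration.
#' @param smooth_width Total width of the Gaussian smoothing filter, seconds.
#' @return Object of class `psth_matrix`: list with `rates` and `smoothed`
#'   (directions x bins, spikes/s), `bin_centers`, `bin_width`, `n_trials`,
#'   `duration`, `neuron_id`, `condition`.
#' @export
build_psth <- function(rec, bin_width = 0.025, smooth_width = 0.3) {
  stopifnot(inherits(rec, "neuron_recording"))
  if (rec$n_trials < 1 || rec$n_directions < 1)
    stop("recording has no trials")
  dur <- rec$duration
  nb <- dur / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("`bin_width` must divide the epoch duration")
  nb <- as.integer(round(nb))
  breaks <- seq(0, dur, by = bin_width)
  rates <- matrix(0, rec$n_directions, nb)
  sp <- rec$spikes
  in_epoch <- sp$spike_time_s >= 0 & sp$spike_time_s < dur
  if (any(in_epoch)) {
    s <- sp[in_epoch, ]
    bin <- pmin(nb, as.integer(floor(s$spike_time_s / bin_width)) + 1L)
    counts <- table(factor(s$direction_index, levels = seq_len(rec$n_directions)),
                    factor(bin, levels = seq_len(nb)))
    rates <- unclass(counts) / (rec$n_trials * bin_width)
    dimnames(rates) <- NULL
  }
  smoothed <- gauss_smooth_rows(rates, bin_width, smooth_width)
  structure(
    list(rates = rates, smoothed = smoothed,
         bin_centers = breaks[-length(breaks)] + bin_width / 2,
         bin_width = bin_width, smooth_width = smooth_width,
         n_trials = rec$n_trials, duration = dur,
         neuron_id = rec$neuron_id, condition = rec$condition),
    class = "psth_matrix"
  )
}

# Gaussian smoothing of each matrix row; kernel support = width (truncated at
# +/- width/2), SD = width/6, renormalized within the data range at the edges
gauss_smooth_rows <- function(m, bin_width, width) {
  half <- as.integer(floor((width / 2) / bin_width))
  if (half < 1) return(m)
  sd_bins <- (width / 6) / bin_width
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  nb <- ncol(m)
  out <- matrix(0, nrow(m), nb)
  # renormalization weights: sum of kernel taps that fall inside the range
  for (j in seq_len(nb)) {
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= nb
    w <- k[ok] / sum(k[ok])
    out[, j] <- m[, idx[ok], drop = FALSE] %*% w
  }
  out
}

#' Construct a PSTH object from a precomputed rate matrix
#'
#' For workflows that start from an already-binned directions-by-time PSTH
#' (rather than spike events). Rates must be non-negative, in spikes/s.
#'
#' @param rates Directions x bins matrix, spikes/s.
#' @param bin_width Bin width, seconds.
#' @param smooth Apply the standard Gaussian smoothing (default TRUE); when
#'   FALSE the `smoothed` slot equals `rates`.
#' @param smooth_width Gaussian filter width, seconds.
#' @param n_trials Trials the matrix was averaged over (metadata only).
#' @param neuron_id,condition Labels.
#' @return A `psth_matrix`.
#' @export
psth_matrix <- function(rates, bin_width = 0.025, smooth = TRUE,
                        smooth_width = 0.3, n_trials = NA_integer_,
                        neuron_id = "n1", condition = "translation") {
  rates <- as.matrix(rates)
  if (any(rates < 0)) stop("rates must be non-negative")
  nb <- ncol(rates)
  duration <- nb * bin_width
  structure(
    list(rates = rates,
         smoothed = if (smooth) gauss_smooth_rows(rates, bin_width,
                                                  smooth_width) else rates,
         bin_centers = bin_width * (seq_len(nb) - 0.5),
         bin_width = bin_width, smooth_width = smooth_width,
         n_trials = n_trials, duration = duration,
         neuron_id = neuron_id, condition = condition),
    class = "psth_matrix"
  )
}

#' @export
print.psth_matrix <- function(x, ...) {
  cat(sprintf("<psth_matrix> %s [%s]: %d directions x %d bins (%.0f ms), peak %.1f spikes/s\n",
              x$neuron_id, x$condition, nrow(x$rates), ncol(x$rates),
              x$bin_width * 1000, max(x$smoothed)))
  invisible(x)
}

#' Tidy a PSTH matrix into a long tibble
#'
#' @param x A `psth_matrix`.
#' @param ... Unused.
#' @return Tibble with `direction_index`, `time_s`, `rate`, `smoothed_rate`.
#' @method tidy psth_matrix
#' @export
tidy.psth_matrix <- function(x, ...) {
  tibble::tibble(
    direction_index = rep(seq_len(nrow(x$rates)), times = ncol(x$rates)),
    time_s = rep(x$bin_centers, each = nrow(x$rates)),
    rate = as.vector(x$rates),
    smoothed_rate = as.vector(x$smoothed)
  )
}

#' Per-trial sliding-window firing rates
#'
#' Divides the stimulus epoch into overlapping analysis windows (default
#' 300 ms wide, stepped every 25 ms: 60 windows for a 1.5 s epoch, centred at
#' `step/2, 3*step/2, ...`) and computes each trial's mean rate in each
#' window. Edge windows extend into the recorded pre-/post-stimulus margins,
#' which must be long enough to cover them.
#'
#' @param rec A [neuron_recording()].
#' @param window Window length, seconds (> `step`).
#' @param step Step between window centres, seconds.
#' @return Object of class `windowed_rates`: a 3-d array
#'   directions x windows x trials (spikes/s) with attributes
#'   `window_centers`, `window`, `step`.
#' @export
sliding_window_rates <- function(rec, window = 0.3, step = 0.025) {
  stopifnot(inherits(rec, "neuron_recording"))
  if (window <= step) stop("`window` must exceed `step`")
  if (rec$n_trials < 1) stop("recording has no trials")
  dur <- rec$duration
  nw <- as.integer(round(dur / step))
  centers <- step / 2 + step * (seq_len(nw) - 1)
  lo <- centers - window / 2
  hi <- centers + window / 2
  need_pre <- -min(lo)
  need_post <- max(hi) - dur
  if (rec$pre_window < need_pre - 1e-9 || rec$post_window < need_post - 1e-9)
    stop(sprintf("pre/post recording margins (%.3f/%.3f s) too short for edge windows (need %.3f/%.3f s)",
                 rec$pre_window, rec$post_window, need_pre, need_post))
  out <- array(0, dim = c(rec$n_directions, nw, rec$n_trials))
  sp <- rec$spikes
  if (nrow(sp) > 0) {
    key <- split(sp$spike_time_s,
                 list(d = sp$direction_index, tr = sp$trial), drop = FALSE)
    for (d in seq_len(rec$n_directions)) {
      for (tr in seq_len(rec$n_trials)) {
        st <- key[[paste(d, tr, sep = ".")]]
        if (length(st) == 0) next
        st <- sort(st)
        cnt <- findInterval(hi - 1e-12, st) - findInterval(lo - 1e-12, st)
        out[d, , tr] <- cnt / window
      }
    }
  }
  attr(out, "window_centers") <- centers
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "neuron_id") <- rec$neuron_id
  attr(out, "condition") <- rec$condition
  class(out) <- c("windowed_rates", class(out))
  out
}

#' Per-trial spontaneous firing rates
#'
#' Mean rate of each trial over the baseline span from 100 ms before to
#' 300 ms after stimulus onset.
#'
#' @param rec A [neuron_recording()] with `pre_window >= 0.1` s.
#' @return Matrix directions x trials of baseline rates, spikes/s.
#' @export
spontaneous_rates <- function(rec) {
  stopifnot(inherits(rec, "neuron_recording"))
  if (rec$pre_window < 0.1 - 1e-9)
    stop("spontaneous window needs >= 0.1 s of pre-stimulus recording, have ",
         rec$pre_window, " s")
  lo <- -0.1
  hi <- 0.3
  out <- matrix(0, rec$n_directions, rec$n_trials)
  sp <- rec$spikes
  keep <- sp$spike_time_s >= lo & sp$spike_time_s < hi
  if (any(keep)) {
    s <- sp[keep, ]
    cnt <- table(factor(s$direction_index, levels = seq_len(rec$n_directions)),
                 factor(s$trial, levels = seq_len(rec$n_trials)))
    out <- unclass(cnt) / (hi - lo)
    dimnames(out) <- NULL
  }
  out
}

#' Export a PSTH matrix as CSV
#'
#' First column is the direction index; remaining column names are the bin
#' centres in seconds.
#'
#' @param psth A `psth_matrix`.
#' @param path Output file.
#' @param smoothed Write the smoothed matrix (default) or the raw one.
#' @return `path`, invisibly.
#' @export
write_psth_csv <- function(psth, path, smoothed = TRUE) {
  m <- if (smoothed) psth$smoothed else psth$rates
  df <- data.frame(direction_index = seq_len(nrow(m)), m)
  names(df)[-1] <- sprintf("t%.4f", psth$bin_centers)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
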