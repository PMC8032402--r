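#' Trial-organized spike recording
#'
#' Constructor for the container holding one neuron's spike times per
#' direction and trial, together with the protocol metadata downstream
#' analyses need. Spike times are in seconds relative to stimulus onset and
#' must lie within `[-pre_window, duration + post_window]`.
#'
#' @param spikes Tibble with columns `direction_index`, `trial`,
#'   `spike_time_s`.
#' @param n_trials Trials per direction (all analyses assume a balanced
#'   design).
#' @param n_directions Number of grid directions (default 26).
#' @param duration Stimulus epoch length, seconds.
#' @param pre_window,post_window Recorded time before onset / after offset,
#'   seconds.
#' @param neuron_id,condition Labels carried into reports.
#' @param ground_truth Optional [model_params()] that generated the data.
#' @return An object of class `neuron_recording`.
#' @export
neuron_recording <- function(spikes, n_trials, n_directions = 26,
                             duration = 1.5, pre_window = 0.3,
                             post_window = 0.3, neuron_id = "n1",
                             condition = "translation",
                             ground_truth = NULL) {
  spikes <- tibble::as_tibble(spikes)
  need <- c("direction_index", "trial", "spike_time_s")
  if (!all(need %in% names(spikes)))
    stop("`spikes` needs columns: ", paste(need, collapse = ", "))
  if (nrow(spikes) > 0) {
    if (any(spikes$direction_index < 1 | spikes$direction_index > n_directions))
      stop("direction_index out of range 1..", n_directions)
    bad <- spikes$spike_time_s < -pre_window - 1e-9 |
      spikes$spike_time_s > duration + post_window + 1e-9
    if (any(bad))
      stop(sum(bad), " spike time(s) outside [-pre_window, duration + post_window]")
  }
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  structure(
    list(spikes = spikes, n_trials = as.integer(n_trials),
         n_directions = as.integer(n_directions), duration = duration,
         pre_window = pre_window, post_window = post_window,
         neuron_id = neuron_id, condition = condition,
         ground_truth = ground_truth),
    class = "neuron_recording"
  )
}

#' @export
print.neuron_recording <- function(x, ...) {
  cat(sprintf(
    "<neuron_recording> %s [%s]: %d directions x %d trials, %d spikes, epoch %.2fs (+%.2f/-%.2f)\n",
    x$neuron_id, x$condition, x$n_directions, x$n_trials,
    nrow(x$spikes), x$duration, x$pre_window, x$post_window))
  invisible(x)
}

#' Simulate a tuned neuron from ground-truth model parameters
#'
#' Draws trial-repeated spike trains from an inhomogeneous Poisson process
#' whose rate is the rectified spatiotemporal model evaluated along each grid
#' direction ([model_response()]), over the full recorded span
#' `[-pre_window, duration + post_window]`. Spikes are generated by thinning
#' against the per-direction maximum rate, which is exact for a bounded rate
#' function.
#'
#' @param params [model_params()] ground truth.
#' @param grid Direction grid.
#' @param profile [gaussian_velocity_profile()] motion profile; supplies the
#'   epoch duration and stimulus peak time.
#' @param n_trials Trials per direction (default 5).
#' @param baseline_rate Optional spontaneous rate, spikes/s; when given it
#'   replaces `params$FR0` in the generating rate.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param pre_window,post_window Recorded seconds before onset / after offset.
#' @param neuron_id,condition Labels.
#' @return A [neuron_recording()] with `ground_truth` attached.
#' @export
simulate_neuron <- function(params, grid, profile, n_trials = 5,
                            baseline_rate = NULL, seed = 1,
                            pre_window = 0.3, post_window = 0.3,
                            neuron_id = "n1", condition = "translation") {
  stopifnot(inherits(params, "model_params"))
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (!is.null(baseline_rate)) {
    if (baseline_rate < 0) stop("`baseline_rate` must be >= 0")
    params$FR0 <- baseline_rate
  }
  duration <- attr(profile, "duration")
  center <- attr(profile, "center")
  dt <- min(attr(profile, "dt"), 0.001)
  tt <- seq(-pre_window, duration + post_window, by = dt)
  rate <- model_response(params, grid, tt, center = center)

  spikes <- with_seed(seed, {
    rows <- vector("list", nrow(grid) * n_trials)
    k <- 0L
    for (d in seq_len(nrow(grid))) {
      r <- rate[d, ]
      lam_max <- max(r)
      span <- diff(range(tt))
      for (tr in seq_len(n_trials)) {
        k <- k + 1L
        st <- numeric(0)
        if (lam_max > 0) {
          n_cand <- stats::rpois(1, lam_max * span)
          if (n_cand > 0) {
            cand <- sort(stats::runif(n_cand, tt[1], tt[length(tt)]))
            lam <- stats::approx(tt, r, xout = cand)$y
            st <- cand[stats::runif(n_cand) < lam / lam_max]
          }
        }
        rows[[k]] <- tibble::tibble(direction_index = d, trial = tr,
                                    spike_time_s = st)
      }
    }
    dplyr::bind_rows(rows)
  })
  neuron_recording(spikes, n_trials = n_trials, n_directions = nrow(grid),
                   duration = duration, pre_window = pre_window,
                   post_window = post_window, neuron_id = neuron_id,
                   condition = condition, ground_truth = params)
}

#' Simulate an untuned (null) neuron
#'
#' Homogeneous Poisson firing at `baseline_rate` for every direction and
#' trial; the synthetic analogue of a spontaneously active but
#' stimulus-insensitive cell (and of the sound-control outcome, where no
#' neuron shows temporal tuning).
#'
#' @inheritParams simulate_neuron
#' @param baseline_rate Constant rate, spikes/s; >= 0.
#' @return A [neuron_recording()] (no `ground_truth`).
#' @export
simulate_null_neuron <- function(baseline_rate, grid, profile, n_trials = 5,
                                 seed = 1, pre_window = 0.3,
                                 post_window = 0.3, neuron_id = "n1",
                                 condition = "translation") {
  if (baseline_rate < 0) stop("`baseline_rate` must be >= 0")
  duration <- attr(profile, "duration")
  span <- pre_window + duration + post_window
  spikes <- with_seed(seed, {
    rows <- vector("list", nrow(grid) * n_trials)
    k <- 0L
    for (d in seq_len(nrow(grid))) {
      for (tr in seq_len(n_trials)) {
        k <- k + 1L
        n <- if (baseline_rate > 0) stats::rpois(1, baseline_rate * span) else 0L
        st <- if (n > 0)
          sort(stats::runif(n, -pre_window, duration + post_window))
        else numeric(0)
        rows[[k]] <- tibble::tibble(direction_index = d, trial = tr,
                                    spike_time_s = st)
      }
    }
    dplyr::bind_rows(rows)
  })
  neuron_recording(spikes, n_trials = n_trials, n_directions = nrow(grid),
                   duration = duration, pre_window = pre_window,
                   post_window = post_window, neuron_id = neuron_id,
                   condition = condition, ground_truth = NULL)
}

#' Simulate a population of neurons
#'
#' One recording per row of `population`; per-neuron seeds are derived
#' deterministically from the master seed so the population is reproducible
#' as a whole.
#'
#' @param population Tibble with one row per neuron: a `params` list-column
#'   ([model_params()] for tuned cells, `NULL` for null cells), and optional
#'   columns `n_trials` (default 5), `baseline_rate` (default: `params$FR0`,
#'   or 10 for null cells), `neuron_id`, `condition`.
#' @param grid,profile Shared protocol.
#' @param seed Master seed.
#' @param pre_window,post_window Recording margins, seconds.
#' @return List of [neuron_recording()] objects.
#' @export
simulate_population <- function(population, grid, profile, seed = 1,
                                pre_window = 0.3, post_window = 0.3) {
  population <- tibble::as_tibble(population)
  if (nrow(population) == 0) stop("`population` must have at least one row")
  if (!"params" %in% names(population))
    stop("`population` needs a `params` list-column (model_params or NULL)")
  n <- nrow(population)
  seeds <- derive_seeds(seed, n)
  col_or <- function(nm, default) {
    if (nm %in% names(population)) population[[nm]] else default
  }
  n_trials <- col_or("n_trials", rep(5L, n))
  ids <- col_or("neuron_id", sprintf("sim%03d", seq_len(n)))
  cond <- col_or("condition", rep("translation", n))
  lapply(seq_len(n), function(i) {
    p <- population$params[[i]]
    base <- if ("baseline_rate" %in% names(population))
      population$baseline_rate[i] else NA_real_
    if (is.null(p)) {
      simulate_null_neuron(ifelse(is.na(base), 10, base), grid, profile,
                           n_trials = n_trials[i], seed = seeds[i],
                           pre_window = pre_window, post_window = post_window,
                           neuron_id = ids[i], condition = cond[i])
    } else {
      simulate_neuron(p, grid, profile, n_trials = n_trials[i],
                      baseline_rate = if (is.na(base)) NULL else base,
                      seed = seeds[i], pre_window = pre_window,
                      post_window = post_window, neuron_id = ids[i],
                      condition = cond[i])
    }
  })
}
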