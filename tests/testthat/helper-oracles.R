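# Shared fixtures and independent oracle implementations for the test suite.
# The oracles below are written directly from the published equations, in
# deliberately naive loop form, independent of the package's vectorized code.

the_grid <- build_direction_grid()
the_profile <- translation_profile()
psth_times <- 0.025 * (1:60 - 0.5)

# ---- independent oracle: rectified spatiotemporal model, naive loops ----
oracle_model_response <- function(params, grid, times, center) {
  nd <- nrow(grid)
  out <- matrix(NA_real_, nd, length(times))
  K <- length(params$components)
  # per-component temporal kernels, unit peak, straight from the printed forms
  kern <- matrix(NA_real_, length(times), K)
  for (m in seq_len(K)) {
    vals <- numeric(length(times))
    for (ti in seq_along(times)) {
      u <- times[ti] - center - params$tau
      s <- params$sigma_t
      vals[ti] <- switch(params$components[m],
        V = exp(-u^2 / (2 * s^2)),
        A = (u / s^2) * exp(-u^2 / (2 * s^2)),
        J = -((u^2 - s^2) / s^4) * exp(-u^2 / (2 * s^2)),
        P = integrate(function(x) exp(-(x - params$tau)^2 / (2 * s^2)),
                      lower = -10, upper = u + params$tau,
                      rel.tol = 1e-12)$value
      )
    }
    kern[, m] <- vals / max(abs(vals))
  }
  for (d in seq_len(nd)) {
    for (ti in seq_along(times)) {
      acc <- 0
      for (m in seq_len(K)) {
        delta <- angular_separation(
          c(grid$azimuth_deg[d], grid$elevation_deg[d]),
          c(params$preferred$azimuth_deg[m], params$preferred$elevation_deg[m]))
        x <- cos(delta * pi / 180)
        o <- params$offsets[m]
        y <- o + (1 - abs(o)) * x
        acc <- acc + params$weights[m] * kern[ti, m] * y
      }
      out[d, ti] <- max(0, params$A * acc + params$FR0)
    }
  }
  out
}

# ---- independent oracle: DDI from the printed formula, naive loops ----
oracle_ddi <- function(windowed) {
  nd <- dim(windowed)[1]; nw <- dim(windowed)[2]; nt <- dim(windowed)[3]
  dirmean <- matrix(0, nd, nw)
  for (d in 1:nd) for (w in 1:nw) dirmean[d, w] <- mean(windowed[d, w, ])
  epoch_mean <- numeric(nd)
  for (d in 1:nd) epoch_mean[d] <- mean(dirmean[d, ])
  best_dir <- which.max(epoch_mean)
  best_win <- which.max(dirmean[best_dir, ])
  r_max <- dirmean[best_dir, best_win]
  r_min <- min(dirmean[setdiff(1:nd, best_dir), best_win])
  sse <- 0
  for (d in 1:nd) {
    mu <- mean(windowed[d, best_win, ])
    for (tr in 1:nt) sse <- sse + (windowed[d, best_win, tr] - mu)^2
  }
  n <- nd * nt
  (r_max - r_min) / (r_max - r_min + 2 * sqrt(sse / (n - nd)))
}

# windowed-rates array with arbitrary content, for formula-level tests
fake_windowed <- function(values, nd, nw, nt) {
  arr <- array(values, dim = c(nd, nw, nt))
  attr(arr, "window_centers") <- 0.025 / 2 + 0.025 * (seq_len(nw) - 1)
  attr(arr, "window") <- 0.3
  attr(arr, "step") <- 0.025
  class(arr) <- c("windowed_rates", class(arr))
  arr
}

# deterministic spike recording built directly from spike-time lists
recording_from_spikes <- function(spike_list, n_trials, duration = 1.5,
                                  pre_window = 0.3, post_window = 0.3) {
  rows <- list()
  for (d in seq_along(spike_list)) {
    for (tr in seq_along(spike_list[[d]])) {
      st <- spike_list[[d]][[tr]]
      if (length(st) > 0)
        rows[[length(rows) + 1]] <- tibble::tibble(
          direction_index = d, trial = tr, spike_time_s = st)
    }
  }
  spikes <- if (length(rows) > 0) dplyr::bind_rows(rows)
  else tibble::tibble(direction_index = integer(), trial = integer(),
                      spike_time_s = numeric())
  neuron_recording(spikes, n_trials = n_trials,
                   n_directions = length(spike_list), duration = duration,
                   pre_window = pre_window, post_window = post_window)
}

# a velocity-dominant tuned cell used across tests
example_tuned_params <- function(pref_az = 90, pref_el = 0, A = 60,
                                 FR0 = 10) {
  model_params(
    A = A, FR0 = FR0, tau = 0, sigma_t = profile_sigma(0.3, 1),
    weights = c(V = 0.8, A = 0.2),
    preferred = data.frame(azimuth_deg = c(pref_az, pref_az),
                           elevation_deg = c(pref_el, pref_el)),
    offsets = c(V = 0, A = 0))
}
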