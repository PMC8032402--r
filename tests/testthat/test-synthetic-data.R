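test_that("amplitude-zero simulation is homogeneous Poisson at baseline", {
  p <- model_params(A = 0, FR0 = 0, tau = 0, sigma_t = 0.18,
                    weights = c(V = 1),
                    preferred = data.frame(azimuth_deg = 0,
                                           elevation_deg = 0),
                    offsets = c(V = 0))
  rec <- simulate_neuron(p, the_grid, the_profile, n_trials = 5,
                         baseline_rate = 10, seed = 42,
                         pre_window = 0, post_window = 0)
  # expected count 10 spikes/s * 1.5 s * 130 trials = 1950, Poisson variance
  total <- nrow(rec$spikes)
  expect_lt(abs(total - 1950), 4 * sqrt(1950))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- example_tuned_params()
  r1 <- simulate_neuron(p, the_grid, the_profile, n_trials = 3, seed = 7)
  r2 <- simulate_neuron(p, the_grid, the_profile, n_trials = 3, seed = 7)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- simulate_neuron(p, the_grid, the_profile, n_trials = 3, seed = 8)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("velocity-only neuron fires ~A above baseline at preferred, clipped at antipode", {
  pref_idx <- which(the_grid$azimuth_deg == 90 & the_grid$elevation_deg == 0)
  anti_idx <- which(the_grid$azimuth_deg == 270 & the_grid$elevation_deg == 0)
  A <- 50; base <- 20
  p <- model_params(A = A, FR0 = base, tau = 0, sigma_t = 0.18,
                    weights = c(V = 1),
                    preferred = data.frame(azimuth_deg = 90,
                                           elevation_deg = 0),
                    offsets = c(V = 0))
  rec <- simulate_neuron(p, the_grid, the_profile, n_trials = 60, seed = 5)
  w <- sliding_window_rates(rec)
  dirmean <- rowMeans(w, dims = 2)
  peak_pref <- max(dirmean[pref_idx, ])
  peak_anti <- max(dirmean[anti_idx, ])
  # peak rate at preferred ~ base + A (window-averaged Gaussian is slightly
  # below its peak); antipode is rectified to 0 through the response but the
  # windowed max picks up baseline noise, so compare the difference to A
  expect_gt(peak_pref - peak_anti, 0.65 * A)
  expect_lt(peak_pref - peak_anti, 1.2 * A)
})

test_that("null neuron matches its homogeneous Poisson statistics", {
  expect_equal(nrow(simulate_null_neuron(0, the_grid, the_profile,
                                         n_trials = 3, seed = 1)$spikes), 0)
  rec <- simulate_null_neuron(20, the_grid, the_profile, n_trials = 5,
                              seed = 99)
  span <- 0.3 + 1.5 + 0.3
  per_dir <- tapply(rec$spikes$direction_index, rec$spikes$direction_index,
                    length) / (5 * span)
  se <- sqrt(20 / (5 * span))
  expect_true(all(abs(per_dir - 20) < 3.5 * se))
})

test_that("population simulation is reproducible row-per-row", {
  pop <- tibble::tibble(
    params = list(example_tuned_params(), NULL, example_tuned_params(0, 45)),
    n_trials = c(2L, 2L, 2L), baseline_rate = c(10, 15, 10))
  recs <- simulate_population(pop, the_grid, the_profile, seed = 3)
  expect_length(recs, 3)
  recs2 <- simulate_population(pop, the_grid, the_profile, seed = 3)
  expect_identical(lapply(recs, `[[`, "spikes"),
                   lapply(recs2, `[[`, "spikes"))
  expect_error(simulate_population(pop[0, ], the_grid, the_profile), "one row")
})

test_that("time-rescaled inter-spike intervals are exponential(1)", {
  # time-rescaling theorem: Lambda(t_i) - Lambda(t_{i-1}) ~ Exp(1) when the
  # spikes come from the claimed inhomogeneous rate
  p <- example_tuned_params()
  rec <- simulate_neuron(p, the_grid, the_profile, n_trials = 5, seed = 21)
  tt <- seq(-0.3, 1.8, by = 0.001)
  rate <- model_response(p, the_grid, tt, center = attr(the_profile, "center"))
  rescaled <- c()
  for (d in seq_len(26)) {
    Lam <- cumsum(rate[d, ]) * 0.001
    for (tr in 1:5) {
      st <- sort(rec$spikes$spike_time_s[rec$spikes$direction_index == d &
                                           rec$spikes$trial == tr])
      if (length(st) < 2) next
      L <- approx(tt, Lam, xout = st)$y
      rescaled <- c(rescaled, diff(L))
    }
  }
  ks <- suppressWarnings(ks.test(rescaled, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean spike count per trial equals the integrated rate", {
  p <- example_tuned_params()
  pref_idx <- which(the_grid$azimuth_deg == 90 & the_grid$elevation_deg == 0)
  one_dir <- the_grid[pref_idx, ]
  attr_adj <- attr(the_grid, "adjacency")
  # simulate many trials of the preferred direction only
  g1 <- the_grid[pref_idx, ]
  attr(g1, "adjacency") <- matrix(FALSE, 1, 1)
  rec <- simulate_neuron(p, g1, the_profile, n_trials = 1000, seed = 77)
  tt <- seq(-0.3, 1.8, by = 0.001)
  rate <- model_response(p, g1, tt, center = attr(the_profile, "center"))
  expected <- sum(rate[1, ]) * 0.001
  observed <- nrow(rec$spikes) / 1000
  # Monte-Carlo error of the per-trial mean over 1000 Poisson trials
  se <- sqrt(expected / 1000)
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("recordings reject spikes outside the recorded span", {
  bad <- tibble::tibble(direction_index = 1L, trial = 1L, spike_time_s = 2.5)
  expect_error(neuron_recording(bad, n_trials = 1), "outside")
  bad2 <- tibble::tibble(direction_index = 30L, trial = 1L,
                         spike_time_s = 0.5)
  expect_error(neuron_recording(bad2, n_trials = 1), "direction_index")
})
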