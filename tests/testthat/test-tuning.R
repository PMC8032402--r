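test_that("all-zero spike data is untuned without error", {
  rec <- recording_from_spikes(rep(list(list(numeric(0), numeric(0))), 26),
                               n_trials = 2)
  w <- sliding_window_rates(rec)
  sp <- spontaneous_rates(rec)
  tt <- temporal_tuning_test(w, sp, the_grid)
  expect_false(tt$tuned)
  expect_length(tt$qualifying_directions, 0)
})

test_that("a strongly modulated neuron passes the temporal screen", {
  p <- example_tuned_params(A = 40, FR0 = 10)  # peak ~4x baseline
  rec <- simulate_neuron(p, the_grid, the_profile, n_trials = 5, seed = 31)
  w <- sliding_window_rates(rec)
  sp <- spontaneous_rates(rec)
  tt <- temporal_tuning_test(w, sp, the_grid)
  expect_true(tt$tuned)
  # at least two qualifying directions (excited near the preferred axis or
  # suppressed near the antipode - the rank-sum test is two-sided)
  expect_gte(length(tt$qualifying_directions), 2)
})

test_that("single-trial recordings are rejected by the screens", {
  rec <- simulate_null_neuron(10, the_grid, the_profile, n_trials = 1,
                              seed = 1)
  w <- sliding_window_rates(rec)
  sp <- spontaneous_rates(rec)
  expect_error(temporal_tuning_test(w, sp, the_grid), "2 trials")
  expect_error(spatial_anova(w), "2 trials")
})

test_that("spatial ANOVA separates directions and handles degenerate input", {
  # identical rates everywhere: p = 1 by convention
  w0 <- fake_windowed(5, 26, 10, 4)
  expect_true(all(spatial_anova(w0) == 1))
  # one direction far above the rest: tiny p in every window
  w1 <- fake_windowed(stats::rnorm(26 * 10 * 4, 10, 1), 26, 10, 4)
  w1[7, , ] <- w1[7, , ] + 50
  expect_true(all(spatial_anova(w1) < 1e-6))
})

test_that("peak counting distinguishes single- and double-peak cells", {
  w0 <- fake_windowed(5, 26, 10, 4)
  pk0 <- count_peaks(w0, spatial_anova(w0))
  expect_equal(pk0$n_peaks, 0L)
  # velocity-like: one response epoch, consistent spatial vector
  pv <- example_tuned_params()
  rec <- simulate_neuron(pv, the_grid, the_profile, n_trials = 5, seed = 17)
  w <- sliding_window_rates(rec)
  pk <- count_peaks(w, spatial_anova(w))
  expect_equal(pk$n_peaks, 1L)
  # acceleration-like: two phases preferring opposite directions
  pa <- model_params(A = 60, FR0 = 15, tau = 0, sigma_t = 0.18,
                     weights = c(A = 1),
                     preferred = data.frame(azimuth_deg = 90,
                                            elevation_deg = 0),
                     offsets = c(A = 0))
  reca <- simulate_neuron(pa, the_grid, the_profile, n_trials = 8, seed = 18)
  wa <- sliding_window_rates(reca)
  pka <- count_peaks(wa, spatial_anova(wa))
  expect_equal(pka$n_peaks, 2L)
  # the two peak windows bracket the velocity peak and their direction
  # vectors anticorrelate
  dirmean <- rowMeans(wa, dims = 2)
  expect_lt(cor(dirmean[, pka$peak_windows[1]],
                dirmean[, pka$peak_windows[2]]), 0)
})

test_that("DDI reproduces hand-computed values and formula limits", {
  # R_max = 30, R_min = 10, SSE = 2600, N = 130, M = 26 -> 20/(20+10)
  nd <- 26; nt <- 5
  base <- matrix(10, nd, nt)
  base[1, ] <- 30                       # best direction, no within-dir noise
  # inject SSE = 2600 via symmetric deviations that keep the means intact:
  # add +/- delta pairs within each direction (delta^2 * 2 per pair)
  w <- array(0, dim = c(nd, 2, nt))
  w[, 2, ] <- base
  w[, 1, ] <- base                      # window 1 mirrors window 2, lower
  w[, 1, ] <- 0
  delta <- sqrt(2600 / (nd * 2))
  w[, 2, 1] <- w[, 2, 1] + delta
  w[, 2, 2] <- w[, 2, 2] - delta
  got <- compute_ddi(fake_windowed(w, nd, 2, nt))
  expect_equal(got$r_max, 30)
  expect_equal(got$r_min, 10)
  expect_equal(got$sse, 2600, tolerance = 1e-12)
  expect_equal(got$ddi, 20 / (20 + 2 * sqrt(2600 / 104)), tolerance = 1e-12)
  expect_equal(got$ddi, 2 / 3, tolerance = 1e-4)
  # SSE = 0 with R_max > R_min: DDI = 1
  w0 <- array(rep(base, each = 1), dim = c(nd, 1, nt))
  expect_equal(compute_ddi(fake_windowed(w0, nd, 1, nt))$ddi, 1)
  # R_max = R_min: DDI = 0
  wc <- array(stats::rnorm(26 * 1 * 5, 0, 1e-9) + 10, dim = c(nd, 1, nt))
  wc <- wc - wc + 10
  expect_equal(compute_ddi(fake_windowed(wc, nd, 1, nt))$ddi, 0)
  # precondition: N > M
  expect_error(compute_ddi(fake_windowed(1, 26, 3, 1)), "more total trials")
})

test_that("DDI equals the brute-force oracle on random instances", {
  for (s in 1:50) {
    set.seed(400 + s)
    nd <- sample(4:10, 1); nw <- sample(3:8, 1); nt <- sample(3:6, 1)
    w <- fake_windowed(stats::rgamma(nd * nw * nt, 4, 0.3), nd, nw, nt)
    expect_equal(compute_ddi(w)$ddi, oracle_ddi(w), tolerance = 1e-12)
  }
})

test_that("DDI is invariant to additive shifts and positive rescaling", {
  set.seed(5)
  w <- fake_windowed(stats::rgamma(26 * 10 * 5, 5, 0.2), 26, 10, 5)
  d0 <- compute_ddi(w)$ddi
  ws <- fake_windowed(as.vector(w) + 13, 26, 10, 5)
  expect_equal(compute_ddi(ws)$ddi, d0, tolerance = 1e-12)
  wr <- fake_windowed(as.vector(w) * 3.7, 26, 10, 5)
  expect_equal(compute_ddi(wr)$ddi, d0, tolerance = 1e-12)
})

test_that("DDI permutation test is seeded and maximal tuning gives minimal p", {
  # noise-free strongly tuned cell: no permutation can beat the observed DDI
  w <- array(1, dim = c(26, 5, 5))
  w[3, , ] <- 50
  w <- w + array(seq(0, 1e-4, length.out = 26 * 25), dim = c(26, 5, 5))
  wt <- fake_windowed(w, 26, 5, 5)
  res <- ddi_permutation_test(wt, n_perm = 500, seed = 3)
  expect_equal(res$p, 1 / 501, tolerance = 1e-12)
  res2 <- ddi_permutation_test(wt, n_perm = 500, seed = 3)
  expect_identical(res, res2)
  expect_error(ddi_permutation_test(wt, n_perm = 50), "at least 100")
})

test_that("preferred direction recovers exact and degenerate geometries", {
  # response in a single direction: preferred is that grid vector exactly
  w <- array(0, dim = c(26, 4, 3))
  w[9, 2, ] <- 20
  pd <- preferred_direction(fake_windowed(w, 26, 4, 3), the_grid,
                            peak_windows = 2)
  expect_true(pd$defined)
  expect_equal(pd$azimuth_deg, the_grid$azimuth_deg[9], tolerance = 1e-9)
  expect_equal(pd$elevation_deg, the_grid$elevation_deg[9], tolerance = 1e-9)
  # equal response everywhere: antipodal cancellation, undefined
  we <- fake_windowed(8, 26, 4, 3)
  pde <- preferred_direction(we, the_grid, peak_windows = 2)
  expect_false(pde$defined)
  expect_equal(pde$magnitude, 0)
  # cosine tuning about (45, 0) + uniform baseline: baseline cancels by grid
  # symmetry and the resultant lies along the preferred axis
  xyz <- as.matrix(the_grid[, c("x", "y", "z")])
  pref <- drop(vestuning:::sph_to_cart(45, 0))
  rates <- 10 + 5 * (xyz %*% pref)
  wc <- array(rep(rates, 4 * 3), dim = c(26, 4, 3))
  pdc <- preferred_direction(fake_windowed(wc, 26, 4, 3), the_grid,
                             peak_windows = 1)
  expect_equal(pdc$azimuth_deg, 45, tolerance = 1e-6)
  expect_equal(pdc$elevation_deg, 0, tolerance = 1e-6)
})

test_that("uniformity test flags concentration and passes uniform samples", {
  # all points identical: maximal resultant, minimal p
  same <- data.frame(azimuth_deg = rep(90, 40), elevation_deg = rep(0, 40))
  expect_lte(uniformity_test(same, n_resample = 2000, seed = 1)$p, 0.001)
  expect_error(uniformity_test(same[1:3, ]), ">= 10")
  # uniform-on-sphere samples: p above 0.05 in most seeds
  passes <- vapply(1:20, function(s) {
    set.seed(700 + s)
    z <- matrix(stats::rnorm(300 * 3), 300, 3)
    z <- z / sqrt(rowSums(z^2))
    sph <- t(apply(z, 1, function(v) vestuning:::cart_to_sph(v)))
    d <- data.frame(azimuth_deg = sph[, 1], elevation_deg = sph[, 2])
    uniformity_test(d, n_resample = 500, seed = s)$p > 0.05
  }, logical(1))
  expect_gte(mean(passes), 0.85)
})
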