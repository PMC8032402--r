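test_that("temporal kernels have the printed shapes and unit peaks", {
  times <- seq(0, 1.5, by = 0.0005)
  tau <- 0.05; sig <- 0.18; center <- 0.75
  k <- temporal_kernels(times, tau, sig, c("P", "V", "A", "J"),
                        center = center)
  # velocity kernel peaks at 1 exactly at t = center + tau
  expect_equal(unname(k[which.min(abs(times - (center + tau))), "V"]), 1)
  expect_equal(max(abs(k[, "A"])), 1)
  expect_equal(max(abs(k[, "J"])), 1)
  # position kernel: monotone nondecreasing with plateau 1
  expect_true(all(diff(k[, "P"]) >= -1e-12))
  expect_equal(max(k[, "P"]), 1)
  # jerk kernel is the time derivative of the acceleration kernel
  # (unnormalized, as printed)
  kr <- temporal_kernels(times, tau, sig, c("A", "J"), center = center,
                         normalize = FALSE)
  fd <- diff(kr[, "A"]) / diff(times)
  mid <- (kr[-1, "J"] + kr[-nrow(kr), "J"]) / 2
  expect_lt(max(abs(fd - mid)) / max(abs(kr[, "J"])), 1e-4)
  expect_error(temporal_kernels(times, 0, -1), "sigma_t")
})

test_that("spatial kernel implements y(x) = o + (1 - |o|) x on the cosine", {
  expect_equal(spatial_kernel(c(123, 45), c(20, -60), o = 1), 1)
  expect_equal(spatial_kernel(c(0, 0), c(0, 0), o = 0), 1)
  expect_equal(spatial_kernel(c(180, 0), c(0, 0), o = 0), -1)
  expect_equal(spatial_kernel(c(0, 0), c(0, 0), o = -0.5), 0)
  expect_equal(spatial_kernel(c(180, 0), c(0, 0), o = -0.5), -1)
  # 90 degrees off: x = 0, y = o
  expect_equal(spatial_kernel(c(90, 0), c(0, 0), o = 0.3), 0.3)
  expect_error(spatial_kernel(c(0, 0), c(0, 0), o = 1.5), "\\[-1, 1\\]")
})

test_that("model response is constant at baseline when A = 0 and clips at 0", {
  p0 <- model_params(A = 0, FR0 = 7, tau = 0, sigma_t = 0.18,
                     weights = c(V = 1),
                     preferred = data.frame(azimuth_deg = 0,
                                            elevation_deg = 0),
                     offsets = c(V = 0))
  r <- model_response(p0, the_grid, psth_times, center = 0.75)
  expect_true(all(r == 7))
  # velocity-only, no baseline: antipreferred direction is fully rectified
  p1 <- model_params(A = 30, FR0 = 0, tau = 0, sigma_t = 0.18,
                     weights = c(V = 1),
                     preferred = data.frame(azimuth_deg = 90,
                                            elevation_deg = 0),
                     offsets = c(V = 0))
  r1 <- model_response(p1, the_grid, psth_times, center = 0.75)
  anti <- which(the_grid$azimuth_deg == 270 & the_grid$elevation_deg == 0)
  pref <- which(the_grid$azimuth_deg == 90 & the_grid$elevation_deg == 0)
  expect_true(all(r1[anti, ] == 0))
  expect_equal(max(r1[pref, ]), 30, tolerance = 1e-6)
  expect_true(all(r1 >= 0))
})

test_that("model response matches a naive direct evaluation of the equations", {
  for (s in 1:20) {
    comps <- if (s %% 2 == 0) c("P", "V", "A", "J") else c("V", "A")
    p <- random_model_params(components = comps, A = 20 + 3 * s,
                             FR0 = s %% 5, tau = (s %% 7 - 3) / 30,
                             sigma_t = 0.12 + 0.01 * (s %% 4), seed = s)
    times <- seq(0.0125, 1.4875, length.out = 25)
    got <- model_response(p, the_grid, times, center = 0.75)
    want <- oracle_model_response(p, the_grid, times, center = 0.75)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("component contributions sum to the unrectified drive", {
  p <- random_model_params(seed = 9)
  contr <- component_contributions(p, the_grid, psth_times, center = 0.75)
  total <- Reduce(`+`, contr)
  full <- model_response(p, the_grid, psth_times, center = 0.75)
  expect_equal(pmax(total + p$FR0, 0), full, tolerance = 1e-12)
})

test_that("model parameter validation enforces the documented constraints", {
  pref2 <- data.frame(azimuth_deg = c(0, 0), elevation_deg = c(0, 0))
  expect_error(model_params(40, 10, 0, 0.18, c(V = 0.5, A = 0.3), pref2,
                            c(V = 0, A = 0)), "sum to 1")
  expect_error(model_params(40, 10, 0, 0.18, c(V = 1.2, A = -0.2), pref2,
                            c(V = 0, A = 0)), "non-negative")
  expect_error(model_params(-1, 10, 0, 0.18, c(V = 0.5, A = 0.5), pref2,
                            c(V = 0, A = 0)), "`A`")
  expect_error(model_params(40, 10, 0, 0.18, c(V = 0.5, A = 0.5), pref2,
                            c(V = 0, A = 2)), "offsets")
  expect_error(model_params(40, 10, 0, -0.1, c(V = 0.5, A = 0.5), pref2,
                            c(V = 0, A = 0)), "sigma_t")
})
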