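test_that("direction grid has the canonical 26-vector structure", {
  g <- the_grid
  expect_equal(nrow(g), 26)
  xyz <- as.matrix(g[, c("x", "y", "z")])
  expect_true(all(abs(sqrt(rowSums(xyz^2)) - 1) < 1e-12))
  # no duplicate vectors
  expect_equal(nrow(unique(round(xyz, 9))), 26)
  # 8 directions in the horizontal plane, poles appear exactly once each
  expect_equal(sum(g$elevation_deg == 0), 8)
  expect_equal(sum(g$elevation_deg == 90), 1)
  expect_equal(sum(g$elevation_deg == -90), 1)
  # closed under sign flip: 13 antipodal pairs
  has_antipode <- vapply(seq_len(26), function(i) {
    any(colSums((t(xyz) + xyz[i, ])^2) < 1e-18)
  }, logical(1))
  expect_true(all(has_antipode))
  # antipodal symmetry: vectors sum to zero
  expect_lt(sqrt(sum(colSums(xyz)^2)), 1e-9)
})

test_that("grid adjacency links lattice neighbours and nothing farther", {
  g <- the_grid
  adj <- grid_adjacency(g)
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  xyz <- as.matrix(g[, c("x", "y", "z")])
  sep <- acos(pmin(1, pmax(-1, tcrossprod(xyz)))) * 180 / pi
  expect_true(all(sep[adj] <= 45 + 1e-6))
  expect_true(all(sep[!adj & sep > 1e-6] > 45 + 1e-6))
  # poles touch the whole neighbouring ring
  pole_up <- which(g$elevation_deg == 90)
  expect_equal(sum(adj[pole_up, ]), 8)
})

test_that("angular separation reproduces known geometry", {
  expect_equal(angular_separation(c(30, 10), c(30, 10)), 0)
  expect_equal(angular_separation(c(0, 0), c(180, 0)), 180)
  expect_equal(angular_separation(c(0, 0), c(0, 90)), 90)
  expect_equal(angular_separation(c(0, 45), c(180, -45)), 180)
})

test_that("Gaussian velocity profile matches closed-form kinematics", {
  # translation protocol: peak speed 0.3 units/s, sigma chosen so that peak
  # acceleration is 1 units/s^2
  prof <- gaussian_velocity_profile(0.3, 0.1819, 1.5, 0.001)
  expect_equal(max(abs(prof$acceleration)), 1.0, tolerance = 1e-3)
  expect_equal(max(abs(prof$velocity)), 0.3, tolerance = 1e-9)
  # rotation protocol: 20 deg/s peak, sigma for 60 deg/s^2
  rot <- gaussian_velocity_profile(20, 0.2022, 1.5, 0.001)
  expect_equal(max(abs(rot$acceleration)), 60, tolerance = 0.1)
  # zero amplitude: all traces identically zero
  z <- gaussian_velocity_profile(0, 0.18, 1.5, 0.001)
  expect_true(all(z$velocity == 0 & z$acceleration == 0 &
                    z$jerk == 0 & z$position == 0))
})

test_that("profile traces are mutually consistent derivatives/integrals", {
  prof <- translation_profile(dt = 0.0005)
  dt <- attr(prof, "dt")
  # acceleration ~ finite-difference derivative of velocity
  fd_acc <- diff(prof$velocity) / dt
  mid_acc <- (prof$acceleration[-1] + prof$acceleration[-nrow(prof)]) / 2
  expect_lt(max(abs(fd_acc - mid_acc)) / max(abs(prof$acceleration)), 1e-4)
  # jerk ~ derivative of acceleration
  fd_jerk <- diff(prof$acceleration) / dt
  mid_jerk <- (prof$jerk[-1] + prof$jerk[-nrow(prof)]) / 2
  expect_lt(max(abs(fd_jerk - mid_jerk)) / max(abs(prof$jerk)), 1e-4)
  # position ~ trapezoid integral of velocity
  trap <- cumsum(c(0, (prof$velocity[-1] + prof$velocity[-nrow(prof)]) / 2 * dt))
  expect_lt(max(abs(trap + prof$position[1] - prof$position)) /
              max(prof$position), 1e-5)
  # net acceleration integrates to ~0; terminal displacement is the
  # Gaussian integral peak_speed * sigma * sqrt(2*pi)
  expect_lt(abs(sum(prof$acceleration) * dt), 1e-6)
  expect_equal(prof$position[nrow(prof)],
               0.3 * attr(prof, "sigma_s") * sqrt(2 * pi),
               tolerance = 0.01)
})

test_that("profile rejects invalid sampling parameters by name", {
  expect_error(gaussian_velocity_profile(0.3, 0.18, -1, 0.001), "duration")
  expect_error(gaussian_velocity_profile(0.3, 0.18, 1.5, 0), "dt")
  expect_error(gaussian_velocity_profile(0.3, 0.18, 1.5, 0.2), "sigma_s")
  expect_error(gaussian_velocity_profile(-1, 0.18, 1.5, 0.001), "peak_speed")
})

test_that("direction grid survives a CSV round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_direction_grid(the_grid, path)
  g2 <- read_direction_grid(path)
  expect_equal(as.data.frame(g2), as.data.frame(the_grid), tolerance = 1e-12)
  expect_equal(grid_adjacency(g2), grid_adjacency(the_grid))
})
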