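#' Build the 26-direction sampling grid for 3D self-motion stimuli
#'
#' Constructs the standard set of 26 motion vectors equally distributed in 3D
#' space: all combinations of azimuth \{0, 45, ..., 315\} degrees with
#' elevation \{-45, 0, +45\} degrees (24 vectors) plus the two poles at
#' elevation -90 and +90 (one vector each, azimuth fixed at 0). The same grid
#' serves as translation directions or as rotation axes (right-hand rule).
#'
#' Coordinate convention: azimuth 0 is straight ahead, azimuth 90 is leftward,
#' elevation +90 is upward. Cartesian coordinates are
#' `x = cos(el) cos(az)` (forward), `y = cos(el) sin(az)` (leftward),
#' `z = sin(el)` (up). Rows are ordered elevation-major (-90, -45, 0, +45,
#' +90) with azimuth ascending within each elevation ring; this canonical
#' order is stable across sessions and file round-trips.
#'
#' Two directions are *adjacent* when they are lattice neighbours on the
#' sampled sphere, i.e. separated by at most 45 degrees of arc (azimuth
#' neighbours within a ring, elevation neighbours at the same azimuth, and
#' each pole with the whole neighbouring ring). Retrieve the relation with
#' [grid_adjacency()].
#'
#' @return A tibble of class `direction_grid` with 26 rows and columns
#'   `direction_index` (1-26), `azimuth_deg`, `elevation_deg`, `x`, `y`, `z`,
#'   carrying the adjacency matrix as attribute `"adjacency"`.
#' @examples
#' grid <- build_direction_grid()
#' nrow(grid)                       # 26
#' sum(grid$elevation_deg == 0)     # 8 directions in the horizontal plane
#' @export
build_direction_grid <- function() {
  ring_az <- seq(0, 315, by = 45)
  tab <- rbind(
    data.frame(azimuth_deg = 0, elevation_deg = -90),
    data.frame(azimuth_deg = ring_az, elevation_deg = -45),
    data.frame(azimuth_deg = ring_az, elevation_deg = 0),
    data.frame(azimuth_deg = ring_az, elevation_deg = 45),
    data.frame(azimuth_deg = 0, elevation_deg = 90)
  )
  xyz <- sph_to_cart(tab$azimuth_deg, tab$elevation_deg)
  grid <- tibble::tibble(
    direction_index = seq_len(nrow(tab)),
    azimuth_deg = tab$azimuth_deg,
    elevation_deg = tab$elevation_deg,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  attr(grid, "adjacency") <- make_adjacency(xyz)
  class(grid) <- c("direction_grid", class(grid))
  grid
}

#' Adjacency relation of a direction grid
#'
#' @param grid A `direction_grid` from [build_direction_grid()] (or any tibble
#'   with `x`, `y`, `z` unit vectors).
#' @return A symmetric logical matrix; entry `[i, j]` is `TRUE` when
#'   directions `i` and `j` are lattice neighbours (angular separation
#'   no larger than 45 degrees).
#' @export
grid_adjacency <- function(grid) {
  adj <- attr(grid, "adjacency")
  if (!is.null(adj)) return(adj)
  make_adjacency(as.matrix(grid[, c("x", "y", "z")]))
}

# lattice-neighbour relation: pairs separated by <= 45 degrees of arc
# (tolerances sized so that CSV-rounded coordinates give the same relation)
make_adjacency <- function(xyz) {
  xyz <- xyz / sqrt(rowSums(xyz^2))
  sep <- angular_separation_matrix(xyz)
  adj <- sep > 1e-3 & sep <= 45 + 1e-3
  diag(adj) <- FALSE
  adj
}

sph_to_cart <- function(azimuth_deg, elevation_deg) {
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  cbind(x = cos(el) * cos(az), y = cos(el) * sin(az), z = sin(el))
}

cart_to_sph <- function(v) {
  v <- unname(v)
  az <- atan2(v[2], v[1]) * 180 / pi
  if (az < 0) az <- az + 360
  el <- asin(max(-1, min(1, v[3] / sqrt(sum(v^2))))) * 180 / pi
  c(azimuth_deg = az, elevation_deg = el)
}

angular_separation_matrix <- function(xyz) {
  dots <- tcrossprod(xyz)
  dots[dots > 1] <- 1
  dots[dots < -1] <- -1
  acos(dots) * 180 / pi
}

#' Great-circle angle between two directions
#'
#' @param a,b Directions as `(azimuth, elevation)` pairs in degrees.
#' @return Angular separation in degrees, in \[0, 180\].
#' @examples
#' angular_separation(c(0, 0), c(180, 0))  # 180
#' angular_separation(c(0, 0), c(0, 90))   # 90
#' @export
angular_separation <- function(a, b) {
  u <- sph_to_cart(a[1], a[2])
  v <- sph_to_cart(b[1], b[2])
  d <- sum(u * v)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Gaussian-velocity motion profile
#'
#' Builds the kinematics of one stimulus epoch: a Gaussian velocity pulse
#' centred at `duration / 2`, with its analytically derived biphasic
#' acceleration, triphasic jerk, and sigmoidal position traces. These are the
#' motion profiles delivered by the platform in both the translation
#' (peak speed ~0.3 m/s, peak acceleration 1 m/s^2) and rotation
#' (peak ~20 deg/s, 60 deg/s^2) protocols.
#'
#' @param peak_speed Peak of the velocity Gaussian (profile units/s); >= 0.
#' @param sigma_s Width (SD) of the velocity Gaussian, seconds. The default
#'   protocols do not print it; derive it from the printed peak speed and peak
#'   acceleration with [profile_sigma()].
#' @param duration Epoch length in seconds (default 1.5).
#' @param dt Sampling step in seconds; must satisfy `0 < dt < sigma_s`.
#' @return A tibble of class `motion_profile` with columns `time_s`,
#'   `position`, `velocity`, `acceleration`, `jerk`, sampled on
#'   `[0, duration]`, and attributes `peak_speed`, `sigma_s`, `duration`,
#'   `dt`, `center` (= duration/2), `onset_time` (= 0).
#' @examples
#' prof <- gaussian_velocity_profile(0.3, profile_sigma(0.3, 1), 1.5, 0.001)
#' max(abs(prof$acceleration))  # ~1 m/s^2
#' @export
gaussian_velocity_profile <- function(peak_speed,
                                      sigma_s,
                                      duration = 1.5,
                                      dt = 0.001) {
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive, got ", duration)
  if (!is.finite(dt) || dt <= 0)
    stop("`dt` must be positive, got ", dt)
  if (!is.finite(sigma_s) || sigma_s <= 0)
    stop("`sigma_s` must be positive, got ", sigma_s)
  if (dt >= sigma_s)
    stop("`dt` (", dt, ") must be smaller than `sigma_s` (", sigma_s, ")")
  if (peak_speed < 0)
    stop("`peak_speed` must be non-negative, got ", peak_speed)

  times <- seq(0, duration, by = dt)
  center <- duration / 2
  u <- (times - center) / sigma_s
  g <- exp(-u^2 / 2)
  velocity <- peak_speed * g
  acceleration <- -peak_speed * u / sigma_s * g
  jerk <- peak_speed * (u^2 - 1) / sigma_s^2 * g
  position <- peak_speed * sigma_s * sqrt(2 * pi) * stats::pnorm(u)

  prof <- tibble::tibble(
    time_s = times, position = position, velocity = velocity,
    acceleration = acceleration, jerk = jerk
  )
  attr(prof, "peak_speed") <- peak_speed
  attr(prof, "sigma_s") <- sigma_s
  attr(prof, "duration") <- duration
  attr(prof, "dt") <- dt
  attr(prof, "center") <- center
  attr(prof, "onset_time") <- 0
  class(prof) <- c("motion_profile", class(prof))
  prof
}

#' Velocity-Gaussian width implied by printed peak kinematics
#'
#' For a Gaussian velocity pulse the peak acceleration is
#' `peak_speed * exp(-1/2) / sigma`, so the width consistent with a printed
#' (peak speed, peak acceleration) pair is
#' `sigma = peak_speed * exp(-1/2) / peak_acceleration`:
#' ~0.182 s for the translation protocol (0.3 m/s, 1 m/s^2) and
#' ~0.202 s for the rotation protocol (20 deg/s, 60 deg/s^2).
#'
#' @param peak_speed Peak speed, profile units/s.
#' @param peak_acceleration Peak acceleration, profile units/s^2.
#' @return Width in seconds.
#' @export
profile_sigma <- function(peak_speed, peak_acceleration) {
  if (peak_speed <= 0 || peak_acceleration <= 0)
    stop("peak_speed and peak_acceleration must be positive")
  peak_speed * exp(-0.5) / peak_acceleration
}

#' Default translation-protocol motion profile (0.3 m/s, 1 m/s^2, 1.5 s)
#' @param dt Sampling step, seconds.
#' @return A `motion_profile`.
#' @export
translation_profile <- function(dt = 0.001) {
  gaussian_velocity_profile(0.3, profile_sigma(0.3, 1), 1.5, dt)
}

#' Default rotation-protocol motion profile (20 deg/s, 60 deg/s^2, 1.5 s)
#' @param dt Sampling step, seconds.
#' @return A `motion_profile`.
#' @export
rotation_profile <- function(dt = 0.001) {
  gaussian_velocity_profile(20, profile_sigma(20, 60), 1.5, dt)
}

#' Write / read a direction grid as CSV
#'
#' Round-trips the 26-row table (index, azimuth_deg, elevation_deg, x, y, z);
#' adjacency is recomputed on read.
#'
#' @param grid A `direction_grid`.
#' @param path File path.
#' @return `write_direction_grid()` returns `path` invisibly;
#'   `read_direction_grid()` returns a `direction_grid`.
#' @export
write_direction_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_direction_grid
#' @export
read_direction_grid <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("direction_index", "azimuth_deg", "elevation_deg", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("grid file must have columns: ", paste(need, collapse = ", "))
  grid <- tibble::as_tibble(tab[need])
  attr(grid, "adjacency") <- make_adjacency(as.matrix(grid[, c("x", "y", "z")]))
  class(grid) <- c("direction_grid", class(grid))
  grid
}
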