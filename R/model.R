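#' Spatiotemporal receptive-field model parameters
#'
#' Container for the parameters of the rectified spatiotemporal response
#' model. The firing rate along direction `(theta, phi)` at time `t` is
#'
#' \deqn{R(\theta,\phi,t) = \left[A \sum_m w_m f_m(t-\tau)\,
#'   y_m(\cos\Delta_m) + FR_0\right]_+}
#'
#' where `m` runs over the model's temporal components (a subset of position
#' `P`, velocity `V`, acceleration `A`, jerk `J`), `f_m` are unit-peak
#' temporal kernels sharing one width `sigma_t` and delay `tau`,
#' `cos(Delta_m)` is the cosine of the angle between the stimulus direction
#' and component `m`'s preferred direction, `y(x) = o + (1 - |o|) x` reshapes
#' the cosine tuning (offset `o` in \[-1, 1\]), and `[.]_+` sets any negative
#' rate to zero.
#'
#' @param A Response amplitude, spikes/s; >= 0.
#' @param FR0 Baseline (spontaneous) rate, spikes/s; >= 0.
#' @param tau Response delay in seconds relative to the stimulus peak.
#' @param sigma_t Temporal kernel width (SD), seconds; > 0.
#' @param weights Named non-negative weights over components, names from
#'   `c("P", "V", "A", "J")`; must sum to 1 (small numerical error is
#'   renormalized away).
#' @param preferred Matrix or data frame with one row per component (same
#'   order as `weights`) and columns `azimuth_deg`, `elevation_deg`: each
#'   component's preferred direction.
#' @param offsets Named numeric in \[-1, 1\], one per component: the spatial
#'   tuning offset `o`.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(
#'   A = 40, FR0 = 10, tau = 0, sigma_t = 0.18,
#'   weights = c(V = 0.7, A = 0.3),
#'   preferred = data.frame(azimuth_deg = c(90, 90), elevation_deg = c(0, 0)),
#'   offsets = c(V = 0, A = 0)
#' )
#' @export
model_params <- function(A, FR0, tau, sigma_t, weights, preferred, offsets) {
  comps <- names(weights)
  if (is.null(comps) || !all(comps %in% c("P", "V", "A", "J")) ||
      anyDuplicated(comps))
    stop("`weights` must be uniquely named with components from P, V, A, J")
  if (any(weights < -1e-12)) stop("component weights must be non-negative")
  weights <- pmax(weights, 0)
  s <- sum(weights)
  if (abs(s - 1) > 1e-6) stop("component weights must sum to 1 (got ", s, ")")
  weights <- weights / s
  if (A < 0) stop("`A` must be non-negative")
  if (FR0 < 0) stop("`FR0` must be non-negative")
  if (sigma_t <= 0) stop("`sigma_t` must be positive")
  preferred <- as.data.frame(preferred)
  if (nrow(preferred) != length(comps))
    stop("`preferred` must have one row per component")
  if (!all(c("azimuth_deg", "elevation_deg") %in% names(preferred)))
    stop("`preferred` needs columns azimuth_deg, elevation_deg")
  offsets <- offsets[comps]
  if (any(is.na(offsets)) || any(abs(offsets) > 1 + 1e-12))
    stop("offsets must be named per component and lie in [-1, 1]")
  offsets <- pmin(1, pmax(-1, offsets))
  structure(
    list(A = A, FR0 = FR0, tau = tau, sigma_t = sigma_t,
         components = comps, weights = weights,
         preferred = tibble::as_tibble(preferred[c("azimuth_deg",
                                                   "elevation_deg")]),
         offsets = offsets),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> components:", paste(x$components, collapse = ""),
      sprintf("| A=%.3g FR0=%.3g tau=%.3gs sigma_t=%.3gs\n",
              x$A, x$FR0, x$tau, x$sigma_t))
  for (i in seq_along(x$components)) {
    cat(sprintf("  %s: w=%.3f pref=(%.1f, %.1f) o=%+.2f\n",
                x$components[i], x$weights[i],
                x$preferred$azimuth_deg[i], x$preferred$elevation_deg[i],
                x$offsets[i]))
  }
  invisible(x)
}

#' Temporal response kernels
#'
#' Evaluates the model's temporal kernels on a time base. With
#' `u = t - center - tau` and width `sigma_t`:
#' velocity `f_v = exp(-u^2 / 2 sigma^2)` (Gaussian, tracking stimulus
#' velocity); acceleration `f_a = (u / sigma^2) exp(-u^2 / 2 sigma^2)`
#' (biphasic); jerk `f_j = -((u^2 - sigma^2) / sigma^4) exp(-u^2 / 2 sigma^2)`
#' (triphasic, the time derivative of `f_a`); position
#' `f_p = integral of f_v` (sigmoidal). Each trace is rescaled to unit peak
#' magnitude over the supplied times so that component weights are
#' comparable.
#'
#' Note the kernel set is defined exactly in this printed form: `f_a` is the
#' negative of the calculus derivative of `f_v`. A sign flip is equivalent to
#' an antipodal flip of that component's preferred direction, so the
#' convention has no effect on the model class.
#'
#' @param times Numeric vector of times, seconds.
#' @param tau Delay, seconds.
#' @param sigma_t Kernel width, seconds; > 0.
#' @param components Character subset of `c("P", "V", "A", "J")`.
#' @param center Time of the stimulus velocity peak; defaults to the midpoint
#'   of `times` (the stimulus peaks at `duration / 2`).
#' @param normalize Rescale each kernel to `max(abs(.)) == 1` (default TRUE).
#' @return Matrix `length(times)` x `length(components)`, columns named.
#' @export
temporal_kernels <- function(times, tau, sigma_t,
                             components = c("P", "V", "A", "J"),
                             center = NULL, normalize = TRUE) {
  if (sigma_t <= 0) stop("`sigma_t` must be positive")
  if (!all(components %in% c("P", "V", "A", "J")))
    stop("components must be among P, V, A, J")
  center <- center %||% mean(range(times))
  u <- times - center - tau
  g <- exp(-u^2 / (2 * sigma_t^2))
  out <- vapply(components, function(m) {
    switch(m,
      V = g,
      A = u / sigma_t^2 * g,
      J = -(u^2 - sigma_t^2) / sigma_t^4 * g,
      P = sigma_t * sqrt(2 * pi) * stats::pnorm(u / sigma_t)
    )
  }, numeric(length(times)))
  out <- matrix(out, nrow = length(times),
                dimnames = list(NULL, components))
  if (normalize) {
    for (j in seq_len(ncol(out))) {
      pk <- max(abs(out[, j]))
      if (pk > 0) out[, j] <- out[, j] / pk
    }
  }
  out
}

#' Spatial tuning kernel
#'
#' Cosine tuning reshaped by the offset function `y(x) = o + (1 - |o|) x`,
#' where `x` is the cosine of the angular difference between the stimulus
#' direction and the preferred direction. `o = 0` gives pure cosine tuning;
#' `o -> 1` flattens it; negative `o` narrows it.
#'
#' @param direction `(azimuth, elevation)` in degrees, or a matrix/data frame
#'   of such rows.
#' @param preferred `(azimuth, elevation)` in degrees.
#' @param o Offset in \[-1, 1\].
#' @return Numeric value(s) in \[-1, 1\].
#' @export
spatial_kernel <- function(direction, preferred, o) {
  if (abs(o) > 1) stop("offset `o` must lie in [-1, 1]")
  dirs <- if (is.matrix(direction) || is.data.frame(direction)) {
    as.matrix(direction)
  } else matrix(direction, ncol = 2)
  u <- sph_to_cart(dirs[, 1], dirs[, 2])
  p <- drop(sph_to_cart(preferred[1], preferred[2]))
  x <- pmin(1, pmax(-1, u %*% p))
  drop(o + (1 - abs(o)) * x)
}

# cosine-similarity of grid unit vectors against one cartesian preferred
# direction, reshaped by the offset; xyz is the 26 x 3 grid matrix
spatial_kernel_cart <- function(xyz, pref_cart, o) {
  x <- pmin(1, pmax(-1, drop(xyz %*% pref_cart)))
  o + (1 - abs(o)) * x
}

#' Predicted direction-by-time response of the spatiotemporal model
#'
#' Evaluates the rectified model rate for every grid direction at every time:
#' `[A * sum_m w_m f_m(t - tau) y_m(cos Delta_m) + FR0]_+`.
#'
#' @param params A [model_params()] object.
#' @param grid A [build_direction_grid()] grid (defines rows).
#' @param times Time base in seconds (defines columns).
#' @param center Stimulus peak time; default `mean(range(times))`.
#' @return Matrix `nrow(grid)` x `length(times)` of non-negative rates,
#'   spikes/s.
#' @export
model_response <- function(params, grid, times, center = NULL) {
  stopifnot(inherits(params, "model_params"))
  drive <- model_drive(params, grid, times, center)
  resp <- params$A * drive + params$FR0
  resp[resp < 0] <- 0
  resp
}

# unrectified weighted sum of component drives, excluding A and FR0:
# sum_m w_m f_m(t) y_m(d); returns directions x times
model_drive <- function(params, grid, times, center = NULL) {
  ftk <- temporal_kernels(times, params$tau, params$sigma_t,
                          params$components, center = center)
  xyz <- as.matrix(grid[, c("x", "y", "z")])
  Ym <- vapply(seq_along(params$components), function(i) {
    p <- drop(sph_to_cart(params$preferred$azimuth_deg[i],
                          params$preferred$elevation_deg[i]))
    spatial_kernel_cart(xyz, p, params$offsets[i])
  }, numeric(nrow(xyz)))
  Yw <- sweep(matrix(Ym, nrow = nrow(xyz)), 2, params$weights, "*")
  Yw %*% t(ftk)
}

#' Per-component contributions to the modelled response
#'
#' Returns, for each temporal component, its unrectified contribution
#' `A * w_m * f_m(t - tau) * y_m(cos Delta_m)` (no baseline), as used for
#' component partial-correlation analysis.
#'
#' @inheritParams model_response
#' @return Named list of `nrow(grid)` x `length(times)` matrices.
#' @export
component_contributions <- function(params, grid, times, center = NULL) {
  ftk <- temporal_kernels(times, params$tau, params$sigma_t,
                          params$components, center = center)
  xyz <- as.matrix(grid[, c("x", "y", "z")])
  out <- lapply(seq_along(params$components), function(i) {
    p <- drop(sph_to_cart(params$preferred$azimuth_deg[i],
                          params$preferred$elevation_deg[i]))
    y <- spatial_kernel_cart(xyz, p, params$offsets[i])
    params$A * params$weights[i] * (y %*% t(ftk[, i, drop = FALSE]))
  })
  names(out) <- params$components
  out
}
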