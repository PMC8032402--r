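#' Draw random ground-truth model parameters
#'
#' Convenience generator for simulation studies: component weights are drawn
#' uniformly on the simplex, preferred directions uniformly on the sphere,
#' offsets uniformly in \[-0.5, 0.5\]; `tau = 0` and `sigma_t` equal to the
#' stimulus velocity width unless overridden.
#'
#' @param components Temporal components, default `c("P","V","A","J")`.
#' @param A,FR0 Amplitude and baseline, spikes/s.
#' @param tau Delay, seconds.
#' @param sigma_t Kernel width, seconds (default: translation-protocol
#'   stimulus width).
#' @param weights Optional fixed named weights; drawn randomly when `NULL`.
#' @param seed Integer seed.
#' @return A [model_params()] object.
#' @export
random_model_params <- function(components = c("P", "V", "A", "J"),
                                A = 40, FR0 = 10, tau = 0,
                                sigma_t = profile_sigma(0.3, 1),
                                weights = NULL, seed = 1) {
  with_seed(seed, {
    K <- length(components)
    if (is.null(weights)) {
      w <- stats::rexp(K)
      w <- w / sum(w)
      names(w) <- components
    } else {
      w <- weights[components]
    }
    z <- matrix(stats::rnorm(3 * K), K, 3)
    z <- z / sqrt(rowSums(z^2))
    pref <- t(apply(z, 1, cart_to_sph))
    model_params(
      A = A, FR0 = FR0, tau = tau, sigma_t = sigma_t, weights = w,
      preferred = data.frame(azimuth_deg = pref[, 1],
                             elevation_deg = pref[, 2]),
      offsets = stats::setNames(stats::runif(K, -0.5, 0.5), components)
    )
  })
}

#' Write / read spike-event tables
#'
#' Spike events go to a CSV with columns `neuron_id`, `condition`,
#' `direction_index`, `trial`, `spike_time_s`; the protocol (epoch duration,
#' recording margins, per-neuron trial counts — needed to reconstruct trials
#' that contain no spikes) goes to a JSON sidecar at `<path>.json`. The
#' round-trip reproduces recordings exactly (spike times to 1e-6 s).
#'
#' @param recordings List of [neuron_recording()] objects.
#' @param path CSV file path.
#' @return `write_spike_events()` returns `path` invisibly;
#'   `read_spike_events()` returns a list of [neuron_recording()]s.
#' @export
write_spike_events <- function(recordings, path) {
  ev <- purrr::list_rbind(purrr::map(recordings, function(r) {
    dplyr::mutate(r$spikes, neuron_id = r$neuron_id, condition = r$condition,
                  .before = 1)
  }))
  ev$spike_time_s <- round(ev$spike_time_s, 6)
  readr::write_csv(ev, path)
  sidecar <- list(
    duration = recordings[[1]]$duration,
    pre_window = recordings[[1]]$pre_window,
    post_window = recordings[[1]]$post_window,
    neurons = purrr::map(recordings, function(r)
      list(neuron_id = r$neuron_id, condition = r$condition,
           n_trials = r$n_trials, n_directions = r$n_directions))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_events
#' @param protocol_path JSON sidecar path (default `<path>.json`).
#' @export
read_spike_events <- function(path, protocol_path = paste0(path, ".json")) {
  if (!file.exists(protocol_path))
    stop("protocol sidecar not found: ", protocol_path)
  proto <- jsonlite::read_json(protocol_path, simplifyVector = FALSE)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "condition", "direction_index", "trial",
            "spike_time_s")
  if (!all(need %in% names(ev)))
    stop("spike-event file must have columns: ", paste(need, collapse = ", "))
  if (nrow(ev) > 0) {
    bad <- which(!is.finite(ev$spike_time_s) |
                   !is.finite(ev$direction_index) | !is.finite(ev$trial))
    if (length(bad) > 0)
      stop("malformed spike-event row(s): ", paste(utils::head(bad, 5),
                                                   collapse = ", "))
  }
  purrr::map(proto$neurons, function(nr) {
    sel <- ev$neuron_id == nr$neuron_id & ev$condition == nr$condition
    sp <- tibble::as_tibble(ev[sel, c("direction_index", "trial",
                                      "spike_time_s")])
    if (nrow(sp) > 0) {
      out_of_range <- which(sp$direction_index < 1 |
                              sp$direction_index > nr$n_directions)
      if (length(out_of_range) > 0)
        stop("neuron ", nr$neuron_id, ": direction_index out of [1, ",
             nr$n_directions, "] at row(s) ",
             paste(utils::head(which(sel)[out_of_range], 5), collapse = ", "))
    }
    neuron_recording(sp, n_trials = nr$n_trials,
                     n_directions = nr$n_directions,
                     duration = proto$duration,
                     pre_window = proto$pre_window,
                     post_window = proto$post_window,
                     neuron_id = nr$neuron_id, condition = nr$condition)
  })
}

#' Load a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or validates one already in memory).
#' Recognized sections: `protocol` (`peak_speed`, `peak_acceleration` or
#' `sigma_s`, `duration`, `dt`, `pre_window`, `post_window`), `simulation`
#' (`n_tuned`, `n_null`, `n_trials`, `baseline_rate`, `amplitude`, optional
#' `components`), `screen` (`alpha`, `min_run`, `n_perm`), `fit` (`enabled`,
#' `n_restarts`, `maxit`), plus top-level `seed` and `output_dir`.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    seed = 1, output_dir = NULL,
    protocol = list(peak_speed = 0.3, peak_acceleration = 1, duration = 1.5,
                    dt = 0.001, pre_window = 0.3, post_window = 0.3),
    simulation = list(n_tuned = 5, n_null = 5, n_trials = 5,
                      baseline_rate = 10, amplitude = 40,
                      components = c("P", "V", "A", "J")),
    screen = list(alpha = 0.01, min_run = 5, n_perm = 1000),
    fit = list(enabled = TRUE, n_restarts = 20, maxit = 300)
  ), config)
  if (cfg$screen$alpha <= 0 || cfg$screen$alpha >= 1)
    stop("screen alpha must lie in (0, 1)")
  if (cfg$simulation$n_tuned + cfg$simulation$n_null < 1)
    stop("simulation must include at least one neuron")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

#' Run the simulate -> screen -> fit -> compare pipeline
#'
#' Simulates a population from the configuration, screens every neuron for
#' temporal/spatial tuning and DDI, optionally fits the VA and PVAJ models
#' with BIC/BDI comparison, writes all reports to `output_dir` (when set),
#' and returns the result bundle. Per-neuron model-fit failures are caught,
#' logged and counted; the pipeline always completes.
#'
#' Written files (when `output_dir` is set): `spikes.csv` (+ `.json`
#' protocol sidecar), `screen.csv`, `fits.json`, `comparison.csv` and
#' `summary.json` (tuned fractions, DDI summary, weight distributions, BDI
#' summary, master seed).
#'
#' @param config A [pipeline_config()], path, or list.
#' @return List of class `pipeline_result`: `recordings`, `screen`
#'   (tibble), `comparison` (tibble or NULL), `fits` (list), `summary`
#'   (list), `n_fit_failures`, `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  proto <- cfg$protocol
  sigma_s <- proto$sigma_s %||%
    profile_sigma(proto$peak_speed, proto$peak_acceleration)
  profile <- gaussian_velocity_profile(proto$peak_speed, sigma_s,
                                       proto$duration, proto$dt)
  grid <- build_direction_grid()

  sim <- cfg$simulation
  n_total <- sim$n_tuned + sim$n_null
  param_seeds <- derive_seeds(cfg$seed + 1L, max(sim$n_tuned, 1))
  pop <- tibble::tibble(
    params = c(
      lapply(seq_len(sim$n_tuned), function(i)
        random_model_params(components = sim$components, A = sim$amplitude,
                            FR0 = sim$baseline_rate, sigma_t = sigma_s,
                            seed = param_seeds[i])),
      rep(list(NULL), sim$n_null)
    ),
    n_trials = rep(as.integer(sim$n_trials), n_total),
    baseline_rate = rep(sim$baseline_rate, n_total),
    neuron_id = sprintf("sim%03d", seq_len(n_total))
  )
  recordings <- simulate_population(pop, grid, profile, seed = cfg$seed,
                                    pre_window = proto$pre_window,
                                    post_window = proto$post_window)

  screen <- screen_population(recordings, grid, seed = cfg$seed,
                              alpha = cfg$screen$alpha,
                              min_run = cfg$screen$min_run,
                              n_perm = cfg$screen$n_perm)

  fits <- list()
  comparison <- NULL
  n_fail <- 0L
  if (isTRUE(cfg$fit$enabled)) {
    fit_seeds <- derive_seeds(cfg$seed + 2L, length(recordings))
    rows <- list()
    for (i in seq_along(recordings)) {
      res <- tryCatch({
        psth <- build_psth(recordings[[i]])
        compare_models(psth, grid, profile,
                       n_restarts = cfg$fit$n_restarts,
                       seed = fit_seeds[i], maxit = cfg$fit$maxit)
      }, error = function(e) {
        message("fit failed for ", recordings[[i]]$neuron_id, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) { n_fail <- n_fail + 1L; next }
      fits[[recordings[[i]]$neuron_id]] <- res
      rows[[length(rows) + 1]] <- res$summary
    }
    if (length(rows) > 0) comparison <- purrr::list_rbind(rows)
  }

  pvaj_weights <- if (length(fits) > 0)
    purrr::list_rbind(purrr::map(fits, function(f) tidy(f$fit_pvaj)))
  else NULL
  summary <- list(
    seed = cfg$seed,
    n_neurons = length(recordings),
    fraction_temporally_tuned = mean(screen$temporally_tuned),
    fraction_spatially_tuned = mean(screen$spatially_tuned),
    ddi = list(mean = mean(screen$ddi), median = stats::median(screen$ddi)),
    bdi = if (!is.null(comparison))
      list(median = stats::median(comparison$bdi),
           fraction_positive = mean(comparison$bdi > 0)) else NULL,
    weights = if (!is.null(pvaj_weights))
      as.list(tapply(pvaj_weights$weight, pvaj_weights$component, mean))
    else NULL,
    n_fit_failures = n_fail
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_reports(list(recordings = recordings, screen = screen,
                       comparison = comparison, fits = fits,
                       summary = summary),
                  cfg$output_dir)
  }

  structure(list(recordings = recordings, screen = screen,
                 comparison = comparison, fits = fits, summary = summary,
                 n_fit_failures = n_fail, config = cfg),
            class = "pipeline_result")
}

#' Write pipeline reports to a directory
#'
#' @param results A `pipeline_result`, or a list with any of `recordings`,
#'   `screen`, `comparison`, `fits`, `summary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(results$recordings))
    write_spike_events(results$recordings, file.path(dir, "spikes.csv"))
  if (!is.null(results$screen))
    readr::write_csv(results$screen, file.path(dir, "screen.csv"))
  if (!is.null(results$comparison))
    readr::write_csv(results$comparison, file.path(dir, "comparison.csv"))
  if (length(results$fits %||% list()) > 0) {
    fit_json <- purrr::map(results$fits, function(cmp) {
      list(va = fit_to_list(cmp$fit_va), pvaj = fit_to_list(cmp$fit_pvaj),
           bdi = cmp$summary$bdi)
    })
    jsonlite::write_json(fit_json, file.path(dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$summary))
    jsonlite::write_json(results$summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

fit_to_list <- function(fit) {
  p <- fit$params
  list(model_kind = fit$model_kind, r2 = fit$r2, rss = fit$rss,
       bic = fit$bic, n_points = fit$n_points, n_free = fit$n_free,
       converged = fit$converged, n_restarts_used = fit$n_restarts_used,
       A = p$A, FR0 = p$FR0, tau = p$tau, sigma_t = p$sigma_t,
       components = p$components, weights = as.list(p$weights),
       preferred = p$preferred, offsets = as.list(p$offsets))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d neurons | tuned: %.0f%% temporal, %.0f%% spatial | fit failures: %d\n",
              x$summary$n_neurons,
              100 * x$summary$fraction_temporally_tuned,
              100 * x$summary$fraction_spatially_tuned,
              x$n_fit_failures))
  invisible(x)
}
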