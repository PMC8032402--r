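#' Fit the spatiotemporal model to a PSTH matrix
#'
#' Constrained nonlinear least squares of the rectified VA or PVAJ model to a
#' neuron's smoothed PSTH, all 26 directions jointly. Optimization runs over
#' a smooth reparameterization — softmax for the simplex of component
#' weights, unnormalized 3-vectors for preferred directions — with box
#' bounds (`tau` in \[-0.3, 0.3\] s, `sigma_t` in \[0.5, 2\] x the stimulus
#' velocity width, offsets in \[-1, 1\], `A`, `FR0` >= 0) via bounded
#' Levenberg-Marquardt trust-region least squares ([minpack.lm::nls.lm()]).
#' Multiple seeded restarts initialize the preferred directions at the grid
#' vectors with the strongest single-direction responses; the lowest-RSS
#' solution wins (ties broken by restart index).
#'
#' @param psth A [build_psth()] object (the smoothed matrix is fitted).
#' @param grid Direction grid.
#' @param profile Motion profile (supplies the stimulus peak time and the
#'   stimulus velocity width used to bound `sigma_t`).
#' @param model_kind `"PVAJ"` (position/velocity/acceleration/jerk) or
#'   `"VA"` (velocity/acceleration).
#' @param n_restarts Number of multi-start restarts (default 20).
#' @param seed Integer seed for the restart initializations.
#' @param maxit Iteration cap per restart.
#' @return Object of class `st_model_fit`: `params` ([model_params()]),
#'   `model_kind`, `r2`, `rss`, `n_points`, `n_free`, `bic`, `converged`,
#'   `n_restarts_used`, `fitted` and `observed` matrices, `times`.
#'   Free-parameter counts used for BIC: VA = 11
#'   (A, FR0, tau, sigma_t, 1 simplex weight, 2 x (azimuth, elevation,
#'   offset)), PVAJ = 19 (3 simplex weights, 4 component direction/offset
#'   triples).
#' @export
fit_model <- function(psth, grid, profile, model_kind = c("PVAJ", "VA"),
                      n_restarts = 20, seed = 1, maxit = 300) {
  stopifnot(inherits(psth, "psth_matrix"))
  model_kind <- match.arg(model_kind)
  comps <- if (model_kind == "PVAJ") c("P", "V", "A", "J") else c("V", "A")
  K <- length(comps)
  Y <- psth$smoothed
  times <- psth$bin_centers
  center <- attr(profile, "center")
  sigma_stim <- attr(profile, "sigma_s")
  xyz <- as.matrix(grid[, c("x", "y", "z")])
  rate_max <- max(Y)
  rate_min <- min(Y)

  # parameter vector layout:
  # [A, FR0, tau, sigma_t, logits (K-1), then per component vx, vy, vz, o]
  n_core <- 4L
  idx_logit <- n_core + seq_len(K - 1)
  idx_comp <- function(i) n_core + (K - 1) + (i - 1) * 4 + 1:4

  lower <- c(0, 0, -0.3, 0.5 * sigma_stim, rep(-8, K - 1),
             rep(c(-2, -2, -2, -1), K))
  upper <- c(max(4 * (rate_max - rate_min), 1), max(2 * rate_max, 1),
             0.3, 2 * sigma_stim, rep(8, K - 1),
             rep(c(2, 2, 2, 1), K))

  unpack <- function(par) {
    w <- exp(c(par[idx_logit], 0))
    w <- w / sum(w)
    pref <- matrix(0, K, 3)
    off <- numeric(K)
    for (i in seq_len(K)) {
      ci <- idx_comp(i)
      v <- par[ci[1:3]]
      nv <- sqrt(sum(v^2))
      pref[i, ] <- if (nv < 1e-8) c(1, 0, 0) else v / nv
      off[i] <- par[ci[4]]
    }
    list(A = par[1], FR0 = par[2], tau = par[3], sigma_t = par[4],
         w = w, pref = pref, off = off)
  }

  predict_mat <- function(p) {
    # inlined unit-peak temporal kernels (hot path)
    u <- times - center - p$tau
    s2 <- p$sigma_t^2
    g <- exp(-u^2 / (2 * s2))
    ftk <- matrix(0, length(u), K)
    for (j in seq_len(K)) {
      col <- switch(comps[j],
        V = g,
        A = u / s2 * g,
        J = -(u^2 - s2) / (s2 * s2) * g,
        P = stats::pnorm(u / p$sigma_t))
      pk <- max(abs(col))
      ftk[, j] <- if (pk > 0) col / pk else col
    }
    Ym <- xyz %*% t(p$pref)                       # cosines, nd x K
    for (j in seq_len(K)) {
      o <- p$off[j]
      Ym[, j] <- p$w[j] * (o + (1 - abs(o)) * Ym[, j])
    }
    resp <- p$A * (Ym %*% t(ftk)) + p$FR0
    resp[resp < 0] <- 0
    resp
  }

  residual_fn <- function(par) {
    as.vector(Y - predict_mat(unpack(par)))
  }

  # analytic warm start: with tau = 0 and sigma = stimulus sigma the model is
  # linear in per-direction kernel coefficients c[m, d] = A w_m y_m(d);
  # regressing each direction's trace on the kernels recovers c, from which
  # weights, preferred directions and offsets are read off (rectification and
  # the true tau/sigma make this approximate - it seeds the trust region)
  warm <- tryCatch({
    ftk0 <- temporal_kernels(times, 0, sigma_stim, comps, center = center)
    B <- qr.solve(cbind(1, ftk0), t(Y))            # (K+1) x nd
    fr_init <- min(max(mean(B[1, ]), 0), max(2 * rate_max, 1))
    pw <- lapply(seq_len(K), function(m) {
      cd <- B[m + 1, ]
      S <- (max(cd) + min(cd)) / 2
      D <- (max(cd) - min(cd)) / 2
      v <- drop(crossprod(xyz, cd)) / c(8, 8, 10)  # undo the grid metric
      nv <- sqrt(sum(v^2))
      list(aw = D + abs(S),
           o = max(-0.9, min(0.9, S / (D + abs(S) + 1e-12))),
           v = if (nv > 1e-9) v / nv else xyz[which.max(cd), ])
    })
    aw <- vapply(pw, `[[`, numeric(1), "aw")
    A_init <- max(sum(aw), 1e-3)
    w_init <- pmax(aw / A_init, 0.02)
    w_init <- w_init / sum(w_init)
    c(min(A_init, max(4 * (rate_max - rate_min), 1)), fr_init, 0, sigma_stim,
      log(w_init[-K] / w_init[K]),
      unlist(lapply(pw, function(q) c(q$v, q$o))))
  }, error = function(e) NULL)

  # remaining restarts: preferred directions spread over the grid vectors
  # ranked by peak response
  rank_dirs <- order(apply(Y, 1, max), decreasing = TRUE)
  a0 <- max(rate_max - rate_min, 1)
  fr0 <- max(rate_min, 0.1)
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  n_used <- 0L
  for (r in seq_len(n_restarts)) {
    d0 <- rank_dirs[((r - 1) %% nrow(xyz)) + 1]
    par0 <- if (r == 1 && !is.null(warm)) warm
    else if (r == 2 && !is.null(warm)) {
      with_seed(seeds[r], warm * stats::runif(length(warm), 0.8, 1.2))
    } else with_seed(seeds[r], {
      p <- c(a0 * stats::runif(1, 0.5, 1.5),
             fr0 * stats::runif(1, 0.5, 1.5),
             stats::runif(1, -0.05, 0.05),
             sigma_stim * stats::runif(1, 0.9, 1.2),
             stats::rnorm(K - 1, 0, 0.6))
      for (i in seq_len(K)) {
        # spread components over the strongest directions, then everywhere
        di <- if (r <= ceiling(n_restarts / 2)) rank_dirs[sample.int(8, 1)]
        else sample.int(nrow(xyz), 1)
        p <- c(p, xyz[di, ] + stats::rnorm(3, 0, 0.2),
               stats::runif(1, -0.4, 0.4))
      }
      p
    })
    par0 <- pmin(upper - 1e-9, pmax(lower + 1e-9, par0))
    res <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, nprint = 0)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_used <- n_used + 1L
    res$value <- res$deviance
    res$convergence <- if (res$info %in% 1:4) 0L else 1L
    if (is.null(best) || res$value < best$value - 1e-12) {
      best <- res
    }
  }
  if (is.null(best))
    stop("all restarts failed; check the PSTH input")

  p <- unpack(best$par)
  pref_sph <- t(apply(p$pref, 1, cart_to_sph))
  params <- model_params(
    A = p$A, FR0 = p$FR0, tau = p$tau, sigma_t = p$sigma_t,
    weights = stats::setNames(p$w, comps),
    preferred = data.frame(azimuth_deg = pref_sph[, 1],
                           elevation_deg = pref_sph[, 2]),
    offsets = stats::setNames(p$off, comps)
  )
  fitted <- predict_mat(p)
  rss <- best$value
  n_points <- length(Y)
  n_free <- if (model_kind == "PVAJ") 19L else 11L
  structure(
    list(params = params, model_kind = model_kind,
         r2 = goodness_of_fit(fitted, Y), rss = rss,
         n_points = n_points, n_free = n_free,
         bic = bic(max(rss, .Machine$double.xmin), n_points, n_free),
         converged = best$convergence == 0, n_restarts_used = n_used,
         fitted = fitted, observed = Y, times = times,
         neuron_id = psth$neuron_id, condition = psth$condition,
         center = center, grid = grid),
    class = "st_model_fit"
  )
}

#' @export
print.st_model_fit <- function(x, ...) {
  cat(sprintf("<st_model_fit> %s model, %s [%s]: R2=%.3f RSS=%.2f BIC=%.1f (%s)\n",
              x$model_kind, x$neuron_id, x$condition, x$r2, x$rss, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Coefficient of determination between fitted and observed responses
#'
#' `R^2 = 1 - RSS / TSS` over all direction-by-time points pooled.
#'
#' @param predicted,observed Matrices (or vectors) of matching shape.
#' @return R-squared, or `NA` (with a warning) when the observed data have
#'   zero variance.
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (!all(dim(as.matrix(predicted)) == dim(as.matrix(observed))))
    stop("`predicted` and `observed` must have the same shape")
  obs <- as.vector(observed)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) {
    warning("observed response has zero variance; R2 undefined")
    return(NA_real_)
  }
  1 - sum((obs - as.vector(predicted))^2) / tss
}

#' Log ratio of two component weights
#'
#' `log10(w_num / w_den)`; by default the velocity-to-acceleration ratio,
#' positive when the velocity component dominates. A zero weight yields a
#' signed infinity, which population summaries should exclude.
#'
#' @param fit An `st_model_fit`.
#' @param numerator,denominator Component letters (default `"V"`, `"A"`).
#' @return The log10 weight ratio.
#' @export
log_weight_ratio <- function(fit, numerator = "V", denominator = "A") {
  w <- fit$params$weights
  if (!all(c(numerator, denominator) %in% names(w)))
    stop("components ", numerator, "/", denominator, " not in the fitted model")
  log10(w[[numerator]] / w[[denominator]])
}

#' Tidy the parameters of a fitted spatiotemporal model
#'
#' @param x An `st_model_fit`.
#' @param ... Unused.
#' @return Tibble with one row per temporal component (`weight`,
#'   `pref_azimuth_deg`, `pref_elevation_deg`, `offset`) and the shared
#'   parameters (`A`, `FR0`, `tau_s`, `sigma_t_s`) repeated on each row.
#' @method tidy st_model_fit
#' @export
tidy.st_model_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    component = p$components,
    weight = unname(p$weights),
    pref_azimuth_deg = p$preferred$azimuth_deg,
    pref_elevation_deg = p$preferred$elevation_deg,
    offset = unname(p$offsets),
    A = p$A, FR0 = p$FR0, tau_s = p$tau, sigma_t_s = p$sigma_t
  )
}

#' One-row summary of a fitted spatiotemporal model
#'
#' @param x An `st_model_fit`.
#' @param ... Unused.
#' @return Tibble: `model_kind`, `r2`, `rss`, `bic`, `n_points`, `n_free`,
#'   `converged`, `n_restarts_used`.
#' @method glance st_model_fit
#' @export
glance.st_model_fit <- function(x, ...) {
  tibble::tibble(
    model_kind = x$model_kind, r2 = x$r2, rss = x$rss, bic = x$bic,
    n_points = x$n_points, n_free = x$n_free, converged = x$converged,
    n_restarts_used = x$n_restarts_used
  )
}
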