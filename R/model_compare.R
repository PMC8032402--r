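#' Bayesian information criterion for a least-squares fit
#'
#' `BIC = n * ln(RSS / n) + p * ln(n)`, the Gaussian-residual form that
#' penalizes free parameters; smaller is better.
#'
#' @param rss Residual sum of squares (> 0; `rss = 0` returns `-Inf` with a
#'   warning).
#' @param n_points Number of fitted data points (> `n_free`).
#' @param n_free Number of free parameters (>= 1).
#' @return BIC value.
#' @examples
#' bic(100, 100, 5)  # 5 * log(100)
#' @export
bic <- function(rss, n_points, n_free) {
  if (n_free < 1) stop("`n_free` must be >= 1")
  if (n_points <= n_free)
    stop("`n_points` (", n_points, ") must exceed `n_free` (", n_free, ")")
  if (rss < 0) stop("`rss` must be non-negative")
  if (rss == 0) {
    warning("RSS is zero; BIC is -Inf")
    return(-Inf)
  }
  n_points * log(rss / n_points) + n_free * log(n_points)
}

#' BIC difference index (BDI)
#'
#' `BDI = (BIC_VA - BIC_PVAJ) / |BIC_PVAJ|`. Positive values mean the full
#' PVAJ model is preferred even after the BIC penalty for its extra
#' parameters; negative values favour the reduced VA model.
#'
#' @param bic_va,bic_pvaj BIC values of the two fits (`bic_pvaj != 0`).
#' @return The BDI.
#' @export
bdi <- function(bic_va, bic_pvaj) {
  if (!is.finite(bic_pvaj) || bic_pvaj == 0)
    stop("`bic_pvaj` must be finite and non-zero")
  (bic_va - bic_pvaj) / abs(bic_pvaj)
}

#' Fit and compare the VA and PVAJ models on one neuron
#'
#' Fits both model kinds to the same smoothed PSTH and summarizes the
#' comparison (BICs, BDI, per-component partial correlations of the PVAJ
#' fit).
#'
#' @inheritParams fit_model
#' @return List of class `model_comparison`: `fit_va`, `fit_pvaj`, and
#'   `summary`, a one-row tibble with `neuron_id`, `condition`, `r2_va`,
#'   `r2_pvaj`, `bic_va`, `bic_pvaj`, `bdi`, and `partial_r_P/V/A/J` +
#'   `partial_p_P/V/A/J`.
#' @export
compare_models <- function(psth, grid, profile, n_restarts = 20, seed = 1,
                           maxit = 300) {
  fit_va <- fit_model(psth, grid, profile, "VA", n_restarts = n_restarts,
                      seed = seed, maxit = maxit)
  fit_pvaj <- fit_model(psth, grid, profile, "PVAJ", n_restarts = n_restarts,
                        seed = seed + 1, maxit = maxit)
  pc <- component_partial_correlation(psth, fit_pvaj)
  out <- tibble::tibble(
    neuron_id = psth$neuron_id, condition = psth$condition,
    r2_va = fit_va$r2, r2_pvaj = fit_pvaj$r2,
    bic_va = fit_va$bic, bic_pvaj = fit_pvaj$bic,
    bdi = bdi(fit_va$bic, fit_pvaj$bic)
  )
  for (m in pc$component) {
    out[[paste0("partial_r_", m)]] <- pc$partial_r[pc$component == m]
    out[[paste0("partial_p_", m)]] <- pc$partial_p[pc$component == m]
  }
  structure(list(fit_va = fit_va, fit_pvaj = fit_pvaj, summary = out),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s: R2 VA=%.3f PVAJ=%.3f, BDI=%.3f (%s preferred)\n",
              x$summary$neuron_id, x$summary$r2_va, x$summary$r2_pvaj,
              x$summary$bdi,
              if (x$summary$bdi > 0) "PVAJ" else "VA"))
  invisible(x)
}

#' Partial correlation between the response and each fitted component
#'
#' For each temporal component of a fitted model, the Pearson correlation
#' between the pooled observed response (direction x time vector) and that
#' component's fitted contribution, controlling for the other components'
#' contributions. Computed from the precision matrix (inverse of the joint
#' correlation matrix); p-values use the t distribution with
#' `df = n - k - 2`, where `n` is the number of pooled points and `k` the
#' number of conditioning variables. `n` counts every direction-by-bin point
#' with no autocorrelation correction, so the stated df (and hence p) are
#' anti-conservative for smoothed PSTHs; treat them as a ranking device, as
#' the per-component weights carry the effect size.
#'
#' Components with constant contribution (zero weight) are flagged undefined
#' (`NA`) and excluded from the conditioning set, as are exactly collinear
#' contributions.
#'
#' @param psth A `psth_matrix` (the smoothed matrix is used).
#' @param fit An `st_model_fit` for the same neuron.
#' @return Tibble with `component`, `partial_r`, `partial_p`, `defined`.
#' @export
component_partial_correlation <- function(psth, fit) {
  stopifnot(inherits(fit, "st_model_fit"))
  obs <- as.vector(psth$smoothed)
  contr <- fit_component_matrix(fit)
  comps <- colnames(contr)
  K <- length(comps)
  usable <- apply(contr, 2, stats::sd) > 1e-12
  # drop exact collinearity among usable contributions
  if (sum(usable) > 1) {
    cc <- stats::cor(contr[, usable, drop = FALSE])
    dup <- rep(FALSE, sum(usable))
    for (i in seq_len(ncol(cc))) for (j in seq_len(i - 1)) {
      if (!dup[i] && abs(cc[i, j]) > 1 - 1e-10) dup[i] <- TRUE
    }
    u_idx <- which(usable)
    usable[u_idx[dup]] <- FALSE
  }
  r <- rep(NA_real_, K)
  p <- rep(NA_real_, K)
  if (any(usable) && stats::sd(obs) > 0) {
    # a contribution perfectly collinear with the observation saturates the
    # partial correlation at +/-1 and would make the joint correlation matrix
    # singular; report the limit directly
    exact <- rep(FALSE, K)
    for (j in which(usable)) {
      rj <- stats::cor(obs, contr[, j])
      if (abs(rj) > 1 - 1e-12) {
        r[j] <- sign(rj); p[j] <- 0
        exact[j] <- TRUE; usable[j] <- FALSE
      }
    }
    if (any(usable)) {
      X <- cbind(obs, contr[, usable, drop = FALSE])
      R <- stats::cor(X)
      Pm <- tryCatch(solve(R), error = function(e) NULL)
      if (!is.null(Pm)) {
        n <- length(obs)
        k <- sum(usable) - 1        # conditioning variables per test
        df <- n - k - 2
        ui <- which(usable)
        for (j in seq_along(ui)) {
          rj <- -Pm[1, j + 1] / sqrt(Pm[1, 1] * Pm[j + 1, j + 1])
          rj <- max(-1, min(1, rj))
          r[ui[j]] <- rj
          tstat <- rj * sqrt(df / max(1 - rj^2, 1e-300))
          p[ui[j]] <- 2 * stats::pt(-abs(tstat), df)
        }
      }
    }
    usable <- usable | exact
  }
  tibble::tibble(component = comps, partial_r = r, partial_p = p,
                 defined = !is.na(r))
}

# pooled (direction*time) x component matrix of fitted contributions
fit_component_matrix <- function(fit) {
  p <- fit$params
  nd <- nrow(fit$observed)
  grid <- fit$grid %||% build_direction_grid()
  stopifnot(nrow(grid) == nd)
  cl <- component_contributions(p, grid, fit$times, center = fit$center)
  out <- vapply(cl, as.vector, numeric(nd * length(fit$times)))
  colnames(out) <- names(cl)
  out
}
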