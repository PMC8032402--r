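#' Temporal tuning screen
#'
#' Tests, for every (direction, window) cell, whether the per-trial windowed
#' rates differ from the neuron's spontaneous activity (two-sided Wilcoxon
#' rank-sum, normal approximation). A neuron is temporally tuned only when
#' (1) some direction shows at least `min_run` consecutive significant
#' windows at `alpha`, and (2) that happens in at least two *adjacent*
#' directions (grid lattice neighbours). The conjunction keeps the
#' false-positive rate of the screen far below the per-test level.
#'
#' Each direction's window rates are compared against the spontaneous rates
#' of that direction's own trials. Keeping the reference sample per direction
#' makes the 26 direction-level decisions statistically independent under the
#' null, which is what lets the two-adjacent-directions conjunction suppress
#' false positives (a reference pooled across directions would correlate all
#' decisions through shared baseline noise and inflate the family-wise rate).
#'
#' @param windowed A [sliding_window_rates()] array (needs >= 2 trials).
#' @param spontaneous Matrix from [spontaneous_rates()] (directions x trials).
#' @param grid Direction grid (supplies adjacency).
#' @param alpha Per-test significance level (default 0.01).
#' @param min_run Required run of consecutive significant windows (default 5).
#' @return List of class `temporal_tuning`: `tuned` (logical), `p_values`
#'   (directions x windows), `sig_mask`, `qualifying_directions`.
#' @export
temporal_tuning_test <- function(windowed, spontaneous, grid,
                                 alpha = 0.01, min_run = 5) {
  dims <- dim(windowed)
  nd <- dims[1]; nw <- dims[2]; nt <- dims[3]
  if (nt < 2)
    stop("temporal tuning test needs >= 2 trials per direction (have ",
         nt, ")")
  spontaneous <- matrix(spontaneous, nrow = nd)
  p <- matrix(1, nd, nw)
  for (d in seq_len(nd)) {
    spont <- spontaneous[d, ]
    for (w in seq_len(nw)) {
      x <- windowed[d, w, ]
      if (all(x == spont[1]) && length(unique(spont)) == 1L) next
      p[d, w] <- suppressWarnings(
        stats::wilcox.test(x, spont, exact = FALSE)$p.value)
      if (is.na(p[d, w])) p[d, w] <- 1
    }
  }
  sig <- p < alpha
  qualifies <- apply(sig, 1, function(s) max_run(s) >= min_run)
  adj <- grid_adjacency(grid)
  tuned <- FALSE
  q <- which(qualifies)
  if (length(q) >= 2) tuned <- any(adj[q, q, drop = FALSE])
  structure(list(tuned = tuned, p_values = p, sig_mask = sig,
                 qualifying_directions = q,
                 alpha = alpha, min_run = min_run),
            class = "temporal_tuning")
}

max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Per-window one-way ANOVA across directions
#'
#' For each analysis window, the classical fixed-effects one-way F-test of
#' trial rates across the grid directions. Windows with zero total variance
#' get p = 1 by convention; windows whose group means differ but whose
#' within-group variance is zero get p = 0.
#'
#' @param windowed A [sliding_window_rates()] array (needs >= 2 trials).
#' @return Numeric vector of p-values, one per window.
#' @export
spatial_anova <- function(windowed) {
  dims <- dim(windowed)
  nd <- dims[1]; nw <- dims[2]; nt <- dims[3]
  if (nt < 2) stop("spatial ANOVA needs >= 2 trials per direction")
  g <- factor(rep(seq_len(nd), times = nt))
  vapply(seq_len(nw), function(w) {
    y <- as.vector(windowed[, w, ])
    if (stats::var(y) == 0) return(1)
    gm <- tapply(y, g, mean)
    if (all(abs(y - gm[g]) < 1e-12)) return(0)
    stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
  }, numeric(1))
}

#' Count response peaks across analysis windows
#'
#' Among windows with significant spatial tuning (`anova_p < alpha`), a local
#' peak is a window whose across-direction maximum mean rate exceeds its
#' neighbouring windows'. Successive local peaks are grouped by the Pearson
#' correlation of their 26-direction response vectors: positive correlation
#' means the same underlying peak, negative correlation a distinct one.
#' At most two peaks are reported (higher-order peaks are small and
#' unreliable); when more groups exist, the two with the largest responses
#' are kept, in temporal order.
#'
#' @param windowed A [sliding_window_rates()] array.
#' @param anova_p Per-window p-values from [spatial_anova()].
#' @param alpha Significance level for window selection (default 0.01).
#' @return List: `n_peaks` (0, 1 or 2) and `peak_windows` (window indices,
#'   one representative per peak, in time order).
#' @export
count_peaks <- function(windowed, anova_p, alpha = 0.01) {
  dirmean <- rowMeans(windowed, dims = 2)
  nw <- ncol(dirmean)
  sig <- which(anova_p < alpha)
  if (length(sig) == 0) return(list(n_peaks = 0L, peak_windows = integer(0)))
  maxresp <- apply(dirmean, 2, max)
  is_local_peak <- vapply(sig, function(w) {
    left_ok <- w == 1 || maxresp[w] > maxresp[w - 1]
    right_ok <- w == nw || maxresp[w] > maxresp[w + 1]
    left_ok && right_ok
  }, logical(1))
  peaks <- sig[is_local_peak]
  if (length(peaks) == 0) {
    # significant tuning but a plateau-shaped envelope: take the best window
    peaks <- sig[which.max(maxresp[sig])]
  }
  # group successive local peaks by the sign of the correlation between
  # their direction-response vectors
  groups <- list(peaks[1])
  if (length(peaks) > 1) {
    for (i in 2:length(peaks)) {
      prev <- groups[[length(groups)]]
      r <- suppressWarnings(
        stats::cor(dirmean[, peaks[i]], dirmean[, prev[length(prev)]]))
      if (!is.na(r) && r > 0) {
        groups[[length(groups)]] <- c(prev, peaks[i])
      } else {
        groups[[length(groups) + 1]] <- peaks[i]
      }
    }
  }
  rep_win <- vapply(groups, function(g) g[which.max(maxresp[g])], integer(1))
  rep_amp <- maxresp[rep_win]
  if (length(rep_win) > 2) {
    keep <- order(rep_amp, decreasing = TRUE)[1:2]
    rep_win <- rep_win[sort(keep)]
  }
  rep_win <- sort(rep_win)
  list(n_peaks = length(rep_win), peak_windows = rep_win)
}

#' Direction discrimination index (DDI)
#'
#' \deqn{DDI = \frac{R_{max} - R_{min}}
#'   {R_{max} - R_{min} + 2\sqrt{SSE / (N - M)}}}
#'
#' The maximum-response direction is found from the mean rate over the full
#' stimulus epoch; within that direction the best analysis window gives
#' `R_max`; `R_min` is the minimum mean rate across the other 25 directions
#' *in that same window*; `SSE` is the within-direction sum of squared
#' deviations of trial rates at that window (all `M = 26` directions pooled)
#' and `N` the total number of trials at that window. DDI approaches 1 for
#' strong modulation relative to trial-to-trial variability and 0 for none.
#'
#' @param windowed A [sliding_window_rates()] array with more total trials
#'   than directions (`N > M`).
#' @return List: `ddi`, plus the selected `best_direction`, `best_window`,
#'   `r_max`, `r_min`, `sse`, `n`, `m`.
#' @export
compute_ddi <- function(windowed) {
  dims <- dim(windowed)
  nd <- dims[1]; nw <- dims[2]; nt <- dims[3]
  n_total <- nd * nt
  if (n_total <= nd)
    stop("DDI needs more total trials (N = ", n_total,
         ") than directions (M = ", nd, ")")
  # units: one row per (direction, trial), columns = windows
  tu <- matrix(aperm(windowed, c(1, 3, 2)), nd * nt, nw)
  ddi_from_units(tu, rep(seq_len(nd), nt), nd, nt)
}

# DDI from the (direction*trial) x window unit matrix and a direction-label
# vector; shared by compute_ddi and the permutation test
ddi_from_units <- function(tu, group, nd, nt) {
  dirmean <- unname(rowsum(tu, group, reorder = TRUE)) / nt   # nd x nw
  best_dir <- unname(which.max(rowMeans(dirmean)))
  best_win <- unname(which.max(dirmean[best_dir, ]))
  r_max <- dirmean[best_dir, best_win]
  r_min <- min(dirmean[-best_dir, best_win])
  x <- tu[, best_win]
  sse <- sum((x - dirmean[group, best_win])^2)
  n_total <- nd * nt
  list(ddi = ddi_formula(r_max, r_min, sse, n_total, nd),
       best_direction = best_dir, best_window = best_win,
       r_max = r_max, r_min = r_min, sse = sse, n = n_total, m = nd)
}

ddi_formula <- function(r_max, r_min, sse, n, m) {
  num <- r_max - r_min
  den <- num + 2 * sqrt(sse / (n - m))
  if (den == 0) return(0)
  num / den
}

#' Permutation test for DDI significance
#'
#' Shuffles whole trials across direction labels (keeping the balanced
#' design), recomputes the full DDI — including re-selection of the best
#' direction and window — and reports the add-one-corrected fraction of
#' permuted DDIs at least as large as the observed one.
#'
#' @param windowed A [sliding_window_rates()] array.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return List: `p`, `ddi_observed`, `n_perm`.
#' @export
ddi_permutation_test <- function(windowed, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  dims <- dim(windowed)
  nd <- dims[1]; nw <- dims[2]; nt <- dims[3]
  tu <- matrix(aperm(windowed, c(1, 3, 2)), nd * nt, nw)
  group <- rep(seq_len(nd), nt)
  obs <- ddi_from_units(tu, group, nd, nt)$ddi
  count <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      if (ddi_from_units(tu, sample(group), nd, nt)$ddi >= obs)
        cnt <- cnt + 1L
    }
    cnt
  })
  list(p = (count + 1) / (n_perm + 1), ddi_observed = obs, n_perm = n_perm)
}

#' Vector-sum preferred direction
#'
#' Sums the 26 grid unit vectors weighted by each direction's mean rate at
#' the (first) peak window and returns the resultant in spherical
#' coordinates. For double-peak neurons only the first peak window is used.
#' A zero resultant (e.g. equal responses everywhere, which cancel by the
#' grid's antipodal symmetry) yields an undefined direction, flagged rather
#' than fabricated.
#'
#' @param windowed A [sliding_window_rates()] array.
#' @param grid Direction grid.
#' @param peak_windows Window indices from [count_peaks()]; the first is
#'   used. When empty or missing, the overall best window is used.
#' @return One-row tibble: `azimuth_deg`, `elevation_deg`, `magnitude`
#'   (spikes/s), `window`, `defined`.
#' @export
preferred_direction <- function(windowed, grid, peak_windows = NULL) {
  dirmean <- rowMeans(windowed, dims = 2)
  win <- if (!is.null(peak_windows) && length(peak_windows) > 0) {
    peak_windows[1]
  } else {
    best_dir <- which.max(rowMeans(dirmean))
    which.max(dirmean[best_dir, ])
  }
  wts <- dirmean[, win]
  xyz <- as.matrix(grid[, c("x", "y", "z")])
  v <- drop(crossprod(xyz, wts))
  mag <- sqrt(sum(v^2))
  if (mag < 1e-9 * max(1, max(abs(wts)))) {
    return(tibble::tibble(azimuth_deg = NA_real_, elevation_deg = NA_real_,
                          magnitude = 0, window = win, defined = FALSE))
  }
  sph <- cart_to_sph(v)
  tibble::tibble(azimuth_deg = sph[["azimuth_deg"]],
                 elevation_deg = sph[["elevation_deg"]],
                 magnitude = mag, window = win, defined = TRUE)
}

#' Monte-Carlo uniformity test for preferred directions on the sphere
#'
#' Rayleigh-type resultant-length test: the observed statistic is the length
#' of the mean unit vector of the sample; its null distribution is obtained
#' by drawing the same number of directions uniformly on the sphere. Small p
#' means the sample is more concentrated than uniform.
#'
#' @param directions Data frame/tibble with `azimuth_deg` and
#'   `elevation_deg` columns (degrees), >= 10 rows.
#' @param n_resample Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @return List: `p`, `resultant_length`, `n`, `n_resample`, `method`.
#' @export
uniformity_test <- function(directions, n_resample = 10000, seed = 1) {
  directions <- as.data.frame(directions)
  directions <- directions[stats::complete.cases(
    directions[c("azimuth_deg", "elevation_deg")]), ]
  n <- nrow(directions)
  if (n < 10) stop("uniformity test needs >= 10 directions, have ", n)
  u <- sph_to_cart(directions$azimuth_deg, directions$elevation_deg)
  r_obs <- sqrt(sum(colMeans(u)^2))
  count <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_resample)) {
      z <- matrix(stats::rnorm(3 * n), n, 3)
      z <- z / sqrt(rowSums(z^2))
      if (sqrt(sum(colMeans(z)^2)) >= r_obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(p = (count + 1) / (n_resample + 1), resultant_length = r_obs,
       n = n, n_resample = n_resample,
       method = "Monte-Carlo resultant-length (Rayleigh-type) test")
}
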