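#' Visual responsiveness by Bonferroni-corrected paired t-tests
#'
#' A cell is called visually responsive if, for at least one stimulus
#' condition, the paired two-sided t-test between its per-trial baseline
#' and stimulus dF/F values is significant after Bonferroni correction
#' across conditions: responsive iff `min(p) < alpha / n_conditions`.
#'
#' Degenerate conditions are handled by contract: if every paired
#' difference is exactly zero the condition's p-value is 1; if the
#' differences have zero variance but are not all zero the condition is
#' skipped (p = `NA`) with a warning. Conditions with fewer than two
#' trial pairs are likewise skipped.
#'
#' @param pairs Data frame with columns `condition`, `baseline`,
#'   `stimulus` (one row per trial).
#' @param alpha Familywise significance level (default 0.05).
#' @param n_conditions Number of conditions for the Bonferroni divisor;
#'   defaults to the number of distinct conditions present.
#' @return A list: `responsive` (logical), `p_values` (named by
#'   condition), `alpha_corrected`.
#' @export
responsiveness_test <- function(pairs, alpha = 0.05, n_conditions = NULL) {
  stopifnot(all(c("condition", "baseline", "stimulus") %in% names(pairs)))
  conds <- sort(unique(pairs$condition))
  if (is.null(n_conditions)) n_conditions <- length(conds)
  p <- vapply(conds, function(cd) {
    i <- pairs$condition == cd
    if (sum(i) < 2) return(NA_real_)
    d <- pairs$stimulus[i] - pairs$baseline[i]
    if (all(d == 0)) return(1)
    if (stats::sd(d) == 0) {
      warning("zero-variance nonzero paired differences in condition ", cd,
              "; condition skipped")
      return(NA_real_)
    }
    stats::t.test(pairs$stimulus[i], pairs$baseline[i], paired = TRUE)$p.value
  }, numeric(1))
  names(p) <- conds
  thr <- alpha / n_conditions
  list(responsive = isTRUE(any(p < thr, na.rm = TRUE)),
       p_values = p, alpha_corrected = thr)
}

#' Average responses to opposite drift directions
#'
#' Orientation tuning treats a grating and its 180-degree-opposite
#' drift direction as the same stimulus orientation, so their responses
#' are averaged: the response at orientation `theta` is the mean of the
#' responses at directions `theta` and `theta + 180`.
#'
#' @param directions_deg Stimulus directions in degrees.
#' @param responses Mean response per direction (same length).
#' @return Data frame `(orientation_deg, response)` sorted by
#'   orientation on `[0, 180)`.
#' @export
collapse_directions <- function(directions_deg, responses) {
  stopifnot(length(directions_deg) == length(responses))
  ori <- directions_deg %% 180
  agg <- tapply(responses, ori, mean)
  data.frame(orientation_deg = as.numeric(names(agg)),
             response = as.numeric(agg), row.names = NULL)
}

#' Convert Von Mises concentration to tuning width in degrees
#'
#' The concentration `kappa` of the orientation-domain Von Mises fit
#' corresponds to a variance of `1/kappa` (in squared radians on the
#' doubled-angle circle), reported as a standard deviation in degrees:
#' `sigma = (180 / pi) * sqrt(1 / kappa)`.
#'
#' @param kappa Concentration(s), > 0.
#' @return Tuning width(s) in degrees; strictly decreasing in `kappa`.
#' @examples
#' kappa_to_sigma(1)  # 57.2958
#' @export
kappa_to_sigma <- function(kappa) {
  stopifnot(all(kappa > 0))
  (180 / pi) * sqrt(1 / kappa)
}

# internal: residual for nls.lm, angles in degrees
vm_residual <- function(p, theta, y) y - von_mises(theta, p[1], p[2], p[3], p[4])

#' Fit a Von Mises orientation tuning curve by least squares
#'
#' Fits `B + R * exp(kappa * (cos(2 * (theta - mu)) - 1))` to mean
#' responses per orientation by bounded Levenberg--Marquardt least
#' squares, minimizing the sum of squared residuals. Constraints:
#' `R >= 0`, `kappa` in `(0, kappa_max]`; `mu` is reported folded to
#' `[0, 180)`.
#'
#' The optimizer is multi-started to avoid the periodic local minima of
#' the orientation domain: `mu` is initialized at every observed local
#' peak of the response profile (circularly), `kappa` at each of
#' `{0.5, 2, 8}`, with `B = min(response)` and `R = max - min`. The
#' lowest-SSE converged solution wins. A `start` vector
#' `(B, R, kappa, mu_deg)` replaces the multi-start (used for
#' warm-started bootstrap refits). If no start converges, `fit_ok` is
#' `FALSE` and parameters are `NA`.
#'
#' For a flat profile (`max == min`) the fitted `R` is ~0 and `mu` is
#' non-identifiable; the fit is still reported (`fit_ok = TRUE`) and
#' such cells are screened out downstream by the bootstrap reliability.
#'
#' @param orientations_deg Orientations in degrees (>= 4 distinct).
#' @param responses Mean response per orientation.
#' @param start Optional `(B, R, kappa, mu_deg)` single start.
#' @param kappa_max Upper concentration bound (default 50, a width of
#'   about 8 degrees -- below one stimulus step).
#' @return A list: `B`, `R`, `kappa`, `mu_deg`, `sigma_deg`, `sse`,
#'   `fit_ok`.
#' @export
fit_von_mises <- function(orientations_deg, responses, start = NULL,
                          kappa_max = 50) {
  if (is.null(start) && length(unique(orientations_deg)) < 4)
    stop("need at least 4 distinct orientations")
  stopifnot(length(orientations_deg) == length(responses),
            all(is.finite(responses)))
  lower <- c(-Inf, 0, 1e-3, -Inf)
  upper <- c(Inf, Inf, kappa_max, Inf)

  starts <- if (!is.null(start)) {
    list(pmin(pmax(start, lower), upper))
  } else {
    y <- responses
    n <- length(y)
    left <- y[c(n, seq_len(n - 1))]
    right <- y[c(seq_len(n)[-1], 1)]
    peaks <- which(y >= left & y >= right)
    if (length(peaks) == 0) peaks <- which.max(y)
    B0 <- min(y); R0 <- max(y) - min(y)
    out <- list()
    for (pk in peaks) for (k0 in c(0.5, 2, 8))
      out[[length(out) + 1L]] <- c(B0, R0, k0, orientations_deg[pk])
    out
  }

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = vm_residual, theta = orientations_deg,
                         y = responses, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4) || !all(is.finite(fit$par))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(list(B = NA_real_, R = NA_real_, kappa = NA_real_,
                mu_deg = NA_real_, sigma_deg = NA_real_, sse = NA_real_,
                fit_ok = FALSE))
  p <- best$par
  list(B = p[1], R = p[2], kappa = p[3], mu_deg = p[4] %% 180,
       sigma_deg = kappa_to_sigma(p[3]), sse = best$deviance, fit_ok = TRUE)
}

#' Nearest-rank percentile of bootstrap deviations
#'
#' The reliability statistic is the nearest-rank 90th percentile of the
#' bootstrap deviations: the value at index `ceiling(prob * n)` of the
#' ascending sort, so that a reliability of 20 means 90% of bootstrap
#' preferred orientations fall within 20 degrees of the original fit.
#'
#' @param deviations Nonnegative deviations in degrees.
#' @param prob Percentile level (default 0.9).
#' @return The nearest-rank percentile (degrees).
#' @export
reliability_from_deviations <- function(deviations, prob = 0.9) {
  stopifnot(length(deviations) >= 1, all(is.finite(deviations)))
  sort(deviations)[ceiling(prob * length(deviations))]
}

#' Bootstrap reliability of the preferred orientation
#'
#' Repeats the tuning fit on trial-resampled data: in each of `n_boot`
#' replicates, trials are resampled with replacement independently
#' within each stimulus condition (preserving the design and
#' per-condition sample sizes), condition means are recomputed, opposite
#' directions averaged, and the Von Mises fit repeated with the same
#' multi-start scheme as the original fit (a warm start would anchor
#' weakly tuned cells near the original preferred orientation and
#' understate their variability). The deviation of each replicate is the
#' circular orientation difference between its preferred orientation and
#' the original one, folded to `[0, 90]`; reliability is the
#' nearest-rank 90th percentile of the deviations.
#'
#' Replicates whose refit fails are dropped and counted; if more than
#' `max_fail_frac` of replicates fail, the result is flagged unreliable.
#'
#' @param trials Data frame of one cell's valid trials with columns
#'   `direction_deg`, `response`.
#' @param fit Original fit from [fit_von_mises()] (must have
#'   `fit_ok = TRUE`).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @param max_fail_frac Maximum tolerated fraction of failed refits.
#' @return A list: `reliability_deg`, `n_failed`, `unreliable`,
#'   `deviations`.
#' @export
bootstrap_reliability <- function(trials, fit, n_boot = 1000, seed = 1,
                                  max_fail_frac = 0.2) {
  if (!isTRUE(fit$fit_ok)) stop("original fit must have succeeded")
  by_cond <- split(trials$response, trials$direction_deg)
  dirs <- as.numeric(names(by_cond))
  ori_group <- factor(dirs %% 180)

  set.seed(seed)
  # condition x replicate matrix of resampled means
  cond_means <- vapply(by_cond, function(v) {
    n <- length(v)
    colMeans(matrix(v[sample.int(n, n * n_boot, replace = TRUE)], n, n_boot))
  }, numeric(n_boot))
  cond_means <- t(cond_means)                       # conditions x n_boot
  ori_means <- rowsum(cond_means, ori_group) /
    as.vector(table(ori_group))                     # orientations x n_boot
  ori_deg <- as.numeric(levels(ori_group))

  dev <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    fb <- fit_von_mises(ori_deg, ori_means[, b])
    if (fb$fit_ok) dev[b] <- circ_diff_orientation(fb$mu_deg, fit$mu_deg)
  }
  n_failed <- sum(is.na(dev))
  dev <- dev[!is.na(dev)]
  list(reliability_deg = if (length(dev)) reliability_from_deviations(dev)
       else NA_real_,
       n_failed = n_failed,
       unreliable = n_failed > max_fail_frac * n_boot,
       deviations = dev)
}

#' Classify a cell as tuned from its bootstrap reliability
#'
#' A cell is tuned when its reliability is strictly below the threshold;
#' the default 22.5 degrees is the stimulus-set interval of a
#' 16-direction protocol.
#'
#' @param reliability_deg Reliability value(s) in degrees.
#' @param threshold Strict upper bound (default 22.5).
#' @return Logical: `reliability_deg < threshold` (`NA` stays `NA`).
#' @export
classify_tuned <- function(reliability_deg, threshold = 22.5) {
  reliability_deg < threshold
}

#' Fit orientation tuning for every cell of a response table
#'
#' Runs the whole tuning module per cell: responsiveness test on the
#' paired baseline/stimulus trial values, direction means, collapse to
#' orientations, Von Mises fit, bootstrap reliability, and the
#' tuned/responsive flags. A cell is `tuned` only if it is responsive,
#' its fit succeeded, and its reliability is strictly below
#' `tuned_threshold`.
#'
#' @param resp Response table from [response_table()] /
#'   [session_responses()]: columns `cell`, `direction_deg`, `trial`,
#'   `baseline`, `response`.
#' @param alpha Responsiveness familywise level.
#' @param n_boot Bootstrap replicates per cell.
#' @param seed Master seed; each cell's bootstrap uses a recorded
#'   sub-seed.
#' @param tuned_threshold Reliability cutoff in degrees.
#' @return Data frame with one row per cell: `cell`, `B`, `R`, `kappa`,
#'   `mu_deg`, `sigma_deg`, `reliability_deg`, `responsive`, `tuned`,
#'   `fit_ok`, `n_boot_failed`, `n_boot`, `seed`.
#' @export
fit_tuning_session <- function(resp, alpha = 0.05, n_boot = 1000, seed = 1,
                               tuned_threshold = 22.5) {
  cells <- sort(unique(resp$cell))
  rows <- lapply(cells, function(cl) {
    tr <- resp[resp$cell == cl, ]
    rt <- responsiveness_test(data.frame(condition = tr$direction_deg,
                                         baseline = tr$baseline,
                                         stimulus = tr$response),
                              alpha = alpha)
    dir_means <- tapply(tr$response, tr$direction_deg, mean)
    ori <- collapse_directions(as.numeric(names(dir_means)),
                               as.numeric(dir_means))
    fit <- fit_von_mises(ori$orientation_deg, ori$response)
    rel <- NA_real_; n_failed <- NA_integer_
    if (fit$fit_ok) {
      br <- bootstrap_reliability(tr[, c("direction_deg", "response")], fit,
                                  n_boot = n_boot,
                                  seed = split_seed(seed, 1000L + cl))
      rel <- br$reliability_deg
      n_failed <- br$n_failed
    }
    data.frame(cell = cl, B = fit$B, R = fit$R, kappa = fit$kappa,
               mu_deg = fit$mu_deg, sigma_deg = fit$sigma_deg,
               reliability_deg = rel,
               responsive = rt$responsive,
               tuned = isTRUE(rt$responsive) && isTRUE(fit$fit_ok) &&
                 isTRUE(classify_tuned(rel, tuned_threshold)),
               fit_ok = fit$fit_ok,
               n_boot_failed = n_failed, n_boot = n_boot,
               seed = as.integer(seed))
  })
  do.call(rbind, rows)
}
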