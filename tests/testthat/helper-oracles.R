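# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: plain per-frame loops, sort-and-index
# percentiles, explicit ECDF sweeps, Monte-Carlo references.

# Naive per-frame dF/F recomputation (0-indexed onsets, as in the
# package contract but written as an explicit loop).
oracle_trial_dff <- function(trace, onset_frame, design) {
  b <- round(design$baseline_window_s * design$frame_rate_hz)
  s <- round(design$stim_duration_s * design$frame_rate_hz)
  out <- vector("list", length(onset_frame))
  for (i in seq_along(onset_frame)) {
    on <- onset_frame[i]
    f0_sum <- 0
    for (j in (on - b):(on - 1)) f0_sum <- f0_sum + trace[j + 1]
    f0 <- f0_sum / b
    stim <- numeric(s)
    for (j in 0:(s - 1)) stim[j + 1] <- (trace[on + j + 1] - f0) / f0
    out[[i]] <- list(f0 = f0, stim = stim, mean = sum(stim) / s)
  }
  out
}

# Nearest-rank percentile by explicit sort and index.
oracle_nearest_rank <- function(x, prob) {
  xs <- sort(x)
  xs[ceiling(prob * length(xs))]
}

# Two-sample KS D by explicit ECDF sweep over the pooled support.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (t in pts) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

# Fold an angular difference (degrees) to the [0, 90] orientation range,
# written independently of circ_diff_orientation.
oracle_fold90 <- function(d) {
  d <- abs(d) %% 180
  ifelse(d > 90, 180 - d, d)
}

# Monte-Carlo reference for the folded wrapped-normal step distribution:
# P(folded |step| < thr) for step ~ N(0, sd) wrapped on the 180-circle.
oracle_wrapped_normal_frac <- function(sd, thr, n = 1e6, seed = 99) {
  set.seed(seed)
  mean(oracle_fold90(rnorm(n, 0, sd)) < thr)
}

# Dense brute-force Von Mises SSE: grid over (mu, kappa) with
# closed-form (B, R) by linear least squares at each grid point
# (R clamped at 0, refitting B alone when the unconstrained R < 0).
oracle_vm_grid_sse <- function(ori_deg, y, mus = seq(0, 179.5, by = 0.5),
                               kappas = exp(seq(log(0.05), log(50), length.out = 50))) {
  best <- Inf
  for (k in kappas) {
    for (m in mus) {
      g <- exp(k * (cos(2 * (ori_deg - m) * pi / 180) - 1))
      X <- cbind(1, g)
      cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
      if (is.null(cf)) next
      if (cf[2] < 0) cf <- c(mean(y), 0)
      sse <- sum((y - X %*% cf)^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Deterministic small population for reuse in tests.
toy_population <- function(n = 4, seed = 11) {
  gen_population(n, frac_untuned = 0, seed = seed)
}
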