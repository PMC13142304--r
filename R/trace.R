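#' Estimate the neuropil contamination scale by skew maximization
#'
#' Somatic calcium signals are sparse and positively skewed, while the
#' out-of-focus neuropil contaminant is a smoother, more symmetric
#' signal. Subtracting the correctly scaled contaminant therefore
#' maximizes the skewness of the residual trace. This searches a grid of
#' candidate scales `a` and returns the one maximizing the adjusted
#' Fisher--Pearson sample skewness of `cell - a * neuropil`, breaking
#' ties toward the smallest `a`.
#'
#' A candidate producing a zero-variance (or otherwise undefined-skew)
#' residual is excluded from the search. If every candidate is excluded
#' the estimate is 0 and `all_excluded` is set (with a warning).
#'
#' @param cell,neuropil Equal-length numeric traces (fluorescence units).
#' @param grid Candidate scales in `[0, 1]`; default 0 to 1 in steps of
#'   0.01.
#' @return A list: `a` (the estimate), `skew` (profile over the grid,
#'   `-Inf` where excluded), `grid`, `all_excluded`.
#' @export
estimate_neuropil_scale <- function(cell, neuropil, grid = seq(0, 1, by = 0.01)) {
  if (length(cell) != length(neuropil)) stop("traces must have equal length")
  if (length(grid) == 0 || any(grid < 0) || any(grid > 1))
    stop("`grid` must be nonempty with values in [0, 1]")
  grid <- sort(grid)
  sk <- vapply(grid, function(a) {
    v <- cell - a * neuropil
    s <- e1071::skewness(v, type = 2)
    if (is.finite(s)) s else -Inf
  }, numeric(1))
  if (all(sk == -Inf)) {
    warning("skewness undefined at every candidate scale; returning 0")
    return(list(a = 0, skew = sk, grid = grid, all_excluded = TRUE))
  }
  # which.max returns the first (smallest-a) maximizer on ties
  list(a = grid[which.max(sk)], skew = sk, grid = grid, all_excluded = FALSE)
}

#' Subtract a scaled neuropil trace from a cell trace
#'
#' @param cell,neuropil Equal-length numeric traces.
#' @param a Contamination scale.
#' @return `cell - a * neuropil`.
#' @export
subtract_neuropil <- function(cell, neuropil, a) {
  if (length(cell) != length(neuropil)) stop("traces must have equal length")
  cell - a * neuropil
}

#' Per-trial dF/F segments from a fluorescence trace
#'
#' For each trial onset, F0 is the mean of the `baseline_window_s`
#' preceding frames and dF/F is `(f - F0) / F0` for every frame of the
#' baseline and stimulus windows. Onset frames are 0-indexed; the onset
#' frame is the first frame of the stimulus window and the baseline
#' window is strictly pre-onset.
#'
#' A trial whose F0 is not strictly positive is flagged invalid
#' (`valid = FALSE`, dF/F set to `NA`); the number of such trials is
#' recorded in the `n_invalid` attribute and they are excluded from
#' downstream response tables.
#'
#' @param trace Numeric fluorescence trace.
#' @param onsets Data frame with 0-indexed `onset_frame` and
#'   `direction_deg`.
#' @param design A [trial_design()].
#' @return A data frame with one row per trial: `trial`, `onset_frame`,
#'   `direction_deg`, `f0`, `valid`, plus list-columns `dff_baseline`
#'   and `dff_stim` holding the per-frame dF/F segments. Attribute
#'   `n_invalid` counts excluded trials.
#' @export
trial_dff <- function(trace, onsets, design) {
  fr <- design_frames(design)
  n <- length(trace)
  if (any(onsets$onset_frame - fr$baseline < 0) ||
      any(onsets$onset_frame + fr$stim > n))
    stop("every onset needs >= baseline frames before it and >= stimulus frames after it")

  rows <- lapply(seq_len(nrow(onsets)), function(i) {
    on <- onsets$onset_frame[i]           # 0-indexed
    base_idx <- (on - fr$baseline + 1L):on       # R 1-indexed
    stim_idx <- (on + 1L):(on + fr$stim)
    f0 <- mean(trace[base_idx])
    if (!is.finite(f0) || f0 <= 0) {
      list(f0 = f0, valid = FALSE,
           dff_baseline = rep(NA_real_, fr$baseline),
           dff_stim = rep(NA_real_, fr$stim))
    } else {
      list(f0 = f0, valid = TRUE,
           dff_baseline = (trace[base_idx] - f0) / f0,
           dff_stim = (trace[stim_idx] - f0) / f0)
    }
  })
  out <- data.frame(trial = seq_len(nrow(onsets)),
                    onset_frame = onsets$onset_frame,
                    direction_deg = onsets$direction_deg,
                    f0 = vapply(rows, `[[`, numeric(1), "f0"),
                    valid = vapply(rows, `[[`, logical(1), "valid"))
  out$dff_baseline <- lapply(rows, `[[`, "dff_baseline")
  out$dff_stim <- lapply(rows, `[[`, "dff_stim")
  attr(out, "n_invalid") <- sum(!out$valid)
  out
}

#' Mean evoked dF/F over the stimulus window
#'
#' The evoked response of a trial is the arithmetic mean of dF/F over
#' exactly `round(stim_duration_s * frame_rate_hz)` stimulus frames.
#'
#' @param dff_stim Numeric dF/F segment covering the stimulus window.
#' @param design A [trial_design()].
#' @return The mean dF/F (scalar).
#' @export
evoked_response <- function(dff_stim, design) {
  fr <- design_frames(design)
  if (length(dff_stim) != fr$stim)
    stop("stimulus segment must have exactly ", fr$stim, " frames")
  mean(dff_stim)
}

#' Build a tidy evoked-response table for a session
#'
#' Runs the full trace module over every cell of a session: optional
#' neuropil decontamination (scale estimated per cell by
#' [estimate_neuropil_scale()]), per-trial dF/F extraction, and
#' stimulus-window averaging. The baseline-window mean dF/F is retained
#' per trial as the paired "baseline response" used by the
#' responsiveness test.
#'
#' @param traces Cells x frames matrix of measured fluorescence.
#' @param onsets Data frame of 0-indexed `onset_frame`, `direction_deg`.
#' @param design A [trial_design()].
#' @param neuropil Cells x frames matrix of neuropil traces, or `NULL`
#'   to skip decontamination.
#' @param grid Scale grid passed to [estimate_neuropil_scale()].
#' @return A data frame `(cell, direction_deg, trial, baseline,
#'   response)` containing valid trials only, with attributes
#'   `neuropil_scale` (per-cell estimates, `NA` if skipped) and
#'   `n_invalid` (count of excluded trials).
#' @export
response_table <- function(traces, onsets, design, neuropil = NULL,
                           grid = seq(0, 1, by = 0.01)) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  n_cells <- nrow(traces)
  scales <- rep(NA_real_, n_cells)
  out <- vector("list", n_cells)
  n_invalid <- 0L
  for (c in seq_len(n_cells)) {
    tr <- traces[c, ]
    if (!is.null(neuropil)) {
      est <- estimate_neuropil_scale(tr, neuropil[c, ], grid)
      scales[c] <- est$a
      tr <- subtract_neuropil(tr, neuropil[c, ], est$a)
    }
    td <- trial_dff(tr, onsets, design)
    n_invalid <- n_invalid + attr(td, "n_invalid")
    ok <- which(td$valid)
    out[[c]] <- data.frame(
      cell = c,
      direction_deg = td$direction_deg[ok],
      trial = td$trial[ok],
      baseline = vapply(td$dff_baseline[ok], mean, numeric(1)),
      response = vapply(td$dff_stim[ok], function(s) evoked_response(s, design),
                        numeric(1)))
  }
  res <- do.call(rbind, out)
  attr(res, "neuropil_scale") <- scales
  attr(res, "n_invalid") <- n_invalid
  res
}

#' Extract responses from a synthetic session
#'
#' Convenience wrapper running [response_table()] on a
#' [gen_session()] object.
#'
#' @param session A `synthetic_session`.
#' @param correct_neuropil Estimate and subtract the neuropil component?
#' @param ... Passed to [response_table()].
#' @export
session_responses <- function(session, correct_neuropil = TRUE, ...) {
  stopifnot(inherits(session, "synthetic_session"))
  response_table(session$traces, session$onsets, session$design,
                 neuropil = if (correct_neuropil) session$neuropil else NULL,
                 ...)
}
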