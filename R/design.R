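#' Drifting-grating trial design
#'
#' Describes the stimulus protocol from which evoked responses are
#' extracted: a set of grating drift directions presented for a fixed
#' stimulus period, separated by an inter-trial interval (ITI), with a
#' pre-stimulus baseline window used to compute F0 for dF/F.
#'
#' Defaults follow a standard orientation-tuning protocol: 16 directions
#' at 22.5 degree increments, 2 s stimulus, 4 s ITI, 15 Hz acquisition,
#' with F0 taken over the 1 s preceding each stimulus onset.
#'
#' Frame windows are computed as `round(duration_s * frame_rate_hz)`
#' frames. Frames are 0-indexed; the onset frame belongs to the stimulus
#' window and the baseline window is strictly pre-onset.
#'
#' @param directions Stimulus drift directions in degrees, strictly
#'   increasing within `[0, 360)`.
#' @param stim_duration_s Stimulus duration in seconds.
#' @param iti_s Inter-trial interval in seconds.
#' @param baseline_window_s Pre-onset window, in seconds, averaged to F0.
#' @param frame_rate_hz Acquisition frame rate.
#' @param trials_per_condition Trials per direction (at least 2).
#' @return An object of class `trial_design`.
#' @examples
#' d <- trial_design()
#' design_frames(d)
#' @export
trial_design <- function(directions = seq(0, 337.5, by = 22.5),
                         stim_duration_s = 2,
                         iti_s = 4,
                         baseline_window_s = 1,
                         frame_rate_hz = 15,
                         trials_per_condition = 10) {
  stopifnot(length(directions) >= 1, is.numeric(directions))
  if (any(diff(directions) <= 0) || any(directions < 0) || any(directions >= 360))
    stop("`directions` must be strictly increasing within [0, 360)")
  if (stim_duration_s <= 0 || iti_s <= 0 || baseline_window_s <= 0)
    stop("stimulus, ITI and baseline durations must be positive")
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be positive")
  trials_per_condition <- as.integer(trials_per_condition)
  if (trials_per_condition < 2) stop("`trials_per_condition` must be >= 2")
  if (baseline_window_s > iti_s)
    stop("baseline window cannot be longer than the ITI")
  structure(
    list(directions = as.numeric(directions),
         stim_duration_s = stim_duration_s,
         iti_s = iti_s,
         baseline_window_s = baseline_window_s,
         frame_rate_hz = frame_rate_hz,
         trials_per_condition = trials_per_condition),
    class = "trial_design")
}

#' Frame-window sizes implied by a trial design
#'
#' @param design A [trial_design()].
#' @return A list with integer elements `stim`, `iti` and `baseline`
#'   (frames per window).
#' @export
design_frames <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  list(stim = as.integer(round(design$stim_duration_s * design$frame_rate_hz)),
       iti = as.integer(round(design$iti_s * design$frame_rate_hz)),
       baseline = as.integer(round(design$baseline_window_s * design$frame_rate_hz)))
}

#' @export
print.trial_design <- function(x, ...) {
  fr <- design_frames(x)
  cat(sprintf(
    "trial_design: %d directions (%g deg steps), %g s stim / %g s ITI @ %g Hz\n",
    length(x$directions),
    if (length(x$directions) > 1) x$directions[2] - x$directions[1] else NA,
    x$stim_duration_s, x$iti_s, x$frame_rate_hz))
  cat(sprintf("  %d trials/condition; windows (frames): stim %d, iti %d, baseline %d\n",
              x$trials_per_condition, fr$stim, fr$iti, fr$baseline))
  invisible(x)
}

# Derive a reproducible 32-bit sub-seed from a master seed. All package
# randomness flows from one user seed through this splitter so that
# sub-streams (trial order, neuropil, noise, ...) are independent and
# recorded.
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + 104729 * k) %% 2147483629)
}
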