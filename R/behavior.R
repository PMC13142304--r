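#' Conditioned place preference score
#'
#' `(t_cocaine - t_saline) / (t_cocaine + t_saline)`: -1 is maximal
#' preference for the saline-paired chamber, +1 maximal preference for
#' the cocaine-paired chamber, 0 no preference. Vectorized over
#' sessions.
#'
#' @param time_cocaine_s,time_saline_s Chamber times in seconds
#'   (both >= 0, not both 0).
#' @return Score(s) in `[-1, 1]`.
#' @examples
#' cpp_score(0, 1200)   # -1
#' cpp_score(1200, 0)   # +1
#' @export
cpp_score <- function(time_cocaine_s, time_saline_s) {
  if (any(time_cocaine_s < 0) || any(time_saline_s < 0))
    stop("chamber times must be >= 0")
  tot <- time_cocaine_s + time_saline_s
  if (any(tot == 0)) stop("chamber times cannot both be 0")
  (time_cocaine_s - time_saline_s) / tot
}

#' Percent prepulse inhibition of the startle reflex
#'
#' `%PPI = (pulse_alone - prepulse_pulse) / pulse_alone * 100`, computed
#' from the mean startle amplitudes of the two trial types. Values may
#' be negative (prepulse facilitation) and are not clipped.
#'
#' @param pulse_alone Mean startle amplitude on pulse-alone trials
#'   (> 0).
#' @param prepulse_pulse Mean startle amplitude on prepulse+pulse trials
#'   (>= 0); vectorized over prepulse levels.
#' @return Percent PPI value(s).
#' @examples
#' ppi_percent(200, 150)  # 25
#' @export
ppi_percent <- function(pulse_alone, prepulse_pulse) {
  if (any(pulse_alone <= 0)) stop("`pulse_alone` must be > 0")
  if (any(prepulse_pulse < 0)) stop("`prepulse_pulse` must be >= 0")
  (pulse_alone - prepulse_pulse) / pulse_alone * 100
}

#' Per-level percent PPI from a startle trial table
#'
#' Averages startle amplitudes within each trial type and applies
#' [ppi_percent()] at each prepulse level. Per-level values are the
#' primary output; the across-level mean is returned only on request.
#'
#' @param trials Data frame with columns `trial_type`
#'   (`"pulse_alone"` / `"prepulse_pulse"` / `"null"`), `prepulse_db`,
#'   `amplitude` -- e.g. the `ppi` component of [gen_behavior()].
#' @param average Also return the mean across prepulse levels?
#' @return Data frame `(prepulse_db, ppi_percent)`; if `average`, an
#'   extra row with `prepulse_db = NA` holding the across-level mean.
#' @export
ppi_table <- function(trials, average = FALSE) {
  pa <- mean(trials$amplitude[trials$trial_type == "pulse_alone"])
  levs <- sort(unique(trials$prepulse_db[trials$trial_type == "prepulse_pulse"]))
  pp <- vapply(levs, function(l) {
    mean(trials$amplitude[trials$trial_type == "prepulse_pulse" &
                            trials$prepulse_db == l])
  }, numeric(1))
  out <- data.frame(prepulse_db = levs, ppi_percent = ppi_percent(pa, pp))
  if (average)
    out <- rbind(out, data.frame(prepulse_db = NA_real_,
                                 ppi_percent = mean(out$ppi_percent)))
  out
}

#' Novel object recognition preference score
#'
#' `(t_novel - t_familiar) / (t_novel + t_familiar)` by default, so a
#' positive score means preference for the novel object (the convention
#' in which intact recognition memory plots positive). Set
#' `novel_positive = FALSE` for the opposite subtraction order.
#'
#' @param time_novel_s,time_familiar_s Object interaction times in
#'   seconds (both >= 0, sum > 0).
#' @param novel_positive Sign convention (default `TRUE`).
#' @return Score(s) in `[-1, 1]`.
#' @examples
#' nor_preference(30, 10)  # 0.5
#' @export
nor_preference <- function(time_novel_s, time_familiar_s,
                           novel_positive = TRUE) {
  if (any(time_novel_s < 0) || any(time_familiar_s < 0))
    stop("interaction times must be >= 0")
  tot <- time_novel_s + time_familiar_s
  if (any(tot == 0)) stop("total interaction time must be > 0")
  s <- (time_novel_s - time_familiar_s) / tot
  if (novel_positive) s else -s
}
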