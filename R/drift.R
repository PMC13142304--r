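#' Circular difference between two preferred orientations
#'
#' Orientation lives on a 180-degree circle, so the difference between
#' two preferred orientations is folded to `[0, 90]`: both angles are
#' reduced modulo 180 and the smaller of the two arc lengths is
#' returned, `min(|d|, 180 - |d|)`. Symmetric in its arguments and
#' invariant under adding multiples of 180 to either.
#'
#' @param mu1,mu2 Orientations in degrees (vectorized).
#' @return Difference(s) in degrees, in `[0, 90]`.
#' @examples
#' circ_diff_orientation(170, 10)  # 20, across the wrap
#' @export
circ_diff_orientation <- function(mu1, mu2) {
  d <- abs((mu1 %% 180) - (mu2 %% 180))
  pmin(d, 180 - d)
}

#' Per-cell change in preferred orientation between two sessions
#'
#' Joins the tuning fits of two sessions over a matched-cell map and
#' returns one drift record per retained pair: the circular change in
#' preferred orientation on `[0, 90]`. A pair is retained when both fits
#' succeeded and, if `require_tuned_a`, the session-A cell is tuned
#' (reliability below threshold on the reference day) -- the standard
#' inclusion rule for cross-session drift.
#'
#' @param fits_a,fits_b Fit tables from [fit_tuning_session()].
#' @param match Data frame with columns `cell_a`, `cell_b` (each cell at
#'   most once per side).
#' @param require_tuned_a Require `tuned` on session A (default `TRUE`).
#' @param interval Label for the session pair (e.g. `"D1-D3"`).
#' @return Data frame `(cell_a, cell_b, interval, delta_pref_deg)`.
#' @export
drift_table <- function(fits_a, fits_b, match, require_tuned_a = TRUE,
                        interval = "A-B") {
  stopifnot(all(c("cell_a", "cell_b") %in% names(match)))
  if (anyDuplicated(match$cell_a) || anyDuplicated(match$cell_b))
    stop("each cell may appear at most once per side of the match map")
  ia <- match(match$cell_a, fits_a$cell)
  ib <- match(match$cell_b, fits_b$cell)
  if (anyNA(ia))
    stop("no session-A fit for matched cell(s): ",
         paste(match$cell_a[is.na(ia)], collapse = ", "))
  if (anyNA(ib))
    stop("no session-B fit for matched cell(s): ",
         paste(match$cell_b[is.na(ib)], collapse = ", "))
  keep <- fits_a$fit_ok[ia] & fits_b$fit_ok[ib]
  if (require_tuned_a) keep <- keep & fits_a$tuned[ia]
  data.frame(cell_a = match$cell_a[keep],
             cell_b = match$cell_b[keep],
             interval = interval,
             delta_pref_deg = circ_diff_orientation(fits_a$mu_deg[ia][keep],
                                                    fits_b$mu_deg[ib][keep]))
}

#' Summarize a drift table
#'
#' Reports the fraction of matched cells whose preferred orientation
#' changed by less than the stability threshold (default 10 degrees),
#' the median change, and the number of cells.
#'
#' @param records Drift table from [drift_table()], or a numeric vector
#'   of deltas in degrees.
#' @param stability_threshold_deg Strict threshold in degrees.
#' @return A list: `fraction_below`, `median_delta`, `n`.
#' @export
drift_summary <- function(records, stability_threshold_deg = 10) {
  deltas <- if (is.data.frame(records)) records$delta_pref_deg else records
  n <- length(deltas)
  if (n == 0) return(list(fraction_below = NA_real_,
                          median_delta = NA_real_, n = 0L))
  list(fraction_below = sum(deltas < stability_threshold_deg) / n,
       median_delta = stats::median(deltas),
       n = n)
}
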