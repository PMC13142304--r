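#' Write a synthetic session to a directory
#'
#' Serializes traces and neuropil traces as delimited text (one row per
#' cell), the trial table as CSV, and the design, ground truth and seed
#' record as JSON.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(session$traces, file.path(dir, "traces.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(session$neuropil, file.path(dir, "neuropil.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.csv(session$onsets, file.path(dir, "onsets.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(session$design), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(session$seeds), file.path(dir, "seeds.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a synthetic session written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `synthetic_session`.
#' @export
read_session <- function(dir) {
  design <- jsonlite::read_json(file.path(dir, "design.json"),
                                simplifyVector = TRUE)
  design <- trial_design(directions = design$directions,
                         stim_duration_s = design$stim_duration_s,
                         iti_s = design$iti_s,
                         baseline_window_s = design$baseline_window_s,
                         frame_rate_hz = design$frame_rate_hz,
                         trials_per_condition = design$trials_per_condition)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(
    list(traces = as.matrix(utils::read.table(file.path(dir, "traces.tsv"))),
         neuropil = as.matrix(utils::read.table(file.path(dir, "neuropil.tsv"))),
         onsets = utils::read.csv(file.path(dir, "onsets.csv")),
         design = design,
         truth = truth,
         seeds = unlist(jsonlite::read_json(file.path(dir, "seeds.json"),
                                            simplifyVector = TRUE))),
    class = "synthetic_session")
}

#' Write or read a tidy response table as CSV
#'
#' @param resp Response table from [response_table()].
#' @param path CSV path.
#' @export
write_response_table <- function(resp, path) {
  utils::write.csv(resp, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) utils::read.csv(path)

#' Write a grayscale image as PNG
#'
#' Intensities are stored 16-bit, scaled by `max_value` (defaults to the
#' image maximum).
#'
#' @param image Numeric matrix.
#' @param path PNG path.
#' @param max_value Intensity mapped to white.
#' @export
write_image_png <- function(image, path, max_value = max(image)) {
  png::writePNG(pmin(pmax(image / max_value, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @param scale Multiplier applied on read to restore intensity units.
#' @export
read_image_png <- function(path, scale = 1) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * scale
}
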