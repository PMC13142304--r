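# 8-connected component labeling of a logical matrix by BFS over the
# foreground pixels. Returns an integer label matrix (0 = background).
# Written here because the particle-analysis contract requires
# 8-connectivity and an edge-count perimeter convention.
label_components8 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  fg <- which(bw)
  if (length(fg) == 0) return(lab)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  cur <- 0L
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((q - 1L) %% nr) + 1L
      nb <- q + off
      # drop neighbors that fall off the grid or wrap between columns
      keep <- nb >= 1L & nb <= nr * nc
      rshift <- rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L), length.out = 8L)
      keep <- keep & (r + rshift >= 1L) & (r + rshift <= nr)
      nb <- nb[keep]
      nb <- nb[bw[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# Boundary-edge perimeter: number of 4-neighbor pixel edges between the
# ROI and its exterior (image border counts as exterior).
roi_perimeter <- function(px, nr, nc) {
  key <- px[, 1] + px[, 2] * (nr + 2L)   # collision-free for in-range pixels
  inside <- new.env(hash = TRUE, size = nrow(px))
  for (k in key) assign(as.character(k), TRUE, envir = inside)
  per <- 0L
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; cc <- px[i, 2]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr < 1L || rr > nr || c2 < 1L || c2 > nc ||
          !exists(as.character(rr + c2 * (nr + 2L)), envir = inside))
        per <- per + 1L
    }
  }
  per
}

#' Segment immunopositive cells by threshold and particle filtering
#'
#' Mirrors the standard particle-analysis chain: binarize the image at a
#' global intensity threshold within the infected-region mask, label
#' 8-connected components, and keep particles passing the size and
#' circularity filters. Circularity is `4 * pi * area / perimeter^2`
#' (clipped to 1) with the perimeter counted as boundary pixel edges.
#'
#' An optional distance-transform watershed stage (via \pkg{EBImage},
#' off by default) splits touching nuclei before filtering.
#'
#' @param image Numeric intensity matrix (2-D, nonnegative).
#' @param mask Logical matrix of the analysis region, or `NULL` for the
#'   whole frame. An all-`FALSE` mask is an error.
#' @param threshold Intensity threshold; pixels strictly above it are
#'   foreground.
#' @param min_area,max_area Particle area bounds in pixels.
#' @param min_circularity Minimum circularity in `[0, 1]`.
#' @param watershed Split touching particles by distance-transform
#'   watershed first? Requires \pkg{EBImage}.
#' @return A list of `cell_roi` objects, each a list with `pixels`
#'   (n x 2 matrix of 0-based `(row, col)`), `area_px`, `perimeter_px`,
#'   `circularity`, `integrated_density`.
#' @export
segment_positive_cells <- function(image, mask = NULL, threshold,
                                   min_area = 30, max_area = 5000,
                                   min_circularity = 0.3,
                                   watershed = FALSE) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (!any(mask)) stop("mask is empty")
  if (min_area < 1) stop("`min_area` must be >= 1")
  bw <- image > threshold & mask
  if (watershed) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("the watershed stage requires the EBImage package")
    lab <- EBImage::watershed(EBImage::distmap(EBImage::Image(bw * 1)))
    lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  } else {
    lab <- label_components8(bw)
  }
  n_lab <- max(lab)
  if (n_lab == 0) return(list())
  nr <- nrow(image); nc <- ncol(image)
  rois <- list()
  for (l in seq_len(n_lab)) {
    idx <- which(lab == l)
    area <- length(idx)
    if (area < min_area || area > max_area) next
    px <- cbind(row = ((idx - 1L) %% nr) + 1L,
                col = ((idx - 1L) %/% nr) + 1L)
    per <- roi_perimeter(px, nr, nc)
    circ <- min(1, 4 * pi * area / per^2)
    if (circ < min_circularity) next
    rois[[length(rois) + 1L]] <- structure(
      list(pixels = px - 1L,                # 0-based
           area_px = area,
           perimeter_px = per,
           circularity = circ,
           integrated_density = sum(image[idx])),
      class = "cell_roi")
  }
  rois
}

#' Integrated density of an ROI
#'
#' Sum of image intensities over the ROI's pixels -- the per-cell
#' expression proxy in immunostaining quantification.
#'
#' @param image Numeric intensity matrix.
#' @param roi A `cell_roi` (0-based pixel coordinates).
#' @return Intensity sum (scalar).
#' @export
integrated_density <- function(image, roi) {
  px <- roi$pixels + 1L
  sum(image[cbind(px[, 1], px[, 2])])
}

#' Positive-cell count normalized by region area
#'
#' @param rois List of `cell_roi` from [segment_positive_cells()].
#' @param mask Logical matrix of the infected region.
#' @return A list: `n_positive`, `region_area_px` (mask pixel count),
#'   `density` (cells per pixel).
#' @export
counts_per_area <- function(rois, mask) {
  area <- sum(mask)
  if (area == 0) stop("mask is empty")
  list(n_positive = length(rois), region_area_px = area,
       density = length(rois) / area)
}

#' Compare two per-cell intensity distributions
#'
#' Two-sample two-sided Kolmogorov--Smirnov test:
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value. Used to
#' compare per-cell integrated-density distributions between
#' experimental conditions.
#'
#' @param a,b Numeric samples (e.g. integrated densities per cell).
#' @return A list: `D`, `p`.
#' @export
compare_intensity_distributions <- function(a, b) {
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
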