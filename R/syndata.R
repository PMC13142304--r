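#' Von Mises orientation tuning curve
#'
#' Evaluates `B + R * exp(kappa * (cos(2 * (theta - mu)) - 1))` with angles
#' in degrees. `B` is the baseline response, `R` the modulation above
#' baseline at the preferred orientation, `kappa` the concentration
#' (sharpness), and `mu` the preferred orientation on the 180-degree
#' orientation circle. The factor 2 inside the cosine makes the curve
#' 180-degree periodic, as appropriate for orientation (not direction)
#' tuning.
#'
#' @param theta_deg Stimulus angle(s), degrees.
#' @param B,R,kappa,mu_deg Tuning parameters (see Details).
#' @return Response value(s), same units as `B` and `R` (dF/F here).
#' @examples
#' von_mises(c(0, 45, 90), B = 0.1, R = 1, kappa = 2, mu_deg = 90)
#' @export
von_mises <- function(theta_deg, B, R, kappa, mu_deg) {
  B + R * exp(kappa * (cos(2 * (theta_deg - mu_deg) * pi / 180) - 1))
}

#' Generate a ground-truth tuned population
#'
#' Draws per-cell Von Mises tuning parameters. A fraction of cells is
#' emitted untuned (`R = 0`); preferred orientations are uniform on
#' `[0, 180)`. Deterministic for a fixed seed.
#'
#' Default ranges are typical of dF/F responses in mouse V1: baseline
#' `B` up to 0.2, modulation `R` in 0.5--1.5, concentration `kappa` in
#' 1--4 (tuning widths of roughly 29--57 degrees).
#'
#' @param n_cells Number of cells (>= 1).
#' @param param_ranges Named list of `c(lo, hi)` ranges for `B`, `R`,
#'   `kappa`. `mu` is always uniform on `[0, 180)`.
#' @param frac_untuned Fraction of cells with `R = 0`, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A data frame with one row per cell: `cell`, `B`, `R`,
#'   `kappa`, `mu`, `tuned_truth`.
#' @export
gen_population <- function(n_cells,
                           param_ranges = list(B = c(0, 0.2),
                                               R = c(0.5, 1.5),
                                               kappa = c(1, 4)),
                           frac_untuned = 0,
                           seed = 1) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (frac_untuned < 0 || frac_untuned > 1) stop("`frac_untuned` must lie in [0, 1]")
  rng <- function(name, lo_ok) {
    r <- param_ranges[[name]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2] || any(!is.finite(r)))
      stop("invalid range for `", name, "`")
    if (r[1] < lo_ok) stop("range for `", name, "` violates its lower bound")
    r
  }
  rB <- rng("B", -Inf); rR <- rng("R", 0); rk <- rng("kappa", 0)
  if (rk[1] <= 0) stop("`kappa` range must be strictly positive")

  set.seed(split_seed(seed, 1L))
  pop <- data.frame(
    cell = seq_len(n_cells),
    B = stats::runif(n_cells, rB[1], rB[2]),
    R = stats::runif(n_cells, rR[1], rR[2]),
    kappa = stats::runif(n_cells, rk[1], rk[2]),
    mu = stats::runif(n_cells, 0, 180))
  n_untuned <- round(frac_untuned * n_cells)
  untuned <- if (n_untuned > 0) sample(n_cells, n_untuned) else integer(0)
  pop$R[untuned] <- 0
  pop$tuned_truth <- !(pop$cell %in% untuned)
  pop
}

# Smooth, positive, low-frequency neuropil contaminant: an AR(1) process
# with a long correlation time, rescaled to a fixed mean and SD in
# fluorescence units. Spectrally distinct from the sparse transient-like
# cell responses so that skew maximization identifies the scale factor.
neuropil_trace <- function(n_frames, mean_f = 50, sd_f = 30, phi = 0.98) {
  x <- as.numeric(stats::filter(stats::rnorm(n_frames), phi, method = "recursive"))
  pmax(mean_f + sd_f * (x - mean(x)) / stats::sd(x), 0)
}

#' Simulate one imaging session of a tuned population
#'
#' Builds per-cell fluorescence traces for a full randomly-interleaved
#' grating session. Each cell's measured trace is
#' `F_base * (1 + kernel) + a_true * neuropil + noise`, where the kernel
#' is a boxcar over each stimulus window at the cell's Von Mises response
#' to that trial's direction, the neuropil trace is a smooth positive
#' low-frequency contaminant, and the noise is white Gaussian with SD
#' `noise_sd` in dF/F units (i.e. `noise_sd * F_base` in fluorescence
#' units). The baseline window preceding each onset carries only
#' `F_base` (plus contaminant and noise), so the noiseless evoked dF/F
#' at angle theta equals the full Von Mises value including `B`.
#'
#' Because the contaminant and noise streams do not depend on `a_true`,
#' the trace generated at `a_true = a` minus `a * neuropil` reproduces
#' the `a_true = 0` trace exactly for the same seed.
#'
#' @param pop Population data frame from [gen_population()].
#' @param design A [trial_design()].
#' @param noise_sd White-noise SD in dF/F units (>= 0).
#' @param a_true True neuropil contamination scale, in `[0, 1]`.
#' @param seed Integer seed.
#' @param f_base Baseline fluorescence level (arbitrary units).
#' @return An object of class `synthetic_session`: list with `traces`
#'   and `neuropil` (cells x frames matrices), `onsets` (data frame of
#'   0-indexed `onset_frame` and `direction_deg`), `design`, `truth`
#'   (the population plus `a_true`), and the sub-seed record.
#' @export
gen_session <- function(pop, design = trial_design(), noise_sd = 0.05,
                        a_true = 0.7, seed = 1, f_base = 100) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (a_true < 0 || a_true > 1) stop("`a_true` must lie in [0, 1]")
  fr <- design_frames(design)
  n_dir <- length(design$directions)
  n_trials <- n_dir * design$trials_per_condition
  n_frames <- fr$iti + n_trials * (fr$stim + fr$iti)
  n_cells <- nrow(pop)

  seeds <- c(order = split_seed(seed, 2L),
             neuropil = split_seed(seed, 3L),
             noise = split_seed(seed, 4L))
  set.seed(seeds[["order"]])
  dir_order <- sample(rep(design$directions, design$trials_per_condition))
  onset_frame <- fr$iti + (seq_len(n_trials) - 1L) * (fr$stim + fr$iti)

  # response kernel shared across cells up to tuning parameters
  kernel <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_trials)) {
    cols <- (onset_frame[i] + 1L):(onset_frame[i] + fr$stim)
    kernel[, cols] <- von_mises(dir_order[i], pop$B, pop$R, pop$kappa, pop$mu)
  }
  clean <- f_base * (1 + kernel)

  set.seed(seeds[["neuropil"]])
  neuropil <- t(vapply(seq_len(n_cells), function(i) neuropil_trace(n_frames),
                       numeric(n_frames)))
  set.seed(seeds[["noise"]])
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(n_cells * n_frames, 0, noise_sd * f_base), n_cells, n_frames)
  else matrix(0, n_cells, n_frames)

  structure(
    list(traces = clean + a_true * neuropil + noise,
         neuropil = neuropil,
         onsets = data.frame(onset_frame = onset_frame,
                             direction_deg = dir_order),
         design = design,
         truth = list(params = pop, a_true = a_true,
                      noise_sd = noise_sd, f_base = f_base),
         seeds = c(master = as.integer(seed), seeds)),
    class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("synthetic_session: %d cells x %d frames, %d trials, a_true = %g, noise_sd = %g\n",
              nrow(x$traces), ncol(x$traces), nrow(x$onsets),
              x$truth$a_true, x$truth$noise_sd))
  invisible(x)
}

#' Simulate multiple sessions with drifting preferred orientation
#'
#' Session 1 uses the population's tuning parameters as-is; each later
#' session perturbs every cell's preferred orientation by an independent
#' wrapped-normal step of SD `drift_sd` degrees on the 180-degree
#' orientation circle (a random walk across sessions, mimicking
#' representational drift over days). All other tuning parameters are
#' held fixed. The per-session true `mu` is recorded in each session's
#' truth.
#'
#' @inheritParams gen_session
#' @param drift_sd Per-step drift SD in degrees (>= 0).
#' @param n_sessions Number of sessions (>= 1).
#' @return A list of `synthetic_session` objects.
#' @export
gen_drifted_sessions <- function(pop, design = trial_design(), drift_sd = 10,
                                 n_sessions = 2, noise_sd = 0.05,
                                 a_true = 0.7, seed = 1) {
  if (drift_sd < 0) stop("`drift_sd` must be >= 0")
  n_sessions <- as.integer(n_sessions)
  if (n_sessions < 1) stop("`n_sessions` must be >= 1")
  sessions <- vector("list", n_sessions)
  mu_k <- pop$mu
  for (k in seq_len(n_sessions)) {
    if (k > 1) {
      set.seed(split_seed(seed, 100L + k))
      mu_k <- (mu_k + stats::rnorm(nrow(pop), 0, drift_sd)) %% 180
    }
    pop_k <- pop
    pop_k$mu <- mu_k
    sessions[[k]] <- gen_session(pop_k, design, noise_sd = noise_sd,
                                 a_true = a_true,
                                 seed = split_seed(seed, 200L + k))
  }
  sessions
}

#' Simulate behavioral sessions with known expected scores
#'
#' Generates the raw quantities from which the three behavioral
#' plasticity scores are computed, under a controlled truth:
#'
#' * **CPP** (conditioned place preference): per-session times in the
#'   cocaine- and saline-paired chambers. The cocaine-side proportion of
#'   a fixed total time is Beta-distributed with mean `(1 + effect) / 2`,
#'   so the expected CPP score equals `effect` exactly (0 for a null
#'   session).
#' * **PPI** (prepulse inhibition): per-trial startle amplitudes for
#'   pulse-alone, prepulse+pulse at each prepulse level, and null trials.
#'   Prepulse trials at attenuation `a` have mean amplitude
#'   `(1 - a) * pulse_mean`, so the expected percent PPI at that level is
#'   `100 * a`. Amplitudes are Gamma-distributed with coefficient of
#'   variation `noise_cv` (set 0 for deterministic amplitudes).
#' * **NOR** (novel object recognition): per-session times with the novel
#'   and familiar objects, Beta scheme as for CPP so the expected
#'   preference score equals `effect`.
#'
#' Any component may instead fix its raw values exactly via `times`
#' (CPP/NOR) for deterministic worked examples.
#'
#' Defaults follow common task parameters: 30-minute (1800 s) CPP test
#' with two paired chambers, a 42-trial startle session (18 pulse-alone,
#' 6 prepulse+pulse at each of 4, 8 and 12 dB above background, 6 null),
#' and 5-minute NOR tests with ~40 s of total object interaction.
#'
#' @param spec A list with optional components `cpp`, `ppi`, `nor`.
#'   `cpp`/`nor`: `list(n, total_s, effect, concentration)` or
#'   `list(times = c(<drug/novel>, <vehicle/familiar>))`.
#'   `ppi`: `list(n_pulse, n_prepulse_each, pulse_mean, attenuation,
#'   null_mean, noise_cv)` with `attenuation` named by prepulse level in
#'   dB above background.
#' @param seed Integer seed.
#' @return An object of class `behavior_truth`: list with data frames
#'   `cpp` (`session`, `time_cocaine_s`, `time_saline_s`), `ppi`
#'   (`trial`, `trial_type`, `prepulse_db`, `amplitude`), `nor`
#'   (`session`, `time_novel_s`, `time_familiar_s`), plus the expected
#'   scores under the generating truth.
#' @export
gen_behavior <- function(spec = list(), seed = 1) {
  out <- list(expected = list())

  beta_times <- function(cfg, seed_off, labels) {
    n <- cfg$n %||% 1L
    total <- cfg$total_s %||% 1800
    effect <- cfg$effect %||% 0
    conc <- cfg$concentration %||% 20
    if (!is.null(cfg$times)) {
      stopifnot(length(cfg$times) == 2, all(cfg$times >= 0), sum(cfg$times) > 0)
      d <- data.frame(session = 1L, a = cfg$times[1], b = cfg$times[2])
    } else {
      if (abs(effect) > 1) stop("`effect` must lie in [-1, 1]")
      m <- (1 + effect) / 2
      set.seed(split_seed(seed, seed_off))
      p <- if (m %in% c(0, 1)) rep(m, n) else stats::rbeta(n, m * conc, (1 - m) * conc)
      d <- data.frame(session = seq_len(n), a = total * p, b = total * (1 - p))
    }
    names(d)[2:3] <- labels
    list(d = d, effect = if (is.null(cfg$times)) effect
         else unname((cfg$times[1] - cfg$times[2]) / sum(cfg$times)))
  }

  if (!is.null(spec$cpp)) {
    r <- beta_times(spec$cpp, 11L, c("time_cocaine_s", "time_saline_s"))
    out$cpp <- r$d
    out$expected$cpp_score <- r$effect
  }
  if (!is.null(spec$nor)) {
    cfg <- spec$nor
    cfg$total_s <- cfg$total_s %||% 40
    r <- beta_times(cfg, 12L, c("time_novel_s", "time_familiar_s"))
    out$nor <- r$d
    out$expected$nor_preference <- r$effect
  }
  if (!is.null(spec$ppi)) {
    cfg <- spec$ppi
    n_pulse <- cfg$n_pulse %||% 18L
    n_pre <- cfg$n_prepulse_each %||% 6L
    pulse_mean <- cfg$pulse_mean %||% 200
    att <- cfg$attenuation %||% c("4" = 0.3, "8" = 0.5, "12" = 0.7)
    null_mean <- cfg$null_mean %||% 5
    cv <- cfg$noise_cv %||% 0.2
    if (any(att < 0)) stop("attenuations must be >= 0")
    draw <- function(n, m) {
      if (cv == 0 || m == 0) rep(m, n)
      else stats::rgamma(n, shape = 1 / cv^2, scale = m * cv^2)
    }
    set.seed(split_seed(seed, 13L))
    rows <- list(data.frame(trial_type = "pulse_alone", prepulse_db = NA_real_,
                            amplitude = draw(n_pulse, pulse_mean)))
    for (lev in names(att)) {
      rows[[length(rows) + 1L]] <- data.frame(
        trial_type = "prepulse_pulse", prepulse_db = as.numeric(lev),
        amplitude = draw(n_pre, (1 - att[[lev]]) * pulse_mean))
    }
    rows[[length(rows) + 1L]] <- data.frame(trial_type = "null",
                                            prepulse_db = NA_real_,
                                            amplitude = draw(6L, null_mean))
    ppi <- do.call(rbind, rows)
    ppi <- cbind(trial = seq_len(nrow(ppi)), ppi)
    out$ppi <- ppi
    out$expected$ppi_percent <- 100 * att
  }
  out$seed <- as.integer(seed)
  structure(out, class = "behavior_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize a labeled-nuclei image with known positive cells
#'
#' Plants non-overlapping bright disks ("immunopositive nuclei") of
#' known center, radius and intensity on a low constant background,
#' inside an infected-region mask, and records the ground truth of every
#' planted cell including its exact rasterized pixel count and total
#' intensity. A disk's pixels are those whose center lies within the
#' radius of the planted center; disk pixels take the cell's intensity
#' value (replacing background).
#'
#' Placement is by rejection sampling with a minimum center separation
#' of `r_i + r_j + min_sep`; if `n_cells` cannot be placed after
#' `200 * n_cells` tries the generator stops with an error.
#'
#' @param n_cells Number of cells to plant (>= 0).
#' @param radius_range `c(lo, hi)` disk radius in pixels.
#' @param intensity_range `c(lo, hi)` disk intensity (must exceed
#'   `background`).
#' @param shape `c(rows, cols)` image size.
#' @param mask Logical matrix of the infected region, or `NULL` for the
#'   full frame.
#' @param background Constant background intensity.
#' @param min_sep Extra center separation in pixels beyond touching.
#' @param seed Integer seed.
#' @return An object of class `synthetic_image`: list with `image`
#'   (numeric matrix), `mask` (logical matrix) and `truth` (data frame
#'   `cell`, `row`, `col` (0-based centers), `radius`, `intensity`,
#'   `n_px`, `total_intensity`).
#' @export
gen_ensemble_image <- function(n_cells, radius_range = c(4, 8),
                               intensity_range = c(120, 200),
                               shape = c(256, 256), mask = NULL,
                               background = 10, min_sep = 3, seed = 1) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 0) stop("`n_cells` must be >= 0")
  if (min(intensity_range) <= background)
    stop("planted intensities must exceed the background")
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  if (!identical(dim(mask), as.integer(shape)))
    stop("`mask` must match `shape`")
  if (!any(mask)) stop("`mask` is empty")

  img <- matrix(background, shape[1], shape[2])
  set.seed(split_seed(seed, 21L))
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0); intens <- numeric(0)
  tries <- 0L; max_tries <- max(200L * n_cells, 1L)
  mask_idx <- which(mask, arr.ind = TRUE)
  while (nrow(centers) < n_cells) {
    if (tries >= max_tries)
      stop("could not place ", n_cells, " non-overlapping cells (generation error)")
    tries <- tries + 1L
    r <- stats::runif(1, radius_range[1], radius_range[2])
    ctr <- mask_idx[sample.int(nrow(mask_idx), 1L), ]
    if (ctr[1] - r < 1 || ctr[1] + r > shape[1] ||
        ctr[2] - r < 1 || ctr[2] + r > shape[2]) next
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
      if (any(d < radii + r + min_sep)) next
    }
    centers <- rbind(centers, ctr)
    radii <- c(radii, r)
    intens <- c(intens, stats::runif(1, intensity_range[1], intensity_range[2]))
  }

  n_px <- integer(n_cells); total <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    rr <- ceiling(radii[i])
    rows <- max(1, centers[i, 1] - rr):min(shape[1], centers[i, 1] + rr)
    cols <- max(1, centers[i, 2] - rr):min(shape[2], centers[i, 2] + rr)
    sub <- expand.grid(row = rows, col = cols)
    inside <- (sub$row - centers[i, 1])^2 + (sub$col - centers[i, 2])^2 <= radii[i]^2
    px <- sub[inside, ]
    img[cbind(px$row, px$col)] <- intens[i]
    n_px[i] <- nrow(px)
    total[i] <- intens[i] * nrow(px)
  }

  truth <- data.frame(cell = seq_len(n_cells),
                      row = centers[, 1] - 1, col = centers[, 2] - 1,
                      radius = radii, intensity = intens,
                      n_px = n_px, total_intensity = total)
  if (n_cells == 0)
    truth <- data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
                        radius = numeric(0), intensity = numeric(0),
                        n_px = integer(0), total_intensity = numeric(0))
  structure(list(image = img, mask = mask, truth = truth,
                 background = background, seed = as.integer(seed)),
            class = "synthetic_image")
}
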