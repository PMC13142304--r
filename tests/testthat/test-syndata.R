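test_that("population generation is deterministic and honors the untuned fraction", {
  p1 <- gen_population(100, seed = 1)
  p2 <- gen_population(100, seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, gen_population(100, seed = 2)))

  one <- gen_population(1, frac_untuned = 1, seed = 3)
  expect_identical(one$R, 0)
  expect_false(one$tuned_truth)

  half <- gen_population(200, frac_untuned = 0.5, seed = 4)
  expect_equal(sum(half$R == 0), 100)
  expect_true(all(half$kappa > 0), all(half$mu >= 0 & half$mu < 180))

  expect_error(gen_population(10, param_ranges = list(B = c(0, 1), R = c(-1, 1),
                                                      kappa = c(1, 2))),
               "lower bound")
  expect_error(gen_population(10, param_ranges = list(B = c(1, 0), R = c(0, 1),
                                                      kappa = c(1, 2))),
               "invalid range")
})

test_that("preferred orientations are uniform on [0, 180)", {
  pop <- gen_population(10000, seed = 5)
  counts <- table(cut(pop$mu, seq(0, 180, by = 18), include.lowest = TRUE))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("session construction is exact: noiseless identity and additive contamination", {
  pop <- toy_population()
  d <- trial_design(trials_per_condition = 3)
  s0 <- gen_session(pop, d, noise_sd = 0, a_true = 0, seed = 7)
  resp <- session_responses(s0, correct_neuropil = FALSE)
  for (cl in pop$cell) {
    r <- resp[resp$cell == cl, ]
    expect_equal(r$response,
                 von_mises(r$direction_deg, pop$B[cl], pop$R[cl],
                           pop$kappa[cl], pop$mu[cl]),
                 tolerance = 1e-12)
  }

  s7 <- gen_session(pop, d, noise_sd = 0.05, a_true = 0.7, seed = 7)
  sz <- gen_session(pop, d, noise_sd = 0.05, a_true = 0, seed = 7)
  expect_equal(s7$traces - 0.7 * s7$neuropil, sz$traces, tolerance = 1e-12)
  expect_identical(gen_session(pop, d, seed = 8)$traces,
                   gen_session(pop, d, seed = 8)$traces)
  expect_error(gen_session(pop, d, noise_sd = -0.1), "noise_sd")
})

test_that("session onsets leave room for baseline and stimulus windows", {
  pop <- toy_population(2)
  d <- trial_design(trials_per_condition = 2)
  s <- gen_session(pop, d, seed = 1)
  fr <- design_frames(d)
  expect_true(all(s$onsets$onset_frame - fr$baseline >= 0))
  expect_true(all(s$onsets$onset_frame + fr$stim <= ncol(s$traces)))
  expect_equal(nrow(s$truth$params), nrow(s$traces))
})

test_that("drifted sessions perturb mu as a wrapped-normal walk", {
  pop <- toy_population(6)
  d <- trial_design(trials_per_condition = 2)
  still <- gen_drifted_sessions(pop, d, drift_sd = 0, n_sessions = 3,
                                noise_sd = 0, a_true = 0, seed = 2)
  for (s in still) expect_equal(s$truth$params$mu, pop$mu)

  single <- gen_drifted_sessions(pop, d, drift_sd = 10, n_sessions = 1, seed = 2)
  expect_length(single, 1)
  expect_equal(single[[1]]$truth$params$mu, pop$mu)
  expect_error(gen_drifted_sessions(pop, d, drift_sd = -1), "drift_sd")

  # median folded step matches a direct Monte-Carlo of the wrapped normal
  big <- gen_population(1000, seed = 3)
  ss <- gen_drifted_sessions(big, trial_design(trials_per_condition = 2),
                             drift_sd = 10, n_sessions = 2,
                             noise_sd = 0, a_true = 0, seed = 4)
  deltas <- oracle_fold90(ss[[2]]$truth$params$mu - ss[[1]]$truth$params$mu)
  set.seed(42)
  ref <- median(oracle_fold90(rnorm(1e6, 0, 10)))
  expect_lt(abs(median(deltas) - ref), 0.75)  # ~3 SE of a median over n=1000
})

test_that("behavior generator supports fixed, null, and effect sessions", {
  fixed <- gen_behavior(list(cpp = list(times = c(900, 300))), seed = 1)
  expect_identical(fixed$cpp$time_cocaine_s, 900)
  expect_identical(fixed$cpp$time_saline_s, 300)

  null <- gen_behavior(list(cpp = list(n = 10000, effect = 0)), seed = 2)
  sc <- cpp_score(null$cpp$time_cocaine_s, null$cpp$time_saline_s)
  expect_lt(abs(mean(sc)), 3 * sd(sc) / sqrt(length(sc)))

  eff <- gen_behavior(list(nor = list(n = 10000, effect = 0.4)), seed = 3)
  pr <- nor_preference(eff$nor$time_novel_s, eff$nor$time_familiar_s)
  expect_lt(abs(mean(pr) - 0.4), 3 * sd(pr) / sqrt(length(pr)))

  # deterministic amplitudes: expected %PPI equals 100 * attenuation
  ppi <- gen_behavior(list(ppi = list(attenuation = c("8" = 0.5),
                                      noise_cv = 0)), seed = 4)
  tab <- ppi_table(ppi$ppi)
  expect_equal(tab$ppi_percent, 50)
  expect_true(all(ppi$ppi$amplitude >= 0))
})

test_that("ensemble image generator plants disks with recorded truth", {
  blank <- gen_ensemble_image(0, seed = 1)
  expect_equal(unique(as.vector(blank$image)), blank$background)
  expect_equal(nrow(blank$truth), 0)

  img <- gen_ensemble_image(8, seed = 2)
  expect_equal(nrow(img$truth), 8)
  # planted totals match c * pi * r^2 up to rasterization of the disk
  expect_equal(img$truth$total_intensity,
               img$truth$intensity * img$truth$n_px)
  expect_true(all(abs(img$truth$n_px - pi * img$truth$radius^2)
                  < 6 * img$truth$radius))
  # non-overlap: no pixel brighter than one cell's intensity + background
  expect_lte(sum(img$image > img$background), sum(img$truth$n_px))

  expect_error(gen_ensemble_image(500, radius_range = c(20, 30),
                                  shape = c(64, 64), seed = 3),
               "generation error")
  expect_error(gen_ensemble_image(1, intensity_range = c(1, 5),
                                  background = 10), "background")
})

test_that("session round-trips through directory serialization", {
  pop <- toy_population(2)
  d <- trial_design(trials_per_condition = 2)
  s <- gen_session(pop, d, seed = 9)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(unname(as.matrix(s2$traces)), unname(s$traces), tolerance = 1e-10)
  expect_equal(s2$onsets, s$onsets)
  expect_equal(s2$design$directions, d$directions)
  expect_equal(s2$truth$params$mu, pop$mu, tolerance = 1e-10)
})
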