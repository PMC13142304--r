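test_that("neuropil subtraction is exact arithmetic", {
  expect_equal(subtract_neuropil(c(2, 4), c(2, 2), 0.5), c(1, 3))
  expect_equal(subtract_neuropil(c(2, 4), c(9, 9), 0), c(2, 4))
  expect_equal(subtract_neuropil(c(2, 4), c(2, 4), 1), c(0, 0))
  expect_error(subtract_neuropil(1:3, 1:4, 0.5), "equal length")
})

test_that("skew-maximizing scale handles degenerate contaminants by contract", {
  set.seed(1)
  cell <- rexp(500)
  # zero contaminant: all skews equal, tie broken toward the smallest a
  est <- estimate_neuropil_scale(cell, rep(0, 500))
  expect_equal(est$a, 0)
  # cell == neuropil exactly: a = 1 gives zero variance and is excluded
  est2 <- estimate_neuropil_scale(cell, cell)
  expect_equal(est2$skew[est2$grid == 1], -Inf)
  expect_false(est2$all_excluded)
  expect_true(est2$a < 1)
  # constant traces: every candidate degenerate -> 0 with a warning
  expect_warning(est3 <- estimate_neuropil_scale(rep(2, 100), rep(1, 100)),
                 "returning 0")
  expect_true(est3$all_excluded)
  expect_equal(est3$a, 0)
})

test_that("skew-maximizing scale recovers the true contamination", {
  pop <- gen_population(1, seed = 2)
  d <- trial_design()
  errs <- vapply(1:10, function(s) {
    sess <- gen_session(pop, d, noise_sd = 0.05, a_true = 0.7, seed = s)
    abs(estimate_neuropil_scale(sess$traces[1, ], sess$neuropil[1, ])$a - 0.7)
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("scale estimate improves with trace length", {
  pop <- gen_population(1, seed = 3)
  short_d <- trial_design(trials_per_condition = 2)
  long_d <- trial_design(trials_per_condition = 10)
  err <- function(d, s) {
    sess <- gen_session(pop, d, noise_sd = 0.05, a_true = 0.5, seed = s)
    abs(estimate_neuropil_scale(sess$traces[1, ], sess$neuropil[1, ])$a - 0.5)
  }
  e_short <- vapply(1:50, function(s) err(short_d, s), numeric(1))
  e_long <- vapply(1:50, function(s) err(long_d, s), numeric(1))
  expect_lt(median(e_long), median(e_short))
})

test_that("trial dF/F follows the window conventions exactly", {
  d <- trial_design(trials_per_condition = 2)
  fr <- design_frames(d)
  onsets <- data.frame(onset_frame = c(20, 80), direction_deg = c(0, 90))

  # constant trace: dF/F identically zero
  td <- trial_dff(rep(3, 200), onsets, d)
  expect_true(all(unlist(td$dff_stim) == 0))
  expect_true(all(unlist(td$dff_baseline) == 0))

  # baseline 1.0, stimulus 1.5: stimulus-window dF/F = 0.5
  tr <- rep(1, 200)
  for (on in onsets$onset_frame) tr[(on + 1):(on + fr$stim)] <- 1.5
  td <- trial_dff(tr, onsets, d)
  expect_equal(unique(unlist(td$dff_stim)), 0.5)
  expect_equal(vapply(td$dff_stim, function(s) evoked_response(s, d),
                      numeric(1)), c(0.5, 0.5))

  # onsets too close to the edges are rejected
  expect_error(trial_dff(rep(1, 50), data.frame(onset_frame = 5,
                                                direction_deg = 0), d),
               "baseline frames")
})

test_that("trial dF/F matches a naive per-frame oracle on random traces", {
  d <- trial_design()
  fr <- design_frames(d)
  set.seed(4)
  trace <- 50 + cumsum(rnorm(1000)) + rexp(1000)
  onsets <- data.frame(onset_frame = c(30, 150, 400, 900),
                       direction_deg = c(0, 45, 90, 135))
  td <- trial_dff(trace, onsets, d)
  orc <- oracle_trial_dff(trace, onsets$onset_frame, d)
  for (i in seq_len(4)) {
    expect_equal(td$f0[i], orc[[i]]$f0)
    expect_equal(td$dff_stim[[i]], orc[[i]]$stim)
    expect_equal(evoked_response(td$dff_stim[[i]], d), orc[[i]]$mean)
  }
})

test_that("dF/F is invariant to positive rescaling of the trace", {
  d <- trial_design()
  set.seed(5)
  trace <- 20 + rexp(600)
  onsets <- data.frame(onset_frame = c(40, 200), direction_deg = c(0, 90))
  a <- trial_dff(trace, onsets, d)
  b <- trial_dff(3.7 * trace, onsets, d)
  expect_equal(unlist(a$dff_stim), unlist(b$dff_stim), tolerance = 1e-12)
})

test_that("non-positive F0 flags the trial invalid and excludes it downstream", {
  d <- trial_design(trials_per_condition = 2)
  trace <- rep(1, 300)
  trace[101:115] <- 0   # baseline window of the second trial
  onsets <- data.frame(onset_frame = c(40, 115), direction_deg = c(0, 90))
  td <- trial_dff(trace, onsets, d)
  expect_equal(td$valid, c(TRUE, FALSE))
  expect_equal(attr(td, "n_invalid"), 1L)
  rt <- response_table(trace, onsets, d)
  expect_equal(nrow(rt), 1)
  expect_equal(attr(rt, "n_invalid"), 1L)
})

test_that("evoked response averages exactly the stimulus window", {
  d <- trial_design()
  expect_equal(evoked_response(rep(0.5, 30), d), 0.5)
  ramp <- seq(0, 1, length.out = 30)
  expect_equal(evoked_response(ramp, d), mean(c(0, 1)))
  expect_error(evoked_response(rep(0.5, 29), d), "exactly 30 frames")
})
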