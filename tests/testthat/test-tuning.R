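test_that("responsiveness test applies the Bonferroni rule and degenerate contracts", {
  # all paired differences exactly zero -> p = 1, not responsive
  pairs <- data.frame(condition = rep(1:4, each = 3),
                      baseline = rep(0.1, 12), stimulus = rep(0.1, 12))
  rt <- responsiveness_test(pairs, n_conditions = 16)
  expect_false(rt$responsive)
  expect_true(all(rt$p_values == 1))

  # a strong effect in one condition is detected
  set.seed(1)
  eff <- data.frame(condition = rep(1:16, each = 10),
                    baseline = rnorm(160, 0, 0.01),
                    stimulus = rnorm(160, 0, 0.01))
  eff$stimulus[eff$condition == 7] <- eff$stimulus[eff$condition == 7] + 0.1
  expect_true(responsiveness_test(eff)$responsive)

  # constant nonzero differences are skipped with a warning
  degen <- data.frame(condition = rep(1, 3), baseline = c(0, 0, 0),
                      stimulus = c(1, 1, 1))
  expect_warning(rd <- responsiveness_test(degen), "skipped")
  expect_false(rd$responsive)
})

test_that("null cells are rarely called responsive", {
  set.seed(2)
  calls <- vapply(1:200, function(i) {
    p <- data.frame(condition = rep(1:16, each = 10),
                    baseline = rnorm(160, 0, 0.02),
                    stimulus = rnorm(160, 0, 0.02))
    responsiveness_test(p)$responsive
  }, logical(1))
  expect_lt(mean(calls), 0.1)
})

test_that("opposite drift directions average into orientations", {
  dirs <- seq(0, 337.5, by = 22.5)
  resp <- rep(1.5, 16)
  col <- collapse_directions(dirs, resp)
  expect_equal(nrow(col), 8)
  expect_true(all(col$response == 1.5))
  expect_equal(col$orientation_deg, seq(0, 157.5, by = 22.5))

  two <- collapse_directions(c(0, 180), c(1, 3))
  expect_equal(two$response, 2)
})

test_that("kappa converts to tuning width in degrees", {
  expect_equal(kappa_to_sigma(1), 57.2958, tolerance = 1e-5)
  expect_equal(kappa_to_sigma(4), 28.6479, tolerance = 1e-5)
  k <- seq(0.2, 40, length.out = 50)
  expect_true(all(diff(kappa_to_sigma(k)) < 0))
  expect_error(kappa_to_sigma(0))
})

test_that("Von Mises fit recovers noiseless generating parameters", {
  ori <- seq(0, 157.5, by = 22.5)
  truth <- c(B = 0.1, R = 1, kappa = 2, mu = 90)
  y <- von_mises(ori, truth["B"], truth["R"], truth["kappa"], truth["mu"])
  fit <- fit_von_mises(ori, y)
  expect_true(fit$fit_ok)
  expect_equal(fit$B, unname(truth["B"]), tolerance = 1e-4)
  expect_equal(fit$R, unname(truth["R"]), tolerance = 1e-4)
  expect_equal(fit$kappa, unname(truth["kappa"]), tolerance = 1e-4)
  expect_equal(fit$mu_deg, unname(truth["mu"]), tolerance = 1e-4)
  expect_error(fit_von_mises(c(0, 45, 90), c(1, 2, 1)), "4 distinct")
})

test_that("flat responses fit with R ~ 0", {
  ori <- seq(0, 157.5, by = 22.5)
  fit <- fit_von_mises(ori, rep(0.3, 8))
  expect_true(fit$fit_ok)
  expect_equal(fit$R, 0, tolerance = 1e-6)
  expect_equal(fit$B + fit$R, 0.3, tolerance = 1e-6)
})

test_that("fit SSE is no worse than a dense brute-force grid", {
  ori <- seq(0, 157.5, by = 22.5)
  set.seed(3)
  for (i in 1:3) {
    y <- von_mises(ori, 0.05, runif(1, 0.3, 1.5), runif(1, 0.5, 6),
                   runif(1, 0, 180)) + rnorm(8, 0, 0.05)
    fit <- fit_von_mises(ori, y)
    expect_true(fit$fit_ok)
    expect_lte(fit$sse, oracle_vm_grid_sse(ori, y) + 1e-6)
  }
})

test_that("rotating orientation labels rotates mu and leaves the shape alone", {
  ori <- seq(0, 157.5, by = 22.5)
  y <- von_mises(ori, 0.1, 0.8, 3, 60)
  base <- fit_von_mises(ori, y)
  for (delta in c(10, 45, 120)) {
    rot <- fit_von_mises(ori + delta, y)
    expect_lt(circ_diff_orientation(rot$mu_deg, base$mu_deg + delta), 1e-3)
    expect_equal(rot$kappa, base$kappa, tolerance = 1e-3)
    expect_equal(rot$R, base$R, tolerance = 1e-4)
    expect_equal(rot$B, base$B, tolerance = 1e-4)
  }
})

test_that("nearest-rank reliability matches a sort-and-index oracle for all sizes", {
  set.seed(4)
  for (n in c(1:50, 101, 500, 999, 1000)) {
    devs <- runif(n, 0, 30)
    expect_identical(reliability_from_deviations(devs),
                     oracle_nearest_rank(devs, 0.9))
  }
  # the documented reading: reliability 20 means 90% of bootstraps
  # within 20 degrees of the original fit
  expect_equal(reliability_from_deviations((1:1000) / 45), 20)
})

test_that("bootstrap reliability is zero when every replicate reproduces the fit", {
  pop <- toy_population(1)
  d <- trial_design(trials_per_condition = 3)
  s <- gen_session(pop, d, noise_sd = 0, a_true = 0, seed = 5)
  resp <- session_responses(s, correct_neuropil = FALSE)
  dir_means <- tapply(resp$response, resp$direction_deg, mean)
  ori <- collapse_directions(as.numeric(names(dir_means)), as.numeric(dir_means))
  fit <- fit_von_mises(ori$orientation_deg, ori$response)
  br <- bootstrap_reliability(resp[, c("direction_deg", "response")], fit,
                              n_boot = 50, seed = 6)
  expect_equal(br$reliability_deg, 0, tolerance = 1e-6)
  expect_equal(br$n_failed, 0L)
  expect_false(br$unreliable)
})

test_that("tuned classification is a strict threshold", {
  expect_true(classify_tuned(22.4))
  expect_false(classify_tuned(22.5))
  expect_true(classify_tuned(0))
  expect_false(classify_tuned(90))
})

test_that("session-level fits carry coherent flags", {
  pop <- gen_population(4, frac_untuned = 0.25, seed = 7)
  d <- trial_design()
  s <- gen_session(pop, d, noise_sd = 0.05, a_true = 0.5, seed = 8)
  fits <- fit_tuning_session(session_responses(s), n_boot = 100, seed = 9)
  expect_true(all(!fits$tuned | (fits$responsive & fits$fit_ok)))
  expect_true(all(fits$reliability_deg >= 0 & fits$reliability_deg <= 90,
                  na.rm = TRUE))
  expect_true(all(fits$sigma_deg[fits$fit_ok] > 0))
  expect_true(all(fits$mu_deg[fits$fit_ok] >= 0 & fits$mu_deg[fits$fit_ok] < 180))
})
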