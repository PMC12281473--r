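test_that("percent enhancement follows its definition and baseline convention", {
  scene <- cortex_scene()
  ser <- simulate_told(scene, gas_schedule(0, 15, "air", 0.21), 20, 45)
  cv <- compute_dm_percent(ser, roi = "cortex")
  expect_equal(cv$dm, rep(0, 45))  # constant series

  # a frame at 1.05 x baseline is +5% (baseline window kept clear of it)
  ser2 <- ser
  ser2$data[, , 40] <- ser$data[, , 40] * 1.05
  cv2 <- compute_dm_percent(ser2, roi = "cortex", baseline_frames = 1:15)
  expect_equal(cv2$dm[40], 5, tolerance = 1e-12)

  # baseline-window mean is zero by construction
  scene3 <- cortex_scene(noise_sigma = 0.02)
  ser3 <- simulate_told(scene3, challenge_schedule(), 20, 45, seed = 5)
  cv3 <- compute_dm_percent(ser3, roi = "cortex")
  expect_equal(mean(cv3$dm[cv3$baseline_frames]), 0, tolerance = 1e-12)
})

test_that("enhancement curves match the generator ground truth", {
  scene <- cortex_scene(s_max = 5.18, t_ox = 1 / 1.69, k_oc = 1.55)
  ser <- simulate_told(scene, challenge_schedule(), 20, 45)
  cv <- compute_dm_percent(ser, roi = "cortex")
  expect_equal(cv$dm, ser$truth_curves$cortex, tolerance = 1e-10)
})

test_that("enhancement is invariant under global intensity scaling", {
  scene <- cortex_scene(noise_sigma = 0.01)
  ser <- simulate_told(scene, challenge_schedule(), 20, 45, seed = 3)
  cv1 <- compute_dm_percent(ser, roi = "cortex")
  ser$data <- ser$data * 123.4
  cv2 <- compute_dm_percent(ser, roi = "cortex")
  expect_equal(cv1$dm, cv2$dm, tolerance = 1e-12)
})

test_that("ROI curves average intensities before forming the enhancement", {
  scene <- cortex_scene(noise_sigma = 0.05)
  ser <- simulate_told(scene, challenge_schedule(), 20, 45, seed = 9)
  roi <- ser$labels == 1
  cv <- compute_dm_percent(ser, roi = roi)
  m <- vapply(1:45, function(k) mean(ser$data[, , k][roi]), 0)
  mb <- mean(m[ser$baseline_frames])
  expect_equal(cv$dm, 100 * (m - mb) / mb)
  expect_length(cv$sd, 45)
})

test_that("degenerate enhancement inputs are rejected", {
  scene <- cortex_scene()
  ser <- simulate_told(scene, challenge_schedule(), 20, 45)
  expect_error(compute_dm_percent(ser), "exactly one")
  expect_error(compute_dm_percent(ser, roi = "thalamus"), "thalamus")
  expect_error(compute_dm_percent(ser, roi = array(FALSE, c(16, 16))),
               "empty")
  expect_error(compute_dm_percent(ser, roi = "cortex",
                                  baseline_frames = integer()),
               "baseline")
  # background pixel has zero baseline intensity
  expect_error(compute_dm_percent(ser, pixel = c(1, 1)), "positive")
})

test_that("wash-in fit recovers the in vivo cortex kinetics noiselessly", {
  scene <- cortex_scene(s_max = 5.18, t_ox = 1 / 1.69)
  ser <- simulate_told(scene, challenge_schedule(), 20, 45)
  cv <- compute_dm_percent(ser, roi = "cortex")
  fit <- fit_oxygenation(cv)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["s_max"]), 5.18, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["k_ox"]), 1.69, tolerance = 1e-4)
  # k_ox * T_ox = 1 exactly, and the curve passes 63.2% at onset + T_ox
  expect_equal(unname(coef(fit)["k_ox"] * coef(fit)["t_ox"]), 1)
  expect_equal(predict(fit, 5 + coef(fit)[["t_ox"]]),
               (1 - exp(-1)) * coef(fit)[["s_max"]])
})

test_that("wash-in fit handles degenerate and negative responses", {
  scene <- cortex_scene()
  ser <- simulate_told(scene, gas_schedule(0, 15, "air", 0.21), 20, 45)
  cv <- compute_dm_percent(ser, roi = "cortex")
  expect_error(fit_oxygenation(cv), "challenge")
  flat <- fit_oxygenation(cv, onset = 5, window_end = 10)
  expect_false(flat$converged)
  expect_equal(unname(coef(flat)["s_max"]), 0)
  # fewer than 4 frames rejected
  ser2 <- simulate_told(scene, challenge_schedule(), 20, 45)
  cv2 <- compute_dm_percent(ser2, roi = "cortex")
  expect_error(fit_oxygenation(cv2, onset = 5, window_end = 5.5),
               "4 frames")
  # a nitrogen-style negative-going response fits a negative plateau
  scene_n <- cortex_scene(s_max = -8, t_ox = 1)
  ser_n <- simulate_told(scene_n, challenge_schedule("nitrogen", 0),
                         20, 45)
  fit_n <- fit_oxygenation(compute_dm_percent(ser_n, roi = "cortex"))
  expect_equal(unname(coef(fit_n)["s_max"]), -8, tolerance = 1e-4)
})

test_that("semi-log decay slope recovers the consumption rate exactly", {
  # construct an exact exponential decay curve directly
  t <- seq(0, 15, by = 1 / 3)
  dm <- ifelse(t > 10, 5 * exp(-1.55 * (t - 10)),
               ifelse(t >= 5, 5, 0))
  cv <- structure(list(time_min = t, dm = dm, sd = NULL,
                       source = "synthetic", schedule = NULL,
                       baseline_frames = 1:15),
                  class = "dm_curve")
  fit <- fit_consumption(cv, offset = 10, n_points = 5)
  expect_equal(unname(coef(fit)["k_oc"]), 1.55, tolerance = 1e-12)
  # oracle: closed-form least-squares slope on the log values
  use <- which(t > 10)[1:5]
  o <- oracle_ls_line(t[use], log(dm[use]))
  expect_equal(unname(coef(fit)["k_oc"]), -unname(o["slope"]),
               tolerance = 1e-12)

  # constant positive tail gives zero consumption
  cv$dm <- ifelse(t > 10, 4, dm)
  expect_equal(unname(coef(fit_consumption(cv, offset = 10))["k_oc"]), 0)
})

test_that("consumption fit excludes non-positive points and needs two", {
  t <- seq(0, 15, by = 1 / 3)
  dm <- ifelse(t > 10, 5 * exp(-1.55 * (t - 10)), 0)
  dm[t > 10][2] <- -0.01  # one corrupted point inside the window
  cv <- structure(list(time_min = t, dm = dm, sd = NULL,
                       source = "synthetic", schedule = NULL,
                       baseline_frames = 1:15),
                  class = "dm_curve")
  expect_message(fit <- fit_consumption(cv, offset = 10, n_points = 5),
                 "excluded")
  expect_equal(unname(coef(fit)["k_oc"]), 1.55, tolerance = 1e-12)
  cv$dm <- ifelse(t > 10, -1, dm)
  expect_error(fit_consumption(cv, offset = 10), "positive")
})

test_that("noisy decay estimates are median-unbiased within 10%", {
  scene <- cortex_scene(noise_sigma = 0.02, k_oc = 1.55)
  est <- vapply(1:20, function(s) {
    ser <- simulate_told(scene, challenge_schedule(), 20, 45, seed = s)
    cv <- compute_dm_percent(ser, roi = "cortex")
    unname(coef(fit_consumption(cv))["k_oc"])
  }, 0)
  expect_lt(abs(stats::median(est) - 1.55) / 1.55, 0.10)
})

test_that("TOLD maps show the plateau per region with correct sign", {
  scene <- brain_phantom()
  # 16-min challenge sampled at 43 s over 29 frames; the default map
  # compares the last 5 frames (deep in the plateau) to the air baseline
  sched <- gas_schedule(c(0, 5), c(5, 21), c("air", "carbogen"),
                        c(0.21, 0.95))
  ser <- simulate_told(scene, sched, 43, 29)
  m <- map_told(ser)
  labs <- ser$labels
  expect_equal(mean(m$values[labs == 1]), 5.08, tolerance = 1e-6)
  expect_equal(mean(m$values[labs == 3]), 3.08, tolerance = 1e-6)
  # background has no signal: flagged invalid, never fabricated
  expect_false(any(m$valid[labs == 0]))
  # identical windows give an all-zero map
  z <- map_told(ser, window_base = 1:5, window_challenge = 1:5)
  expect_equal(max(abs(z$values[z$valid])), 0)
  # negative plateau region maps negative
  scene_n <- cortex_scene(s_max = -8)
  ser_n <- simulate_told(scene_n, sched, 43, 29)
  mn <- map_told(ser_n)
  expect_lt(mean(mn$values[ser_n$labels == 1]), -7.9)
})
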