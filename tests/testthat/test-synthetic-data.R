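test_that("variable-TR forward model evaluates the stated signal equation", {
  t1 <- scalar_map(matrix(1, 2, 2), unit = "s")
  m0 <- scalar_map(matrix(100, 2, 2), unit = "intensity")

  # TR >> T1 saturates recovery completely
  ser <- simulate_variable_tr(t1, m0, tr_s = 15)
  expect_equal(ser$data[1, 1, 1], 100, tolerance = 1e-6)

  # direct evaluation at every protocol TR for T1 = 1.85 s
  t1b <- scalar_map(matrix(1.85, 2, 2), unit = "s")
  ser <- simulate_variable_tr(t1b, m0, default_tr_s())
  expect_equal(ser$data[1, 1, ], 100 * (1 - exp(-default_tr_s() / 1.85)))
  expect_equal(ser$data[2, 2, 12], 100 * (1 - exp(-0.1 / 1.85)))
})

test_that("simulation is deterministic under a fixed seed", {
  t1 <- scalar_map(matrix(1.85, 4, 4), unit = "s")
  m0 <- scalar_map(matrix(100, 4, 4), unit = "intensity")
  a <- simulate_variable_tr(t1, m0, default_tr_s(), noise_sigma = 0.02,
                            seed = 42)
  b <- simulate_variable_tr(t1, m0, default_tr_s(), noise_sigma = 0.02,
                            seed = 42)
  expect_identical(a$data, b$data)
  c <- simulate_variable_tr(t1, m0, default_tr_s(), noise_sigma = 0.02,
                            seed = 43)
  expect_false(identical(a$data, c$data))

  scene <- cortex_scene(noise_sigma = 0.02)
  s1 <- simulate_told(scene, challenge_schedule(), 20, 45, seed = 7)
  s2 <- simulate_told(scene, challenge_schedule(), 20, 45, seed = 7)
  expect_identical(s1$data, s2$data)
})

test_that("degenerate simulation inputs are rejected with a named value", {
  t1 <- scalar_map(matrix(1, 2, 2), unit = "s")
  m0 <- scalar_map(matrix(100, 2, 2), unit = "intensity")
  expect_error(simulate_variable_tr(t1, m0, c(1, -0.5)), "-0.5")
  bad_t1 <- scalar_map(matrix(c(1, 1, 1, -2), 2, 2), unit = "s",
                       valid = matrix(TRUE, 2, 2))
  expect_error(simulate_variable_tr(bad_t1, m0, 1), "-2")
  scene <- cortex_scene()
  expect_error(simulate_told(scene, challenge_schedule(), 0, 10),
               "frame interval")
  expect_error(simulate_told(scene, challenge_schedule(), 60, 46),
               "span")
})

test_that("TOLD trajectory follows the wash-in definition of T_ox", {
  # at one time constant after onset the signal is 63.2% of the plateau
  t_ox <- 1 / 1.69
  scene <- cortex_scene(s_max = 5.18, t_ox = t_ox)
  # sample at T_ox/25 with the challenge onset on a frame time, so a
  # frame lands exactly at onset + T_ox
  dt_min <- t_ox / 25
  onset <- 200 * dt_min
  sched <- gas_schedule(c(0, onset, 12), c(onset, 12, 15),
                        c("air", "carbogen", "air"), c(0.21, 0.95, 0.21))
  ser <- simulate_told(scene, sched, dt_min * 60, 400)
  roi <- ser$labels == 1
  k <- 226  # frame time (k - 1) * dt = onset + T_ox
  m_base <- mean(ser$data[, , 1][roi])
  dm <- 100 * (mean(ser$data[, , k][roi]) - m_base) / m_base
  expect_equal(dm, (1 - exp(-1)) * 5.18, tolerance = 1e-9)
})

test_that("TOLD decay is exponential toward baseline at rate k_oc", {
  scene <- cortex_scene(k_oc = 1.55)
  ser <- simulate_told(scene, challenge_schedule(), 20, 45)
  roi <- ser$labels == 1
  after <- which(ser$time_min > 10)
  m_base <- mean(ser$data[, , 1][roi])
  dm <- vapply(after, function(k)
    100 * (mean(ser$data[, , k][roi]) - m_base) / m_base, 0)
  sl <- oracle_ls_line(ser$time_min[after], log(dm))
  expect_equal(unname(sl["slope"]), -1.55, tolerance = 1e-9)
})

test_that("an air-only schedule produces a flat baseline series", {
  scene <- cortex_scene()
  sched <- gas_schedule(0, 15, "air", 0.21)
  ser <- simulate_told(scene, sched, 20, 45)
  expect_true(all(apply(ser$data, c(1, 2), function(v)
    max(v) - min(v)) == 0))
})

test_that("the frame containing a gas switch gets the incoming gas", {
  sched <- challenge_schedule()
  expect_identical(gas_at(sched, 5), "carbogen")
  expect_identical(gas_at(sched, 5 - 1e-9), "air")
  expect_identical(gas_at(sched, 10), "air")
})

test_that("scenes enforce disjoint regions and positive T1", {
  r1 <- phantom_region("a", "disc", center = c(8, 8), radius = 4,
                       t1 = c(air = 1))
  r2 <- phantom_region("b", "disc", center = c(9, 9), radius = 4,
                       t1 = c(air = 2))
  expect_error(phantom_scene(c(16, 16), list(r1, r2)), "disjoint")
  r3 <- phantom_region("c", "box", center = c(4, 12), halfwidth = c(1, 1),
                       t1 = c(air = -1))
  expect_error(phantom_scene(c(16, 16), list(r1, r3)), "non-positive T1")
})

test_that("the brain phantom carries the measured per-gas T1 means", {
  scene <- brain_phantom()
  t1 <- vapply(scene$regions, function(r) r$t1, numeric(3))
  expect_equal(t1[["air", 1]], 1.85)       # cortex, air
  expect_equal(t1[["air", 2]], 2.84)       # ventricles, air
  expect_equal(t1[["carbogen", 1]], 1.72)  # cortex, carbogen
  expect_equal(t1[["carbogen", 3]], 1.60)  # caudate, carbogen
  labs <- scene_labels(scene)
  expect_setequal(unique(as.integer(labs)), 0:3)
})
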