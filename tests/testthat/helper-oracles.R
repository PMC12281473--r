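# Independent oracles and small fixtures used across the suite.

# Brute-force saturation-recovery fit: grid search over T1 with the
# closed-form least-squares M0 at each grid point. Deliberately naive;
# used only to cross-check fit_t1().
oracle_t1_grid <- function(signal, tr_s, t1_grid =
                             exp(seq(log(0.01), log(20),
                                     length.out = 20000))) {
  rss <- vapply(t1_grid, function(t1) {
    g <- 1 - exp(-tr_s / t1)
    m0 <- sum(signal * g) / sum(g * g)
    sum((signal - m0 * g)^2)
  }, 0)
  t1_grid[which.min(rss)]
}

# Closed-form ordinary least-squares slope and intercept.
oracle_ls_line <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - sl * mean(x), slope = sl)
}

# Single-region 16 x 16 scene with the in vivo cortex kinetics, for
# fast kinetic round trips.
cortex_scene <- function(noise_sigma = 0, s_max = 5.18,
                         t_ox = 1 / 1.69, k_oc = 1.55) {
  phantom_scene(
    shape = c(16, 16),
    regions = list(
      phantom_region("cortex", "disc", center = c(8, 8), radius = 6,
                     t1 = c(air = 1.85, carbogen = 1.72),
                     m0 = 100, s_max = s_max, t_ox = t_ox, k_oc = k_oc)),
    noise_sigma = noise_sigma)
}

# Standard 15-min challenge paradigm: air 5 min, carbogen 5, air 5.
challenge_schedule <- function(gas = "carbogen", frac = 0.95)
  gas_schedule(c(0, 5, 10), c(5, 10, 15), c("air", gas, "air"),
               c(0.21, frac, 0.21))
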