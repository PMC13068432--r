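test_that("fold-change normalisation is exact, scale-free and guarded", {
  tt <- 0:300
  expect_equal(fold_change_normalize(rep(3, 301), c(0, 150), t = tt),
               rep(1, 301))
  y <- 1 + 0.2 * exp(-(tt - 180)^2 / 200)
  a <- fold_change_normalize(y, c(0, 150), t = tt)
  b <- fold_change_normalize(3 * y, c(0, 150), t = tt)
  expect_equal(a, b, tolerance = 1e-14)
  expect_error(fold_change_normalize(rep(-1, 301), c(0, 150), t = tt),
               "non-positive")
})

test_that("a symmetric linear ramp yields k_on_obs = A/T exactly", {
  p <- stimulus_protocol(t_start = 150, light_duration = 30,
                         sampling_interval = 1, t_end = 600)
  tt <- protocol_times(p)
  A <- 0.5
  Tr <- 100
  y <- rep(1, length(tt))
  rise <- tt >= 150 & tt <= 150 + Tr
  y[rise] <- 1 + A * (tt[rise] - 150) / Tr
  fall <- tt > 150 + Tr & tt <= 150 + 2 * Tr
  y[fall] <- 1 + A * (1 - (tt[fall] - 150 - Tr) / Tr)
  k <- observed_rates(data.frame(t = tt, value = y), p)
  # 0.8 A over 0.8 T on both flanks
  expect_equal(k$k_on_obs, A / Tr, tolerance = 1e-10)
  expect_equal(k$k_off_obs, A / Tr, tolerance = 1e-10)
  expect_equal(k$peak_amplitude, A, tolerance = 1e-12)
})

test_that("an exponential rise gives the closed-form mean 10-90% slope", {
  # y = 1 + A(1 - exp(-k(t - t0))): t10 = ln(10/9)/k, t90 = ln(10)/k,
  # so the secant slope is 0.8 A k / ln 9
  p <- stimulus_protocol(t_start = 150, light_duration = 440,
                         t_end = 600)
  tt <- protocol_times(p)
  A <- 0.4
  k <- 0.03
  y <- rep(1, length(tt))
  on <- tt >= 150
  y[on] <- 1 + A * (1 - exp(-k * (tt[on] - 150)))
  # close the transient so a falling phase exists
  y[tt > 500] <- approx(c(500, 600), c(max(y), 1), xout = tt[tt > 500])$y
  obs <- observed_rates(data.frame(t = tt, value = y), p)
  expect_equal(obs$k_on_obs, 0.8 * A * k / log(9), tolerance = 1e-3)
})

test_that("halving the time axis doubles both observed rates", {
  traj <- noiseless_trajectory("membrane_wt")
  p1 <- default_protocol()
  k1 <- observed_rates(data.frame(t = traj$t, value = traj$observation), p1)
  p2 <- stimulus_protocol(t_start = 75, light_duration = 15,
                          baseline_window = c(0, 75),
                          sampling_interval = 0.5, t_end = 300)
  k2 <- observed_rates(data.frame(t = traj$t / 2, value = traj$observation), p2)
  expect_equal(k2$k_on_obs, 2 * k1$k_on_obs, tolerance = 1e-9)
  expect_equal(k2$k_off_obs, 2 * k1$k_off_obs, tolerance = 1e-9)
})

test_that("observed rates ignore an additive offset applied to the raw trace", {
  traj <- noiseless_trajectory("membrane_wt")
  p <- default_protocol()
  a <- observed_rates(data.frame(t = traj$t, value = traj$observation), p)
  b <- observed_rates(data.frame(t = traj$t,
                                 value = traj$observation + 5), p)
  expect_equal(a$k_on_obs, b$k_on_obs, tolerance = 1e-12)
  expect_equal(a$k_off_obs, b$k_off_obs, tolerance = 1e-12)
  expect_equal(a$peak_amplitude, b$peak_amplitude, tolerance = 1e-12)
})

test_that("traces without a qualifying transient raise metric errors", {
  p <- default_protocol()
  tt <- protocol_times(p)
  expect_error(observed_rates(data.frame(t = tt, value = rep(1, length(tt))), p),
               "no qualifying")
  # rising-only trace: the falling crossings are missing
  y <- 1 + pmax(0, (tt - 150)) / 450 * 0.3
  expect_error(observed_rates(data.frame(t = tt, value = y), p),
               "crossing")
})

test_that("decay half-life fitting recovers the closed form and rejects junk", {
  k <- 0.0700499
  tt <- seq(0, 60, by = 1)
  y <- 0.176 * exp(-k * tt)
  hl <- decay_half_life(tt, y)
  expect_equal(hl$half_life, log(2) / k, tolerance = 1e-6)
  expect_error(decay_half_life(tt, rep(1, length(tt))), "not decaying")
  expect_error(decay_half_life(tt[1:4], y[1:4]), "5 samples")
  # noisy recovery: 1% of the initial amplitude
  set.seed(21)
  hls <- replicate(15, {
    yn <- y + rnorm(length(y), 0, 0.01 * 0.176)
    decay_half_life(tt, yn)$half_life
  })
  expect_lt(abs(median(hls) - log(2) / k) / (log(2) / k), 0.05)
})
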