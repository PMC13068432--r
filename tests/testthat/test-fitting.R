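test_that("residual loss equals the hand-computed dot product on a toy trace", {
  p <- stimulus_protocol()
  lp <- ref_larg_params()
  cp <- ref_circuit_params("membrane_wt")
  tt <- c(0, 100, 200, 300, 400)
  traj <- simulate_circuit(lp, cp, p)
  model <- approx(traj$t, traj$observation, xout = tt)$y
  r <- c(0.01, -0.02, 0.005, 0, 0.03)
  data <- data.frame(t = tt, value = model + r)
  loss <- residual_loss(cp, lp, p, data)
  expect_equal(loss, sum(r * r), tolerance = 1e-6)
  # doubling every residual quadruples the loss
  data2 <- data.frame(t = tt, value = model + 2 * r)
  expect_equal(residual_loss(cp, lp, p, data2), 4 * sum(r * r),
               tolerance = 1e-6)
})

test_that("loss vanishes on self-generated data and rejects out-of-horizon grids", {
  p <- stimulus_protocol()
  lp <- ref_larg_params()
  cp <- ref_circuit_params("membrane_wt")
  data <- noiseless_trace("membrane_wt")
  expect_lt(residual_loss(cp, lp, p, data), 1e-12)
  bad <- data.frame(t = c(0, 700), value = c(1, 1))
  expect_error(residual_loss(cp, lp, p, bad), "horizon")
})

test_that("recruitment kinetics are recovered from a noiseless trace", {
  lp <- ref_larg_params()
  p <- stimulus_protocol()
  sim <- simulate_larg(lp, p, rtol = 1e-10, atol = 1e-12)
  fit <- fit_larg_kinetics(data.frame(t = sim$t, value = sim$larg), p)
  expect_true(fit$converged)
  expect_lt(relerr(fit$estimates[["k_on"]], lp$k_on), 0.01)
  expect_lt(relerr(fit$estimates[["k_off"]], lp$k_off), 0.01)
})

test_that("degenerate recruitment traces are rejected as non-identifiable", {
  p <- stimulus_protocol()
  tt <- protocol_times(p)
  expect_error(fit_larg_kinetics(data.frame(t = tt, value = rep(0, length(tt))), p),
               "non-identifiable")
  ramp <- data.frame(t = tt, value = seq(0, 1, length.out = length(tt)))
  expect_error(fit_larg_kinetics(ramp, p), "non-identifiable")
})

test_that("recruitment fits stay nearly unbiased under frame noise", {
  lp <- ref_larg_params()
  p <- stimulus_protocol()
  sim <- simulate_larg(lp, p, rtol = 1e-10, atol = 1e-12)
  # noise SD of an average over 500 ROIs with per-ROI SD 0.02
  sd_eff <- 0.02 / sqrt(500)
  set.seed(314)
  ests <- replicate(12, {
    y <- sim$larg + rnorm(length(sim$larg), 0, sd_eff)
    f <- fit_larg_kinetics(data.frame(t = sim$t, value = y), p,
                           n_starts = 2)
    f$estimates[["k_off"]]
  })
  expect_lt(abs(median(ests) - lp$k_off) / lp$k_off, 0.05)
})

test_that("fitting is invariant to a joint shift of the time origin", {
  lp <- ref_larg_params()
  p1 <- stimulus_protocol(t_start = 150)
  p2 <- stimulus_protocol(t_start = 200, baseline_window = c(0, 200))
  s1 <- simulate_larg(lp, p1, rtol = 1e-10, atol = 1e-12)
  s2 <- simulate_larg(lp, p2, rtol = 1e-10, atol = 1e-12)
  f1 <- fit_larg_kinetics(data.frame(t = s1$t, value = s1$larg), p1)
  f2 <- fit_larg_kinetics(data.frame(t = s2$t, value = s2$larg), p2)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-4)
})

test_that("a flat response drives the Rho activation rate to its lower bound", {
  p <- stimulus_protocol()
  tt <- protocol_times(p)
  flat <- data.frame(t = tt, value = rep(1, length(tt)))
  fit <- fit_rho_circuit(flat, ref_larg_params(), "WT", p, n_starts = 6,
                         seed = 5)
  expect_lte(fit$estimates[["v_on_rho"]],
             fit$bounds_used$lower[["v_on_rho"]] * 1.01)
  expect_true(fit$at_bound_flags[["v_on_rho"]])
})

test_that("the returned circuit fit beats every recorded start point", {
  fit <- membrane_wt_fit()
  data <- noiseless_trace("membrane_wt")
  p <- default_protocol()
  lp <- ref_larg_params()
  for (st in fit$start_points[seq_len(min(4, length(fit$start_points)))]) {
    cp <- do.call(rho_circuit_params, c(list(variant = "WT"), as.list(st)))
    l0 <- try(residual_loss(cp, lp, p, data), silent = TRUE)
    if (!inherits(l0, "try-error")) expect_lte(fit$loss, l0 + 1e-12)
  }
})

test_that("fitted WT trajectory matches the generating trajectory within 0.1% RMS", {
  fit <- membrane_wt_fit()
  traj_hat <- simulate_circuit(ref_larg_params(), as_circuit_params(fit),
                               default_protocol())
  traj <- noiseless_trajectory("membrane_wt")
  rms <- sqrt(mean((traj_hat$observation - traj$observation)^2))
  expect_lt(rms / max(traj$rho), 0.001)
})

test_that("fit bounds are validated", {
  expect_error(fit_bounds(c(a = 1), c(a = 1)), "lower")
  expect_error(fit_bounds(c(a = 1), c(a = 2), init = c(a = 5)), "init")
  b <- default_fit_bounds("KO")
  expect_setequal(names(b$lower),
                  c("v_on_gap", "k_off_gap", "v_on_rho", "km_on_rho",
                    "v_off_rho", "km_off_rho"))
})
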