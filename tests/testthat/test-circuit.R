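# closed-form oracle for the linear recruitment model under a boxcar,
# written out independently of the package helper
boxcar_larg_oracle <- function(k_on, k_off, t, t0, dur, amp) {
  plateau <- k_on / k_off * amp
  y <- numeric(length(t))
  on <- t >= t0 & t <= t0 + dur
  y[on] <- plateau * (1 - exp(-k_off * (t[on] - t0)))
  y_off <- plateau * (1 - exp(-k_off * dur))
  off <- t > t0 + dur
  y[off] <- y_off * exp(-k_off * (t[off] - (t0 + dur)))
  y
}

test_that("numeric recruitment solution matches the piecewise closed form", {
  p <- stimulus_protocol()
  lp <- ref_larg_params()
  sim <- simulate_larg(lp, p, rtol = 1e-10, atol = 1e-12)
  cf <- boxcar_larg_oracle(lp$k_on, lp$k_off, sim$t, 150, 30, 1)
  big <- cf > 1e-8
  expect_lt(max(abs(sim$larg[big] - cf[big]) / cf[big]), 1e-6)
  expect_lt(max(abs(sim$larg[!big] - cf[!big])), 1e-9)
})

test_that("zero activation constant gives an identically zero recruitment", {
  p <- stimulus_protocol()
  sim <- simulate_larg(larg_params(0, 0.07), p)
  expect_true(all(sim$larg == 0))
})

test_that("a long light window saturates recruitment at k_on/k_off", {
  lp <- ref_larg_params()
  p <- stimulus_protocol(t_start = 150, light_duration = 440, t_end = 600)
  sim <- simulate_larg(lp, p)
  plateau <- lp$k_on / lp$k_off
  expect_equal(sim$larg[sim$t == 590], plateau, tolerance = 1e-6)
})

test_that("recruitment halves in ln2/k_off seconds after light-off", {
  lp <- ref_larg_params()
  half <- log(2) / lp$k_off # ~9.9 s with the published constants
  expect_lt(abs(half - 10.8) / 10.8, 0.15)
  p <- stimulus_protocol(sampling_interval = 0.1)
  sim <- simulate_larg(lp, p)
  y_off <- sim$larg[sim$t == 180]
  y_half <- approx(sim$t, sim$larg, xout = 180 + half)$y
  expect_equal(y_half / y_off, 0.5, tolerance = 1e-4)
})

test_that("an unstimulated WT circuit stays quiescent", {
  p <- stimulus_protocol(amplitude = 0)
  traj <- simulate_circuit(ref_larg_params(), ref_circuit_params("membrane_wt"), p)
  expect_true(all(traj$larg == 0))
  expect_true(all(traj$gap == 0))
  expect_true(all(traj$rho == 0))
  expect_true(all(traj$observation == 1))
})

test_that("with the GAP branch removed, terminal Rho equals the activation integral", {
  # quadrature oracle: integrate v_on_rho * L/(km_on + L) over the
  # closed-form recruitment curve
  lp <- ref_larg_params()
  cp <- rho_circuit_params("WT", v_on_gap = 1e-30, km_gap = 1,
                           k_off_gap = 1, v_on_rho = 0.0061944,
                           km_on_rho = 0.0118618, v_off_rho = 25.2258,
                           km_off_rho = 60.6878)
  p <- stimulus_protocol()
  traj <- simulate_circuit(lp, cp, p, rtol = 1e-10, atol = 1e-12)
  expect_true(all(diff(traj$rho) >= -1e-12)) # monotone non-decreasing
  f <- function(t) {
    L <- boxcar_larg_oracle(lp$k_on, lp$k_off, t, 150, 30, 1)
    cp$v_on_rho * L / (cp$km_on_rho + L)
  }
  oracle <- integrate(f, 0, 600, subdivisions = 2000, rel.tol = 1e-10)
  expect_equal(traj$rho[length(traj$rho)], oracle$value, tolerance = 1e-5)
})

test_that("KO GAP settles at v_on_gap/k_off_gap (analytic linear relaxation)", {
  cp <- ref_circuit_params("membrane_ko")
  traj <- simulate_circuit(ref_larg_params(), cp, stimulus_protocol())
  ss <- cp$v_on_gap / cp$k_off_gap
  after <- traj$t > 5 / cp$k_off_gap
  expect_true(all(abs(traj$gap[after] - ss) / ss < 0.01))
})

test_that("the saturating circuit linearises when both Michaelis constants dominate", {
  lp <- ref_larg_params()
  big <- 1e4
  cp <- rho_circuit_params("WT", v_on_gap = 25, km_gap = 0.1,
                           k_off_gap = 66, v_on_rho = 0.006 * big,
                           km_on_rho = big, v_off_rho = 25 * big,
                           km_off_rho = big)
  # bounds in the constructor allow large values; simulate directly
  p <- stimulus_protocol()
  traj <- simulate_circuit(lp, cp, p, rtol = 1e-10, atol = 1e-12)
  # independent fully linear system with slopes v/km
  linear_rhs <- function(t, y, parms) {
    f <- if (t >= 150 && t < 180) 1 else 0
    dl <- lp$k_on * f - lp$k_off * y[1]
    dg <- 25 * y[3] / (0.1 + y[3]) - 66 * y[2]
    dr <- 0.006 * y[1] - 25 * y[2] * y[3]
    list(c(dl, dg, dr))
  }
  ref <- deSolve::ode(c(0, 0, 0), traj$t, linear_rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  scale <- max(ref[, 4])
  expect_lt(max(abs(traj$rho - ref[, 4])) / scale, 0.01)
})

test_that("the KO variant is the km_gap -> 0 limit of the WT equations", {
  lp <- ref_larg_params()
  ko <- ref_circuit_params("membrane_ko")
  wt_limit <- rho_circuit_params("WT", v_on_gap = ko$v_on_gap,
                                 km_gap = 1e-9,
                                 k_off_gap = ko$k_off_gap,
                                 v_on_rho = ko$v_on_rho,
                                 km_on_rho = ko$km_on_rho,
                                 v_off_rho = ko$v_off_rho,
                                 km_off_rho = ko$km_off_rho)
  p <- stimulus_protocol()
  a <- simulate_circuit(lp, ko, p, rtol = 1e-10, atol = 1e-12)
  b <- simulate_circuit(lp, wt_limit, p, rtol = 1e-10, atol = 1e-12)
  # deep saturation: at rho = 10 km_gap the activation factor is still
  # 10/11, so percent-level agreement needs rho >> km_gap
  sel <- a$rho > 1000 * 1e-9 & a$t > 150
  expect_lt(max(abs(a$rho[sel] - b$rho[sel]) / a$rho[sel]), 0.01)
})

test_that("states stay non-negative for random positive parameter sets", {
  set.seed(42)
  p <- stimulus_protocol()
  lp <- ref_larg_params()
  for (i in 1:6) {
    th <- 10^runif(7, -3, 1.5)
    cp <- rho_circuit_params("WT", v_on_gap = th[1], km_gap = th[2],
                             k_off_gap = th[3], v_on_rho = th[4],
                             km_on_rho = th[5], v_off_rho = th[6],
                             km_off_rho = th[7])
    traj <- try(simulate_circuit(lp, cp, p), silent = TRUE)
    if (!inherits(traj, "try-error"))
      expect_gte(min(traj$larg, traj$gap, traj$rho), 0)
  }
})

test_that("the observation map is 1 + Rho and round-trips through fold change", {
  traj <- noiseless_trajectory("membrane_wt")
  obs <- to_observation(traj)
  expect_equal(obs, 1 + traj$rho)
  expect_equal(max(obs) - 1, max(traj$rho))
  # baseline of a noiseless observation is exactly 1, so normalisation
  # is the identity
  renorm <- fold_change_normalize(obs, c(0, 150), t = traj$t)
  expect_equal(renorm, obs, tolerance = 1e-12)
})

test_that("parameter constructors validate their domains", {
  expect_error(larg_params(0.01, 0), "k_off")
  expect_error(larg_params(-1, 0.1), "k_on")
  expect_error(rho_circuit_params("WT", v_on_gap = 1, k_off_gap = 1,
                                  v_on_rho = 1, km_on_rho = 1,
                                  v_off_rho = 1, km_off_rho = 1),
               "km_gap")
  expect_error(rho_circuit_params("KO", v_on_gap = 1, km_gap = 2,
                                  k_off_gap = 1, v_on_rho = 1,
                                  km_on_rho = 1, v_off_rho = 1,
                                  km_off_rho = 1),
               "structurally absent")
  expect_error(rho_circuit_params("WT", v_on_gap = -1, km_gap = 1,
                                  k_off_gap = 1, v_on_rho = 1,
                                  km_on_rho = 1, v_off_rho = 1,
                                  km_off_rho = 1),
               "positive")
})
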