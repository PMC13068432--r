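test_that("a zero-noise ensemble reproduces the observation exactly", {
  traj <- noiseless_trajectory("membrane_wt")
  ens <- generate_roi_ensemble(traj, noise_model(0, 0), n_roi = 5,
                               seed = 1)
  obs <- to_observation(traj)
  for (i in 1:5) expect_equal(unname(ens$traces[i, ]), unname(obs))
})

test_that("ensembles are bit-identical under a fixed seed", {
  traj <- noiseless_trajectory("membrane_wt")
  nm <- noise_model(0.05, 0.3)
  a <- generate_roi_ensemble(traj, nm, n_roi = 50, seed = 99)
  b <- generate_roi_ensemble(traj, nm, n_roi = 50, seed = 99)
  expect_identical(a$traces, b$traces)
  c <- generate_roi_ensemble(traj, nm, n_roi = 50, seed = 100)
  expect_false(identical(a$traces, c$traces))
})

test_that("per-frame noise SD matches the generating model during baseline", {
  traj <- noiseless_trajectory("membrane_wt")
  ens <- generate_roi_ensemble(traj, noise_model(0.05, 0.3),
                               n_roi = 2000, seed = 7)
  base_cols <- which(ens$t <= 150)
  sds <- apply(ens$traces[, base_cols[1:50]], 2, sd)
  # during baseline the response is zero so only additive noise remains
  expect_lt(abs(mean(sds) - 0.05) / 0.05, 0.05)
})

test_that("aggregating a noiseless ensemble returns the observation with a degenerate band", {
  traj <- noiseless_trajectory("membrane_wt")
  ens <- generate_roi_ensemble(traj, noise_model(0, 0), n_roi = 10,
                               seed = 1)
  agg <- aggregate_ensemble(ens, n_boot = 50, seed = 2)
  obs <- to_observation(traj)
  expect_equal(agg$center, unname(obs), tolerance = 1e-12)
  expect_equal(agg$ci_low, agg$ci_high, tolerance = 1e-12)
  expect_true(all(agg$ci_low <= agg$center & agg$center <= agg$ci_high))
  expect_equal(agg$n_roi, 10)
})

test_that("traces with non-positive baseline are excluded with a warning", {
  traj <- noiseless_trajectory("membrane_wt")
  ens <- generate_roi_ensemble(traj, noise_model(0, 0), n_roi = 4,
                               seed = 1)
  ens$traces[2, ] <- -1
  expect_warning(agg <- aggregate_ensemble(ens, n_boot = 0),
                 "excluded")
  expect_equal(agg$n_roi, 3)
  ens$traces[, ] <- -1
  expect_error(suppressWarnings(aggregate_ensemble(ens, n_boot = 0)),
               "all traces excluded")
})

test_that("fold-change aggregation is invariant to a global multiplicative scale", {
  traj <- noiseless_trajectory("membrane_wt")
  ens <- generate_roi_ensemble(traj, noise_model(0.02, 0.2), n_roi = 40,
                               seed = 11)
  scaled <- ens
  scaled$traces <- ens$traces * 7.3
  a <- aggregate_ensemble(ens, n_boot = 0)
  b <- aggregate_ensemble(scaled, n_boot = 0)
  expect_equal(a$center, b$center, tolerance = 1e-12)
})

test_that("fold-change normalisation is idempotent on normalised traces", {
  traj <- noiseless_trajectory("membrane_wt")
  y <- to_observation(traj)
  once <- fold_change_normalize(y, c(0, 150), t = traj$t)
  twice <- fold_change_normalize(once, c(0, 150), t = traj$t)
  expect_equal(once, twice, tolerance = 1e-14)
})

test_that("noise model and ensemble inputs are validated", {
  expect_error(noise_model(-0.1, 0.3))
  traj <- noiseless_trajectory("membrane_wt")
  expect_error(generate_roi_ensemble(traj, noise_model(), n_roi = 0),
               "n_roi")
})
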