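test_that("an empty scene yields no detections", {
  spec <- synthetic_cell_spec(n_fa = 0, seed = 3)
  scene <- synthesize_cell_image(spec)
  expect_equal(nrow(scene$fa_centers), 0)
  mask <- segment_cell(scene$biosensor[, , 1])
  fa <- detect_focal_adhesions(scene$paxillin[, , 1], mask)
  expect_equal(nrow(fa$centers), 0)
})

test_that("scenes are bit-identical under a fixed seed", {
  a <- synthesize_cell_image(synthetic_cell_spec(seed = 10))
  b <- synthesize_cell_image(synthetic_cell_spec(seed = 10))
  expect_identical(a$biosensor, b$biosensor)
  expect_identical(a$paxillin, b$paxillin)
})

test_that("FA disks carry the contrast implied by the generator parameters", {
  spec <- synthetic_cell_spec(seed = 5, noise_sd = 0)
  scene <- synthesize_cell_image(spec)
  pax <- scene$paxillin[, , 1]
  g <- list(row = matrix(rep(0:(spec$size - 1), spec$size), spec$size),
            col = matrix(rep(0:(spec$size - 1), each = spec$size),
                         spec$size))
  in_disks <- Reduce(`|`, lapply(seq_len(nrow(scene$fa_centers)),
    function(i) (g$row - scene$fa_centers[i, 1])^2 +
                (g$col - scene$fa_centers[i, 2])^2 <= 9))
  measured <- mean(pax[in_disks]) / mean(pax[scene$cell_mask])
  # expected ratio from the rendered Gaussian spot: average the spot
  # profile over a radius-3 disk (independent direct computation)
  xy <- expand.grid(u = -3:3, v = -3:3)
  xy <- xy[xy$u^2 + xy$v^2 <= 9, ]
  spot_mean <- mean(exp(-0.5 * ((xy$u / spec$fa_length)^2 +
                                (xy$v / spec$fa_width)^2)))
  expected_disk <- spec$cytosol + (spec$fa_peak - spec$cytosol) * spot_mean
  cell_mean <- mean(pax[scene$cell_mask])
  expect_lt(abs(measured - expected_disk / cell_mean) /
              (expected_disk / cell_mean), 0.1)
})

test_that("cell segmentation recovers the true mask", {
  spec <- synthetic_cell_spec(seed = 8)
  scene <- synthesize_cell_image(spec)
  mask <- segment_cell(scene$biosensor[, , 1])
  jac <- sum(mask & scene$cell_mask) / sum(mask | scene$cell_mask)
  expect_gte(jac, 0.9)
  area_ratio <- sum(mask) / sum(scene$cell_mask)
  expect_true(area_ratio >= 0.5 && area_ratio <= 1.5)
  # inverted contrast with the polarity flag gives the same mask
  inv <- max(scene$biosensor[, , 1]) - scene$biosensor[, , 1]
  mask2 <- segment_cell(inv, invert = TRUE)
  expect_gte(sum(mask & mask2) / sum(mask | mask2), 0.99)
  expect_error(segment_cell(matrix(5, 64, 64)), "contrast")
})

test_that("FA detection is accurate at default SNR and filters dominate", {
  spec <- synthetic_cell_spec(seed = 12)
  scene <- synthesize_cell_image(spec)
  mask <- segment_cell(scene$biosensor[, , 1])
  fa <- detect_focal_adhesions(scene$paxillin[, , 1], mask)
  m <- match_centers(fa$centers, scene$fa_centers)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
  none <- detect_focal_adhesions(scene$paxillin[, , 1], mask,
                                 size_range = c(1, 2))
  expect_equal(nrow(none$centers), 0)
  none2 <- detect_focal_adhesions(scene$paxillin[, , 1], mask,
                                  max_edge_distance = 0)
  expect_equal(nrow(none2$centers), 0)
})

test_that("detection is equivariant to whole-pixel scene translations", {
  s1 <- synthetic_cell_spec(seed = 4, noise_sd = 0)
  s2 <- synthetic_cell_spec(seed = 4, noise_sd = 0,
                            center = c(128 + 6, 128 - 4))
  a <- synthesize_cell_image(s1)
  b <- synthesize_cell_image(s2)
  fa_a <- detect_focal_adhesions(a$paxillin[, , 1], a$cell_mask)
  fa_b <- detect_focal_adhesions(b$paxillin[, , 1], b$cell_mask)
  expect_equal(nrow(fa_a$centers), nrow(fa_b$centers))
  shift_a <- sweep(fa_a$centers, 2, c(-6, 4))
  ord_a <- order(shift_a[, 1], shift_a[, 2])
  ord_b <- order(fa_b$centers[, 1], fa_b$centers[, 2])
  expect_lt(max(abs(shift_a[ord_a, ] - fa_b$centers[ord_b, ])), 0.5)
})

test_that("ROI pairing produces disjoint FA / non-FA pairs with paxillin contrast", {
  spec <- synthetic_cell_spec(seed = 6, n_fa = 1)
  scene <- synthesize_cell_image(spec)
  mask <- segment_cell(scene$biosensor[, , 1])
  fa <- detect_focal_adhesions(scene$paxillin[, , 1], mask)
  expect_equal(nrow(fa$centers), 1)
  rois <- select_stimulation_rois(fa, mask)
  expect_equal(nrow(rois), 2)
  expect_setequal(rois$class, c("FA", "non-FA"))
  d <- sqrt(sum((as.numeric(rois[rois$class == "FA", c("row", "col")]) -
                 as.numeric(rois[rois$class == "non-FA",
                                 c("row", "col")]))^2))
  expect_gt(d, 2 * rois$radius[1])
  # infeasible exclusion drops all pairs (one warning per pair plus a
  # final summary warning)
  w <- testthat::capture_warnings(
    empty <- select_stimulation_rois(fa, mask, exclusion_dilation = 300))
  expect_true(any(grepl("dropped", w)))
  expect_equal(nrow(empty), 0)
})

test_that("trace extraction is exact on piecewise-constant images", {
  img <- matrix(2, 64, 64)
  img[1:20, 1:20] <- 8
  stack <- array(img, c(64, 64, 3))
  rois <- data.frame(row = c(8, 45), col = c(8, 45), radius = 3,
                     class = c("FA", "non-FA"), pair_id = c(1L, 1L))
  class(rois) <- c("roi_set", class(rois))
  ens <- extract_roi_traces(stack, rois)
  expect_equal(unname(ens$traces[1, ]), rep(8, 3))
  expect_equal(unname(ens$traces[2, ]), rep(2, 3))
  # uniform stack: constant traces at the uniform value
  uni <- extract_roi_traces(array(5, c(64, 64, 2)), rois)
  expect_true(all(uni$traces == 5))
  # out-of-bounds ROI errors by name
  bad <- rois
  bad$row[1] <- 63
  expect_error(extract_roi_traces(stack, bad), "ROI 1")
})

test_that("the full scene pipeline runs end to end and yields pulse kinetics", {
  p <- stimulus_protocol(sampling_interval = 10)
  traj <- noiseless_trajectory("membrane_ko")
  obs <- approx(traj$t, traj$observation, xout = protocol_times(p))$y
  spec <- synthetic_cell_spec(seed = 9, noise_sd = 10)
  scene <- synthesize_cell_image(spec, n_frames = length(obs),
                                 time_course = obs)
  mask <- segment_cell(scene$biosensor[, , 1])
  fa <- detect_focal_adhesions(scene$paxillin[, , 1], mask)
  rois <- select_stimulation_rois(fa, mask)
  ens <- extract_roi_traces(scene$biosensor, rois, t = protocol_times(p))
  agg <- aggregate_ensemble(ens, c(0, 150), n_boot = 50, seed = 1)
  k <- observed_rates(data.frame(t = agg$t, value = agg$center), p)
  expect_gt(k$peak_amplitude, 0)
  expect_gt(k$k_on_obs, 0)
  # the injected cell-wide time course is recovered inside the ROIs
  i_peak <- which.max(obs)
  expect_equal(agg$center[i_peak], max(obs),
               tolerance = 0.05)
})
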