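test_that("generators are bitwise deterministic under a fixed seed", {
  a <- make_structural_stack(stack_recipe(shape = c(5, 24, 24), seed = 7))
  b <- make_structural_stack(stack_recipe(shape = c(5, 24, 24), seed = 7))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$mask, b$truth$mask)
  c <- make_structural_stack(stack_recipe(shape = c(5, 24, 24), seed = 8))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
  rec <- session_recipe(n_neurons = 3, frame_shape = c(48, 48), fov_um = 40,
                        duration_s = 10, seed = 5)
  m1 <- make_activity_movie(rec)
  m2 <- make_activity_movie(rec)
  expect_identical(m1$movie$frames, m2$movie$frames)
  expect_identical(lapply(m1$truth$neurons, `[[`, "spike_times_s"),
                   lapply(m2$truth$neurons, `[[`, "spike_times_s"))
})

test_that("shot noise in uniform regions is Poisson (variance ~ mean)", {
  rec <- stack_recipe(shape = c(2, 160, 160),
                      vessels = list(n = 3, radius_range_um = c(4, 8)),
                      photon_scale = 40, sbr0 = 8,
                      depth_limit_um = 3000, seed = 41)
  res <- make_structural_stack(rec)
  bg <- res$stack$voxels[1, , ][!res$truth$mask]
  expect_gte(length(bg), 1e4)
  expect_gt(var(bg) / mean(bg), 0.9)
  expect_lt(var(bg) / mean(bg), 1.1)
})

test_that("spike trains map to superposed exponential rate transients", {
  kin <- indicator_kinetics()
  flat <- spikes_to_rate(numeric(0), kin, 300, 2, 0.01)
  expect_true(all(flat$rate_hz == 300))
  one <- spikes_to_rate(0, kin, 300, 2, 0.01)
  expect_equal(one$rate_hz[1], 300 * 1.7)
  at_tau <- which.min(abs(one$time_s - 0.29))
  expect_equal(one$rate_hz[at_tau] / 300, 1 + 0.7 / exp(1), tolerance = 1e-3)
  two <- spikes_to_rate(c(0.5, 0.5), kin, 300, 2, 0.005)
  k <- which.min(abs(two$time_s - 0.5))
  expect_equal(two$rate_hz[k], 300 * (1 + 2 * 0.7), tolerance = 1e-6)
  expect_error(spikes_to_rate(3, kin, 300, 2, 0.01), "within")
})

test_that("structural stacks encode the recipe SBR model in their truth", {
  rec <- stack_recipe(shape = c(8, 32, 32), sbr0 = 50, depth_limit_um = 2000,
                      seed = 3)
  res <- make_structural_stack(rec)
  z <- res$truth$z_positions_um
  expect_equal(res$truth$sbr_true, 50^(1 - z / 2000))
  expect_equal(res$truth$background_mean,
               res$truth$signal_mean / res$truth$sbr_true)
  zero <- make_structural_stack(stack_recipe(shape = c(3, 16, 16),
                                             photon_scale = 0, seed = 2))
  expect_true(all(zero$stack$voxels == 0))
  expect_error(stack_recipe(vessels = NULL, somata = NULL), "empty geometry")
  expect_error(stack_recipe(sbr0 = 0.5), "sbr0")
})

test_that("the depth limit of a generated stack is recoverable", {
  rec <- stack_recipe(seed = 11)  # sbr0 100, limit 2500 um, 26 slices
  res <- make_structural_stack(rec)
  prof <- sbr_depth_profile(res$stack, truth_roi_pairs(res$stack,
                                                      res$truth$mask))
  dl <- depth_limit(prof)
  expect_equal(dl, res$truth$depth_limit_um, tolerance = 0.1)
})

test_that("44 somata fit the functional field without overlap", {
  rec <- session_recipe(duration_s = 2, seed = 1)
  res <- make_activity_movie(rec)
  nn <- res$truth$neurons
  expect_length(nn, 44)
  cov <- matrix(0L, 120, 120)
  for (n in nn) {
    px <- n$roi$coordinates + 1
    expect_true(all(px >= 1 & px <= 120))
    cov[px] <- cov[px] + 1L
  }
  expect_lte(max(cov), 1L)  # disjoint masks
  # soma diameters within the recipe range (10-15 um at 0.833 um/px)
  radii <- vapply(nn, `[[`, numeric(1), "radius_px")
  expect_true(all(radii >= 10 / 2 / (100 / 120) - 1e-9))
  expect_true(all(radii <= 15 / 2 / (100 / 120) + 1e-9))
})

test_that("a movie with no spikes yields flat traces", {
  rec <- session_recipe(n_neurons = 4, frame_shape = c(60, 60), fov_um = 50,
                        duration_s = 20, spike_rate_hz = 0, seed = 23)
  res <- make_activity_movie(rec)
  for (n in res$truth$neurons) {
    expect_length(n$spike_times_s, 0)
    expect_true(all(n$rate_multiplier == 1))
    tr <- extract_trace(res$movie, n$roi)
    expect_equal(mean(tr$values), n$baseline_counts_per_frame,
                 tolerance = 0.05)
  }
})

test_that("single transients at the 99% budget tier are detected", {
  # one isolated spike per neuron at f0 = 305 photons/neuron/s; matched
  # filter against the known onset should detect ~99% of transients
  n <- 44
  spikes <- lapply(seq_len(n), function(i) 5 + 0.45 * (i - 1))
  rec <- session_recipe(n_neurons = n, duration_s = 30, spike_times = spikes,
                        seed = 29)
  res <- make_activity_movie(rec)
  fs <- res$truth$frame_rate_hz
  tau <- res$truth$kinetics$tau_1e_s
  hits <- vapply(res$truth$neurons, function(nn) {
    tr <- extract_trace(res$movie, nn$roi)
    ts <- nn$spike_times_s[1]
    k0 <- floor(ts * fs) + 1
    kk <- k0:(k0 + 3)
    w <- exp(-((kk - 0.5) / fs - ts) / tau)
    w[w > 1] <- 1
    b <- nn$baseline_counts_per_frame
    score <- sum(w * (tr$values[kk] - b))
    mu <- sum(w * (nn$rate_multiplier[kk] - 1) * nn$f0_photons_s / fs)
    score > mu / 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("calibration fixtures behave across noise settings", {
  exact <- make_calibration_fixture(3, n_points = 10, noise = FALSE)
  expect_equal(fit_conversion_factor(exact$pixel_values,
                                     exact$photon_counts)$conversion_factor, 3)
  tiny <- make_calibration_fixture(3, n_points = 2, noise = FALSE)
  expect_error(fit_conversion_factor(tiny$pixel_values, tiny$photon_counts))
})
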