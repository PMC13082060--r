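test_that("photon conversion is linear and range-flagged", {
  cal <- photon_calibration(2.5, linear_range_max = 100)
  expect_equal(pixels_to_photons(matrix(0, 3, 3), cal), matrix(0, 3, 3))
  expect_equal(as.numeric(pixels_to_photons(10, cal)), 25)
  x <- matrix(1:20, 4, 5)
  expect_equal(pixels_to_photons(2 * x, cal), 2 * pixels_to_photons(x, cal))
  expect_warning(out <- pixels_to_photons(c(50, 150), cal), "linear range")
  expect_equal(attr(out, "out_of_linear_range"), 1)
})

test_that("conversion-factor fit recovers exact and noisy slopes", {
  x <- c(10, 20, 30, 40)
  cal <- fit_conversion_factor(x, 3 * x)
  expect_equal(cal$conversion_factor, 3)
  expect_equal(cal$linear_range_max, 40)
  fix <- make_calibration_fixture(2.4, n_points = 20, noise = TRUE, seed = 8)
  noisy <- fit_conversion_factor(fix$pixel_values, fix$photon_counts)
  expect_equal(noisy$conversion_factor, 2.4, tolerance = 0.05)
  expect_error(fit_conversion_factor(c(1, 2), c(3, 6)), "at least 3")
  expect_error(fit_conversion_factor(x, c(0, 1, 2, 3)))
})

test_that("line profiles sample nearest pixels in photons per pulse", {
  # flat image: constant profile value * factor / pulses
  vox <- array(7, dim = c(1, 20, 30))
  st <- image_stack(vox, pixel_size_um = 1.5, z_positions_um = 100,
                    pulses_per_pixel = 4)
  cal <- photon_calibration(2)
  r <- roi("polyline", rbind(c(10, 2), c(10, 25)), slice_index = 0)
  prof <- line_profile(st, r, cal)
  expect_true(all(prof$photons_per_pulse == 7 * 2 / 4))
  expect_equal(max(prof$arclength_um), 23 * 1.5)
  # Gaussian ridge: peak located within 1 px of the true center
  ny <- 40; nx <- 40
  img <- outer(rep(1, ny), exp(-((seq_len(nx) - 21)^2) / (2 * 3^2))) * 100
  st2 <- image_stack(array(round(img), dim = c(1, ny, nx)), 1, 0)
  r2 <- roi("polyline", rbind(c(19, 3), c(19, 36)), slice_index = 0)
  prof2 <- line_profile(st2, r2, photon_calibration(1))
  peak_col <- 3 + prof2$arclength_um[which.max(prof2$photons_per_pulse)]
  expect_lte(abs(peak_col - 20), 1)  # 0-based col of the ridge center
  expect_error(line_profile(st, roi("polyline", rbind(c(1, 1), c(1, 1))),
                            photon_calibration(1)), "zero-length")
})

test_that("SBR is the ROI mean ratio, scale-invariant, zero-flagged", {
  vox <- array(4, dim = c(2, 10, 10))
  vox[1, 1:3, 1:3] <- 40
  st <- image_stack(vox, 1, c(0, 100))
  sig <- square_roi(0, 2, 0, 2)
  bg <- square_roi(5, 9, 5, 9)
  expect_equal(sbr(st, sig, bg), 10)
  expect_equal(sbr(st, bg, bg), 1)
  st2 <- image_stack(vox * 7, 1, c(0, 100))
  expect_equal(sbr(st2, sig, bg), 10)
  zvox <- vox; zvox[1, 5:10, 5:10] <- 0
  stz <- image_stack(zvox, 1, c(0, 100))
  out <- sbr(stz, sig, bg)
  expect_true(is.infinite(out))
  expect_true(attr(out, "zero_background"))
  expect_error(sbr(st, sig, square_roi(5, 9, 5, 9, slice = 1)), "same slice")
})

test_that("depth profile aggregates pairs per slice and orders by depth", {
  vox <- array(2, dim = c(3, 12, 12))
  vox[1, 1:4, 1:4] <- 20; vox[2, 1:4, 1:4] <- 10; vox[3, 1:4, 1:4] <- 4
  st <- image_stack(vox, 1, c(100, 200, 300))
  pairs <- lapply(0:2, function(k) list(
    signal = square_roi(0, 3, 0, 3, slice = k, label = paste0("s", k)),
    background = square_roi(6, 11, 6, 11, slice = k)))
  prof <- sbr_depth_profile(st, rev(pairs))  # supply out of order
  expect_s3_class(prof, "sbr_profile")
  expect_equal(prof$depth_um, c(100, 200, 300))
  expect_equal(prof$sbr, c(10, 5, 2))
  expect_equal(prof$n_pairs, rep(1L, 3))
  empty <- sbr_depth_profile(st, list())
  expect_equal(nrow(empty), 0)
})

test_that("depth limit interpolates log-linearly between bracketing slices", {
  prof <- data.frame(depth_um = c(2000, 2400, 2500), sbr = c(4, 2, 1))
  expect_equal(depth_limit(prof), 2500)
  expect_true(is.na(depth_limit(data.frame(depth_um = c(1, 2),
                                           sbr = c(9, 4)))))
  prof2 <- data.frame(depth_um = c(2300, 2500), sbr = c(2, 0.5))
  expect_equal(depth_limit(prof2), 2300 + 200 * log(2) / log(4))
  # result lies inside the profile's depth range whenever defined
  prof3 <- data.frame(depth_um = c(100, 900, 1700), sbr = c(30, 3, 0.3))
  dl <- depth_limit(prof3)
  expect_gte(dl, 100); expect_lte(dl, 1700)
  # monotone re-indexing of slices does not move the crossing
  expect_equal(depth_limit(prof3[c(3, 1, 2), ]), dl)
  expect_error(depth_limit(prof3[0, ]), "empty")
})

test_that("EAL estimation inverts the cube-law decay", {
  z <- seq(0, 900, by = 100)
  en <- rep(2, length(z))
  sig <- (en * exp(-z / 300))^3
  est <- estimate_eal(z, sig, en, seed = 1)
  expect_equal(est$eal_um, 300, tolerance = 1e-6)
  # energy-ramped acquisition normalizes out through the energy column
  en2 <- 2 * exp(z / 600)
  sig2 <- (en2 * exp(-z / 300))^3
  expect_equal(estimate_eal(z, sig2, en2, seed = 1)$eal_um, 300,
               tolerance = 1e-6)
  expect_error(estimate_eal(z, rep(5, length(z)), en, seed = 1),
               "no attenuation")
  expect_error(estimate_eal(z[1:3], sig[1:3], en[1:3]), "at least 4")
})

test_that("EAL recovery from Poisson-noised synthetic stacks", {
  for (eal in c(200, 300, 400)) {
    rec <- stack_recipe(shape = c(10, 48, 48), z_range_um = c(0, 1.5 * eal),
                        tissue = uniform_tissue(eal),
                        energy_ramp = "constant", photon_scale = 200,
                        sbr0 = 500, depth_limit_um = 2500, seed = 33)
    res <- make_structural_stack(rec)
    sig <- slice_signal_means(res$stack, res$truth$mask)
    est <- estimate_eal(res$truth$z_positions_um, sig,
                        res$truth$surface_energies_nj, seed = 2)
    expect_equal(est$eal_um, eal, tolerance = 0.1)
  }
})

test_that("histogram stretching clips the requested tails", {
  expect_equal(histogram_stretch(matrix(5, 4, 4)), array(0, c(4, 4)))
  x <- matrix(0:999, 25, 40)
  out <- histogram_stretch(x, 0.002)
  expect_equal(range(out), c(0, 1))
  expect_true(all(out[x >= 998] == 1))
  expect_true(all(out[x <= 1] == 0))
  expect_error(histogram_stretch(x, 0.1), "0.05")
})

test_that("photon conversion preserves Poisson variance-mean scaling", {
  set.seed(4)
  counts <- matrix(rpois(20000, 30), 100, 200)
  phot <- pixels_to_photons(counts, photon_calibration(1))
  expect_equal(var(as.numeric(phot)) / mean(phot), 1, tolerance = 0.1)
})
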