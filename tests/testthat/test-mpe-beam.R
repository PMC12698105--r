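# Limiting-aperture safety analysis and beam-geometry computations.

test_that("fiber-to-camera distance follows the cone geometry", {
  expect_equal(fiber_to_camera_distance(5, 0.22), 11.09, tolerance = 1e-3)
  expect_equal(fiber_to_camera_distance(5, 0.50), 5 * sqrt(3) / 2,
               tolerance = 1e-12)  # asin(0.5) = 30 deg
  expect_gt(fiber_to_camera_distance(5, 1e-4), 2e4)
  expect_error(fiber_to_camera_distance(5, 1), "NA_fiber")
})

test_that("safety standards produce the expected MPE irradiance", {
  iec <- safety_standard()
  expect_equal(iec$mpe_irradiance, 0.2 * 10^(0.002 * 85))
  expect_equal(safety_standard("ansi")$mpe_irradiance, 0.28)
  expect_equal(safety_standard(mpe_irradiance = 0.5)$mpe_irradiance, 0.5)
  # point-source limit = MPE x aperture area (~28 mW at 785 nm, IEC)
  expect_equal(point_source_power_limit(iec) * 1000, 28.46, tolerance = 1e-3)
})

test_that("aperture-averaged irradiance obeys the small- and large-beam rules", {
  std <- safety_standard()
  # uniform flat-top larger than the aperture: max average = beam irradiance
  ft <- generate_beam_image("flattop", diameter = 5, pixel_pitch = 0.05,
                            total_power = 0.05)
  beam_area_cm2 <- pi * 0.25^2
  m <- max_aperture_averaged_irradiance(ft, 3.5)
  expect_equal(m$max_irradiance, 0.05 / beam_area_cm2, tolerance = 0.01)
  # sub-aperture beam: total power averaged over the whole aperture
  small <- generate_beam_image("gaussian", diameter = 0.5, pixel_pitch = 0.008,
                               total_power = 0.01, image_width = 6)
  ms <- max_aperture_averaged_irradiance(small, 3.5)
  expect_equal(ms$max_irradiance, 0.01 / (pi * 0.175^2), tolerance = 0.005)
  # symmetric beam: the scan's maximizing aperture sits at the centroid
  g <- generate_beam_image("gaussian", diameter = 5, pixel_pitch = 0.05)
  mg <- max_aperture_averaged_irradiance(g, 3.5)
  ctr <- (nrow(g$irradiance) + 1) / 2
  expect_lt(max(abs(mg$center - ctr)), 2)
  expect_error(
    max_aperture_averaged_irradiance(
      generate_beam_image("flattop", 5, 0.05, image_width = 6), 3.5),
    "margin")
})

test_that("allowed power depends on shape only and favors flat-tops", {
  std <- safety_standard()
  ft1 <- generate_beam_image("flattop", 5, 0.05, total_power = 1)
  ft2 <- generate_beam_image("flattop", 5, 0.05, total_power = 123)
  expect_equal(allowed_power(ft1, std), allowed_power(ft2, std),
               tolerance = 1e-10)
  g <- generate_beam_image("gaussian", 5, 0.05)
  expect_gt(allowed_power(ft1, std), allowed_power(g, std))
  # sub-aperture beam hits the point-source limit
  small <- generate_beam_image("gaussian", 0.5, 0.008, image_width = 6)
  expect_equal(allowed_power(small, std), point_source_power_limit(std),
               tolerance = 0.005)
})

test_that("aperture power fractions match closed forms", {
  ft <- generate_beam_image("flattop", 5, 0.05)
  expect_equal(fraction_in_aperture(ft, 3.5), (3.5 / 5)^2, tolerance = 0.005)
  expect_equal(fraction_in_aperture(ft, 20), 1.0)
  g <- generate_beam_image("gaussian", 5, 0.05)
  w <- 2.5  # 1/e^2 radius
  for (d in c(2, 3.5, 5)) {
    expect_equal(fraction_in_aperture(g, d), 1 - exp(-2 * (d / 2)^2 / w^2),
                 tolerance = 0.01)
  }
})

test_that("headroom and SNR-gain algebra behave as documented", {
  expect_equal(aperture_power_headroom(1), 1)
  expect_equal(aperture_power_headroom(0.911), 1 / 0.911)
  expect_error(aperture_power_headroom(0), "fraction")
  expect_equal(theoretical_snr_gain(1, 1, 1), 1)
  expect_equal(theoretical_snr_gain(2, 0.8, 0.911), 2 * 0.8 / 0.911)
  # linear in each argument
  expect_equal(theoretical_snr_gain(4, 0.8, 0.911),
               2 * theoretical_snr_gain(2, 0.8, 0.911))
  expect_equal(theoretical_snr_gain(2, 0.4, 0.911),
               theoretical_snr_gain(2, 0.8, 0.911) / 2)
})

test_that("uniformity report recovers generator shapes", {
  ft <- generate_beam_image("flattop", 5, 0.05)
  rep_ft <- beam_uniformity_report(ft, smooth_px = 5)
  rad <- rep_ft$radial_profile
  inside <- rad$radius_mm < 2.2
  outside <- rad$radius_mm > 2.8 & rad$radius_mm < 5
  expect_lt(diff(range(rad$mean_irradiance[inside])) /
              mean(rad$mean_irradiance[inside]), 0.01)
  expect_true(all(rad$mean_irradiance[outside] == 0))

  g <- generate_beam_image("gaussian", 5, 0.05)
  rep_g <- beam_uniformity_report(g, smooth_px = 5)
  radg <- rep_g$radial_profile
  sel <- radg$radius_mm < 4
  predicted <- max(g$irradiance) * exp(-2 * radg$radius_mm[sel]^2 / 2.5^2)
  rms <- sqrt(mean((radg$mean_irradiance[sel] - predicted)^2)) /
    max(predicted)
  expect_lt(rms, 0.02)
  # equal power in matched diameters: the Gaussian peak must be higher
  expect_gt(max(g$irradiance), max(ft$irradiance))
  expect_gt(rep_g$peak_irradiance, rep_ft$peak_irradiance)
})

test_that("frame preprocessing averages, subtracts and clips", {
  set.seed(5)
  base <- generate_beam_image("gaussian", 5, 0.1)$irradiance
  expect_equal(preprocess_frames(list(base, base), background = 0,
                                 pixel_pitch = 0.1)$irradiance, base)
  # background equal to the mean frame zeroes the profile
  p0 <- preprocess_frames(list(base), background = base, pixel_pitch = 0.1)
  expect_equal(sum(p0$irradiance), 0)
  # pure zero-mean noise averages down as 1/sqrt(N)
  n_frames <- 64
  frames <- lapply(seq_len(n_frames), function(i)
    matrix(rnorm(100 * 100, 0, 1), 100, 100))
  avg <- preprocess_frames(frames, background = 0, pixel_pitch = 0.1)
  expect_lt(max(avg$irradiance), 5 / sqrt(n_frames))
  expect_error(preprocess_frames(list(base, base[1:10, 1:10]),
                                 background = 0, pixel_pitch = 0.1),
               "shape")
})

test_that("beam maps round-trip through TIFF and CSV with sidecars", {
  g <- generate_beam_image("gaussian", 5, 0.1, total_power = 0.031)
  for (ext in c(".tif", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_beam_profile(g, path)
    back <- read_beam_profile(path)
    expect_equal(back$pixel_pitch, g$pixel_pitch)
    expect_equal(back$total_power, g$total_power, tolerance = 1e-3)
    expect_equal(back$irradiance, g$irradiance,
                 tolerance = if (ext == ".tif") 1e-3 else 1e-6)
  }
})
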