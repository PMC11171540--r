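test_that("synthetic patch spectra are reproducible, bounded and low rank", {
  R1 <- synth_patch_spectra(24, 6, seed = 7)
  R2 <- synth_patch_spectra(24, 6, seed = 7)
  expect_identical(R1, R2)
  expect_false(identical(R1, synth_patch_spectra(24, 6, seed = 8)))
  expect_true(all(R1 >= 0.02 & R1 <= 0.95))
  # centred rank equals basis_dim (raw rank at most basis_dim + 1)
  expect_equal(qr(sweep(R1, 1, rowMeans(R1)))$rank, 6)
  expect_lte(qr(R1)$rank, 7)
  # basis_dim = 1 gives one dominant principal component
  basis <- fit_basis(synth_patch_spectra(12, 1, seed = 3), 0.9, 12)
  expect_equal(basis$k, 1)
  expect_error(synth_patch_spectra(4, 6), "n >= basis_dim")
})

test_that("camera simulation honours offsets, linearity and its seed", {
  g <- default_grid()
  d65 <- illuminant_spd("D65", g)
  zero <- matrix(0, g$n, 2)
  cam <- camera_model(offset = 10, encode_gamma = TRUE, quantize = FALSE)
  out <- simulate_camera(zero, d65, cam)
  expect_equal(unname(out), matrix(encode_srgb(10 / 255), 3, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # linear mode doubles with reflectance
  lin_cam <- camera_model(encode_gamma = FALSE, quantize = FALSE)
  R <- synth_patch_spectra(6, 3, seed = 1)
  expect_equal(simulate_camera(0.5 * R, d65, lin_cam) * 2,
               simulate_camera(R, d65, lin_cam), tolerance = 1e-12,
               ignore_attr = TRUE)
  # noise is reproducible per seed
  noisy <- camera_model(noise_sd = 1, quantize = FALSE, seed = 9)
  expect_identical(simulate_camera(R, d65, noisy),
                   simulate_camera(R, d65, noisy))
})

test_that("the undistorted colorimetric camera reproduces spectrum_to_xyz", {
  g <- default_grid()
  d65 <- illuminant_spd("D65", g)
  R <- synth_patch_spectra(24, 6, seed = 5)
  # identity crosstalk, linear output: readings are exactly XYZ/100
  cam <- camera_model(encode_gamma = FALSE, quantize = FALSE)
  expect_equal(100 * unname(simulate_camera(R, d65, cam)),
               unname(spectrum_to_xyz(R, d65)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # through the full sRGB encode/decode path, still exact
  srgb <- simulate_camera(R, d65, ideal_srgb_camera())
  expect_equal(unname(linear_rgb_to_xyz(decode_srgb(srgb, "unit"))),
               unname(spectrum_to_xyz(R, d65)), tolerance = 1e-6)
  # with 8-bit quantization, within a quantisation step
  srgb8 <- simulate_camera(R, d65, ideal_srgb_camera(quantize = TRUE))
  expect_equal(attr(srgb8, "encoding"), "8bit")
  expect_lt(max(abs(linear_rgb_to_xyz(decode_srgb(srgb8, "8bit")) -
                      spectrum_to_xyz(R, d65))), 0.5)
})

test_that("the cubic sensor response inverts its declared polynomial", {
  d <- cubic_distortion(0.01, 0.9, 0.3)
  y <- seq(0.011, 1.2, length.out = 50)
  u <- savehsi:::distortion_inverse(d, y)
  expect_equal(savehsi:::distortion_forward(d, u), y, tolerance = 1e-12)
  expect_error(cubic_distortion(a1 = -1), "monoton")
})

test_that("phantoms attenuate vessels at the absorber bands only as configured", {
  g <- default_grid()
  ph0 <- make_phantom(phantom_spec(height = 16, width = 16, depth = 0,
                                   seed = 6))
  expect_equal(ph0$vessel$values, ph0$background$values)
  ph <- make_phantom(phantom_spec(height = 16, width = 16, depth = 0.4,
                                  seed = 6))
  at <- function(curve, nm) curve$values[g$wavelengths == nm]
  expect_lt(at(ph$vessel, 415), at(ph$background, 415))
  expect_lt(at(ph$vessel, 540), at(ph$background, 540))
  # far from both bands the attenuation is negligible
  expect_equal(at(ph$vessel, 700), at(ph$background, 700), tolerance = 1e-3)
  # a vessel pixel carries the vessel spectrum, background pixels the base
  vi <- which(ph$mask, arr.ind = TRUE)[1, ]
  bi <- which(!ph$mask, arr.ind = TRUE)[1, ]
  expect_equal(unname(ph$cube$values[vi[1], vi[2], ]), ph$vessel$values)
  expect_equal(unname(ph$cube$values[bi[1], bi[2], ]), ph$background$values)
})

test_that("phantom mask area tracks the geometric expectation across seeds", {
  spec0 <- phantom_spec()
  expected <- spec0$n_vessels * spec0$vessel_width / spec0$width
  fracs <- vapply(1:10, function(s)
    mean(make_phantom(phantom_spec(seed = s))$mask), numeric(1))
  expect_true(all(abs(fracs - expected) / expected < 0.2))
})

test_that("full-loop recovery stays below 0.06 RMSE under noise across seeds", {
  # 8-bit quantization + 0.5-count sensor noise + 2-count dark current
  rmses <- vapply(1:6, function(seed) {
    s <- synth_setup(seed = seed, offset = 2, noise_sd = 0.5, quantize = TRUE)
    model <- calibrate(s$meas)
    corrected <- apply_correction(model$correction, meas_camera_xyz(s$meas))
    spectral_rmse(reconstruct_spectrum(model$reconstruction, corrected),
                  s$R)$mean
  }, numeric(1))
  expect_lt(mean(rmses), 0.06)
  expect_true(all(rmses < 0.06))
})

test_that("simulation manifests round-trip into working measurement sets", {
  dir <- withr::local_tempdir()
  path <- write_simulation(dir, seed = 11, n = 24, basis_dim = 6)
  expect_true(file.exists(path))
  meas <- read_calibration_manifest(path)
  expect_equal(ncol(meas$spectra), 24)
  expect_equal(meas$rgb_encoding, "8bit")
  # spectra survive the CSV round trip to write precision
  R <- synth_patch_spectra(24, 6, seed = 11)
  expect_equal(unname(meas$spectra), unname(R), tolerance = 1e-6)
  # and the manifest is calibratable end to end
  model <- calibrate(meas)
  expect_lt(model$correction$rmse, 0.5355)
})
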