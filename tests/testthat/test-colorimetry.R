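test_that("sRGB transfer function has the standard fixed points and values", {
  expect_equal(decode_srgb(0, "8bit"), 0)
  expect_equal(decode_srgb(255, "8bit"), 1)
  # ((128/255 + 0.055)/1.055)^2.4, evaluated independently
  expect_equal(decode_srgb(128, "8bit"), 0.2158605001, tolerance = 1e-9)
  expect_true(all(diff(decode_srgb(0:255, "8bit")) > 0)) # monotone
  expect_error(decode_srgb(256, "8bit"), "out of")
  expect_error(decode_srgb(-0.1, "unit"), "out of")
  expect_error(encode_srgb(1.5), "out of")
})

test_that("encode/decode round-trips all 256 8-bit codes exactly", {
  codes <- 0:255
  expect_identical(encode_srgb(decode_srgb(codes, "8bit"), "8bit"),
                   as.numeric(codes))
  u <- seq(0, 1, length.out = 101)
  expect_equal(decode_srgb(encode_srgb(u)), u, tolerance = 1e-12)
})

test_that("linear RGB to XYZ is the standard sRGB matrix on the 0-100 scale", {
  expect_equal(linear_rgb_to_xyz(c(0, 0, 0)), c(X = 0, Y = 0, Z = 0))
  # reference white = row sums of the published matrix
  expect_equal(unname(linear_rgb_to_xyz(c(1, 1, 1))),
               100 * c(0.4124 + 0.3576 + 0.1805,
                       0.2126 + 0.7152 + 0.0722,
                       0.0193 + 0.1192 + 0.9505), tolerance = 1e-12)
  # primary = column extraction
  expect_equal(unname(linear_rgb_to_xyz(c(1, 0, 0))),
               100 * c(0.4124, 0.2126, 0.0193), tolerance = 1e-12)
  # matrix form round-trips through the inverse
  m <- matrix(runif(30), nrow = 3)
  expect_equal(xyz_to_linear_rgb(linear_rgb_to_xyz(m)), m,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("spectrum integration normalises a perfect reflector to Y = 100", {
  g <- default_grid()
  d65 <- illuminant_spd("D65", g)
  ones <- spectral_curve(rep(1, g$n), g)
  xyz <- spectrum_to_xyz(ones, d65)
  expect_equal(unname(xyz["Y"]), 100, tolerance = 1e-12)
  expect_equal(unname(spectrum_to_xyz(spectral_curve(rep(0, g$n), g), d65)),
               c(0, 0, 0))
  half <- spectrum_to_xyz(spectral_curve(rep(0.5, g$n), g), d65)
  expect_equal(unname(half["Y"]), 50, tolerance = 1e-12)
})

test_that("spectrum integration is linear in reflectance and k ignores R", {
  g <- default_grid()
  d65 <- illuminant_spd("D65", g)
  set.seed(7)
  for (i in 1:5) {
    r1 <- runif(g$n); r2 <- runif(g$n)
    a <- runif(1, 0, 0.6); b <- runif(1, 0, 0.4)
    mix <- spectrum_to_xyz(spectral_curve(a * r1 + b * r2, g), d65)
    parts <- a * spectrum_to_xyz(spectral_curve(r1, g), d65) +
      b * spectrum_to_xyz(spectral_curve(r2, g), d65)
    expect_equal(mix, parts, tolerance = 1e-9)
  }
  expect_equal(luminance_ratio(d65), luminance_ratio(d65), tolerance = 0)
})

test_that("degenerate illuminants and grid mismatches are rejected", {
  g <- default_grid()
  zero_ill <- spectral_curve(rep(0, g$n), g, "power")
  expect_error(spectrum_to_xyz(spectral_curve(rep(1, g$n), g), zero_ill),
               "degenerate illuminant")
  g2 <- wavelength_grid(400, 700, 1)
  expect_error(
    spectrum_to_xyz(spectral_curve(rep(1, g2$n), g2),
                    illuminant_spd("D65", g)),
    class = "savehsi_grid_error")
})

test_that("Lab transform maps the reference white to L=100, a=b=0", {
  white <- linear_rgb_to_xyz(c(1, 1, 1))
  expect_equal(unname(xyz_to_lab(white, white)), c(100, 0, 0),
               tolerance = 1e-9)
  expect_error(xyz_to_lab(white, c(-1, 100, 50)), "positive")
})

test_that("CIEDE2000 reproduces the published verification pairs", {
  # reference values from the standard CIEDE2000 test data set, verified
  # against an independent implementation
  pairs <- rbind(
    c(50, 2.6772, -79.7751, 50, 0.0000, -82.7485, 2.0425),
    c(50, 3.1571, -77.2803, 50, 0.0000, -82.7485, 2.8615),
    c(50, 2.8361, -74.0200, 50, 0.0000, -82.7485, 3.4412),
    c(50, 2.5000, 0.0000, 73, 25.0000, -18.0000, 27.1492),
    c(50, 2.5000, 0.0000, 61, -5.0000, 29.0000, 22.8977),
    c(2.0776, 0.0795, -1.1350, 0.9033, -0.0636, -0.5514, 0.9082))
  for (i in seq_len(nrow(pairs))) {
    got <- delta_e(pairs[i, 1:3], pairs[i, 4:6], "cie2000")
    expect_equal(got, pairs[i, 7], tolerance = 1e-4)
  }
})

test_that("colour differences are symmetric, non-negative and zero on identity", {
  set.seed(11)
  for (i in 1:20) {
    p <- c(runif(1, 0, 100), runif(2, -60, 60))
    q <- c(runif(1, 0, 100), runif(2, -60, 60))
    for (m in c("cie2000", "cie76")) {
      expect_equal(delta_e(p, p, m), 0)
      expect_gte(delta_e(p, q, m), 0)
      expect_equal(delta_e(p, q, m), delta_e(q, p, m), tolerance = 1e-12)
    }
  }
  expect_equal(delta_e(c(50, 10, -10), c(55, 12, -8), "cie76"),
               sqrt(25 + 4 + 4))
})

test_that("CIEDE2000 agrees with an independent library implementation", {
  set.seed(23)
  a <- cbind(runif(25, 0, 100), runif(25, -80, 80), runif(25, -80, 80))
  b <- cbind(runif(25, 0, 100), runif(25, -80, 80), runif(25, -80, 80))
  ours <- delta_e(t(a), t(b), "cie2000")
  theirs <- vapply(seq_len(nrow(a)), function(i)
    farver::compare_colour(a[i, , drop = FALSE], b[i, , drop = FALSE],
                           from_space = "lab", method = "cie2000")[1, 1],
    numeric(1))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("resampling interpolates linearly and holds endpoints", {
  g <- default_grid()
  # already on the grid: unchanged
  v <- runif(g$n)
  expect_equal(resample_to_grid(g$wavelengths, v, g)$values,
               pmin(pmax(v, 0), 1.2))
  # two-point ramp
  ramp <- resample_to_grid(c(380, 780), c(0, 1), g)
  expect_equal(ramp$values[g$wavelengths == 580], 0.5)
  # endpoint hold outside the measured range
  held <- resample_to_grid(seq(400, 700, 10), rep(c(0.3, 0.6), 16)[1:31], g)
  expect_equal(held$values[g$wavelengths == 380],
               held$values[g$wavelengths == 400])
  expect_error(resample_to_grid(c(500, 400), c(1, 2), g), "increasing")
  expect_error(resample_to_grid(c(400, 400, 500), c(1, 2, 3), g), "increasing")
})

test_that("spectrum CSV files round-trip through read/write", {
  g <- default_grid()
  curve <- spectral_curve(seq(0.1, 0.9, length.out = g$n), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(curve, path)
  back <- read_spectrum_csv(path, g)
  expect_equal(back$values, curve$values, tolerance = 1e-12)
})
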