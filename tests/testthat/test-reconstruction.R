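test_that("PCA basis retains orthonormal components and ordered variance", {
  s <- synth_setup()
  basis <- fit_basis(s$R, variance_target = 1, k_max = 12)
  expect_equal(crossprod(basis$EV), diag(basis$k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(basis$explained_variance) <= 1e-12))
  # scores of the mean spectrum are zero
  centred <- s$R - basis$mean_spectrum$values
  expect_equal(unname(t(basis$EV) %*% rowMeans(centred)),
               matrix(0, basis$k, 1), tolerance = 1e-9)
  # full-rank reconstruction reproduces the training set
  rec <- basis$mean_spectrum$values + basis$EV %*% basis$scores
  expect_equal(rec, s$R, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a rank-1 spectra set yields a single dominant component", {
  g <- default_grid()
  base <- 0.4 + 0.2 * sin(seq(0, pi, length.out = g$n))
  R <- outer(base - mean(base), runif(10, -0.5, 0.5)) + 0.5
  basis <- fit_basis(R, variance_target = 0.9, k_max = 12)
  expect_equal(basis$k, 1)
  expect_equal(basis$explained_fraction, 1, tolerance = 1e-9)
})

test_that("variance target selects the smallest sufficient dimension", {
  s <- synth_setup(basis_dim = 6)
  expect_equal(fit_basis(s$R, 0.999, 12)$k, 6)
  expect_equal(fit_basis(s$R, 0.999, 4)$k, 4) # k_max caps
  expect_error(fit_basis(s$R, 0), "variance_target")
  expect_error(fit_basis(s$R, 1.5), "variance_target")
})

test_that("score regression is exact when scores are linear in the expansion", {
  s <- synth_setup(distortion = NULL)
  basis <- fit_basis(s$R)
  xyz <- meas_camera_xyz(s$meas)
  model <- fit_transformation(basis, xyz)
  expect_lt(model$score_rmse, 1e-8)
  # permuting patch order leaves M unchanged
  perm <- sample(ncol(s$R))
  basis_p <- basis
  basis_p$scores <- basis$scores[, perm, drop = FALSE]
  model_p <- fit_transformation(basis_p, xyz[, perm])
  expect_equal(model_p$M, model$M, tolerance = 1e-8)
  expect_error(
    fit_transformation(basis, xyz[, 1:10]),
    "one corrected tristimulus per training spectrum")
})

test_that("noiseless in-span training patches are recovered end to end", {
  s <- synth_setup() # cubic distortion, no noise, no quantization
  model <- calibrate(s$meas)
  corrected <- apply_correction(model$correction, meas_camera_xyz(s$meas))
  S <- reconstruct_spectrum(model$reconstruction, corrected)
  expect_lt(spectral_rmse(S, s$R)$mean, 1e-8)
  # single-patch call agrees with the vectorised path and is a proper curve
  one <- reconstruct_spectrum(model$reconstruction, corrected[, 3])
  expect_s3_class(one, "spectral_curve")
  expect_length(one$values, 401)
  expect_equal(one$values, unname(S[, 3]), tolerance = 1e-12)
})

test_that("a zero expansion vector returns the mean spectrum, clipped outputs", {
  s <- synth_setup(distortion = NULL)
  basis <- fit_basis(s$R)
  lin <- expansion_spec(diag(3), include_constant = FALSE)
  model <- fit_transformation(basis, meas_camera_xyz(s$meas), lin)
  at_zero <- reconstruct_spectrum(model, c(0, 0, 0))
  expect_equal(at_zero$values, basis$mean_spectrum$values, tolerance = 1e-12)
  # outputs always lie in the declared reflectance range
  wild <- reconstruct_spectrum(model, matrix(c(500, 500, 500, -100, 0, 50),
                                             nrow = 3))
  expect_true(all(wild >= 0 & wild <= 1.2))
})

test_that("spectral RMSE reports per-spectrum values and their mean", {
  g <- default_grid()
  A <- matrix(runif(g$n * 3), ncol = 3)
  expect_equal(spectral_rmse(A, A)$per_spectrum, rep(0, 3),
               ignore_attr = TRUE)
  expect_equal(spectral_rmse(A + 0.1, A)$per_spectrum, rep(0.1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # hand-built: one spectrum differing in 3 bands by 0.2 each
  B <- A
  B[1:3, 2] <- A[1:3, 2] + 0.2
  expect_equal(spectral_rmse(B, A)$per_spectrum[2],
               sqrt(3 * 0.2^2 / g$n), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(spectral_rmse(A, A[, 1:2]), "differ")
})

test_that("training spectral RMSE is monotone in k and expansion size", {
  s <- synth_setup(offset = 2, noise_sd = 0.5, quantize = TRUE)
  correction <- fit_correction(s$meas)
  corrected <- apply_correction(correction, meas_camera_xyz(s$meas))
  rmse_at <- function(k, spec = default_expansion_spec()) {
    basis <- fit_basis(s$R, variance_target = 1, k_max = k)
    model <- fit_transformation(basis, corrected, spec)
    spectral_rmse(reconstruct_spectrum(model, corrected), s$R)$mean
  }
  by_k <- vapply(1:8, rmse_at, numeric(1))
  expect_true(all(diff(by_k) <= 1e-10))
  by_spec <- vapply(nested_specs(), function(sp) rmse_at(6, sp), numeric(1))
  expect_true(all(diff(by_spec) <= 1e-10))
})

test_that("calibration archives round-trip losslessly through JSON", {
  s <- synth_setup(offset = 2, noise_sd = 0.5, quantize = TRUE)
  model <- calibrate(s$meas)
  path <- withr::local_tempfile(fileext = ".save.json")
  save_calibration(model, path)
  back <- load_calibration(path)
  expect_equal(back$correction$C, model$correction$C, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(back$reconstruction$M, model$reconstruction$M, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(back$reconstruction$basis$EV, model$reconstruction$basis$EV,
               tolerance = 0, ignore_attr = TRUE)
  expect_equal(back$illuminant$values, model$illuminant$values, tolerance = 0)
  # the loaded model converts identically
  xyz <- meas_camera_xyz(s$meas)
  expect_equal(
    reconstruct_spectrum(back$reconstruction,
                         apply_correction(back$correction, xyz)),
    reconstruct_spectrum(model$reconstruction,
                         apply_correction(model$correction, xyz)),
    tolerance = 0)
  expect_error(load_calibration(withr::local_tempfile(lines = "{}")),
               "not a savehsi calibration")
})
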