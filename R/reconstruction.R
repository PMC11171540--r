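#' Fit a PCA basis over reference reflectance spectra
#'
#' Mean-centred principal component analysis of the reference spectra
#' (via [stats::prcomp]). The number of retained components k is the
#' smallest count whose cumulative explained-variance fraction reaches
#' `variance_target`, capped at `k_max`.
#'
#' @param reference_spectra `grid$n x N` matrix, list of curves, or curves.
#' @param variance_target fraction in (0, 1\].
#' @param k_max upper bound on k.
#' @param grid wavelength grid of the spectra.
#' @return a `pca_basis` with orthonormal components `EV`
#'   (`grid$n x k`), `mean_spectrum`, `scores` (k x N), `explained_variance`
#'   (non-increasing), and `explained_fraction`.
#' @export
fit_basis <- function(reference_spectra, variance_target = 0.999,
                      k_max = 12, grid = default_grid()) {
  abort_if(!is.numeric(variance_target) || variance_target <= 0 ||
             variance_target > 1,
           "variance_target must be in (0, 1]")
  R <- spectra_matrix(reference_spectra, grid)
  abort_if(ncol(R) < 2, "need at least 2 reference spectra")
  pc <- stats::prcomp(t(R), center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  frac <- cumsum(var_all) / sum(var_all)
  k <- which(frac >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(var_all)
  k <- min(k, k_max, ncol(pc$rotation))
  structure(list(
    EV = pc$rotation[, seq_len(k), drop = FALSE],
    mean_spectrum = spectral_curve(pc$center, grid),
    scores = t(pc$x[, seq_len(k), drop = FALSE]),
    explained_variance = var_all[seq_len(k)],
    explained_fraction = frac[k],
    grid = grid, k = k),
    class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> k = %d components, %.5f of variance explained\n",
              x$k, x$explained_fraction))
  invisible(x)
}

#' Fit the transformation matrix from corrected XYZ to PCA scores
#'
#' Least-squares fit of the k x n_terms matrix M with
#' `M = scores %*% pinv(V_color)`, where `V_color` stacks the polynomial
#' expansion of each training patch's corrected tristimulus values. Together
#' with the PCA basis this defines the analog-spectrum synthesis.
#'
#' @param basis a [fit_basis()] result.
#' @param corrected_xyz 3 x N matrix of corrected tristimulus values, one
#'   column per training spectrum (same order as the basis scores).
#' @param color_spec an [expansion_spec()]; defaults to the same term family
#'   as the correction stage.
#' @return a `reconstruction_model` with `M`, `color_spec`, `basis` and the
#'   training `score_rmse`.
#' @export
fit_transformation <- function(basis, corrected_xyz,
                               color_spec = default_expansion_spec()) {
  xyz <- if (is.matrix(corrected_xyz)) corrected_xyz else
    matrix(corrected_xyz, nrow = 3)
  n <- ncol(xyz)
  abort_if(n != ncol(basis$scores),
           "one corrected tristimulus per training spectrum is required")
  abort_if(n < color_spec$n_terms,
           sprintf("underdetermined system: %d patches < %d expansion terms",
                   n, color_spec$n_terms),
           class = "savehsi_underdetermined_error")
  V <- expand_xyz(xyz, color_spec)
  Vp <- pinv(V)
  abort_if(attr(Vp, "rank") < color_spec$n_terms,
           sprintf("variable matrix is rank deficient (rank %d < %d terms)",
                   attr(Vp, "rank"), color_spec$n_terms),
           class = "savehsi_rank_error")
  M <- basis$scores %*% Vp
  res <- M %*% V - basis$scores
  structure(list(M = M, color_spec = color_spec, basis = basis,
                 score_rmse = sqrt(mean(res^2))),
            class = "reconstruction_model")
}

#' Reconstruct analog reflectance spectra from corrected XYZ
#'
#' Synthesises `S = mean_spectrum + EV %*% (M %*% expand_xyz(xyz))` and clips
#' to the declared reflectance range \[0, 1.2\] (overshoot above 1 is kept
#' visible up to the ceiling instead of being flattened at 1; the number of
#' clipped samples is recorded in the `"n_clipped"` attribute).
#'
#' @param model a [fit_transformation()] result.
#' @param corrected_xyz length-3 vector or 3 x N matrix.
#' @return a reflectance [spectral_curve()] for a single input, else a
#'   `grid$n x N` matrix (clipped, with `"n_clipped"` attribute).
#' @export
reconstruct_spectrum <- function(model, corrected_xyz) {
  single <- !is.matrix(corrected_xyz)
  xyz <- if (single) matrix(corrected_xyz, nrow = 3) else corrected_xyz
  S <- model$basis$mean_spectrum$values +
    model$basis$EV %*% (model$M %*% expand_xyz(xyz, model$color_spec))
  if (single) return(spectral_curve(drop(S), model$basis$grid))
  n_clipped <- sum(S < 0 | S > reflectance_ceiling())
  S <- pmin(pmax(S, 0), reflectance_ceiling())
  attr(S, "n_clipped") <- n_clipped
  S
}

#' Per-spectrum and average RMSE between spectra sets
#'
#' RMSE over the wavelength bands (reflectance units) for each
#' reconstructed/reference pair, plus their mean.
#'
#' @param reconstructed,reference matrices of column spectra, lists of
#'   curves, or single curves; equal counts on a shared grid.
#' @param grid wavelength grid.
#' @return list with `per_spectrum` (length-N vector) and `mean`.
#' @export
spectral_rmse <- function(reconstructed, reference, grid = default_grid()) {
  A <- spectra_matrix(reconstructed, grid)
  B <- spectra_matrix(reference, grid)
  abort_if(ncol(A) != ncol(B), "spectra counts differ")
  per <- sqrt(colMeans((A - B)^2))
  list(per_spectrum = per, mean = mean(per))
}

#' Run the full calibration procedure on a patch measurement set
#'
#' Chains the whole fit: camera-error correction ([fit_correction()]), PCA
#' basis over the reference spectra ([fit_basis()]), and the
#' tristimulus-to-score regression ([fit_transformation()]) using the
#' corrected camera tristimulus values of the training patches. The result
#' bundles everything needed to convert images.
#'
#' @param measurements a [patch_measurement_set()].
#' @param correction_spec expansion for the correction stage.
#' @param color_spec expansion for the reconstruction stage.
#' @param variance_target,k_max PCA retention controls, see [fit_basis()].
#' @param cmfs colour matching functions.
#' @return a `calibration_model` with fields `correction`, `reconstruction`,
#'   `illuminant`, `grid` and `provenance`.
#' @export
calibrate <- function(measurements,
                      correction_spec = default_expansion_spec(),
                      color_spec = default_expansion_spec(),
                      variance_target = 0.999, k_max = 12,
                      cmfs = cie_cmfs(measurements$grid)) {
  correction <- fit_correction(measurements, correction_spec, cmfs)
  corrected <- apply_correction(correction, camera_xyz(measurements))
  basis <- fit_basis(measurements$spectra, variance_target, k_max,
                     measurements$grid)
  reconstruction <- fit_transformation(basis, corrected, color_spec)
  structure(list(
    correction = correction,
    reconstruction = reconstruction,
    illuminant = measurements$illuminant,
    grid = measurements$grid,
    provenance = list(created = format(Sys.time(), tz = "UTC"),
                      version = as.character(utils::packageVersion("savehsi")),
                      n_patches = ncol(measurements$spectra))),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<calibration_model> %d patches; XYZ RMSE %.4g; k = %d; ",
    "score RMSE %.3g\n"),
    x$provenance$n_patches, x$correction$rmse,
    x$reconstruction$basis$k, x$reconstruction$score_rmse))
  invisible(x)
}

#' Serialise / load a calibration model
#'
#' The archive is a single versioned JSON file: a header with the expansion
#' specs, PCA dimension, grid and provenance, plus the numeric matrix
#' payloads written at full double precision. The round trip is lossless.
#'
#' @param model a [calibrate()] result.
#' @param path file path (conventionally `.save.json`).
#' @return `save_calibration` returns `path` invisibly; `load_calibration`
#'   returns the `calibration_model`.
#' @export
save_calibration <- function(model, path) {
  spec_js <- function(s) list(terms = unclass(s$terms),
                              include_constant = s$include_constant)
  payload <- list(
    format = "savehsi-calibration",
    format_version = 1L,
    grid = list(start = model$grid$start, stop = model$grid$stop,
                step = model$grid$step),
    provenance = model$provenance,
    illuminant = model$illuminant$values,
    correction = list(C = model$correction$C,
                      spec = spec_js(model$correction$spec),
                      rmse = model$correction$rmse,
                      rmse_uncorrected = model$correction$rmse_uncorrected,
                      residuals = model$correction$residuals,
                      ids = model$correction$ids),
    reconstruction = list(
      M = model$reconstruction$M,
      color_spec = spec_js(model$reconstruction$color_spec),
      score_rmse = model$reconstruction$score_rmse,
      basis = list(EV = model$reconstruction$basis$EV,
                   mean_spectrum = model$reconstruction$basis$mean_spectrum$values,
                   scores = model$reconstruction$basis$scores,
                   explained_variance = model$reconstruction$basis$explained_variance,
                   explained_fraction = model$reconstruction$basis$explained_fraction,
                   k = model$reconstruction$basis$k)))
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE),
             path)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  js <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                           simplifyMatrix = TRUE)
  abort_if(!identical(js$format, "savehsi-calibration"),
           sprintf("%s is not a savehsi calibration archive", path))
  grid <- wavelength_grid(js$grid$start, js$grid$stop, js$grid$step)
  spec_fromjs <- function(s) expansion_spec(matrix(s$terms, ncol = 3),
                                            s$include_constant)
  basis <- structure(list(
    EV = matrix(js$reconstruction$basis$EV, nrow = grid$n),
    mean_spectrum = spectral_curve(js$reconstruction$basis$mean_spectrum, grid),
    scores = matrix(js$reconstruction$basis$scores,
                    nrow = js$reconstruction$basis$k),
    explained_variance = js$reconstruction$basis$explained_variance,
    explained_fraction = js$reconstruction$basis$explained_fraction,
    grid = grid, k = js$reconstruction$basis$k), class = "pca_basis")
  correction <- structure(list(
    C = matrix(js$correction$C, nrow = 3),
    spec = spec_fromjs(js$correction$spec),
    residuals = matrix(js$correction$residuals, nrow = 3),
    rmse = js$correction$rmse,
    rmse_uncorrected = js$correction$rmse_uncorrected,
    ids = js$correction$ids), class = "correction_model")
  reconstruction <- structure(list(
    M = matrix(js$reconstruction$M, nrow = basis$k),
    color_spec = spec_fromjs(js$reconstruction$color_spec),
    basis = basis,
    score_rmse = js$reconstruction$score_rmse), class = "reconstruction_model")
  structure(list(correction = correction, reconstruction = reconstruction,
                 illuminant = spectral_curve(js$illuminant, grid, "power"),
                 grid = grid, provenance = js$provenance),
            class = "calibration_model")
}
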