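#' Polynomial expansion specification for tristimulus values
#'
#' The camera-error correction and the spectral reconstruction both regress
#' against a "variable matrix" built from monomials of the tristimulus
#' values. An `expansion_spec` lists those monomials as exponent triples
#' (a, b, c) meaning `X^a * Y^b * Z^c`, plus an optional constant term. The
#' three linear terms X, Y, Z are always required: they carry the identity
#' part of the correction.
#'
#' The default 14-term family is constant + linear + all degree-2 monomials
#' + XYZ + the pure cubes. The constant absorbs dark-current offsets, the
#' cross terms absorb colour-filter separation and colour shift, and the
#' powers absorb nonlinear sensor response.
#'
#' @param terms integer matrix with 3 columns (exponents of X, Y, Z), one
#'   row per monomial.
#' @param include_constant add a leading constant-1 term.
#' @return an `expansion_spec` object with `terms`, `include_constant` and
#'   `n_terms`.
#' @export
expansion_spec <- function(terms, include_constant = TRUE) {
  terms <- matrix(as.integer(terms), ncol = 3)
  abort_if(nrow(terms) == 0, "expansion needs at least one monomial")
  abort_if(any(terms < 0), "exponents must be non-negative")
  abort_if(anyDuplicated(as.data.frame(terms)) > 0, "duplicate monomials")
  lin <- diag(3)
  has_lin <- vapply(seq_len(3), function(i)
    any(apply(terms, 1, function(r) all(r == lin[i, ]))), logical(1))
  abort_if(!all(has_lin), "the linear terms X, Y, Z must all be present")
  structure(list(terms = terms, include_constant = isTRUE(include_constant),
                 n_terms = nrow(terms) + isTRUE(include_constant)),
            class = "expansion_spec")
}

#' @rdname expansion_spec
#' @export
default_expansion_spec <- function() {
  expansion_spec(rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),          # linear
    c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),          # squares
    c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),          # cross terms
    c(1, 1, 1),                                  # XYZ
    c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)),         # cubes
    include_constant = TRUE)
}

#' Expand tristimulus values into a variable matrix
#'
#' @param xyz length-3 vector or 3 x N matrix (0-100 scale).
#' @param spec an [expansion_spec()].
#' @return length-`n_terms` vector or `n_terms x N` matrix; term order is
#'   constant (if enabled) followed by the monomials in spec order.
#' @export
expand_xyz <- function(xyz, spec = default_expansion_spec()) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 3)
  abort_if(nrow(m) != 3, "expected 3 rows (X, Y, Z)")
  abort_if(!all(is.finite(m)), "non-finite tristimulus input")
  rows <- apply(spec$terms, 1, function(e)
    m[1, ]^e[1] * m[2, ]^e[2] * m[3, ]^e[3])
  V <- t(matrix(rows, ncol = nrow(spec$terms)))
  if (spec$include_constant) V <- rbind(rep(1, ncol(V)), V)
  if (is.matrix(xyz)) V else drop(V)
}

#' Paired calibration measurements for a colour target
#'
#' Bundles, for each patch of a calibration target (24-patch Macbeth-style
#' checker by default), the camera's sRGB reading and the spectrometer's
#' reference reflectance, plus the illuminant under which both were taken.
#'
#' @param camera_rgb 3 x N matrix (or N x 3, auto-transposed) of camera sRGB
#'   readings.
#' @param spectra `grid$n x N` matrix or list of reflectance
#'   [spectral_curve()]s, one per patch.
#' @param illuminant a power [spectral_curve()].
#' @param ids unique patch identifiers.
#' @param rgb_encoding `"8bit"` or `"unit"`, the declared scale of
#'   `camera_rgb`.
#' @return a `patch_measurement_set`.
#' @export
patch_measurement_set <- function(camera_rgb, spectra, illuminant,
                                  ids = NULL, rgb_encoding = c("8bit", "unit")) {
  rgb_encoding <- match.arg(rgb_encoding)
  R <- spectra_matrix(spectra, illuminant$grid)
  rgb <- as.matrix(camera_rgb)
  if (nrow(rgb) != 3 && ncol(rgb) == 3) rgb <- t(rgb)
  abort_if(nrow(rgb) != 3, "camera_rgb must be 3 x N (R, G, B rows)")
  abort_if(ncol(rgb) != ncol(R),
           "camera readings and reference spectra count differ")
  if (is.null(ids)) ids <- sprintf("patch%02d", seq_len(ncol(R)))
  abort_if(anyDuplicated(ids) > 0, "patch ids must be unique")
  structure(list(camera_rgb = rgb, spectra = R, illuminant = illuminant,
                 ids = as.character(ids), rgb_encoding = rgb_encoding,
                 grid = illuminant$grid),
            class = "patch_measurement_set")
}

# camera XYZ from the stored sRGB readings (decode -> matrix, 0-100 scale)
camera_xyz <- function(measurements) {
  linear_rgb_to_xyz(decode_srgb(measurements$camera_rgb,
                                measurements$rgb_encoding))
}

# spectrometer-derived reference XYZ
reference_xyz <- function(measurements, cmfs = cie_cmfs(measurements$grid)) {
  spectrum_to_xyz(measurements$spectra, measurements$illuminant, cmfs)
}

#' Fit the camera-error correction matrix
#'
#' Least-squares fit of the 3 x n_terms matrix C such that
#' `C %*% expand_xyz(camera XYZ)` approximates the spectrometer-derived
#' reference XYZ over the training patches: `C = XYZ_ref %*% pinv(V)` with V
#' the stacked expanded camera tristimulus columns. The pseudo-inverse uses
#' a rank-revealing SVD with relative tolerance 1e-10; a rank-deficient V or
#' fewer patches than terms is an error rather than a silently regularised
#' fit.
#'
#' @param measurements a [patch_measurement_set()].
#' @param spec an [expansion_spec()]; default [default_expansion_spec()].
#' @param cmfs colour matching functions on the measurement grid.
#' @return a `correction_model` with fields `C`, `spec`, per-patch
#'   `residuals` (3 x N), pooled `rmse`, and `rmse_uncorrected`.
#' @export
fit_correction <- function(measurements, spec = default_expansion_spec(),
                           cmfs = cie_cmfs(measurements$grid)) {
  xyz_ref <- reference_xyz(measurements, cmfs)
  xyz_cam <- camera_xyz(measurements)
  n <- ncol(xyz_ref)
  abort_if(n < spec$n_terms,
           sprintf("underdetermined system: %d patches < %d expansion terms",
                   n, spec$n_terms),
           class = "savehsi_underdetermined_error")
  V <- expand_xyz(xyz_cam, spec)
  Vp <- pinv(V)
  abort_if(attr(Vp, "rank") < spec$n_terms,
           sprintf("variable matrix is rank deficient (rank %d < %d terms)",
                   attr(Vp, "rank"), spec$n_terms),
           class = "savehsi_rank_error")
  C <- xyz_ref %*% Vp
  fitted <- C %*% V
  res <- fitted - xyz_ref
  structure(list(
    C = C, spec = spec,
    residuals = res,
    rmse = sqrt(mean(res^2)),
    rmse_uncorrected = sqrt(mean((xyz_cam - xyz_ref)^2)),
    ids = measurements$ids),
    class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %d terms; training XYZ RMSE %.4g (uncorrected %.4g)\n",
              x$spec$n_terms, x$rmse, x$rmse_uncorrected))
  invisible(x)
}

#' Apply a fitted correction to camera tristimulus values
#'
#' @param model a `correction_model` from [fit_correction()].
#' @param xyz length-3 vector or 3 x N matrix of camera-derived XYZ.
#' @return corrected XYZ of the same shape.
#' @export
apply_correction <- function(model, xyz) {
  out <- model$C %*% expand_xyz(xyz, model$spec)
  rownames(out) <- c("X", "Y", "Z")
  if (is.matrix(xyz)) out else drop(out)
}

#' Pooled RMSE between two sets of tristimulus values
#'
#' Root mean squared componentwise difference pooled over all 3 components
#' and all patches (a single mean over `3 * N` squared differences). If
#' every component differs by exactly delta the result is delta.
#'
#' @param set_a,set_b 3 x N matrices (or length-3 vectors).
#' @return non-negative scalar.
#' @export
xyz_rmse <- function(set_a, set_b) {
  a <- if (is.matrix(set_a)) set_a else matrix(set_a, nrow = 3)
  b <- if (is.matrix(set_b)) set_b else matrix(set_b, nrow = 3)
  abort_if(!all(dim(a) == dim(b)), "tristimulus sets differ in length")
  sqrt(mean((a - b)^2))
}
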