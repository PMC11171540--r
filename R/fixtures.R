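# --- synthetic calibration target ------------------------------------------

# smooth raised-cosine bump on the grid
raised_cosine <- function(grid, center, halfwidth) {
  w <- grid$wavelengths
  out <- 0.5 * (1 + cos(pi * (w - center) / halfwidth))
  out[abs(w - center) > halfwidth] <- 0
  out
}

# project columns of B onto the metameric-black subspace of the given
# illuminant/observer: the result integrates to zero against S*xbar, S*ybar
# and S*zbar, i.e. is invisible to the colorimetric pipeline.
metameric_black <- function(B, illuminant, cmfs) {
  W <- illuminant$values * cbind(cmfs$xbar, cmfs$ybar, cmfs$zbar)
  B - W %*% solve(crossprod(W), crossprod(W, B))
}

#' Generate a synthetic set of smooth calibration-patch reflectances
#'
#' Emulates the 24-patch reflectance target used for camera calibration.
#' Spectra are built as `mean + deviation` where the deviation lives in an
#' exactly `basis_dim`-dimensional span of smooth curves, so the set has
#' rank `basis_dim` after centring (at most `basis_dim + 1` raw).
#'
#' The span is constructed so that the set is *identifiable from
#' tristimulus values*: the first `min(3, basis_dim)` components are broad
#' raised cosines with independent seeded coefficients (these determine the
#' patch's XYZ), while any further components are smooth metameric blacks —
#' curves invisible to the given illuminant/observer — whose coefficients
#' are seeded degree-2 polynomials of the primary coefficients. The
#' patch-to-score map of such a set is a degree-2 polynomial in XYZ, inside
#' the span of the default expansion, which is what makes exact noiseless
#' recovery through the calibration pipeline possible at all: reflectance
#' components that are both tristimulus-invisible and statistically
#' independent of the visible ones are unrecoverable from RGB by any method.
#'
#' Values are kept within \[0.02, 0.95\] by scaling the deviation (never by
#' clipping, which would break the polynomial structure); the draw is fully
#' determined by `seed`.
#'
#' @param n number of patches (>= basis_dim).
#' @param basis_dim dimension of the deviation span (>= 1).
#' @param seed integer seed.
#' @param grid wavelength grid.
#' @param illuminant,cmfs observer model defining the metameric-black
#'   subspace used for components beyond the third.
#' @return a `grid$n x n` matrix of column reflectance spectra in
#'   \[0.02, 0.95\].
#' @export
synth_patch_spectra <- function(n = 24, basis_dim = 6, seed = 42,
                                grid = default_grid(),
                                illuminant = illuminant_spd("D65", grid),
                                cmfs = cie_cmfs(grid)) {
  abort_if(basis_dim < 1 || n < basis_dim, "need n >= basis_dim >= 1")
  mean_curve <- 0.45 + 0.06 * cos(2 * pi * (grid$wavelengths - 380) / 550)
  n_primary <- min(3L, basis_dim)
  P <- sapply(c(445, 555, 665)[seq_len(n_primary)], function(ctr)
    raised_cosine(grid, ctr, 150))
  n_black <- basis_dim - n_primary
  if (n_black > 0) {
    Gk <- sapply(seq_len(n_black), function(m)
      cos(2 * pi * (m + 1) * (grid$wavelengths - 380) / 400))
    Bk <- metameric_black(Gk, illuminant, cmfs)
    # renormalise each black component to unit peak so amplitudes are comparable
    Bk <- sweep(Bk, 2, apply(abs(Bk), 2, max), "/")
  }
  amp <- c(0.55, 0.45, 0.40)[seq_len(n_primary)]
  with_seed(seed, {
    U <- matrix(stats::runif(n * n_primary, -1, 1), nrow = n_primary) # primary coefs
    dev <- P %*% (amp * U)
    if (n_black > 0) {
      # degree-2 monomials of the primary coefficients (no constant)
      mono <- rbind(U, U^2)
      if (n_primary >= 2) mono <- rbind(mono, U[1, ] * U[2, ])
      if (n_primary >= 3) mono <- rbind(mono, U[1, ] * U[3, ], U[2, ] * U[3, ])
      Q <- matrix(stats::rnorm(n_black * nrow(mono), sd = 0.45),
                  nrow = n_black)
      dev <- dev + 0.35 * Bk %*% (Q %*% mono)
    }
    dev
  }) -> dev
  # scalar rescale of the deviation so all values sit inside [0.02, 0.95]
  lo <- 0.02; hi <- 0.95
  room_hi <- (hi - mean_curve); room_lo <- (mean_curve - lo)
  f <- 1
  pos <- dev > 0; neg <- dev < 0
  if (any(pos)) f <- min(f, min((room_hi / dev)[pos]))
  if (any(neg)) f <- min(f, min((-room_lo / dev)[neg]))
  R <- mean_curve + f * dev
  colnames(R) <- sprintf("patch%02d", seq_len(n))
  R
}

# --- forward camera model ---------------------------------------------------

#' Per-channel cubic sensor nonlinearity
#'
#' Specifies a camera's nonlinear response by the monotone cubic
#' `scene = a0 + a1 * reading + a3 * reading^3` (on the normalised XYZ/100
#' scale) that maps the camera's reported value back to the true scene
#' value. The simulator applies the inverse of this polynomial to produce
#' readings; the calibration stage is expected to recover the polynomial
#' itself, whose terms lie inside the default expansion span.
#'
#' @param a0,a1,a3 polynomial coefficients; `a1 > 0`, `a3 >= 0` so the
#'   response is strictly monotone.
#' @return a `cubic_distortion`.
#' @export
cubic_distortion <- function(a0 = 0, a1 = 0.92, a3 = 0.25) {
  abort_if(a1 <= 0 || a3 < 0, "need a1 > 0 and a3 >= 0 for monotonicity")
  structure(list(a0 = a0, a1 = a1, a3 = a3), class = "cubic_distortion")
}

# evaluate and invert the distortion (vectorised Newton; p' >= a1 > 0)
distortion_forward <- function(d, u) d$a0 + d$a1 * u + d$a3 * u^3
distortion_inverse <- function(d, y) {
  u <- (y - d$a0) / d$a1
  for (i in 1:60) {
    u <- u - (distortion_forward(d, u) - y) / (d$a1 + 3 * d$a3 * u^2)
  }
  u
}

#' Forward camera model for simulating calibration captures
#'
#' A parametric camera whose error sources mirror those the correction
#' stage is built to absorb: nonlinear response (`distortion`), dark
#' current (`offset`, in 1/255 "count" units), channel crosstalk and colour
#' shift (`crosstalk` matrix), and sensor noise (`noise_sd`, counts). The
#' default spectral sensitivities are the CIE 1931 colour matching
#' functions themselves, so the undistorted camera is exactly colorimetric
#' and the noiseless pipeline has an exact oracle.
#'
#' @param sensitivities `grid$n x 3` non-negative matrix of channel
#'   sensitivities; `NULL` means the CMFs.
#' @param gain per-channel gain; `"auto"` scales so a perfect reflector's
#'   ybar-channel reads 1 (i.e. readings are XYZ/100 for CMF sensitivities).
#' @param offset per-channel dark current in counts (1/255 units).
#' @param crosstalk 3 x 3 channel mixing matrix, applied after the
#'   nonlinearity.
#' @param noise_sd Gaussian sensor noise standard deviation in counts.
#' @param encode_gamma apply sRGB encoding to the output.
#' @param quantize round the output to 8-bit codes.
#' @param distortion a [cubic_distortion()] or `NULL` for a linear sensor.
#' @param seed integer seed driving the noise draw.
#' @return a `camera_model`.
#' @export
camera_model <- function(sensitivities = NULL, gain = "auto", offset = 0,
                         crosstalk = diag(3), noise_sd = 0,
                         encode_gamma = TRUE, quantize = TRUE,
                         distortion = NULL, seed = 1) {
  if (!is.null(sensitivities)) {
    sensitivities <- as.matrix(sensitivities)
    abort_if(ncol(sensitivities) != 3, "sensitivities must have 3 columns")
    abort_if(any(sensitivities < 0), "sensitivities must be non-negative")
  }
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(sensitivities = sensitivities, gain = gain,
                 offset = rep_len(offset, 3), crosstalk = crosstalk,
                 noise_sd = noise_sd, encode_gamma = isTRUE(encode_gamma),
                 quantize = isTRUE(quantize), distortion = distortion,
                 seed = seed),
            class = "camera_model")
}

#' @rdname camera_model
#' @details `ideal_srgb_camera()` is the configuration used throughout the
#'   validation suite: CMF sensitivities, colorimetric auto gain, and the
#'   XYZ-to-linear-sRGB matrix as crosstalk, so its quantized output is an
#'   ordinary 8-bit sRGB rendering of the scene.
#' @export
ideal_srgb_camera <- function(distortion = NULL, offset = 0, noise_sd = 0,
                              quantize = FALSE, seed = 1) {
  camera_model(sensitivities = NULL, gain = "auto", offset = offset,
               crosstalk = .xyz_to_srgb, noise_sd = noise_sd,
               encode_gamma = TRUE, quantize = quantize,
               distortion = distortion, seed = seed)
}

#' Simulate camera readings of reflectance spectra
#'
#' Computes, per channel, `gain * sum(S * R * c_i)` over the grid, applies
#' the sensor nonlinearity (if any), the crosstalk matrix, the dark-current
#' offset, seeded Gaussian noise, then optional sRGB encoding and 8-bit
#' quantization. Deterministic given the camera's seed.
#'
#' @param spectra `grid$n x N` matrix (or curves) of reflectances.
#' @param illuminant a power [spectral_curve()].
#' @param cam a [camera_model()].
#' @param cmfs colour matching functions (used for default sensitivities and
#'   auto gain).
#' @return 3 x N matrix of readings: 8-bit codes if `cam$quantize`, else
#'   unit-scale values; the `"encoding"` attribute records which. The
#'   `"n_clipped"` attribute counts values clipped into the encodable range.
#' @export
simulate_camera <- function(spectra, illuminant, cam = ideal_srgb_camera(),
                            cmfs = cie_cmfs(illuminant$grid)) {
  R <- spectra_matrix(spectra, illuminant$grid)
  sens <- if (is.null(cam$sensitivities)) {
    cbind(cmfs$xbar, cmfs$ybar, cmfs$zbar)
  } else cam$sensitivities
  abort_if(nrow(sens) != illuminant$grid$n,
           "sensitivities are on a different grid")
  gain <- if (identical(cam$gain, "auto")) {
    rep(1 / sum(illuminant$values * cmfs$ybar), 3)
  } else rep_len(cam$gain, 3)
  raw <- (gain * t(sens * illuminant$values)) %*% R # 3 x N
  if (!is.null(cam$distortion)) raw <- distortion_inverse(cam$distortion, raw)
  raw <- cam$crosstalk %*% raw
  raw <- raw + cam$offset / 255
  if (cam$noise_sd > 0) {
    raw <- raw + with_seed(cam$seed,
      matrix(stats::rnorm(length(raw), sd = cam$noise_sd / 255), nrow = 3))
  }
  n_clipped <- 0L
  if (cam$encode_gamma) {
    n_clipped <- sum(raw < 0 | raw > 1)
    raw <- encode_srgb(pmin(pmax(raw, 0), 1))
  }
  if (cam$quantize) {
    raw <- round(pmin(pmax(raw, 0), 1) * 255)
    attr(raw, "encoding") <- "8bit"
  } else {
    attr(raw, "encoding") <- "unit"
  }
  rownames(raw) <- c("R", "G", "B")
  attr(raw, "n_clipped") <- n_clipped
  raw
}

# --- vessel-bearing tissue phantom ------------------------------------------

#' Specification of a synthetic vascular tissue phantom
#'
#' A smooth mucosa-like background reflectance with sinusoidal vessel paths
#' whose spectra are the background attenuated by Gaussian absorption dips
#' at the configured band centres (defaults: the 415 nm and 540 nm
#' haemoglobin bands). A purely geometric/spectral test scaffold, not a
#' biophysical haemoglobin model.
#'
#' @param height,width phantom size in pixels (>= 8).
#' @param n_vessels number of vessel paths.
#' @param vessel_width vessel thickness in pixels.
#' @param tortuosity lateral sinusoidal amplitude of the paths, pixels.
#' @param depth absorption depth(s) in \[0, 1), recycled over bands.
#' @param band_centers absorber centres in nm.
#' @param band_sd Gaussian absorber widths (sd, nm), recycled.
#' @param seed integer seed (vessel placement).
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(height = 128, width = 128, n_vessels = 4,
                         vessel_width = 3, tortuosity = 6, depth = 0.5,
                         band_centers = c(415, 540), band_sd = 15,
                         seed = 1) {
  abort_if(height < 8 || width < 8, "phantom dimensions must be >= 8")
  abort_if(any(depth < 0) || any(depth >= 1), "depth must be in [0, 1)")
  structure(list(height = height, width = width, n_vessels = n_vessels,
                 vessel_width = vessel_width, tortuosity = tortuosity,
                 depth = rep_len(depth, length(band_centers)),
                 band_centers = band_centers,
                 band_sd = rep_len(band_sd, length(band_centers)),
                 seed = seed),
            class = "phantom_spec")
}

#' Build a ground-truth spectral phantom and its vessel mask
#'
#' Vessels run top to bottom as seeded sinusoidal paths of the configured
#' width, so the expected mask area fraction is approximately
#' `n_vessels * vessel_width / width` (minus overlap).
#'
#' @param spec a [phantom_spec()].
#' @param grid wavelength grid.
#' @return list with `cube` (a [spectral_cube()]), logical `mask`
#'   (TRUE = vessel), and the background/vessel spectra as
#'   [spectral_curve()]s.
#' @export
make_phantom <- function(spec = phantom_spec(), grid = default_grid()) {
  w <- grid$wavelengths
  background <- 0.18 + 0.42 / (1 + exp(-(w - 590) / 35))
  absorb <- rep(1, grid$n)
  for (b in seq_along(spec$band_centers)) {
    absorb <- absorb - spec$depth[b] *
      exp(-0.5 * ((w - spec$band_centers[b]) / spec$band_sd[b])^2)
  }
  vessel <- background * pmax(absorb, 0)
  mask <- matrix(FALSE, spec$height, spec$width)
  with_seed(spec$seed, {
    for (v in seq_len(spec$n_vessels)) {
      x0 <- stats::runif(1, 1 + spec$tortuosity,
                         spec$width - spec$tortuosity)
      phase <- stats::runif(1, 0, 2 * pi)
      period <- stats::runif(1, 0.8, 1.5) * spec$height
      for (row in seq_len(spec$height)) {
        xc <- x0 + spec$tortuosity * sin(2 * pi * row / period + phase)
        cols <- which(abs(seq_len(spec$width) - xc) <= spec$vessel_width / 2)
        mask[row, cols] <- TRUE
      }
    }
    mask
  }) -> mask
  vals <- array(rep(background, each = spec$height * spec$width),
                c(spec$height, spec$width, grid$n))
  idx <- which(mask)
  for (b in seq_len(grid$n)) {
    plane <- vals[, , b]
    plane[idx] <- vessel[b]
    vals[, , b] <- plane
  }
  list(cube = spectral_cube(vals, grid), mask = mask,
       background = spectral_curve(background, grid),
       vessel = spectral_curve(vessel, grid))
}

# --- synthetic calibration manifests ----------------------------------------

#' Write a complete synthetic calibration manifest
#'
#' Generates a synthetic patch set, captures it with the given camera, and
#' writes a directory consumable verbatim by the calibration entry points:
#' `manifest.csv` (patch id, camera R,G,B as 8-bit codes, relative path to
#' the patch's reflectance CSV), one spectrum CSV per patch, and
#' `illuminant.csv`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for patches and sensor noise.
#' @param n,basis_dim passed to [synth_patch_spectra()].
#' @param camera a [camera_model()]; its seed is replaced by `seed`.
#' @param illuminant a power [spectral_curve()].
#' @param grid wavelength grid.
#' @return the manifest path, invisibly.
#' @export
write_simulation <- function(dir, seed = 42, n = 24, basis_dim = 6,
                             camera = ideal_srgb_camera(
                               distortion = cubic_distortion(),
                               offset = 2, noise_sd = 0.5, quantize = TRUE,
                               seed = seed),
                             illuminant = illuminant_spd("D65", grid),
                             grid = default_grid()) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  camera$seed <- seed
  R <- synth_patch_spectra(n, basis_dim, seed, grid, illuminant)
  rgb <- simulate_camera(R, illuminant, camera)
  if (!identical(attr(rgb, "encoding"), "8bit")) {
    rgb <- round(pmin(pmax(rgb, 0), 1) * 255)
  }
  rel <- sprintf("spectra/patch%02d.csv", seq_len(n))
  for (i in seq_len(n)) {
    write_spectrum_csv(spectral_curve(R[, i], grid), file.path(dir, rel[i]))
  }
  write_spectrum_csv(illuminant, file.path(dir, "illuminant.csv"))
  manifest <- data.frame(patch_id = colnames(R),
                         R = rgb[1, ], G = rgb[2, ], B = rgb[3, ],
                         spectrum = rel)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration manifest into a measurement set
#'
#' @param path path to a `manifest.csv` written by [write_simulation()] (or
#'   hand-assembled in the same layout: columns `patch_id,R,G,B,spectrum`
#'   with 8-bit camera codes and per-patch spectrum CSVs; an
#'   `illuminant.csv` beside the manifest overrides the default D65).
#' @param grid wavelength grid.
#' @return a [patch_measurement_set()].
#' @export
read_calibration_manifest <- function(path, grid = default_grid()) {
  df <- utils::read.csv(path)
  abort_if(!all(c("patch_id", "R", "G", "B", "spectrum") %in% names(df)),
           sprintf("%s: expected columns patch_id,R,G,B,spectrum", path))
  base <- dirname(path)
  ill_path <- file.path(base, "illuminant.csv")
  illuminant <- if (file.exists(ill_path)) {
    read_spectrum_csv(ill_path, grid, "power")
  } else illuminant_spd("D65", grid)
  spectra <- sapply(df$spectrum, function(p)
    read_spectrum_csv(file.path(base, p), grid)$values)
  patch_measurement_set(t(as.matrix(df[, c("R", "G", "B")])), spectra,
                        illuminant, ids = df$patch_id, rgb_encoding = "8bit")
}
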