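# IEC 61966-2-1 sRGB (D65) linear-RGB -> XYZ matrix (XYZ on the 0-1 scale;
# the package API scales to the 0-100 luminance convention).
.srgb_to_xyz <- matrix(c(
  0.4124, 0.3576, 0.1805,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505), nrow = 3, byrow = TRUE)
.xyz_to_srgb <- solve(.srgb_to_xyz)

#' sRGB transfer function (decode / encode)
#'
#' `decode_srgb` applies the standard sRGB electro-optical transfer function
#' (linear segment below the 0.04045 threshold, power-2.4 segment above) to
#' map encoded channel values to linear light in \[0, 1\]. `encode_srgb` is
#' its inverse. The numeric form of the input is declared explicitly via
#' `encoding` and never guessed: `"unit"` for values already in \[0, 1\],
#' `"8bit"` for integer codes in \[0, 255\].
#'
#' @param x numeric vector/matrix/array of channel values.
#' @param encoding `"unit"` or `"8bit"`.
#' @return numeric object of the same shape; `decode_srgb` returns linear
#'   values in \[0, 1\], `encode_srgb` returns encoded values (unit scale, or
#'   integer codes for `"8bit"`).
#' @examples
#' decode_srgb(128, "8bit") # ~0.2158
#' encode_srgb(decode_srgb(0:255, "8bit"), "8bit") # identity round trip
#' @export
decode_srgb <- function(x, encoding = c("unit", "8bit")) {
  encoding <- match.arg(encoding)
  hi <- if (encoding == "8bit") 255 else 1
  bad <- which(!is.finite(x) | x < 0 | x > hi)
  abort_if(length(bad) > 0,
           sprintf("sRGB value out of [0, %g]: %s", hi,
                   paste(utils::head(x[bad], 3), collapse = ", ")),
           class = "savehsi_range_error")
  u <- x / hi
  out <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  attributes(out) <- attributes(x)
  out
}

#' @rdname decode_srgb
#' @export
encode_srgb <- function(x, encoding = c("unit", "8bit")) {
  encoding <- match.arg(encoding)
  bad <- which(!is.finite(x) | x < 0 | x > 1)
  abort_if(length(bad) > 0,
           sprintf("linear value out of [0, 1]: %s",
                   paste(utils::head(x[bad], 3), collapse = ", ")),
           class = "savehsi_range_error")
  out <- ifelse(x <= 0.04045 / 12.92, x * 12.92,
                1.055 * x^(1 / 2.4) - 0.055)
  attributes(out) <- attributes(x)
  if (encoding == "8bit") round(out * 255) else out
}

#' Linear RGB to CIE 1931 XYZ
#'
#' Applies the fixed sRGB (D65) conversion matrix and scales to the 0-100
#' luminance convention, under which the reference white has Y = 100.
#'
#' @param rgb length-3 vector or 3 x N matrix of linear channel values.
#' @return length-3 XYZ vector, or 3 x N matrix with rows X, Y, Z.
#' @export
linear_rgb_to_xyz <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, nrow = 3)
  abort_if(nrow(m) != 3, "expected 3 rows (R, G, B)")
  abort_if(!all(is.finite(m)), "non-finite RGB input")
  out <- 100 * (.srgb_to_xyz %*% m)
  rownames(out) <- c("X", "Y", "Z")
  if (is.matrix(rgb)) out else drop(out)
}

#' @rdname linear_rgb_to_xyz
#' @param xyz length-3 vector or 3 x N matrix on the 0-100 scale.
#' @export
xyz_to_linear_rgb <- function(xyz) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 3)
  abort_if(nrow(m) != 3, "expected 3 rows (X, Y, Z)")
  out <- .xyz_to_srgb %*% (m / 100)
  rownames(out) <- c("R", "G", "B")
  if (is.matrix(xyz)) out else drop(out)
}

#' Luminance normaliser k for an illuminant
#'
#' The scale factor that makes a perfect reflector's Y equal exactly 100
#' under the given illuminant: `k = 100 / sum(S * ybar)` (rectangle rule on
#' the 1 nm grid). It depends only on the illuminant and ȳ.
#'
#' @param illuminant a power [spectral_curve()].
#' @param cmfs a [cie_cmfs()] object on the same grid.
#' @return scalar k.
#' @export
luminance_ratio <- function(illuminant, cmfs = cie_cmfs(illuminant$grid)) {
  abort_if(!same_grid(illuminant$grid, cmfs$grid),
           "illuminant and colour matching functions are on different grids",
           class = "savehsi_grid_error")
  denom <- sum(illuminant$values * cmfs$ybar)
  abort_if(denom <= 0, "degenerate illuminant: sum(S * ybar) is not positive",
           class = "savehsi_illuminant_error")
  100 / denom
}

#' Integrate reflectance spectra to CIE 1931 XYZ
#'
#' Computes `X = k * sum(S * R * xbar)` (and likewise Y, Z) by the rectangle
#' rule at the grid step, with `k` from [luminance_ratio()] so a perfect
#' reflector has Y = 100. The integration is linear in the reflectance.
#'
#' @param reflectance a [spectral_curve()], a list of curves, or a
#'   `grid$n x N` matrix of column spectra.
#' @param illuminant a power [spectral_curve()].
#' @param cmfs a [cie_cmfs()] object; all inputs must share one grid.
#' @return length-3 XYZ vector for a single curve, else a 3 x N matrix.
#' @export
spectrum_to_xyz <- function(reflectance, illuminant,
                            cmfs = cie_cmfs(illuminant$grid)) {
  single <- inherits(reflectance, "spectral_curve")
  if (single) {
    abort_if(!same_grid(reflectance$grid, illuminant$grid),
             "reflectance and illuminant are on different grids",
             class = "savehsi_grid_error")
  }
  k <- luminance_ratio(illuminant, cmfs)
  R <- spectra_matrix(reflectance, illuminant$grid)
  W <- illuminant$values * cbind(cmfs$xbar, cmfs$ybar, cmfs$zbar) # grid$n x 3
  out <- k * t(W) %*% R
  rownames(out) <- c("X", "Y", "Z")
  if (single) drop(out) else out
}

#' XYZ to CIE Lab
#'
#' Standard CIE 1976 L*a*b* transform relative to a reference white with
#' Y = 100.
#'
#' @param xyz length-3 vector or 3 x N matrix (0-100 scale).
#' @param white length-3 reference-white XYZ with Y = 100 and all components
#'   positive.
#' @return length-3 Lab vector or 3 x N matrix with rows L, a, b.
#' @export
xyz_to_lab <- function(xyz, white = linear_rgb_to_xyz(c(1, 1, 1))) {
  abort_if(any(!is.finite(white)) || any(white <= 0),
           "reference white must be positive in all components")
  abort_if(abs(white[2] - 100) > 1e-6, "reference white must have Y = 100")
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 3)
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(m[1, ] / white[1]); fy <- f(m[2, ] / white[2]); fz <- f(m[3, ] / white[3])
  out <- rbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.matrix(xyz)) out else drop(out)
}

#' Colour difference between Lab coordinates
#'
#' `method = "cie2000"` (default) is the CIEDE2000 revision, the current
#' perceptual standard; `"cie76"` is the plain Euclidean distance in Lab.
#' Both are symmetric and non-negative; the Euclidean form is zero iff the
#' inputs are identical.
#'
#' @param lab1,lab2 length-3 Lab vectors or 3 x N matrices.
#' @param method `"cie2000"` or `"cie76"`.
#' @return non-negative colour difference(s).
#' @export
delta_e <- function(lab1, lab2, method = c("cie2000", "cie76")) {
  method <- match.arg(method)
  a <- if (is.matrix(lab1)) lab1 else matrix(lab1, nrow = 3)
  b <- if (is.matrix(lab2)) lab2 else matrix(lab2, nrow = 3)
  abort_if(ncol(a) != ncol(b), "lab1 and lab2 differ in length")
  out <- if (method == "cie76") {
    sqrt(colSums((a - b)^2))
  } else {
    delta_e2000(a, b)
  }
  if (is.matrix(lab1)) out else drop(out)
}

# CIEDE2000 (Sharma, Wu & Dalal 2005 formulation), vectorised over columns.
delta_e2000 <- function(a, b) {
  L1 <- a[1, ]; a1 <- a[2, ]; b1 <- a[3, ]
  L2 <- b[1, ]; a2 <- b[2, ]; b2 <- b[3, ]
  Cbar <- (sqrt(a1^2 + b1^2) + sqrt(a2^2 + b2^2)) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  ap1 <- (1 + G) * a1; ap2 <- (1 + G) * a2
  Cp1 <- sqrt(ap1^2 + b1^2); Cp2 <- sqrt(ap2^2 + b2^2)
  hp1 <- ifelse(Cp1 == 0, 0, atan2(b1, ap1) %% (2 * pi)) * 180 / pi
  hp2 <- ifelse(Cp2 == 0, 0, atan2(b2, ap2) %% (2 * pi)) * 180 / pi
  dL <- L2 - L1
  dC <- Cp2 - Cp1
  dh <- hp2 - hp1
  dh <- ifelse(Cp1 * Cp2 == 0, 0,
        ifelse(dh > 180, dh - 360, ifelse(dh < -180, dh + 360, dh)))
  dH <- 2 * sqrt(Cp1 * Cp2) * sin(dh * pi / 360)
  Lbp <- (L1 + L2) / 2
  Cbp <- (Cp1 + Cp2) / 2
  hsum <- hp1 + hp2
  hbp <- ifelse(Cp1 * Cp2 == 0, hsum,
         ifelse(abs(hp1 - hp2) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))
  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  Rc <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  Sl <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  Sc <- 1 + 0.045 * Cbp
  Sh <- 1 + 0.015 * Cbp * Tt
  Rt <- -sin(2 * dtheta * pi / 180) * Rc
  sqrt((dL / Sl)^2 + (dC / Sc)^2 + (dH / Sh)^2 + Rt * (dC / Sc) * (dH / Sh))
}
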