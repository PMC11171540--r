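# CIE 1931 2-degree standard observer colour matching functions, 380-780 nm
# at 10 nm, from the standard published tables; finer grids are obtained by
# linear interpolation. Columns: wavelength, xbar, ybar, zbar.
.cie1931_10nm <- matrix(c(
  380, 0.0014, 0.0000, 0.0065,
  390, 0.0042, 0.0001, 0.0201,
  400, 0.0143, 0.0004, 0.0679,
  410, 0.0435, 0.0012, 0.2074,
  420, 0.1344, 0.0040, 0.6456,
  430, 0.2839, 0.0116, 1.3856,
  440, 0.3483, 0.0230, 1.7471,
  450, 0.3362, 0.0380, 1.7721,
  460, 0.2908, 0.0600, 1.6692,
  470, 0.1954, 0.0910, 1.2876,
  480, 0.0956, 0.1390, 0.8130,
  490, 0.0320, 0.2080, 0.4652,
  500, 0.0049, 0.3230, 0.2720,
  510, 0.0093, 0.5030, 0.1582,
  520, 0.0633, 0.7100, 0.0782,
  530, 0.1655, 0.8620, 0.0422,
  540, 0.2904, 0.9540, 0.0203,
  550, 0.4334, 0.9950, 0.0087,
  560, 0.5945, 0.9950, 0.0039,
  570, 0.7621, 0.9520, 0.0021,
  580, 0.9163, 0.8700, 0.0017,
  590, 1.0263, 0.7570, 0.0011,
  600, 1.0622, 0.6310, 0.0008,
  610, 1.0026, 0.5030, 0.0003,
  620, 0.8544, 0.3810, 0.0002,
  630, 0.6424, 0.2650, 0.0000,
  640, 0.4479, 0.1750, 0.0000,
  650, 0.2835, 0.1070, 0.0000,
  660, 0.1649, 0.0610, 0.0000,
  670, 0.0874, 0.0320, 0.0000,
  680, 0.0468, 0.0170, 0.0000,
  690, 0.0227, 0.0082, 0.0000,
  700, 0.0114, 0.0041, 0.0000,
  710, 0.0058, 0.0021, 0.0000,
  720, 0.0029, 0.0010, 0.0000,
  730, 0.0014, 0.0005, 0.0000,
  740, 0.0007, 0.0002, 0.0000,
  750, 0.0003, 0.0001, 0.0000,
  760, 0.0002, 0.0001, 0.0000,
  770, 0.0001, 0.0000, 0.0000,
  780, 0.0000, 0.0000, 0.0000), ncol = 4, byrow = TRUE)

# CIE standard illuminant D65 relative spectral power distribution,
# 380-780 nm at 10 nm, normalised to 100 at 560 nm (standard published table).
.d65_10nm <- matrix(c(
  380,  49.98,  390,  54.65,  400,  82.75,  410,  91.49,  420,  93.43,
  430,  86.68,  440, 104.86,  450, 117.01,  460, 117.81,  470, 114.86,
  480, 115.92,  490, 108.81,  500, 109.35,  510, 107.80,  520, 104.79,
  530, 107.69,  540, 104.41,  550, 104.05,  560, 100.00,  570,  96.33,
  580,  95.79,  590,  88.69,  600,  90.01,  610,  89.60,  620,  87.70,
  630,  83.29,  640,  83.70,  650,  80.03,  660,  80.21,  670,  82.28,
  680,  78.28,  690,  69.72,  700,  71.61,  710,  74.35,  720,  61.60,
  730,  69.89,  740,  75.09,  750,  63.59,  760,  46.42,  770,  66.81,
  780,  63.38), ncol = 2, byrow = TRUE)

#' CIE 1931 2-degree colour matching functions on a grid
#'
#' Returns the standard-observer functions x̄, ȳ, z̄ resampled onto the
#' requested grid. The embedded reference table is the published 10 nm CIE
#' 1931 table; intermediate wavelengths are linearly interpolated.
#'
#' @param grid a [wavelength_grid()].
#' @return an object of class `cmfs` with fields `grid`, `xbar`, `ybar`,
#'   `zbar` (all non-negative, `ybar` peaking near 555 nm).
#' @export
cie_cmfs <- function(grid = default_grid()) {
  key <- sprintf("cmfs_%g_%g_%g", grid$start, grid$stop, grid$step)
  if (!is.null(.grid_env[[key]])) return(.grid_env[[key]])
  w <- .cie1931_10nm[, 1]
  out <- structure(list(
    grid = grid,
    xbar = resample_to_grid(w, .cie1931_10nm[, 2], grid, "power")$values,
    ybar = resample_to_grid(w, .cie1931_10nm[, 3], grid, "power")$values,
    zbar = resample_to_grid(w, .cie1931_10nm[, 4], grid, "power")$values),
    class = "cmfs")
  .grid_env[[key]] <- out
  out
}

#' Built-in illuminant spectral power distributions
#'
#' `"D65"` is the CIE daylight illuminant (embedded 10 nm table, linearly
#' interpolated); `"E"` is the equal-energy illuminant. User illuminants can
#' be loaded from CSV with [read_spectrum_csv()] or built with
#' [resample_to_grid()].
#'
#' @param name `"D65"` or `"E"`.
#' @param grid a [wavelength_grid()].
#' @return a [spectral_curve()] of kind `"power"`.
#' @export
illuminant_spd <- function(name = c("D65", "E"), grid = default_grid()) {
  name <- match.arg(toupper(name), c("D65", "E"))
  if (name == "E") {
    return(spectral_curve(rep(100, grid$n), grid, "power"))
  }
  resample_to_grid(.d65_10nm[, 1], .d65_10nm[, 2], grid, "power")
}
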