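#' Wavelength grid for visible-range spectra
#'
#' All spectra handled by the package live on a fixed, uniform wavelength
#' grid. The default grid spans the visible range 380-780 nm at a 1 nm step
#' (401 samples), the resolution at which reflectance spectra of the
#' calibration target are measured and at which analog spectra are
#' reconstructed.
#'
#' @param start,stop grid endpoints in nm.
#' @param step grid step in nm; must divide `stop - start` exactly.
#' @return an object of class `wavelength_grid` with fields `start`, `stop`,
#'   `step`, `n` and the `wavelengths` vector.
#' @examples
#' g <- wavelength_grid()
#' g$n # 401
#' @export
wavelength_grid <- function(start = 380, stop = 780, step = 1) {
  abort_if(!is.numeric(start) || !is.numeric(stop) || !is.numeric(step) ||
             step <= 0 || stop <= start,
           "invalid grid: need stop > start and step > 0")
  n <- (stop - start) / step + 1
  abort_if(abs(n - round(n)) > 1e-9, "`step` must divide the grid span exactly")
  n <- as.integer(round(n))
  structure(
    list(start = start, stop = stop, step = step, n = n,
         wavelengths = seq(start, stop, by = step)),
    class = "wavelength_grid")
}

# package-wide default 380-780 nm / 1 nm grid (built once at load)
.grid_env <- new.env(parent = emptyenv())

#' @rdname wavelength_grid
#' @export
default_grid <- function() {
  if (is.null(.grid_env$default)) .grid_env$default <- wavelength_grid()
  .grid_env$default
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$start, x$stop, x$step, x$n))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$start, b$start)) && isTRUE(all.equal(a$stop, b$stop)) &&
    isTRUE(all.equal(a$step, b$step))
}

#' Spectral curve on a wavelength grid
#'
#' A `spectral_curve` holds one sampled function of wavelength: either a
#' unitless reflectance (declared range \[0, 1.2\]; regression overshoot above
#' 1 is permitted but bounded) or a spectral power distribution in arbitrary
#' units. Reflectance curves are clipped to the declared range on
#' construction; the number of clipped samples is recorded in the
#' `"n_clipped"` attribute rather than silently discarded.
#'
#' @param values numeric vector, one sample per grid wavelength.
#' @param grid a [wavelength_grid()]; defaults to the package grid.
#' @param kind `"reflectance"` or `"power"`.
#' @return a `spectral_curve` object.
#' @export
spectral_curve <- function(values, grid = default_grid(),
                           kind = c("reflectance", "power")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  abort_if(length(values) != grid$n,
           sprintf("curve has %d samples but grid expects %d",
                   length(values), grid$n))
  abort_if(!all(is.finite(values)), "spectral values must all be finite")
  n_clipped <- 0L
  if (kind == "reflectance") {
    lo <- 0; hi <- reflectance_ceiling()
    n_clipped <- sum(values < lo | values > hi)
    values <- pmin(pmax(values, lo), hi)
  }
  structure(list(grid = grid, values = values, kind = kind),
            n_clipped = n_clipped, class = "spectral_curve")
}

# overshoot ceiling for reconstructed reflectance; above 1 is tolerated so
# that regression overshoot remains visible instead of being flattened at 1
reflectance_ceiling <- function() 1.2

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %s, %d samples on %g-%g nm, range [%.4g, %.4g]\n",
              x$kind, x$grid$n, x$grid$start, x$grid$stop,
              min(x$values), max(x$values)))
  invisible(x)
}

# coerce a curve / vector / 401xN matrix to a plain matrix of column spectra
spectra_matrix <- function(x, grid = default_grid()) {
  if (inherits(x, "spectral_curve")) {
    abort_if(!same_grid(x$grid, grid), "curve is on a different grid")
    return(matrix(x$values, ncol = 1))
  }
  if (is.list(x)) {
    return(do.call(cbind, lapply(x, spectra_matrix, grid = grid)))
  }
  m <- as.matrix(x)
  abort_if(nrow(m) != grid$n,
           sprintf("expected %d rows (one per wavelength), got %d",
                   grid$n, nrow(m)))
  m
}

#' Resample measured spectral data onto a wavelength grid
#'
#' Spectrometer exports rarely match the package's 1 nm grid; this linearly
#' interpolates measured samples onto a target grid. Outside the measured
#' range the endpoint values are held constant (no extrapolation).
#'
#' @param wavelengths strictly increasing nm vector (at least 2 samples).
#' @param values numeric vector, same length as `wavelengths`.
#' @param grid target [wavelength_grid()].
#' @param kind passed to [spectral_curve()].
#' @return a [spectral_curve()] on `grid`.
#' @export
resample_to_grid <- function(wavelengths, values, grid = default_grid(),
                             kind = c("reflectance", "power")) {
  abort_if(length(wavelengths) < 2L, "need at least 2 measured samples")
  abort_if(length(wavelengths) != length(values),
           "wavelengths and values differ in length")
  abort_if(any(diff(wavelengths) <= 0),
           "wavelengths must be strictly increasing (no duplicates)")
  out <- stats::approx(wavelengths, values, xout = grid$wavelengths,
                       method = "linear", rule = 2)$y
  spectral_curve(out, grid, kind = match.arg(kind))
}

#' Read / write a spectrum CSV
#'
#' The interchange format is a two-column UTF-8 CSV with header
#' `wavelength_nm,value`. On read, samples are resampled onto `grid` via
#' [resample_to_grid()].
#'
#' @param path file path.
#' @param grid target grid.
#' @param kind curve kind, see [spectral_curve()].
#' @return `read_spectrum_csv` returns a [spectral_curve()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, grid = default_grid(),
                              kind = c("reflectance", "power")) {
  df <- utils::read.csv(path, header = TRUE)
  abort_if(!all(c("wavelength_nm", "value") %in% names(df)),
           sprintf("%s: expected columns 'wavelength_nm,value'", path))
  resample_to_grid(df$wavelength_nm, df$value, grid, kind = match.arg(kind))
}

#' @rdname read_spectrum_csv
#' @param curve a [spectral_curve()] to write.
#' @export
write_spectrum_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(wavelength_nm = curve$grid$wavelengths, value = curve$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
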