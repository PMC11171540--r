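#' Spectral cube: a per-pixel reflectance image
#'
#' An H x W x bands array of reconstructed reflectance values on a
#' wavelength grid, clipped to the declared reflectance range \[0, 1.2\].
#'
#' @param values numeric H x W x `grid$n` array.
#' @param grid a [wavelength_grid()].
#' @return a `spectral_cube` with `values`, `grid`, `height`, `width`.
#' @export
spectral_cube <- function(values, grid = default_grid()) {
  abort_if(length(dim(values)) != 3 || dim(values)[3] != grid$n,
           sprintf("values must be H x W x %d", grid$n))
  abort_if(!all(is.finite(values)), "cube values must be finite")
  structure(list(values = values, grid = grid,
                 height = dim(values)[1], width = dim(values)[2]),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("<spectral_cube> %d x %d pixels x %d bands (%g-%g nm)\n",
              x$height, x$width, x$grid$n, x$grid$start, x$grid$stop))
  invisible(x)
}

# read an RGB image file into an H x W x 3 array of unit-scale sRGB values
read_rgb_image <- function(path) {
  abort_if(!file.exists(path), sprintf("image file not found: %s", path))
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    # JPEG/TIFF etc. via EBImage; transpose from x,y to row,col order
    e <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(e)) == 3) aperm(e, c(2, 1, 3)) else t(e)
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3] # drop alpha
  abort_if(length(dim(img)) != 3 || dim(img)[3] != 3,
           sprintf("not an RGB image: %s", path),
           class = "savehsi_format_error")
  img
}

#' Convert an sRGB image into a spectral cube
#'
#' Runs the full per-pixel pipeline: sRGB decode, linear-RGB to XYZ,
#' polynomial camera-error correction, and PCA-basis analog-spectrum
#' synthesis. Rows are processed in chunks so working memory stays bounded
#' by `chunk_rows * width` pixels; the result is identical whatever
#' `chunk_rows` is.
#'
#' @param calib a [calibrate()] (or [load_calibration()]) model.
#' @param image an H x W x 3 array of sRGB values in \[0, 1\] or \[0, 255\]
#'   (declared by `encoding`), or a path to a PNG/JPEG file.
#' @param chunk_rows rows per processing chunk (>= 1).
#' @param encoding sRGB scale of an array input; files are always unit scale.
#' @return a [spectral_cube()].
#' @export
convert_image <- function(calib, image, chunk_rows = 64,
                          encoding = c("unit", "8bit")) {
  encoding <- match.arg(encoding)
  abort_if(!is.numeric(chunk_rows) || chunk_rows < 1, "chunk_rows must be >= 1")
  if (is.character(image)) {
    image <- read_rgb_image(image)
    encoding <- "unit"
  }
  abort_if(length(dim(image)) != 3 || dim(image)[3] != 3,
           "image must be an H x W x 3 RGB array",
           class = "savehsi_format_error")
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- array(NA_real_, c(h, w, calib$grid$n))
  for (r0 in seq(1, h, by = chunk_rows)) {
    r1 <- min(r0 + chunk_rows - 1, h)
    nr <- r1 - r0 + 1
    # pixels of the chunk as a 3 x (nr*w) matrix, row-major within the chunk
    chunk <- image[r0:r1, , , drop = FALSE]
    rgb <- t(matrix(chunk, nrow = nr * w, ncol = 3))
    spec <- pixel_spectra(calib, rgb, encoding) # n_bands x (nr*w)
    # fill band by band to avoid a second cube-sized temporary
    for (b in seq_len(calib$grid$n)) {
      out[r0:r1, , b] <- matrix(spec[b, ], nr, w)
    }
  }
  spectral_cube(out, calib$grid)
}

# core per-pixel conversion on a 3 x P sRGB matrix -> n_bands x P
# reflectance; processed in fixed-size pixel blocks so transient
# allocations stay bounded independently of the caller's chunking
pixel_spectra <- function(calib, rgb, encoding, block = 65536L) {
  P <- ncol(rgb)
  out <- matrix(NA_real_, calib$grid$n, P)
  for (i0 in seq(1, P, by = block)) {
    i1 <- min(i0 + block - 1L, P)
    xyz <- linear_rgb_to_xyz(decode_srgb(rgb[, i0:i1, drop = FALSE],
                                         encoding))
    corrected <- apply_correction(calib$correction, xyz)
    S <- reconstruct_spectrum(calib$reconstruction, corrected)
    out[, i0:i1] <- S
  }
  out
}

# --- ENVI-style cube I/O ---------------------------------------------------

#' Write / read a spectral cube in ENVI-style format
#'
#' Writes a plain-text ENVI header (`<path>.hdr`) plus a band-sequential
#' (BSQ) little-endian binary payload at `path`. `dtype = "float64"` is
#' lossless (byte-exact round trip); `dtype = "uint16"` is a lossy option
#' scaling the reflectance range \[0, 1.2\] onto 0-65535.
#'
#' @param cube a [spectral_cube()].
#' @param path payload file path (header written alongside as `path.hdr`).
#' @param dtype `"float64"` or `"uint16"`.
#' @return `write_envi` returns `path` invisibly; `read_envi` returns a
#'   [spectral_cube()].
#' @export
write_envi <- function(cube, path, dtype = c("float64", "uint16")) {
  dtype <- match.arg(dtype)
  hdr <- c(
    "ENVI",
    "description = {savehsi reflectance cube}",
    sprintf("samples = %d", cube$width),
    sprintf("lines = %d", cube$height),
    sprintf("bands = %d", cube$grid$n),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", if (dtype == "float64") 5L else 12L),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = nm",
    sprintf("wavelength = {%s}",
            paste(format(cube$grid$wavelengths, trim = TRUE),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-major, pixels row-major (sample-fastest) within a band;
  # streamed one band at a time so memory stays bounded for large cubes
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(cube$grid$n)) {
    plane <- as.vector(t(cube$values[, , b]))
    if (dtype == "float64") {
      writeBin(plane, con, size = 8, endian = "little")
    } else {
      writeBin(as.integer(round(pmin(pmax(
        plane / reflectance_ceiling(), 0), 1) * 65535)),
        con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  abort_if(!file.exists(hdr_path), sprintf("missing ENVI header: %s", hdr_path))
  lines <- readLines(hdr_path, warn = FALSE)
  getval <- function(key) {
    ln <- grep(sprintf("^%s\\s*=", key), lines, value = TRUE)
    abort_if(length(ln) == 0, sprintf("header lacks '%s'", key))
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  w <- as.integer(getval("samples")); h <- as.integer(getval("lines"))
  b <- as.integer(getval("bands")); dt <- as.integer(getval("data type"))
  abort_if(tolower(getval("interleave")) != "bsq",
           "only BSQ interleave is supported")
  wl_txt <- sub(".*\\{", "", sub("\\}.*", "", paste(
    lines[seq(grep("^wavelength\\s*=", lines)[1], length(lines))],
    collapse = " ")))
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  abort_if(length(wl) != b, "wavelength list length does not match bands")
  grid <- wavelength_grid(wl[1], wl[b], wl[2] - wl[1])
  abort_if(!dt %in% c(5L, 12L), sprintf("unsupported ENVI data type %d", dt))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- array(NA_real_, c(h, w, b))
  for (band in seq_len(b)) {
    plane <- if (dt == 5L) {
      readBin(con, "double", n = w * h, size = 8, endian = "little")
    } else {
      readBin(con, "integer", n = w * h, size = 2, signed = FALSE,
              endian = "little") / 65535 * reflectance_ceiling()
    }
    vals[, , band] <- matrix(plane, h, w, byrow = TRUE)
  }
  spectral_cube(vals, grid)
}
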