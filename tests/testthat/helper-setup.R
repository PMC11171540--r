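# shared fixture: synthetic 24-patch target captured by the ideal sRGB
# camera, with configurable distortion/noise, ready for calibration
synth_setup <- function(seed = 42, n = 24, basis_dim = 6,
                        distortion = cubic_distortion(), offset = 0,
                        noise_sd = 0, quantize = FALSE) {
  g <- default_grid()
  d65 <- illuminant_spd("D65", g)
  R <- synth_patch_spectra(n, basis_dim, seed, g, d65)
  cam <- ideal_srgb_camera(distortion = distortion, offset = offset,
                           noise_sd = noise_sd, quantize = quantize,
                           seed = seed)
  rgb <- simulate_camera(R, d65, cam)
  list(grid = g, illuminant = d65, R = R, rgb = rgb,
       meas = patch_measurement_set(rgb, R, d65,
                                    rgb_encoding = attr(rgb, "encoding")))
}

# camera-derived XYZ from a measurement set, via the public pipeline
meas_camera_xyz <- function(meas) {
  linear_rgb_to_xyz(decode_srgb(meas$camera_rgb, meas$rgb_encoding))
}

# nested expansion family of increasing size (all contain the linear terms)
nested_specs <- function() {
  lin <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sq <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  cross <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  cubes <- rbind(c(1, 1, 1), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  list(expansion_spec(lin),
       expansion_spec(rbind(lin, sq)),
       expansion_spec(rbind(lin, sq, cross)),
       expansion_spec(rbind(lin, sq, cross, cubes)))
}
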