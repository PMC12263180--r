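# Small, fast parameter sets used across the suite. Noise and blur are off
# unless a test is about them.

tiny_params <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(
      spheroid_diameter = 60, field_size = 128, pixel_size = 0.5,
      cell_min_spacing = 8, nucleus_radius = 3,
      staining_time = 30, front_velocity = 1, front_width = 0,
      psf_sigma = 0, poisson_scale = 0, read_noise_sd = 0,
      matrix_background_fraction = 0.1, seed = 42
    ),
    list(...)
  ))
}

# a synthetic disk image (uniform intensity inside a circle), no generator
disk_image <- function(radius_um, field_px = 256, pixel_size = 0.5,
                       value = 12000, outside = 0, channel = "dapi",
                       center_um = NULL) {
  g <- spherostain:::coord_grids(field_px, field_px, pixel_size)
  center_um <- center_um %||% rep(field_px * pixel_size / 2, 2)
  inside <- sqrt((g$x - center_um[1])^2 + (g$y - center_um[2])^2) <= radius_um
  m <- matrix(outside, field_px, field_px)
  m[inside] <- value
  spheroid_image(stats::setNames(list(m), channel), pixel_size = pixel_size,
                 id = "disk")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# hand-built radial_profiles object for unit tests of the profile statistics
make_profiles <- function(depths, intensity_per_line, step, radius) {
  rows <- purrr::map_dfr(seq_along(intensity_per_line), function(k) {
    tibble::tibble(line = k, angle_rad = 2 * pi * (k - 1) / length(intensity_per_line),
                   depth_um = depths, intensity = intensity_per_line[[k]])
  })
  structure(rows, class = c("radial_profiles", class(rows)),
            n_lines = length(intensity_per_line), step_um = step,
            radius_um = radius, transverse_width_um = 0)
}
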