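#' Place cells inside a spheroid by blue-noise sampling
#'
#' Draws candidate points uniformly in the spheroid disk and keeps each one
#' only if it lies at least `cell_min_spacing` from every already-accepted
#' cell center (seeded dart throwing). The spheroid is centered in the field.
#' Sampling stops after `max_attempts` consecutive rejections, giving a
#' near-maximal packing whose density is controlled by the spacing alone.
#'
#' Each cell also receives a fixed Golgi offset direction and nucleus jitter,
#' drawn here so the downstream rendering is a pure function of the geometry.
#'
#' @param params A [sim_params()] object.
#' @param max_attempts Consecutive rejected darts before stopping.
#' @return An object of class `spheroid_geometry`: a list with `center`
#'   (x, y in um), `radius` (um), `cell_centers` (matrix, um), `golgi_angle`
#'   (radians per cell), and the generating `params`.
#' @examples
#' g <- simulate_geometry(sim_params(spheroid_diameter = 60, field_size = 96,
#'                                   pixel_size = 1, seed = 7))
#' nrow(g$cell_centers)
#' @export
simulate_geometry <- function(params, max_attempts = 2000L) {
  validate_sim_params(params)
  radius <- params$spheroid_diameter / 2
  if (params$cell_min_spacing > 2 * radius) {
    abort("cell_min_spacing exceeds the spheroid diameter: no cell can be placed")
  }
  field_um <- params$field_size * params$pixel_size
  center <- c(x = field_um / 2, y = field_um / 2)
  # cells pack all the way to the spheroid surface (surface-cell nuclei are
  # clipped at the boundary when rendered)
  r_max <- radius - 1

  withr::local_seed(params$seed)
  pts <- matrix(numeric(0), ncol = 2)
  misses <- 0L
  spacing2 <- params$cell_min_spacing^2
  while (misses < max_attempts) {
    r <- r_max * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    cand <- c(center[1] + r * cos(th), center[2] + r * sin(th))
    if (nrow(pts) > 0) {
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2
      if (min(d2) < spacing2) {
        misses <- misses + 1L
        next
      }
    }
    pts <- rbind(pts, cand)
    misses <- 0L
  }
  if (nrow(pts) == 0) abort("no cells placed: cell_min_spacing too large")
  golgi_angle <- runif(nrow(pts), 0, 2 * pi)

  structure(
    list(
      center = center,
      radius = radius,
      cell_centers = unname(pts),
      golgi_angle = golgi_angle,
      params = params
    ),
    class = "spheroid_geometry"
  )
}

#' @export
print.spheroid_geometry <- function(x, ...) {
  cat(sprintf("<spheroid_geometry> %d cells, radius %g um, center (%g, %g) um\n",
              nrow(x$cell_centers), x$radius, x$center[1], x$center[2]))
  invisible(x)
}

#' True staining front depth for a parameter set
#'
#' The front advances at `front_velocity` um/min for `staining_time` minutes,
#' and cannot exceed the spheroid radius (complete penetration).
#'
#' @param params A [sim_params()] object.
#' @return Depth in um from the spheroid perimeter.
#' @export
true_front_depth <- function(params) {
  min(params$front_velocity * params$staining_time, params$spheroid_diameter / 2)
}

#' Staining-front attenuation profile
#'
#' Fraction of full stain intensity at a given radial depth from the spheroid
#' perimeter. With `front_width = 0` this is a step: 1 up to the front depth
#' `front_velocity * staining_time`, 0 beyond. With a positive width the step
#' is replaced by a complementary-error-function shoulder centered on the
#' front (value 0.5 exactly at the front), of length scale `front_width`.
#' The profile is monotonically non-increasing in depth.
#'
#' @param depth_from_surface Radial depth(s) in um, measured inward from the
#'   spheroid perimeter. Must be non-negative.
#' @param params A [sim_params()] object.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' p <- sim_params(front_velocity = 1, staining_time = 40)
#' penetration_profile(c(0, 39, 41), p)
#' @export
penetration_profile <- function(depth_from_surface, params) {
  validate_sim_params(params)
  if (any(!is.finite(depth_from_surface)) || any(depth_from_surface < 0)) {
    abort("depth_from_surface must be non-negative and finite")
  }
  front <- params$front_velocity * params$staining_time
  if (params$front_width <= 0) {
    as.numeric(depth_from_surface <= front)
  } else {
    # erfc step: 1 deep inside the stained zone, 0.5 at the front, -> 0 beyond
    z <- (depth_from_surface - front) / (sqrt(2) * params$front_width)
    stats::pnorm(z, lower.tail = FALSE)
  }
}
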