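# Estimator scale constants (um). Stain structures are sparse, so the
# profile estimator averages transversally over ~one cell diameter and
# requires a half-max crossing to persist for longer than a typical
# structure-free gap along a ray (about one cell diameter).
PROFILE_TRANSVERSE_WIDTH <- 10
CROSSING_PERSISTENCE <- 12

# Bilinear interpolation of a matrix at physical coordinates (um).
# Pixel centers sit at ((i - 0.5) * px, (j - 0.5) * px); coordinates are
# clamped to the pixel-center hull so edge samples are well defined.
bilinear_sample <- function(m, x_um, y_um, pixel_size) {
  nr <- nrow(m)
  nc <- ncol(m)
  cx <- pmin(pmax(x_um / pixel_size + 0.5, 1), nc)
  cy <- pmin(pmax(y_um / pixel_size + 0.5, 1), nr)
  c0 <- pmin(floor(cx), nc - 1)
  r0 <- pmin(floor(cy), nr - 1)
  fx <- cx - c0
  fy <- cy - r0
  i00 <- m[cbind(r0, c0)]
  i01 <- m[cbind(r0, c0 + 1)]
  i10 <- m[cbind(r0 + 1, c0)]
  i11 <- m[cbind(r0 + 1, c0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Cast radial line profiles across a spheroid
#'
#' Casts `n_lines` evenly angled rays from the spheroid perimeter toward the
#' center and records intensity as a function of depth (um inward from the
#' perimeter, 0 at the perimeter, `radius` at the center), sampled every
#' `step` um by bilinear interpolation.
#'
#' Each ray is sampled as a thick line: at every depth the reported
#' intensity is the mean of bilinear samples spread along a circular arc of
#' length `transverse_width` centered on the ray, at constant distance from
#' the spheroid center (an annular-sector average, so every sample sits at
#' exactly the nominal depth). Cellular stains are spatially sparse
#' (boundary ridges, rings, puncta), so a one-pixel profile collapses to
#' zero between structures; the transverse average measures the local
#' azimuthal-mean intensity envelope that the half-maximum rule operates
#' on. Set `transverse_width = 0` for classic one-pixel profiles.
#'
#' @param image A [spheroid_image()] or a plain intensity matrix.
#' @param channel Channel name (ignored for plain matrices).
#' @param center Spheroid center, c(x, y) in um.
#' @param radius Spheroid radius in um (> 0).
#' @param n_lines Number of rays (>= 4), default 36.
#' @param step Radial sampling step in um; defaults to the pixel size.
#' @param transverse_width Thick-line width in um, default 10.
#' @param pixel_size Pixel size for plain-matrix input.
#' @return A `radial_profiles` tibble: line, angle_rad, depth_um, intensity;
#'   attributes n_lines, step_um, radius_um, transverse_width_um.
#' @export
extract_profiles <- function(image, channel = NULL, center, radius,
                             n_lines = 36, step = NULL,
                             transverse_width = PROFILE_TRANSVERSE_WIDTH,
                             pixel_size = NULL) {
  if (inherits(image, "spheroid_image")) {
    m <- get_channel(image, channel %||% channel_names(image)[1])
    px <- image$pixel_size
  } else {
    m <- image
    px <- pixel_size %||% abort("pixel_size required for plain-matrix input")
  }
  if (radius <= 0) abort("radius must be positive")
  if (n_lines < 4) abort("need at least 4 line profiles")
  step <- step %||% px

  field_x <- ncol(m) * px
  field_y <- nrow(m) * px
  if (center[1] < 0 || center[1] > field_x || center[2] < 0 || center[2] > field_y) {
    abort("spheroid center lies outside the image")
  }
  # arc samples stay at radial distance <= radius from the center
  half_w <- transverse_width / 2
  if (center[1] - radius < -px || center[1] + radius > field_x + px ||
      center[2] - radius < -px || center[2] + radius > field_y + px) {
    abort("rays leave the image field; spheroid too close to the border")
  }

  depths <- seq(0, radius, by = step)
  angles <- 2 * pi * (seq_len(n_lines) - 1) / n_lines
  t_off <- if (transverse_width > 0) seq(-half_w, half_w, by = px) else 0

  rows <- purrr::map_dfr(seq_len(n_lines), function(k) {
    th <- angles[k]
    # arc offsets at constant radius so every sample sits at the nominal
    # depth; near the center the arc is capped at the full circle
    rad <- radius - depths
    phi <- outer(rad, t_off, function(r, s) {
      pmin(pmax(s / pmax(r, px / 2), -pi), pi)
    })
    xs <- center[1] + rad * cos(th + phi)
    ys <- center[2] + rad * sin(th + phi)
    vals <- bilinear_sample(m, as.vector(xs), as.vector(ys), px)
    inten <- rowMeans(matrix(vals, nrow = length(depths)))
    tibble(line = k, angle_rad = th, depth_um = depths, intensity = inten)
  })
  structure(
    rows,
    class = c("radial_profiles", class(rows)),
    n_lines = n_lines,
    step_um = step,
    radius_um = radius,
    transverse_width_um = transverse_width
  )
}

#' Mean perimeter (rim) intensity of a profile set
#'
#' Pools every profile sample with depth at most `rim_band` over all lines
#' of the spheroid, giving one rim reference per spheroid and channel: the
#' mean stain intensity at the spheroid perimeter against which the
#' half-maximum crossing is judged.
#'
#' @param profiles A [extract_profiles()] result.
#' @param rim_band Perimeter band depth in um (> 0, <= radius).
#' @return Scalar rim mean intensity.
#' @export
rim_reference <- function(profiles, rim_band = 5) {
  stopifnot(inherits(profiles, "radial_profiles"))
  radius <- attr(profiles, "radius_um")
  if (rim_band <= 0 || rim_band > radius) {
    abort("rim_band must be positive and no larger than the radius")
  }
  sel <- profiles$depth_um <= rim_band
  if (!any(sel)) abort("no profile samples within the rim band")
  mean(profiles$intensity[sel])
}

# centered moving average with shrinking windows at the ends
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Half-maximum crossing depth of one radial profile
#'
#' Smooths the profile with a centered moving average of `smoothing_window`
#' samples, then returns the smallest depth at which the smoothed intensity
#' falls below half the rim reference and stays below it (a sustained
#' crossing), linearly interpolated between the bracketing samples. A
#' below-half excursion counts as the front only if it persists for at
#' least `persistence` um or reaches the spheroid center; shorter dips are
#' structure-free gaps between cells, not the staining front. A profile
#' that never sustains a crossing is flagged complete (the stain reached
#' the spheroid center on this line).
#'
#' @param depth_um,intensity Profile samples (depth strictly increasing).
#' @param rim_mean Rim reference intensity (> 0).
#' @param smoothing_window Moving-average width in samples, default 3.
#' @param persistence Minimum below-half run length (um) for a crossing to
#'   count as the front; default 12 um (about one cell diameter).
#' @return List: `depth_um` (NA when complete) and `complete` (logical).
#' @export
half_max_depth <- function(depth_um, intensity, rim_mean, smoothing_window = 3,
                           persistence = CROSSING_PERSISTENCE) {
  if (!is.numeric(rim_mean) || rim_mean <= 0) {
    abort("rim_mean must be positive: the spheroid perimeter appears unstained")
  }
  if (length(depth_um) != length(intensity) || length(depth_um) < 2) {
    abort("profile needs at least two samples")
  }
  s <- moving_average(intensity, smoothing_window)
  half <- rim_mean / 2
  below <- s < half
  n <- length(s)
  step <- stats::median(diff(depth_um))
  persist_n <- max(1L, ceiling(persistence / step))
  runs <- rle(below)
  starts <- cumsum(c(1L, head(runs$lengths, -1L)))
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    reaches_end <- starts[k] + runs$lengths[k] - 1L == n
    if (runs$lengths[k] >= persist_n || reaches_end) {
      i <- starts[k]
      if (i == 1) return(list(depth_um = depth_um[1], complete = FALSE))
      frac <- (s[i - 1] - half) / (s[i - 1] - s[i])
      return(list(
        depth_um = depth_um[i - 1] + frac * (depth_um[i] - depth_um[i - 1]),
        complete = FALSE
      ))
    }
  }
  list(depth_um = NA_real_, complete = TRUE)
}

#' Summarize penetration depth over all lines of a spheroid
#'
#' Applies [half_max_depth()] to every line, averages the per-line depths
#' (lines flagged complete contribute the full radius, since the stain
#' traversed them entirely), and reports the fractional penetration depth,
#' i.e. the mean depth normalized by the spheroid radius and clipped to
#' `[0, 1]`. Fractional depth 1 denotes complete penetration.
#'
#' @param profiles A [extract_profiles()] result.
#' @param rim_mean Rim reference from [rim_reference()].
#' @param radius Spheroid radius in um; defaults to the profile set's.
#' @param smoothing_window Moving-average width in samples.
#' @param persistence Sustained-crossing length (um), see [half_max_depth()].
#' @return One-row tibble: mean_depth_um, sd_depth_um, fractional_depth,
#'   complete, n_lines_used, n_lines_complete.
#' @export
summarize_penetration <- function(profiles, rim_mean, radius = NULL,
                                  smoothing_window = 3,
                                  persistence = CROSSING_PERSISTENCE) {
  stopifnot(inherits(profiles, "radial_profiles"))
  radius <- radius %||% attr(profiles, "radius_um")
  per_line <- profiles |>
    dplyr::group_by(.data$line) |>
    dplyr::group_map(function(df, key) {
      half_max_depth(df$depth_um, df$intensity, rim_mean, smoothing_window,
                     persistence)
    })
  if (length(per_line) < 4) abort("fewer than 4 usable line profiles")
  complete_flags <- vapply(per_line, `[[`, logical(1), "complete")
  depths <- vapply(per_line, `[[`, numeric(1), "depth_um")
  depths[complete_flags] <- radius
  tibble(
    mean_depth_um = mean(depths),
    sd_depth_um = if (length(depths) > 1) sd(depths) else 0,
    fractional_depth = min(1, mean(depths) / radius),
    complete = all(complete_flags),
    n_lines_used = length(depths),
    n_lines_complete = sum(complete_flags)
  )
}

#' Measure half-maximum penetration depth for one spheroid
#'
#' End-to-end per-spheroid measurement: cast radial profiles on the given
#' channel, compute the pooled rim reference, locate the half-maximum
#' crossing on each line and summarize.
#'
#' @param image A [spheroid_image()].
#' @param channel Stain channel to profile (default `"bcatenin"`).
#' @param center,radius Spheroid center (um) and radius (um), e.g. from
#'   [segment_spheroid()] (`center`, `equivalent_diameter_um / 2`).
#' @param n_lines Number of rays, default 36.
#' @param rim_band Rim band in um, default 5.
#' @param smoothing_window Moving-average width in samples, default 3.
#' @param step Radial step in um; defaults to the pixel size.
#' @param transverse_width Thick-line width in um, default 10.
#' @param persistence Sustained-crossing length (um), see [half_max_depth()].
#' @return One-row tibble: id, channel, rim_mean, radius_um plus the
#'   [summarize_penetration()] columns; the profile set is attached as the
#'   `"profiles"` attribute.
#' @export
measure_penetration <- function(image, channel = "bcatenin", center, radius,
                                n_lines = 36, rim_band = 5,
                                smoothing_window = 3, step = NULL,
                                transverse_width = PROFILE_TRANSVERSE_WIDTH,
                                persistence = CROSSING_PERSISTENCE) {
  profiles <- extract_profiles(image, channel, center = center, radius = radius,
                               n_lines = n_lines, step = step,
                               transverse_width = transverse_width)
  rim <- rim_reference(profiles, rim_band = rim_band)
  res <- summarize_penetration(profiles, rim, radius = radius,
                               smoothing_window = smoothing_window,
                               persistence = persistence)
  out <- dplyr::bind_cols(
    tibble(id = image$id %||% NA_character_, channel = channel,
           rim_mean = rim, radius_um = radius),
    res
  )
  attr(out, "profiles") <- profiles
  out
}

#' Plot radial profiles with their half-max reference
#'
#' @param object A [extract_profiles()] result.
#' @param rim_mean Optional rim reference; drawn as a half-max line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_profiles <- function(object, rim_mean = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$depth_um, .data$intensity,
                                            group = .data$line)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "depth from perimeter (um)", y = "intensity")
  if (!is.null(rim_mean)) {
    p <- p + ggplot2::geom_hline(yintercept = rim_mean / 2, linetype = "dashed")
  }
  p
}
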