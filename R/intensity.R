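#' Background-subtracted mean intensity
#'
#' Mean intensity of the positive-thresholded pixels minus the mean
#' background. The value is signed: it is negative exactly when the
#' background region is on average brighter than the positive signal inside
#' the spheroid (e.g. a stain that penetrates poorly but lingers in the
#' surrounding matrix).
#'
#' @param image A [spheroid_image()].
#' @param channel Channel name.
#' @param positive_mask Logical matrix of positive pixels (non-empty).
#' @param mean_background Scalar mean background intensity.
#' @return Scalar signed mean intensity.
#' @export
mean_intensity <- function(image, channel, positive_mask, mean_background) {
  m <- get_channel(image, channel)
  if (!any(positive_mask)) abort("positive_mask is empty; mean intensity undefined")
  mean(m[positive_mask]) - mean_background
}

#' Total normalized intensity
#'
#' Total fluorescence intensity of the positive-thresholded signal, minus
#' the mean background times the number of segmented pixels, divided by the
#' spheroid slice area:
#'
#' \deqn{TNI = \frac{\sum_{p \in positive} I_p - \bar{B}\, N_{positive}}
#'   {A_{spheroid}}}
#'
#' This total-signal form accommodates punctate and heterogeneous stains
#' whose mean over few bright pixels is uninformative. The area denominator
#' is in pixels by default (TNI in intensity per pixel of spheroid area);
#' set `area_unit = "um2"` to normalize by physical area instead.
#'
#' @param image A [spheroid_image()].
#' @param channel Channel name.
#' @param positive_mask Logical matrix of positive pixels (may be empty,
#'   giving 0).
#' @param mean_background Scalar mean background intensity.
#' @param spheroid_area Spheroid slice area (> 0), in the unit of
#'   `area_unit`.
#' @param area_unit `"px"` (default) or `"um2"`; echoed in pipeline output.
#' @return Scalar total normalized intensity.
#' @export
total_normalized_intensity <- function(image, channel, positive_mask,
                                       mean_background, spheroid_area,
                                       area_unit = c("px", "um2")) {
  area_unit <- match.arg(area_unit)
  if (!is.numeric(spheroid_area) || spheroid_area <= 0) {
    abort("spheroid_area must be positive")
  }
  m <- get_channel(image, channel)
  n_pos <- sum(positive_mask)
  (sum(m[positive_mask]) - mean_background * n_pos) / spheroid_area
}

#' Per-channel intensity statistics for one segmented spheroid
#'
#' Computes, for every thresholded channel, the mean background (per the
#' configured region mode), the background-subtracted mean intensity and the
#' total normalized intensity, together with the segmentation bookkeeping
#' needed to audit them.
#'
#' @param image A [spheroid_image()].
#' @param seg A [segment_spheroid()] result for this image.
#' @param background_mode Region mode per [estimate_background()]; either a
#'   single mode or a named character vector per channel (e.g.
#'   `c(lamin = "cytoplasm")`; unnamed channels use `"inverse"`).
#' @param area_unit Area denominator unit for TNI, `"px"` or `"um2"`.
#' @return A tibble with one row per channel: id, channel, threshold,
#'   background_mode, mean_background, positive_pixels, spheroid_area_px,
#'   spheroid_area_um2, equivalent_diameter_um, mean_intensity,
#'   total_normalized_intensity.
#' @export
quantify_intensity <- function(image, seg, background_mode = "inverse",
                               area_unit = c("px", "um2")) {
  stopifnot(inherits(seg, "segmentation_result"))
  area_unit <- match.arg(area_unit)
  chans <- names(seg$masks)
  mode_for <- function(ch) {
    if (length(background_mode) == 1 && is.null(names(background_mode))) {
      background_mode
    } else {
      unname(background_mode[ch] %|NA|% "inverse")
    }
  }
  purrr::map_dfr(chans, function(ch) {
    mode <- mode_for(ch)
    bg <- estimate_background(image, ch, seg$masks[[ch]]$background_mask,
                              spheroid_mask = seg$spheroid_mask,
                              region_mode = mode)
    pos <- seg$masks[[ch]]$positive_mask
    n_pos <- sum(pos)
    area <- if (area_unit == "px") seg$area_px else seg$area_um2
    tibble(
      id = image$id %||% NA_character_,
      channel = ch,
      threshold = unname(seg$thresholds[[ch]]),
      background_mode = mode,
      mean_background = bg,
      positive_pixels = n_pos,
      spheroid_area_px = seg$area_px,
      spheroid_area_um2 = seg$area_um2,
      equivalent_diameter_um = seg$equivalent_diameter_um,
      mean_intensity = if (n_pos > 0) mean_intensity(image, ch, pos, bg) else NA_real_,
      total_normalized_intensity =
        total_normalized_intensity(image, ch, pos, bg, area, area_unit),
      area_unit = area_unit
    )
  })
}

`%|NA|%` <- function(x, y) if (is.null(x) || is.na(x)) y else x
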