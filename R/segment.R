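#' Determine per-channel thresholds for an analysis set
#'
#' One scalar threshold per channel, applied identically to every image of
#' the set so intensity statistics are comparable across conditions. In
#' `"fixed"` mode the supplied values are passed through; in `"auto"` mode
#' the threshold is Otsu's criterion computed on the pooled per-channel pixel
#' histogram of all images in the set.
#'
#' @param images A list of [spheroid_image()] objects (>= 1).
#' @param mode `"auto"` or `"fixed"`.
#' @param fixed Named numeric vector or list of thresholds (fixed mode).
#' @param channels Channels to threshold; defaults to those of the first
#'   image.
#' @return Named numeric vector of thresholds, one per channel.
#' @examples
#' p <- sim_params(spheroid_diameter = 60, field_size = 96, pixel_size = 1)
#' img <- simulate_spheroid(p)$image
#' determine_thresholds(list(img), mode = "fixed", fixed = c(dapi = 500))
#' @export
determine_thresholds <- function(images, mode = c("auto", "fixed"),
                                 fixed = NULL, channels = NULL) {
  mode <- match.arg(mode)
  if (!is.list(images) || length(images) == 0) abort("need at least one image")
  stopifnot(all(vapply(images, inherits, logical(1), "spheroid_image")))
  channels <- channels %||% channel_names(images[[1]])

  if (mode == "fixed") {
    if (is.null(fixed)) abort("fixed mode requires threshold values")
    fixed <- unlist(fixed)
    missing <- setdiff(channels, names(fixed))
    if (length(missing) > 0) {
      abort(paste0("fixed thresholds missing for channel(s): ",
                   paste(missing, collapse = ", ")))
    }
    return(fixed[channels])
  }

  vapply(channels, function(ch) {
    pooled <- unlist(lapply(images, function(img) as.vector(get_channel(img, ch))))
    if (max(pooled) - min(pooled) < .Machine$double.eps * 100) {
      abort(paste0("channel '", ch, "' has a degenerate (constant) histogram; ",
                   "auto thresholding is undefined"))
    }
    # Otsu on the pooled 16-bit histogram
    EBImage::otsu(EBImage::Image(pooled / 65535), range = c(0, 1), levels = 65536) * 65535
  }, numeric(1))
}

#' Split a channel into positive and background masks
#'
#' Pixels at or above the threshold are positive signal; the inverse
#' threshold (pixels below) defines the background set. The two masks are
#' disjoint and together cover the field.
#'
#' @param image A [spheroid_image()].
#' @param channel Channel name.
#' @param threshold Scalar threshold in intensity units.
#' @return List with logical matrices `positive_mask` and `background_mask`.
#' @export
apply_threshold <- function(image, channel, threshold) {
  stopifnot(inherits(image, "spheroid_image"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 65535) {
    abort("threshold must be a scalar within the 16-bit intensity range")
  }
  m <- get_channel(image, channel)
  positive <- m >= threshold
  list(positive_mask = positive, background_mask = !positive)
}

#' Estimate mean background intensity
#'
#' Three region conventions are supported:
#' \describe{
#'   \item{inverse}{mean over all sub-threshold pixels of the whole field
#'     (the default, an inverse threshold);}
#'   \item{matrix_only}{sub-threshold pixels outside the spheroid mask
#'     (residual stain in the gel);}
#'   \item{cytoplasm}{sub-threshold pixels inside the spheroid mask, for
#'     stains with nonspecific cytoplasmic background.}
#' }
#'
#' @param image A [spheroid_image()].
#' @param channel Channel name.
#' @param background_mask Logical matrix from [apply_threshold()].
#' @param spheroid_mask Logical matrix (required for matrix_only/cytoplasm).
#' @param region_mode One of `"inverse"`, `"matrix_only"`, `"cytoplasm"`.
#' @return Scalar mean background intensity.
#' @export
estimate_background <- function(image, channel, background_mask,
                                spheroid_mask = NULL,
                                region_mode = c("inverse", "matrix_only", "cytoplasm")) {
  region_mode <- match.arg(region_mode)
  m <- get_channel(image, channel)
  region <- switch(
    region_mode,
    inverse = background_mask,
    matrix_only = {
      if (is.null(spheroid_mask)) abort("matrix_only mode needs a spheroid_mask")
      background_mask & !spheroid_mask
    },
    cytoplasm = {
      if (is.null(spheroid_mask)) abort("cytoplasm mode needs a spheroid_mask")
      background_mask & spheroid_mask
    }
  )
  if (!any(region)) {
    abort(paste0("background region '", region_mode, "' is empty"))
  }
  mean(m[region])
}

#' Delineate the spheroid from the nuclear channel
#'
#' Thresholds the nuclear channel, closes gaps between nuclei with a
#' morphological closing (disc of radius `closing_radius` um), fills holes,
#' and keeps the largest connected component. Reports the mask, its centroid
#' (um from the top-left pixel center), area and equivalent circular
#' diameter.
#'
#' @param image A [spheroid_image()].
#' @param threshold Nuclear-channel threshold (intensity units).
#' @param nuclear_channel Channel name, default `"dapi"`.
#' @param closing_radius Closing disc radius in um (default 5).
#' @return List: `spheroid_mask` (logical), `center` (x, y um), `area_px`,
#'   `area_um2`, `equivalent_diameter_um`.
#' @export
find_spheroid <- function(image, threshold, nuclear_channel = "dapi",
                          closing_radius = 5) {
  stopifnot(inherits(image, "spheroid_image"))
  m <- get_channel(image, nuclear_channel)
  pos <- m >= threshold
  if (!any(pos)) abort("no positive nuclear pixels; cannot delineate a spheroid")

  px <- image$pixel_size
  r_px <- max(1L, round(closing_radius / px))
  size <- 2L * r_px + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(pos * 1), brush)
  filled <- EBImage::fillHull(closed)
  labels <- EBImage::bwlabel(filled)
  lab <- as.matrix(EBImage::imageData(labels))
  if (max(lab) < 1) abort("no connected component found in the nuclear mask")
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- lab == keep

  idx <- which(mask, arr.ind = TRUE)
  center <- c(
    x = mean((idx[, 2] - 0.5) * px),
    y = mean((idx[, 1] - 0.5) * px)
  )
  area_px <- nrow(idx)
  area_um2 <- area_px * px^2
  list(
    spheroid_mask = mask,
    center = center,
    area_px = area_px,
    area_um2 = area_um2,
    equivalent_diameter_um = 2 * sqrt(area_um2 / pi)
  )
}

#' Segment one spheroid image with set-level thresholds
#'
#' Applies the per-channel thresholds to an image and delineates the
#' spheroid from the nuclear channel. The thresholds must come from
#' [determine_thresholds()] on the whole analysis set, so every image is
#' segmented identically.
#'
#' @param image A [spheroid_image()].
#' @param thresholds Named per-channel thresholds.
#' @param nuclear_channel Channel used for spheroid delineation.
#' @param closing_radius Closing disc radius in um.
#' @return List of class `segmentation_result`: per-channel `positive_mask`
#'   and `background_mask`, plus `spheroid_mask`, `center`, `area_px`,
#'   `area_um2`, `equivalent_diameter_um`, `thresholds`.
#' @export
segment_spheroid <- function(image, thresholds, nuclear_channel = "dapi",
                             closing_radius = 5) {
  chans <- intersect(channel_names(image), names(thresholds))
  if (length(chans) == 0) abort("no threshold provided for any image channel")
  masks <- lapply(setNames(chans, chans), function(ch) {
    apply_threshold(image, ch, thresholds[[ch]])
  })
  sp <- find_spheroid(image, thresholds[[nuclear_channel]],
                      nuclear_channel = nuclear_channel,
                      closing_radius = closing_radius)
  structure(
    c(list(masks = masks, thresholds = thresholds[chans]), sp),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> center (%.1f, %.1f) um, area %d px (%.0f um2), eq. diameter %.1f um\n",
              x$center[1], x$center[2], x$area_px, x$area_um2,
              x$equivalent_diameter_um))
  cat("  thresholds:", paste(sprintf("%s=%.1f", names(x$thresholds), x$thresholds),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Select the mid-depth slice of a z-stack
#'
#' Given the recorded top and bottom z-positions of a spheroid, returns the
#' stack slice nearest the radial center `(z_top + z_bottom) / 2`, together
#' with the overall diameter `|z_bottom - z_top|`. On an exact tie between
#' two slices the lower index wins.
#'
#' @param stack List of [spheroid_image()] (or matrices), one per slice.
#' @param z_positions Numeric z position of each slice, um.
#' @param z_top,z_bottom Recorded spheroid top/bottom z positions, um.
#' @return List: `slice` (element of `stack`), `slice_index`, `mid_depth_um`,
#'   `diameter_um`.
#' @export
select_center_slice <- function(stack, z_positions, z_top, z_bottom) {
  if (length(stack) != length(z_positions)) {
    abort("stack and z_positions lengths differ")
  }
  if (z_top == z_bottom) abort("z_top equals z_bottom: degenerate spheroid extent")
  mid <- (z_top + z_bottom) / 2
  if (mid < min(z_positions) || mid > max(z_positions)) {
    abort("mid-depth lies outside the stack's z range")
  }
  d <- abs(z_positions - mid)
  idx <- which(d == min(d))[1]
  list(
    slice = stack[[idx]],
    slice_index = idx,
    mid_depth_um = mid,
    diameter_um = abs(z_bottom - z_top)
  )
}
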