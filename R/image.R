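#' Multi-channel spheroid image container
#'
#' A light container for one center-slice acquisition: a named list of 2-D
#' intensity matrices (all the same size, 16-bit range) plus the pixel size.
#' Matrices are indexed `[row, col]` with the origin at the top-left pixel;
#' physical coordinates are um from the top-left pixel center, x along
#' columns and y along rows.
#'
#' @param channels Named list of numeric matrices with identical dimensions,
#'   values in `[0, 65535]`.
#' @param pixel_size Pixel size in um/pixel.
#' @param id Optional spheroid identifier carried through result tables.
#' @return An object of class `spheroid_image`.
#' @export
spheroid_image <- function(channels, pixel_size, id = NULL) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("channels must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1)))) {
    abort("each channel must be a numeric matrix")
  }
  if (length(unique(lapply(dims, identity))) != 1) {
    abort("all channels must share the same dimensions")
  }
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < 0 || rng[2] > 65535) {
    abort("channel intensities must lie in [0, 65535]")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("pixel_size must be a positive scalar (um/pixel)")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size, id = id),
    class = "spheroid_image"
  )
}

#' @export
print.spheroid_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<spheroid_image%s> %d x %d px @ %g um/px, channels: %s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.spheroid_image <- function(x) dim(x$channels[[1]])

channel_names <- function(image) names(image$channels)

get_channel <- function(image, channel) {
  if (!channel %in% names(image$channels)) {
    abort(paste0("channel '", channel, "' not present; available: ",
                 paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[channel]]
}

# Physical coordinate grids (um) for a field of nr x nc pixels.
# x runs along columns, y along rows; pixel centers at (i - 0.5) * px.
coord_grids <- function(nr, nc, pixel_size) {
  x <- (seq_len(nc) - 0.5) * pixel_size
  y <- (seq_len(nr) - 0.5) * pixel_size
  list(
    x = matrix(x, nr, nc, byrow = TRUE),
    y = matrix(y, nr, nc, byrow = FALSE)
  )
}

#' Display a spheroid image channel
#'
#' @param object A [spheroid_image()].
#' @param channel Channel name; defaults to the first.
#' @param downsample Keep every n-th pixel for plotting speed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spheroid_image <- function(object, channel = channel_names(object)[1],
                                    downsample = 2L, ...) {
  m <- get_channel(object, channel)
  ri <- seq(1, nrow(m), by = downsample)
  ci <- seq(1, ncol(m), by = downsample)
  df <- expand.grid(y = (ri - 0.5) * object$pixel_size,
                    x = (ci - 0.5) * object$pixel_size)
  df$intensity <- as.vector(m[ri, ci])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = channel,
                  title = object$id %||% "spheroid image")
}
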