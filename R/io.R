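ome_companion_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".companion.ome")
}

#' Write a spheroid image as TIFF with OME companion metadata
#'
#' Writes one 16-bit grayscale TIFF page per channel plus an OME-XML
#' companion file (`<stem>.companion.ome`) carrying the physical pixel size
#' and the channel names, following the OME companion-file layout.
#'
#' @param image A [spheroid_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_spheroid_tiff <- function(image, path) {
  stopifnot(inherits(image, "spheroid_image"))
  pages <- lapply(image$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")

  d <- dim(image$channels[[1]])
  doc <- xml2::xml_new_root(
    "OME", xmlns = "http://www.openmicroscopy.org/Schemas/OME/2016-06"
  )
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0",
                             Name = image$id %||% basename(path))
  px <- xml2::xml_add_child(
    img, "Pixels", ID = "Pixels:0", DimensionOrder = "XYCZT", Type = "uint16",
    SizeX = as.character(d[2]), SizeY = as.character(d[1]),
    SizeC = as.character(length(image$channels)), SizeZ = "1", SizeT = "1",
    PhysicalSizeX = as.character(image$pixel_size),
    PhysicalSizeY = as.character(image$pixel_size),
    PhysicalSizeXUnit = "um", PhysicalSizeYUnit = "um"
  )
  for (i in seq_along(image$channels)) {
    xml2::xml_add_child(px, "Channel", ID = paste0("Channel:0:", i - 1),
                        Name = names(image$channels)[i], SamplesPerPixel = "1")
  }
  xml2::xml_add_child(px, "TiffData")
  xml2::write_xml(doc, ome_companion_path(path))
  invisible(path)
}

#' Read a spheroid image from TIFF
#'
#' Reads a multi-page (or multi-sample) TIFF. Channel names and pixel size
#' are taken from the OME companion file written by [write_spheroid_tiff()]
#' when present; otherwise they must be supplied (`channels` as a character
#' vector in page order; `pixel_size` in um/pixel). A missing pixel size
#' with no override is an error.
#'
#' @param path TIFF path.
#' @param channels Optional channel names overriding/No metadata.
#' @param pixel_size Optional pixel-size override, um/pixel.
#' @param id Spheroid id; defaults to the file stem.
#' @return A [spheroid_image()].
#' @export
read_spheroid_tiff <- function(path, channels = NULL, pixel_size = NULL,
                               id = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 65535)
  })

  meta_path <- ome_companion_path(path)
  meta_names <- NULL
  meta_px <- NULL
  if (file.exists(meta_path)) {
    doc <- xml2::read_xml(meta_path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "ome")
    pixels <- xml2::xml_find_first(doc, ".//ome:Pixels", ns)
    if (!inherits(pixels, "xml_missing")) {
      meta_px <- as.numeric(xml2::xml_attr(pixels, "PhysicalSizeX"))
      chn <- xml2::xml_find_all(pixels, ".//ome:Channel", ns)
      if (length(chn) > 0) meta_names <- xml2::xml_attr(chn, "Name")
    }
  }
  names_out <- channels %||% meta_names
  if (is.null(names_out)) {
    names_out <- paste0("channel", seq_along(mats))
  }
  if (length(names_out) != length(mats)) {
    abort(sprintf("channel name count (%d) does not match TIFF pages (%d)",
                  length(names_out), length(mats)))
  }
  px <- pixel_size %||% meta_px
  if (is.null(px) || !is.finite(px)) {
    abort("pixel size not found in metadata and no override supplied")
  }
  spheroid_image(setNames(mats, names_out), pixel_size = px,
                 id = id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a logical mask as a single-channel TIFF
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Default pipeline configuration
#'
#' @return Named list of analysis settings: thresholds (`"auto"` or a named
#'   list of fixed values), background modes per channel, nuclear and
#'   penetration channels, radial-profiling settings, TNI area unit, alpha
#'   and seed.
#' @export
default_run_config <- function() {
  list(
    thresholds = "auto",
    background_mode = "inverse",
    nuclear_channel = "dapi",
    penetration_channel = "bcatenin",
    closing_radius_um = 5,
    n_lines = 36,
    rim_band_um = 5,
    smoothing_window = 3,
    transverse_width_um = 10,
    persistence_um = 12,
    area_unit = "px",
    pixel_size_override = NULL,
    alpha = 0.05,
    seed = 1L
  )
}

#' Read a pipeline configuration file (YAML)
#'
#' Unspecified settings fall back to [default_run_config()].
#'
#' @param path YAML file path; `NULL` gives the defaults.
#' @return Configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user$alpha) && (user$alpha <= 0 || user$alpha >= 1)) {
      abort("alpha must lie in (0, 1)")
    }
    cfg <- modifyList(cfg, user)
  }
  cfg
}

config_hash <- function(config) rlang::hash(config)
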