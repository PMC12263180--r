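#' Run the full quantification pipeline on an image set
#'
#' Orchestrates the per-set and per-spheroid analyses: thresholds are
#' determined once for the whole set (fixed values from the config, or
#' pooled-histogram Otsu), every image is segmented with those thresholds,
#' intensity statistics and half-maximum penetration are measured per
#' spheroid, and optional condition labels or staining times trigger the
#' two-group comparison or the time-course regression. All result tables
#' carry the configuration hash and the thresholds used, so a run is fully
#' auditable; identical inputs and configuration give identical tables.
#'
#' @param images List of [spheroid_image()] objects (>= 1).
#' @param config Configuration list, see [default_run_config()].
#' @param groups Optional character vector (one label per image, exactly two
#'   distinct labels) enabling the per-channel group comparison. Mean
#'   intensity is compared for nuclear/ring stains (dapi, lamin) and total
#'   normalized intensity for punctate/network stains, matching the
#'   per-channel metric convention.
#' @param times Optional numeric staining time (min) per image, enabling the
#'   penetration time-course regressions (depth and fractional depth).
#' @return List of class `spherostain_run`: tibbles `segmentation`,
#'   `intensity`, `penetration`, optional `comparison` and `timecourse`,
#'   plus `thresholds`, `config`, `config_hash`.
#' @export
run_pipeline <- function(images, config = default_run_config(),
                         groups = NULL, times = NULL) {
  if (!is.list(images) || length(images) == 0) abort("need at least one image")
  ids <- vapply(seq_along(images), function(i) {
    images[[i]]$id %||% sprintf("image%03d", i)
  }, character(1))

  # thresholds are determined once for the channels common to the whole set
  common <- Reduce(intersect, lapply(images, channel_names))
  if (length(common) == 0) abort("images share no channel")
  fixed <- !identical(config$thresholds, "auto")
  if (fixed) common <- intersect(common, names(unlist(config$thresholds)))
  thresholds <- determine_thresholds(
    images,
    mode = if (fixed) "fixed" else "auto",
    fixed = if (fixed) config$thresholds else NULL,
    channels = common
  )

  seg_rows <- list()
  int_rows <- list()
  pen_rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    img$id <- ids[i]
    res <- tryCatch({
      seg <- segment_spheroid(img, thresholds,
                              nuclear_channel = config$nuclear_channel,
                              closing_radius = config$closing_radius_um)
      intens <- quantify_intensity(img, seg,
                                   background_mode = unlist(config$background_mode),
                                   area_unit = config$area_unit)
      pen_channels <- intersect(config$penetration_channel, channel_names(img))
      pens <- purrr::map_dfr(pen_channels, function(ch) {
        measure_penetration(
          img, channel = ch, center = seg$center,
          radius = seg$equivalent_diameter_um / 2,
          n_lines = config$n_lines, rim_band = config$rim_band_um,
          smoothing_window = config$smoothing_window,
          transverse_width = config$transverse_width_um,
          persistence = config$persistence_um
        )
      })
      list(
        seg = tibble(
          id = ids[i],
          center_x_um = seg$center[1], center_y_um = seg$center[2],
          area_px = seg$area_px, area_um2 = seg$area_um2,
          equivalent_diameter_um = seg$equivalent_diameter_um
        ),
        intens = intens,
        pens = pens
      )
    }, error = function(e) {
      abort(paste0("spheroid '", ids[i], "': ", conditionMessage(e)))
    })
    seg_rows[[i]] <- res$seg
    int_rows[[i]] <- res$intens
    pen_rows[[i]] <- res$pens
  }

  hash <- config_hash(config)
  stamp <- function(df) dplyr::mutate(df, config_hash = hash)
  out <- list(
    segmentation = stamp(dplyr::bind_rows(seg_rows)),
    intensity = stamp(dplyr::bind_rows(int_rows)),
    penetration = stamp(dplyr::bind_rows(pen_rows)),
    thresholds = thresholds,
    config = config,
    config_hash = hash
  )

  if (!is.null(groups)) {
    if (length(groups) != length(images)) {
      abort("groups must have one label per image")
    }
    out$comparison <- stamp(compare_conditions(out$intensity, ids, groups,
                                               alpha = config$alpha))
  }
  if (!is.null(times)) {
    if (length(times) != length(images)) {
      abort("times must have one staining time per image")
    }
    tt <- tibble(id = ids, time_min = times)
    pen <- dplyr::left_join(out$penetration, tt, by = "id")
    fits <- dplyr::bind_rows(
      glance(fit_timecourse(pen$time_min, pen$mean_depth_um, "mean_depth_um")),
      glance(fit_timecourse(pen$time_min, pen$fractional_depth, "fractional_depth"))
    )
    fits$predicted_complete_min <- c(
      NA_real_,
      tryCatch(predict_complete_time(
        fit_timecourse(pen$time_min, pen$fractional_depth, "fractional_depth")
      ), error = function(e) NA_real_)
    )
    out$timecourse <- stamp(fits)
  }
  class(out) <- "spherostain_run"
  out
}

# default metric per stain pattern: mean intensity for dense nuclear/ring
# stains, total normalized intensity for punctate/network stains
metric_for_channel <- function(channel) {
  if (channel %in% c("dapi", "lamin")) "mean_intensity" else "total_normalized_intensity"
}

compare_conditions <- function(intensity, ids, groups, alpha = 0.05) {
  labels <- unique(groups)
  if (length(labels) != 2) abort("group comparison needs exactly two distinct labels")
  gmap <- setNames(groups, ids)
  intensity$group <- gmap[intensity$id]
  purrr::map_dfr(unique(intensity$channel), function(ch) {
    metric <- metric_for_channel(ch)
    df <- intensity[intensity$channel == ch, ]
    a <- df[[metric]][df$group == labels[1]]
    b <- df[[metric]][df$group == labels[2]]
    cmp <- compare_groups(a, b, alpha = alpha)
    dplyr::mutate(tidy(cmp), channel = ch, metric = metric,
                  group_a = labels[1], group_b = labels[2], .before = 1)
  })
}

#' @export
print.spherostain_run <- function(x, ...) {
  cat(sprintf("<spherostain_run> %d spheroids, config %s\n",
              nrow(x$segmentation), substr(x$config_hash, 1, 8)))
  cat("  thresholds:", paste(sprintf("%s=%.1f", names(x$thresholds), x$thresholds),
                             collapse = ", "), "\n")
  for (tb in intersect(c("comparison", "timecourse"), names(x))) {
    cat(sprintf("  includes %s table (%d rows)\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Write pipeline result tables to disk
#'
#' Writes one CSV per result table plus a JSON run summary (thresholds,
#' configuration and its hash). File contents are deterministic for a given
#' input set and configuration.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "spherostain_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tb in intersect(c("segmentation", "intensity", "penetration",
                         "comparison", "timecourse"), names(run))) {
    p <- file.path(dir, paste0(tb, ".csv"))
    readr::write_csv(run[[tb]], p)
    paths <- c(paths, p)
  }
  summary_path <- file.path(dir, "run_summary.json")
  jsonlite::write_json(
    list(
      config_hash = run$config_hash,
      thresholds = as.list(run$thresholds),
      config = run$config
    ),
    summary_path, auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(c(paths, summary_path))
}
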