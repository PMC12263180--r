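# Fixed stain-structure geometry (um). The source study reports no such
# constants; these are documented generator choices.
STAIN_GEOMETRY <- list(
  lamin_annulus_width = 1,    # nuclear-envelope ring thickness
  golgi_punctum_radius = 0.8, # Golgi punctum radius
  golgi_offset = 1.5,         # punctum offset beyond the nuclear envelope
  bcat_ridge_width = 1        # cell-boundary ridge thickness
)

#' Render a synthetic multi-channel spheroid image
#'
#' Renders the four stain channels of one equatorial spheroid slice from a
#' cell-packing geometry:
#' \describe{
#'   \item{dapi}{nuclei as filled disks at the cell centers,}
#'   \item{lamin}{nuclear-envelope rings (annuli around the nuclei),}
#'   \item{gm130}{Golgi puncta offset from each nucleus,}
#'   \item{bcatenin}{cell-boundary ridges along the borders between
#'     neighboring cells (the boundary network of the packing).}
#' }
#' Antibody stain structures (lamin, gm130, bcatenin) are attenuated by
#' [penetration_profile()] of their radial depth from the spheroid surface,
#' so only structures shallower than the staining front are lit. The nuclear
#' counterstain (dapi) is a separate small-molecule staining step that
#' saturates the whole spheroid, so its structures are rendered at full
#' intensity at every depth; this is what makes the nuclear channel usable
#' for spheroid delineation even when antibody penetration is partial.
#' Matrix pixels outside the spheroid receive
#' `rim_intensity * matrix_background_fraction` (residual stain that has not
#' washed out of the gel). The field is then blurred with a Gaussian PSF,
#' degraded with Poisson shot noise and Gaussian read noise, clipped and
#' quantized to the 16-bit range. Noise draws are seeded from the geometry's
#' parameters, so identical inputs give bit-identical images.
#'
#' @param geometry A [simulate_geometry()] result.
#' @param params A [sim_params()] object; defaults to the geometry's own.
#' @param id Optional spheroid id stamped on the image.
#' @return A [spheroid_image()] with channels dapi, lamin, gm130, bcatenin.
#' @examples
#' p <- sim_params(spheroid_diameter = 60, field_size = 96, pixel_size = 1,
#'                 staining_time = 30, front_velocity = 1)
#' img <- render_spheroid(simulate_geometry(p))
#' dim(img)
#' @export
render_spheroid <- function(geometry, params = geometry$params, id = NULL) {
  stopifnot(inherits(geometry, "spheroid_geometry"))
  validate_sim_params(params)

  n <- params$field_size
  px <- params$pixel_size
  g <- coord_grids(n, n, px)
  cx <- geometry$center[1]
  cy <- geometry$center[2]
  radius <- geometry$radius
  rr <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  inside <- rr <= radius
  depth <- pmax(radius - rr, 0)
  profile <- matrix(0, n, n)
  profile[inside] <- penetration_profile(depth[inside], params)

  geom_const <- STAIN_GEOMETRY
  cells <- geometry$cell_centers

  # bounding box around the spheroid (plus a small margin) where structures live
  margin <- 2 * params$cell_min_spacing
  ci <- which(colSums(inside) > 0)
  riw <- which(rowSums(inside) > 0)
  pad <- ceiling(margin / px)
  rows <- max(1, min(riw) - pad):min(n, max(riw) + pad)
  cols <- max(1, min(ci) - pad):min(n, max(ci) + pad)
  bx <- g$x[rows, cols]
  by <- g$y[rows, cols]
  bnr <- length(rows)
  bnc <- length(cols)

  # nearest / second-nearest distance to a cell center, via per-cell windows
  m1 <- matrix(Inf, bnr, bnc)
  m2 <- matrix(Inf, bnr, bnc)
  win <- 2 * params$cell_min_spacing
  x0 <- (cols[1] - 0.5) * px
  y0 <- (rows[1] - 0.5) * px
  for (k in seq_len(nrow(cells))) {
    cxk <- cells[k, 1]
    cyk <- cells[k, 2]
    jc <- round((cxk - x0) / px) + 1
    jr <- round((cyk - y0) / px) + 1
    w <- ceiling(win / px)
    rsel <- max(1, jr - w):min(bnr, jr + w)
    csel <- max(1, jc - w):min(bnc, jc + w)
    d <- sqrt((bx[rsel, csel] - cxk)^2 + (by[rsel, csel] - cyk)^2)
    old1 <- m1[rsel, csel]
    old2 <- m2[rsel, csel]
    lt1 <- d < old1
    new2 <- pmin(old2, ifelse(lt1, old1, d))
    m1[rsel, csel] <- pmin(old1, d)
    m2[rsel, csel] <- new2
  }

  zero <- matrix(0, n, n)
  put <- function(bbox_vals) {
    full <- zero
    full[rows, cols] <- bbox_vals
    full
  }
  inside_b <- inside[rows, cols]

  dapi_s <- put((m1 <= params$nucleus_radius) * inside_b)
  lamin_s <- put((abs(m1 - params$nucleus_radius) <= geom_const$lamin_annulus_width / 2) * inside_b)
  bcat_s <- put((is.finite(m2) & (m2 - m1) <= geom_const$bcat_ridge_width) * inside_b)

  # Golgi puncta: one per cell, offset from the nuclear envelope along a
  # per-cell direction fixed in the geometry
  off <- params$nucleus_radius + geom_const$golgi_offset
  gx <- cells[, 1] + off * cos(geometry$golgi_angle)
  gy <- cells[, 2] + off * sin(geometry$golgi_angle)
  gm <- matrix(FALSE, bnr, bnc)
  for (k in seq_along(gx)) {
    jc <- round((gx[k] - x0) / px) + 1
    jr <- round((gy[k] - y0) / px) + 1
    w <- ceiling((geom_const$golgi_punctum_radius + px) / px)
    rsel <- max(1, jr - w):min(bnr, jr + w)
    csel <- max(1, jc - w):min(bnc, jc + w)
    d <- sqrt((bx[rsel, csel] - gx[k])^2 + (by[rsel, csel] - gy[k])^2)
    gm[rsel, csel] <- gm[rsel, csel] | d <= geom_const$golgi_punctum_radius
  }
  gm130_s <- put(gm * inside_b)

  background <- params$rim_intensity * params$matrix_background_fraction * !inside
  compose <- function(structure_mask, attenuation) {
    params$rim_intensity * structure_mask * attenuation + background
  }
  full <- matrix(0, n, n)
  full[inside] <- 1
  chans <- list(
    dapi = compose(dapi_s, full),
    lamin = compose(lamin_s, profile),
    gm130 = compose(gm130_s, profile),
    bcatenin = compose(bcat_s, profile)
  )

  if (params$psf_sigma > 0) {
    sig_px <- params$psf_sigma / px
    chans <- lapply(chans, function(m) {
      as.matrix(EBImage::gblur(m, sigma = sig_px))
    })
  }

  withr::local_seed(derive_seed(params$seed, 1L))
  chans <- lapply(chans, function(m) {
    if (params$poisson_scale > 0) {
      m <- params$poisson_scale * rpois(length(m), pmax(m, 0) / params$poisson_scale)
      dim(m) <- c(n, n)
    }
    if (params$read_noise_sd > 0) {
      m <- m + rnorm(length(m), 0, params$read_noise_sd)
    }
    matrix(round(pmin(pmax(m, 0), 65535)), n, n)
  })

  spheroid_image(chans, pixel_size = px, id = id)
}

#' Simulate one spheroid end to end
#'
#' Convenience wrapper: [simulate_geometry()] then [render_spheroid()].
#'
#' @inheritParams render_spheroid
#' @param params A [sim_params()] object.
#' @return A list with `image` ([spheroid_image()]) and `geometry`
#'   ([simulate_geometry()] output, the ground truth).
#' @export
simulate_spheroid <- function(params, id = NULL) {
  geometry <- simulate_geometry(params)
  list(image = render_spheroid(geometry, params, id = id), geometry = geometry)
}

#' Ground-truth table for a simulated spheroid
#'
#' @param geometry A [simulate_geometry()] result.
#' @param id Spheroid id for the table.
#' @return A tibble with one row per stain channel: id, center, radius,
#'   number of cells, channel and the true staining-front depth (um). The
#'   nuclear counterstain always penetrates fully (depth = radius); the
#'   antibody channels carry the front depth implied by the staining time.
#' @export
ground_truth <- function(geometry, id = NA_character_) {
  stopifnot(inherits(geometry, "spheroid_geometry"))
  depth <- true_front_depth(geometry$params)
  tibble(
    id = id,
    center_x_um = geometry$center[1],
    center_y_um = geometry$center[2],
    radius_um = geometry$radius,
    n_cells = nrow(geometry$cell_centers),
    channel = c("dapi", "lamin", "gm130", "bcatenin"),
    true_front_depth_um = c(geometry$radius, depth, depth, depth)
  )
}

#' Boolean spheroid mask implied by a geometry
#'
#' @param geometry A [simulate_geometry()] result.
#' @return Logical matrix, TRUE inside the spheroid disk.
#' @export
ground_truth_mask <- function(geometry) {
  p <- geometry$params
  g <- coord_grids(p$field_size, p$field_size, p$pixel_size)
  sqrt((g$x - geometry$center[1])^2 + (g$y - geometry$center[2])^2) <= geometry$radius
}

#' Simulate a staining-time course
#'
#' Generates `n_per_time` independent spheroids at each staining time,
#' emulating a time-titration experiment in which the primary staining step
#' is varied and the penetration front is read out per spheroid. Each
#' (time, replicate) pair gets its own seed derived deterministically from
#' the master seed, so the whole experiment is reproducible from one integer.
#'
#' @param params_base A [sim_params()] object; staining_time and seed are
#'   overridden per replicate.
#' @param times Staining times in minutes (non-empty).
#' @param n_per_time Replicate spheroids per time (>= 1).
#' @param seed Master seed.
#' @return A list with `images` (list of [spheroid_image()]) and `truth`
#'   (tibble: id, staining_time_min, replicate, channel, true front depth,
#'   radius, n_cells).
#' @export
simulate_timecourse <- function(params_base, times, n_per_time, seed) {
  validate_sim_params(params_base)
  if (length(times) == 0) abort("times must be non-empty")
  if (n_per_time < 1) abort("n_per_time must be >= 1")
  grid <- expand.grid(replicate = seq_len(n_per_time), time = times)
  images <- vector("list", nrow(grid))
  truths <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    t_i <- grid$time[i]
    rep_i <- grid$replicate[i]
    p <- params_base
    p$staining_time <- t_i
    p$seed <- derive_seed(seed, i)
    id <- sprintf("t%03d_r%02d", round(t_i), rep_i)
    sim <- simulate_spheroid(p, id = id)
    images[[i]] <- sim$image
    truths[[i]] <- dplyr::mutate(
      ground_truth(sim$geometry, id = id),
      staining_time_min = t_i, replicate = rep_i, .after = "id"
    )
  }
  list(images = images, truth = dplyr::bind_rows(truths))
}
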