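test_that("radial profiles have the stated construction", {
  # radially symmetric two-level image: every profile identical
  img <- disk_image(40, field_px = 256, pixel_size = 0.5, value = 1000,
                    outside = 100, channel = "bcatenin")
  center <- c(64, 64)
  prof <- extract_profiles(img, "bcatenin", center = center, radius = 40,
                           n_lines = 8, transverse_width = 0)
  expect_equal(unique(prof$angle_rad), 2 * pi * (0:7) / 8) # 45 degree spacing
  by_line <- split(prof$intensity, prof$line)
  for (k in 2:8) {
    # skip the depth-0 sample, which sits on the pixelated disk edge where
    # bilinear values depend on the ray's angle to the pixel grid
    expect_equal(by_line[[k]][-1], by_line[[1]][-1], tolerance = 1e-6)
  }
  # profile runs from the perimeter (depth 0) to the center (depth = radius)
  one <- prof[prof$line == 1, ]
  expect_equal(one$depth_um[1], 0)
  expect_equal(one$depth_um[nrow(one)], 40)
  expect_equal(nrow(one), 40 / 0.5 + 1)
  expect_true(all(diff(one$depth_um) > 0))
  # center outside the field errors
  expect_error(extract_profiles(img, "bcatenin", center = c(500, 64),
                                radius = 40), "outside")
  expect_error(extract_profiles(img, "bcatenin", center = c(5, 64),
                                radius = 40), "leave")
  expect_error(extract_profiles(img, "bcatenin", center = center, radius = 40,
                                n_lines = 3), "at least 4")
})

test_that("rim reference pools perimeter samples across lines", {
  depths <- seq(0, 50, by = 1)
  flat <- function(v) rep(v, length(depths))
  prof <- make_profiles(depths, list(flat(100), flat(100)), step = 1, radius = 50)
  expect_equal(rim_reference(prof, rim_band = 5), 100)
  # two lines with rim values 80 and 120 and equal counts pool to 100
  prof2 <- make_profiles(depths, list(flat(80), flat(120)), step = 1, radius = 50)
  expect_equal(rim_reference(prof2, rim_band = 5), 100)
  expect_error(rim_reference(prof, rim_band = 0), "positive")
  expect_error(rim_reference(prof, rim_band = 60), "radius")
})

test_that("half-max crossing interpolates linearly and flags complete profiles", {
  depths <- seq(0, 60, by = 1)
  # 100 down to depth 40, then linear to 0 over 40-44: half of rim 100
  # crossed at depth 42
  ramp <- c(rep(100, 40), seq(100, 0, by = -25), rep(0, 16))
  res <- half_max_depth(depths, ramp, rim_mean = 100, smoothing_window = 1)
  expect_false(res$complete)
  expect_equal(res$depth_um, 42)
  # uniform profile at the rim mean never crosses -> complete
  res2 <- half_max_depth(depths, rep(100, 61), rim_mean = 100)
  expect_true(res2$complete)
  expect_true(is.na(res2$depth_um))
  expect_error(half_max_depth(depths, ramp, rim_mean = 0), "unstained")
})

test_that("smoothing and crossing persistence reject transient dips", {
  depths <- seq(0, 60, by = 1)
  base <- c(rep(100, 41), rep(0, 20)) # sharp front at 40
  # +/-5% multiplicative noise does not move the window-3 crossing by more
  # than one sampling step relative to the noiseless profile
  withr::local_seed(5)
  noisy <- base * runif(61, 0.95, 1.05)
  d_clean <- half_max_depth(depths, base, 100, smoothing_window = 3)$depth_um
  d_noisy <- half_max_depth(depths, noisy, 100, smoothing_window = 3)$depth_um
  expect_lt(abs(d_noisy - d_clean), 1 + 1e-9)
  # a short structure-free gap (below half for < persistence) is skipped
  gap <- base
  gap[11:14] <- 0 # 4-um dip well before the front
  d_gap <- half_max_depth(depths, gap, 100, smoothing_window = 1,
                          persistence = 12)$depth_um
  expect_equal(d_gap, d_clean, tolerance = 0.5)
  # but a sustained drop is the front even if signal is zero from there on
  expect_equal(half_max_depth(depths, gap, 100, smoothing_window = 1,
                              persistence = 3)$depth_um, 10.5, tolerance = 1)
})

test_that("per-spheroid penetration summary averages lines and normalizes by radius", {
  depths <- seq(0, 100, by = 1)
  stepped <- function(front) c(rep(100, front + 1), rep(0, 100 - front))
  prof <- make_profiles(depths, replicate(6, stepped(40), simplify = FALSE),
                        step = 1, radius = 100)
  res <- summarize_penetration(prof, rim_mean = 100)
  expect_equal(res$mean_depth_um, 40, tolerance = 0.02)
  expect_equal(res$fractional_depth, 0.4, tolerance = 0.02)
  expect_false(res$complete)
  expect_equal(res$n_lines_used, 6)
  # all lines complete -> mean = radius, fractional exactly 1
  prof2 <- make_profiles(depths, replicate(6, rep(100, 101), simplify = FALSE),
                         step = 1, radius = 100)
  res2 <- summarize_penetration(prof2, rim_mean = 100)
  expect_equal(res2$mean_depth_um, 100)
  expect_equal(res2$fractional_depth, 1)
  expect_true(res2$complete)
  expect_equal(res2$n_lines_complete, 6)
  # fewer than 4 lines is refused
  prof3 <- make_profiles(depths, replicate(3, stepped(40), simplify = FALSE),
                         step = 1, radius = 100)
  expect_error(summarize_penetration(prof3, rim_mean = 100), "4 usable")
})

test_that("the half-max estimator recovers generator fronts on noiseless spheroids", {
  # sharp fronts at 25/50/75% of the radius; measured depth within one pixel
  p0 <- tiny_params(spheroid_diameter = 120, field_size = 300)
  for (frac in c(0.25, 0.5, 0.75)) {
    p <- tiny_params(spheroid_diameter = 120, field_size = 300,
                     staining_time = frac * 60, front_velocity = 1,
                     seed = 50 + round(frac * 100))
    sim <- simulate_spheroid(p)
    pen <- measure_penetration(sim$image, "bcatenin",
                               center = sim$geometry$center,
                               radius = sim$geometry$radius)
    expect_equal(pen$mean_depth_um, true_front_depth(p),
                 tolerance = p$pixel_size / true_front_depth(p),
                 info = paste("front fraction", frac))
  }
})

test_that("measured penetration is monotone in staining time (noise off)", {
  meas <- vapply(c(10, 25, 40), function(t) {
    p <- tiny_params(spheroid_diameter = 100, field_size = 260,
                     staining_time = t, front_velocity = 1, seed = 9)
    sim <- simulate_spheroid(p)
    measure_penetration(sim$image, "bcatenin", center = sim$geometry$center,
                        radius = sim$geometry$radius)$mean_depth_um
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
})
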