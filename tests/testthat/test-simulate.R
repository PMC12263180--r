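test_that("parameter validation rejects impossible configurations", {
  expect_error(sim_params(spheroid_diameter = 300, field_size = 128,
                          pixel_size = 0.5), "field")
  expect_error(sim_params(matrix_background_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_params(front_velocity = -1), "non-negative")
  expect_error(simulate_geometry(tiny_params(cell_min_spacing = 200)),
               "no cell")
})

test_that("cell placement is contained, deterministic, and density scales with spacing", {
  p <- tiny_params()
  g1 <- simulate_geometry(p)
  g2 <- simulate_geometry(p)
  # determinism: same params + seed give identical centers
  expect_identical(g1$cell_centers, g2$cell_centers)
  # containment: every center within the spheroid radius
  d <- sqrt((g1$cell_centers[, 1] - g1$center[1])^2 +
            (g1$cell_centers[, 2] - g1$center[2])^2)
  expect_true(all(d <= g1$radius))
  # minimum spacing honored (brute-force pairwise check)
  dm <- as.matrix(dist(g1$cell_centers))
  diag(dm) <- Inf
  expect_true(min(dm) >= p$cell_min_spacing)
  # coarser spacing packs strictly fewer cells at the same diameter/seed
  n8 <- nrow(simulate_geometry(tiny_params(cell_min_spacing = 8))$cell_centers)
  n12 <- nrow(simulate_geometry(tiny_params(cell_min_spacing = 12))$cell_centers)
  expect_lt(n12, n8)
})

test_that("penetration profile is a correct, monotone front model", {
  p <- tiny_params(front_velocity = 1, staining_time = 40, front_width = 0)
  # sharp mode: fully stained at the surface, zero beyond the front
  expect_identical(penetration_profile(0, p), 1)
  expect_identical(penetration_profile(39.999, p), 1)
  expect_identical(penetration_profile(40.001, p), 0)
  # smooth mode: exactly half at the front, monotone non-increasing
  ps <- tiny_params(front_velocity = 1, staining_time = 40, front_width = 4)
  expect_equal(penetration_profile(40, ps), 0.5)
  prof <- penetration_profile(seq(0, 60, by = 0.5), ps)
  expect_true(all(diff(prof) <= 0))
  expect_true(all(prof >= 0 & prof <= 1))
  expect_error(penetration_profile(-1, p), "non-negative")
})

test_that("rendering confines stain structures to the spheroid and scales with time", {
  p <- tiny_params()
  g <- simulate_geometry(p)
  img <- render_spheroid(g, p)
  inside <- ground_truth_mask(g)
  bg <- p$rim_intensity * p$matrix_background_fraction
  for (ch in names(img$channels)) {
    # outside the disk only matrix background remains (noise and blur off)
    expect_true(all(img$channels[[ch]][!inside] == bg), info = ch)
  }
  # complete front: a longer staining time changes nothing once saturated
  p_full <- tiny_params(staining_time = 1000)
  p_more <- tiny_params(staining_time = 2000)
  expect_identical(render_spheroid(simulate_geometry(p_full), p_full)$channels,
                   render_spheroid(simulate_geometry(p_more), p_more)$channels)
  # monotonicity: more staining time never darkens any pixel (noise off)
  p20 <- tiny_params(staining_time = 10)
  p40 <- tiny_params(staining_time = 20)
  i20 <- render_spheroid(simulate_geometry(p20), p20)
  i40 <- render_spheroid(simulate_geometry(p40), p40)
  for (ch in names(i20$channels)) {
    expect_true(all(i40$channels[[ch]] >= i20$channels[[ch]]), info = ch)
  }
  # partial sharp front (10 um): antibody structures beyond the front carry
  # only background, while the nuclear counterstain saturates all depths
  grids <- spherostain:::coord_grids(p$field_size, p$field_size, p$pixel_size)
  depth_grid <- g$radius -
    sqrt((grids$x - g$center[1])^2 + (grids$y - g$center[2])^2)
  deep <- inside & depth_grid > true_front_depth(p20) + p$pixel_size
  expect_true(all(i20$channels$bcatenin[deep] == 0))
  expect_true(any(i20$channels$dapi[deep] > 0))
})

test_that("rendering is bit-identical for identical parameters and seed", {
  p <- tiny_params(poisson_scale = 1, read_noise_sd = 30, psf_sigma = 0.75)
  s1 <- simulate_spheroid(p)
  s2 <- simulate_spheroid(p)
  expect_identical(s1$image$channels, s2$image$channels)
  s3 <- simulate_spheroid(tiny_params(poisson_scale = 1, read_noise_sd = 30,
                                      psf_sigma = 0.75, seed = 43))
  expect_false(identical(s1$image$channels, s3$image$channels))
})

test_that("shot noise has Poisson mean-variance structure", {
  # Monte-Carlo oracle: track one bright pixel across repeated renders of
  # the same geometry with fresh noise seeds; sample variance must match
  # the sample mean within 3 standard errors of a Poisson variance estimate
  p <- tiny_params(poisson_scale = 1, read_noise_sd = 0, psf_sigma = 0)
  g <- simulate_geometry(p)
  ref <- render_spheroid(g, tiny_params())
  px_idx <- which.max(ref$channels$dapi)
  vals <- vapply(seq_len(100), function(k) {
    pk <- p
    pk$seed <- 1000L + k
    render_spheroid(g, pk)$channels$dapi[px_idx]
  }, numeric(1))
  m <- mean(vals)
  v <- var(vals)
  se_var <- v * sqrt(2 / (length(vals) - 1))
  expect_lt(abs(v - m), 3 * se_var)
})

test_that("time-course simulation tracks ground truth deterministically", {
  p <- tiny_params()
  sim <- simulate_timecourse(p, times = c(20, 120), n_per_time = 2, seed = 7)
  expect_length(sim$images, 4)
  bc <- sim$truth[sim$truth$channel == "bcatenin", ]
  expect_equal(sort(bc$true_front_depth_um),
               sort(pmin(c(20, 20, 120, 120) * p$front_velocity, p$spheroid_diameter / 2)))
  # v = 0.5 um/min at t = 60 -> recorded depth 30 um
  p2 <- tiny_params(front_velocity = 0.5)
  sim2 <- simulate_timecourse(p2, times = 60, n_per_time = 1, seed = 7)
  expect_equal(sim2$truth$true_front_depth_um[sim2$truth$channel == "bcatenin"], 30)
  # same master seed -> identical truth tables
  sim3 <- simulate_timecourse(p, times = c(20, 120), n_per_time = 2, seed = 7)
  expect_identical(sim$truth, sim3$truth)
})
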