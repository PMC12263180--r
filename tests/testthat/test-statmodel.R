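# closed-form oracles, independent of the package implementation
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r2 = if (sst > 0) 1 - sum(resid^2) / sst else 0)
}

student_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

f_oracle <- function(a, b) {
  f <- var(a) / var(b)
  tail <- pf(f, length(a) - 1, length(b) - 1)
  list(f = f, p = 2 * min(tail, 1 - tail))
}

test_that("time-course regression matches the closed-form OLS oracle", {
  # exact line
  fit <- fit_timecourse(c(0, 10, 20, 30), c(0, 20, 40, 60))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  # hand-derived: (0,0),(1,1),(2,3) -> slope 3/2, intercept -1/6, R2 27/28
  fit2 <- fit_timecourse(c(0, 1, 2), c(0, 1, 3))
  expect_equal(fit2$slope, 1.5)
  expect_equal(fit2$intercept, -1 / 6)
  expect_equal(fit2$r_squared, 27 / 28)
  # constant response: slope 0, R2 defined as 0
  fit3 <- fit_timecourse(c(0, 1, 2), c(5, 5, 5))
  expect_equal(fit3$slope, 0)
  expect_equal(fit3$r_squared, 0)
  # 100 random fixtures against the normal-equations oracle, to 1e-9
  withr::local_seed(31)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    x <- runif(n, 0, 120)
    if (length(unique(x)) < 2) next
    y <- runif(1, -1, 1) * x + rnorm(n)
    o <- ols_oracle(x, y)
    f <- fit_timecourse(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-9)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-9)
  }
  expect_error(fit_timecourse(c(1, 1, 1), c(1, 2, 3)), "identical")
  expect_error(fit_timecourse(c(1, 2), c(1, 2)), "at least 3")
})

test_that("predicted completion time solves the fitted line at fraction 1", {
  f1 <- fit_timecourse(c(0, 50, 100), c(0, 0.5, 1))
  expect_equal(predict_complete_time(f1), 100)
  # slope 0.005, intercept 0.5 -> 100 min
  fit <- structure(list(slope = 0.005, intercept = 0.5),
                   class = "timecourse_fit")
  expect_equal(predict_complete_time(fit), 100)
  bad <- structure(list(slope = -0.1, intercept = 0.5), class = "timecourse_fit")
  expect_error(predict_complete_time(bad), "not positive")
})

test_that("variance gate picks Student vs Welch and matches closed forms", {
  # identical groups: F p = 1 -> Student; t = 0, p = 1
  cmp <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$test_used, "student")
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)
  # {1,2,3} vs {2,4,6}: F = 1/4 with df (2,2); two-sided p = 0.4 (from the
  # F(2,2) cdf x/(1+x)) -> equal variances not rejected -> Student
  cmp2 <- compare_groups(c(1, 2, 3), c(2, 4, 6))
  expect_equal(cmp2$f_statistic, 1 / 4)
  expect_equal(cmp2$f_p_value, 0.4, tolerance = 1e-12)
  expect_equal(cmp2$test_used, "student")
  # large-n location shift with equal variances is detected
  withr::local_seed(77)
  a <- rnorm(200, 0, 1)
  b <- rnorm(200, 1, 1)
  cmp3 <- compare_groups(a, b)
  expect_equal(cmp3$test_used, "student")
  expect_lt(cmp3$p_value, 0.05)
  expect_true(cmp3$significant)
  expect_error(compare_groups(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("F/Student/Welch match independent closed-form oracles on 100 fixtures", {
  withr::local_seed(123)
  n_welch <- 0
  for (i in 1:100) {
    na <- sample(3:25, 1)
    nb <- sample(3:25, 1)
    a <- rnorm(na, runif(1, -5, 5), runif(1, 0.2, 4))
    b <- rnorm(nb, runif(1, -5, 5), runif(1, 0.2, 4))
    cmp <- compare_groups(a, b)
    fo <- f_oracle(a, b)
    expect_equal(cmp$f_statistic, fo$f, tolerance = 1e-9)
    expect_equal(cmp$f_p_value, fo$p, tolerance = 1e-9)
    o <- if (fo$p < 0.05) {
      n_welch <- n_welch + 1
      expect_equal(cmp$test_used, "welch")
      welch_oracle(a, b)
    } else {
      expect_equal(cmp$test_used, "student")
      student_oracle(a, b)
    }
    expect_equal(cmp$t_statistic, o$t, tolerance = 1e-9)
    expect_equal(cmp$df, o$df, tolerance = 1e-9)
    expect_equal(cmp$p_value, o$p, tolerance = 1e-9)
  }
  expect_gt(n_welch, 0) # both branches exercised
})

test_that("summaries use mean, sample SD and the stated n = 1 convention", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3)
  s1 <- summarize_values(5)
  expect_equal(s1$mean, 5)
  expect_equal(s1$sd, 0)
  expect_true(s1$single_observation)
  expect_equal(summarize_values(rep(7, 10))$sd, 0)
  expect_error(summarize_values(numeric(0)), "no values")
})

test_that("significance stars follow the reporting convention", {
  expect_equal(significance_stars(c(0.00005, 0.0005, 0.005, 0.03, 0.2)),
               c("****", "***", "**", "*", "ns"))
})

test_that("fitted slope recovers the generator front velocity on noisy depth data", {
  # parameter recovery on a small noisy time course: slope within 3 SE of
  # the true front velocity
  p <- tiny_params(spheroid_diameter = 100, field_size = 260,
                   front_velocity = 1, poisson_scale = 1, read_noise_sd = 30,
                   psf_sigma = 0.75)
  sim <- simulate_timecourse(p, times = c(10, 20, 30, 40), n_per_time = 2,
                             seed = 88)
  pen <- purrr::map_dfr(sim$images, function(img) {
    th <- determine_thresholds(list(img), mode = "fixed",
                               fixed = c(dapi = 4000, bcatenin = 4000),
                               channels = c("dapi", "bcatenin"))
    seg <- segment_spheroid(img, th)
    dplyr::mutate(
      measure_penetration(img, "bcatenin", center = seg$center,
                          radius = seg$equivalent_diameter_um / 2),
      id = img$id
    )
  })
  times <- sim$truth$staining_time_min[match(pen$id, sim$truth$id)]
  fit <- fit_timecourse(times, pen$mean_depth_um)
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$slope - p$front_velocity), 3 * se)
})
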