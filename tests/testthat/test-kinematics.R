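test_that("velocity model matches closed-form anchors and a high-precision oracle", {
  expect_equal(velocity_model(c(vf = 0.2, x0 = 0.4, k = 9, n = 1), 0.4), 0.1)
  # frozen from a 40-digit arbitrary-precision evaluation of the formula
  expect_equal(velocity_model(c(vf = 0.25, x0 = 0.35, k = 12, n = 0.7), 0.5),
               0.2009229445788639, tolerance = 1e-14)
  # plateau and foot limits
  p <- c(vf = 0.31, x0 = 0.45, k = 14, n = 0.8)
  expect_lt(abs(velocity_model(p, p[["x0"]] + 50 / p[["k"]]) - p[["vf"]]),
            1e-6 * p[["vf"]])
  expect_lt(velocity_model(p, p[["x0"]] - 50 / p[["k"]]), 1e-8)
  expect_error(velocity_model(p, Inf), "finite")
  expect_error(velocity_model(c(vf = -1, x0 = 0, k = 1, n = 1), 0), "positive")
})

test_that("velocity model is monotone nondecreasing for random valid params", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_params()
    x <- sort(runif(50, -0.5, 2))
    expect_true(all(diff(velocity_model(p, x)) >= -1e-12))
  }
})

test_that("REGR is the velocity derivative and integrates back to vf", {
  p1 <- c(vf = 0.2, x0 = 0.4, k = 9, n = 1)
  expect_equal(regr_profile(p1, 0.4), 0.2 * 9 / 4)  # logistic special case
  set.seed(202)
  for (i in 1:50) {
    p <- random_params()
    x <- runif(5, p[["x0"]] - 3 / p[["k"]], p[["x0"]] + 3 / p[["k"]])
    h <- 1e-6
    fd <- (velocity_model(p, x + h) - velocity_model(p, x - h)) / (2 * h)
    expect_equal(regr_profile(p, x), fd, tolerance = 1e-6)
    # tails vanish
    expect_lt(regr_profile(p, p[["x0"]] + 100 / p[["k"]]),
              1e-8 * p[["vf"]] * p[["k"]])
    expect_lt(regr_profile(p, p[["x0"]] - 100 / p[["k"]]),
              1e-8 * p[["vf"]] * p[["k"]])
    # conservation: integral of REGR across the zone ~ vf
    xx <- seq(p[["x0"]] - 50 / p[["k"]], p[["x0"]] + 50 / p[["k"]],
              length.out = 20001)
    rr <- regr_profile(p, xx)
    integral <- sum((rr[-1] + rr[-length(rr)]) / 2 * diff(xx))
    expect_equal(integral, unname(p[["vf"]]), tolerance = 1e-4)
  }
})

test_that("fitting recovers known parameters from clouds", {
  p <- c(vf = 0.2, x0 = 0.4, k = 9, n = 1.2)
  cl0 <- simulate_velocity_cloud(p, points = 120, noise_sd = 0, seed = 1)
  f0 <- fit_velocity_profile(cl0)
  expect_true(f0$converged)
  expect_equal(unname(f0$params), unname(p), tolerance = 1e-4)

  # modest Monte-Carlo check here; the full 200-seed study runs in the
  # acceptance suite
  errs <- vapply(1:30, function(s) {
    cl <- simulate_velocity_cloud(p, points = 120, noise_sd = 0.01, seed = s)
    f <- fit_velocity_profile(cl)
    abs(f$params[["vf"]] - p[["vf"]]) / p[["vf"]]
  }, numeric(1))
  expect_lt(median(errs), 0.02)

  expect_error(fit_velocity_profile(data.frame(x = 1:5 / 10, v = 1:5)),
               "at least 10")
  expect_error(fit_velocity_profile(data.frame(x = rep(0.3, 12),
                                               v = rnorm(12))), "degenerate")
})

test_that("outlier rejection refit tolerates gross contamination", {
  p <- c(vf = 0.2, x0 = 0.4, k = 9, n = 1)
  cl <- simulate_velocity_cloud(p, points = 120, noise_sd = 0.005, seed = 8)
  cl$v[c(5, 60)] <- cl$v[c(5, 60)] + 0.5
  f <- fit_velocity_profile(cl, reject_outliers = TRUE)
  expect_true(f$converged)
  expect_lt(f$n_points, 120)
  expect_equal(unname(f$params[["vf"]]), 0.2, tolerance = 0.02)
})

test_that("replicate parameters average arithmetically", {
  one <- c(vf = 0.2, x0 = 0.4, k = 9, n = 1)
  expect_equal(average_ril_params(list(one)), one)
  two <- average_ril_params(list(c(vf = 0.1, x0 = 0.3, k = 8, n = 0.9),
                                 c(vf = 0.3, x0 = 0.5, k = 10, n = 1.1)))
  expect_equal(unname(two), c(0.2, 0.4, 9, 1))
  set.seed(33)
  seven <- lapply(1:7, function(i) random_params())
  m <- do.call(rbind, seven)
  expect_equal(average_ril_params(seven), colMeans(m))  # column-means oracle
  expect_error(average_ril_params(list()), "non-empty")
})

test_that("trait closed forms agree with numeric argmax/max of REGR", {
  tr <- extract_traits(c(vf = 0.2, x0 = 0.4, k = 9, n = 1))
  expect_equal(unname(tr["elongation_rate"]), 0.2)
  expect_equal(unname(tr["regr_max_position"]), 0.4)
  expect_equal(unname(tr["regr_max"]), 45)   # 0.2*9/4 = 0.45/h = 45%/h
  # closed-form quadratic for the zone width at fraction 0.2, n = 1
  u <- c(9 + sqrt(80), 9 - sqrt(80))
  expect_equal(unname(tr["zone_length"]), log(u[1] / u[2]) / 9,
               tolerance = 1e-8)

  set.seed(404)
  for (i in 1:200) {
    p <- random_params()
    tr <- extract_traits(p)
    # numeric argmax oracle on a dense local grid + golden-section refine
    xx <- seq(p[["x0"]] - 8 / p[["k"]], p[["x0"]] + 8 / p[["k"]],
              length.out = 40001)
    j <- which.max(regr_profile(p, xx))
    opt <- optimize(function(x) regr_profile(p, x),
                    c(xx[max(1, j - 2)], xx[min(length(xx), j + 2)]),
                    maximum = TRUE, tol = 1e-12)
    expect_equal(unname(tr["regr_max_position"]), opt$maximum,
                 tolerance = 1e-6)
    expect_equal(unname(tr["regr_max"]), 100 * opt$objective,
                 tolerance = 1e-8)
    # zone width from the dense grid agrees with the root-found width
    inside <- xx[regr_profile(p, xx) >= 0.2 * opt$objective]
    width_grid <- diff(range(inside))
    expect_equal(unname(tr["zone_length"]), width_grid,
                 tolerance = 3 * diff(xx[1:2]) / width_grid)
  }
  expect_error(extract_traits(c(vf = 0.2, x0 = 0.4, k = 9, n = 1),
                              zone_fraction = 1.2), "zone_fraction")
})

test_that("traits from fitted parameters converge to truth as noise shrinks", {
  p <- c(vf = 0.22, x0 = 0.42, k = 11, n = 0.9)
  true_tr <- extract_traits(p)
  err <- vapply(c(0.02, 0.005, 0), function(sd) {
    cl <- simulate_velocity_cloud(p, points = 150, noise_sd = sd, seed = 77)
    max(abs(extract_traits(fit_velocity_profile(cl)$params) - true_tr) /
          abs(true_tr))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-12 | err[-1] < err[-3]))
  expect_lt(err[3], 1e-4)
})

test_that("per-RIL workflow fits replicates and tabulates traits", {
  p <- c(vf = 0.2, x0 = 0.4, k = 9, n = 1)
  clouds <- list(
    RIL_A = lapply(1:3, function(s) simulate_velocity_cloud(p, 60, 0.01, seed = s)),
    RIL_B = lapply(4:6, function(s) simulate_velocity_cloud(
      c(vf = 0.3, x0 = 0.5, k = 12, n = 1.1), 60, 0.01, seed = s))
  )
  tab <- ril_kinematic_traits(clouds)
  expect_identical(tab$ril, c("RIL_A", "RIL_B"))
  expect_true(all(tab$n_reps_used == 3))
  expect_equal(tab$vf, c(0.2, 0.3), tolerance = 0.05)
  expect_true(all(tab$zone_length > 0))
})
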