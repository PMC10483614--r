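test_that("pseudo-volume is area^(3/2) and strictly monotone", {
  expect_equal(pseudo_volume(0), 0)
  expect_equal(pseudo_volume(4), 8)
  expect_error(pseudo_volume(-1), "non-negative")
  set.seed(1)
  a <- sort(runif(50, 0, 1e5))
  expect_true(all(diff(pseudo_volume(a)) > 0))
})

test_that("exponential area fit recovers tau and T_d = 2/3 tau exactly", {
  s <- data.frame(time_days = 0:15, area_um2 = 100 * 2^(0:15 / 3))
  fit <- fit_growth(s)
  expect_equal(fit$tau, 3, tolerance = 1e-12)
  expect_equal(fit$T_d, 2, tolerance = 1e-12)
  expect_equal(fit$A0, 100, tolerance = 1e-10)
})

test_that("T_d / tau is identically 2/3 across random growth fits", {
  set.seed(5)
  for (i in 1:20) {
    tau <- runif(1, 0.8, 8); A0 <- runif(1, 50, 5000)
    t <- seq(0, 12, by = 0.5)
    noise <- exp(rnorm(length(t), 0, 0.03))
    fit <- fit_growth(data.frame(time_days = t,
                                 area_um2 = A0 * 2^(t / tau) * noise))
    expect_equal(fit$T_d / fit$tau, 2 / 3, tolerance = 1e-12)
  }
})

test_that("flat and shrinking area series leave T_d undefined", {
  flat <- fit_growth(data.frame(time_days = 0:5, area_um2 = rep(200, 6)))
  expect_equal(flat$tau, Inf)
  expect_true(is.na(flat$T_d))
  shrink <- fit_growth(data.frame(time_days = 0:5, area_um2 = 200 * 2^(-(0:5))))
  expect_true(is.na(shrink$T_d))
  expect_error(fit_growth(data.frame(time_days = 0:5,
                                     area_um2 = c(1, 2, 0, 4, 5, 6))),
               "positive")
})

test_that("doubling time recovery under 5% log-normal noise within 7% median", {
  set.seed(9)
  err <- replicate(100, {
    t <- 0:15
    a <- 100 * 2^(t / 3) * exp(rnorm(16, 0, 0.05))
    abs(fit_growth(data.frame(time_days = t, area_um2 = a))$T_d - 2) / 2
  })
  expect_lte(median(err), 0.07)
})

test_that("growth fit on simulated motility-off assays recovers T_d_true", {
  # area ~ sum n^(2/3): with no motion and no merging the area-doubling
  # timescale is (3/2) T_d_true, so the inferred T_d equals T_d_true
  cfg <- sim_config(mode = "directed", v0 = 0, T_d_true = 2, density = 15,
                    duration = 8, seed = 20)
  tr <- run_assay(cfg)
  expect_equal(nrow(tr$merges), 0)
  fit <- fit_growth(area_series(tr))
  expect_equal(fit$T_d, 2, tolerance = 0.10)
})

test_that("net growth rate: doubling, constant and decaying counts", {
  t <- seq(0, 96, by = 24)
  expect_equal(net_growth_rate(data.frame(time_h = t, count = 100 * 2^(t / 24))),
               log(2) / 24, tolerance = 1e-12)
  expect_equal(net_growth_rate(data.frame(time_h = t, count = rep(50, 5))), 0)
  expect_lt(net_growth_rate(data.frame(time_h = t, count = 100 * exp(-t / 50))),
            0)
  expect_error(net_growth_rate(data.frame(time_h = t, count = c(1, 2, 0, 4, 5))),
               "positive")
})

test_that("correlation matches the covariance-formula oracle", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(correlate_times(d, x, y)$r, 1, tolerance = 1e-12)

  d2 <- data.frame(x = c(-1, 0, 1, 0), y = c(0, 1, 0, -1))
  expect_equal(correlate_times(d2, x, y)$r, 0, tolerance = 1e-12)

  set.seed(3)
  d3 <- data.frame(x = rnorm(30), y = rnorm(30))
  manual <- sum((d3$x - mean(d3$x)) * (d3$y - mean(d3$y))) /
    sqrt(sum((d3$x - mean(d3$x))^2) * sum((d3$y - mean(d3$y))^2))
  expect_equal(correlate_times(d3, x, y)$r, manual, tolerance = 1e-12)
  expect_error(correlate_times(data.frame(x = rep(1, 5), y = 1:5), x, y),
               "variance")
})

test_that("frame alignment recovers integer and subpixel shifts", {
  set.seed(1)
  a <- matrix(rnorm(64 * 64), 64)
  expect_equal(align_frames(a, a), c(dy = 0, dx = 0))
  b <- shift_matrix(a, 5, -3)
  expect_equal(align_frames(a, b), c(dy = 5, dx = -3))

  # subpixel: Gaussian blob shifted by (2.5, -0.7)
  blob <- function(cy, cx) {
    y <- matrix(1:128, 128, 128); x <- t(y)
    exp(-((y - cy)^2 + (x - cx)^2) / 18)
  }
  off <- align_frames(blob(60, 64), blob(62.5, 63.3))
  expect_equal(unname(off[1]), 2.5, tolerance = 0.2 / 2.5)
  expect_lt(abs(off[2] - (-0.7)), 0.2)

  expect_warning(z <- align_frames(matrix(0, 8, 8), matrix(0, 8, 8)), "blank")
  expect_equal(z, c(dy = 0, dx = 0))
  expect_error(align_frames(matrix(0, 4, 4), matrix(0, 5, 5)), "shapes")
})

test_that("area velocity of a translated square is 2 L delta / lag", {
  L <- 40; delta <- 3; ps <- 1  # um
  sq <- function(x0) {
    m <- matrix(0L, 100, 100)
    m[30:(30 + L - 1), x0:(x0 + L - 1)] <- 1L
    class_mask(m, ps)
  }
  v <- area_velocity(sq(20), sq(20 + delta), lag = 3)
  expect_equal(v, 2 * L * delta / 3, tolerance = 1e-12)
  expect_equal(area_velocity(sq(20), sq(20), lag = 3), 0)
})

test_that("area velocity of a translated disk matches the lens-overlap oracle", {
  r_px <- 30; delta <- 4; ps <- 1
  m1 <- disk_image(120, 120, 60, 50, r_px)
  m2 <- disk_image(120, 120, 60, 50 + delta, r_px)
  v <- area_velocity(class_mask(matrix(as.integer(m1), 120, 120), ps),
                     class_mask(matrix(as.integer(m2), 120, 120), ps),
                     lag = 3)
  # exact circle-circle overlap geometry
  overlap <- 2 * r_px^2 * acos(delta / (2 * r_px)) -
    (delta / 2) * sqrt(4 * r_px^2 - delta^2)
  expected <- 2 * (pi * r_px^2 - overlap) / 3
  expect_equal(v, expected, tolerance = 0.02)
})

test_that("area velocity is symmetric and detects shape changes only", {
  set.seed(4)
  m1 <- class_mask(matrix(as.integer(runif(400) > 0.5), 20, 20), 2)
  m2 <- class_mask(matrix(as.integer(runif(400) > 0.5), 20, 20), 2)
  expect_equal(area_velocity(m1, m2), area_velocity(m2, m1))
  expect_error(area_velocity(m1, class_mask(matrix(0L, 10, 10), 2)), "shapes")
  # abs_diff variant: pure translation registers no area change
  sq <- matrix(0L, 50, 50); sq[10:20, 10:20] <- 1L
  sq2 <- matrix(0L, 50, 50); sq2[10:20, 15:25] <- 1L
  expect_equal(area_velocity(class_mask(sq, 1), class_mask(sq2, 1),
                             method = "abs_diff"), 0)
})
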