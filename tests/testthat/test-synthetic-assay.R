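test_that("seeding reproduces density: mean count and Poisson spacing", {
  # mean realised count at 31 cells/mm^3 in a 1 mm^3 box
  counts <- vapply(1:200, function(s) {
    nrow(seed_clusters(sim_config(density = 31, seed = s))$clusters)
  }, numeric(1))
  expect_equal(mean(counts), 31, tolerance = 0.05)

  # Monte-Carlo nearest-neighbour distance vs the Poisson closed form
  # 0.554 * rho^(-1/3); toroidal distances remove box-boundary bias
  box <- 1000
  nn <- unlist(lapply(1:300, function(s) {
    cl <- seed_clusters(sim_config(density = 90.4, seed = 10000 + s))$clusters
    if (nrow(cl) < 2) return(NULL)
    p <- cbind(cl$x, cl$y, cl$z)
    vapply(seq_len(nrow(p)), function(i) {
      d <- abs(sweep(p[-i, , drop = FALSE], 2, p[i, ]))
      d <- pmin(d, box - d)
      min(sqrt(rowSums(d^2)))
    }, numeric(1))
  }))
  expect_equal(mean(nn), expected_nn_distance(90.4), tolerance = 0.02)
  # 0.554 prefactor of the closed form itself
  expect_equal(expected_nn_distance(90.4), 0.554 * (90.4e-9)^(-1 / 3),
               tolerance = 1e-3)
})

test_that("seeding degenerate cases", {
  expect_equal(nrow(seed_clusters(sim_config(density = 0, seed = 1))$clusters), 0)
  expect_error(sim_config(box_edge = 0))
})

test_that("attractant field superposes point sources with analytic gradient", {
  st <- cluster_state(
    data.frame(id = 1:3, x = c(100, 600, 350), y = c(200, 500, 800),
               z = c(300, 400, 100), n_cells = c(1, 4, 9))
  )
  q <- c(500, 500, 500)
  f <- attractant_field(st, q, S = 2, D = 50)
  # term-by-term brute force
  cl <- st$clusters
  manual <- sum(2 * cl$n_cells /
                  (4 * pi * 50 * sqrt((q[1] - cl$x)^2 + (q[2] - cl$y)^2 +
                                        (q[3] - cl$z)^2)))
  expect_equal(f$concentration, manual, tolerance = 1e-12)

  # single source on the +x axis: gradient points back toward the source
  st1 <- cluster_state(data.frame(id = 1, x = 0, y = 0, z = 0, n_cells = 1))
  g <- attractant_field(st1, c(100, 0, 0))$gradient
  expect_true(g[1] < 0)
  expect_equal(g[2:3], c(0, 0))

  # two equal sources at +/- d: zero gradient at the midpoint
  st2 <- cluster_state(data.frame(id = 1:2, x = c(-100, 100), y = c(0, 0),
                                  z = c(0, 0), n_cells = c(1, 1)))
  expect_equal(attractant_field(st2, c(0, 0, 0))$gradient, c(0, 0, 0),
               tolerance = 1e-15)

  # singularity and own-source exclusion
  expect_error(attractant_field(st1, c(0, 0, 0)), "coincides")
  ex <- attractant_field(st2, c(-100, 0, 0), exclude_id = 1)
  expect_equal(ex$concentration, 1 / (4 * pi * 100 * 200))
})

test_that("directed step moves equal clusters toward each other at v0*dt", {
  cfg <- sim_config(mode = "directed", v0 = 2, dt = 0.5, density = 1,
                    T_d_true = 0, seed = 1)
  st <- cluster_state(data.frame(id = 1:2, x = c(400, 600), y = c(500, 500),
                                 z = c(500, 500), n_cells = c(1, 1)),
                      r_cell = 10)
  st2 <- step_clusters(st, cfg)
  expect_equal(sort(st2$clusters$x), c(401, 599))
  expect_equal(st2$clusters$y, c(500, 500))
})

test_that("merging conserves total cell count and is volume-conserving", {
  cfg <- sim_config(mode = "directed", v0 = 5, dt = 0.5, density = 1,
                    r_cell = 10, seed = 1)
  st <- cluster_state(data.frame(id = 1:2, x = c(490, 512), y = c(500, 500),
                                 z = c(500, 500), n_cells = c(3, 5)),
                      r_cell = 10)
  st2 <- step_clusters(st, cfg)
  expect_equal(nrow(st2$clusters), 1)
  expect_equal(st2$clusters$n_cells, 8)
  expect_equal(st2$clusters$radius, 2 * 10)  # 8 cells -> doubled radius
  mg <- attr(st2, "merges")
  expect_equal(nrow(mg), 1)
})

test_that("random-mode ensemble MSD matches 6*D_c*t", {
  # 1024 isolated walkers on a wide grid: no merges, no wall contact
  n_side <- 8; spacing <- 4000
  g <- expand.grid(x = 1:n_side, y = 1:n_side, z = 1:(1024 / n_side^2))
  start <- data.frame(id = seq_len(nrow(g)), x = g$x * spacing + 2000,
                      y = g$y * spacing + 2000, z = g$z * spacing + 1000,
                      n_cells = 1)
  cfg <- sim_config(box_edge = 70000, mode = "random", D_c = 100, dt = 0.5,
                    density = 1, seed = 99)
  st <- cluster_state(start, r_cell = 10, box_edge = 70000)
  set.seed(99)
  p0 <- cbind(start$x, start$y, start$z)
  for (k in 1:20) st <- step_clusters(st, cfg)
  expect_equal(nrow(st$clusters), nrow(start))  # nobody merged
  disp2 <- rowSums((cbind(st$clusters$x, st$clusters$y, st$clusters$z) - p0)^2)
  expect_equal(mean(disp2), 6 * 100 * 10, tolerance = 0.1)
})

test_that("two approaching clusters merge at the kinematic time g/(2 v0)", {
  v0 <- 2; gap <- 60  # surface gap, um
  cfg <- sim_config(mode = "directed", v0 = v0, dt = 0.5, density = 1,
                    r_cell = 10, seed = 1)
  st <- cluster_state(data.frame(id = 1:2, x = c(500 - gap / 2 - 10,
                                                 500 + gap / 2 + 10),
                                 y = c(500, 500), z = c(500, 500),
                                 n_cells = c(1, 1)), r_cell = 10)
  t_merge <- NA
  for (k in 1:200) {
    st <- step_clusters(st, cfg)
    if (nrow(st$clusters) == 1) { t_merge <- st$time_days * 24; break }
  }
  expect_equal(t_merge, gap / (2 * v0), tolerance = 0.04)  # one step of slack
})

test_that("static configs leave the count series constant", {
  cfg <- sim_config(mode = "directed", v0 = 0, T_d_true = 0, density = 30,
                    duration = 3, seed = 4)
  tr <- run_assay(cfg)
  expect_true(all(tr$frames$n_objects == tr$initial_count))
  expect_equal(aggregating_fraction(tr), 0)
})

test_that("growth multiplies total cell count by 2^(t/T_d)", {
  cfg <- sim_config(mode = "directed", v0 = 2, T_d_true = 2, density = 40,
                    duration = 6, seed = 11)
  tr <- run_assay(cfg)
  total_final <- sum(tr$final_state$clusters$n_cells)
  t_end <- max(tr$frames$time_days)
  expect_equal(total_final, tr$initial_count * 2^(t_end / 2),
               tolerance = 1e-10)
})

test_that("aggregating fraction follows the merge-log definition", {
  expect_equal(aggregating_fraction(fake_truth(4, integer(0))), 0)
  expect_equal(aggregating_fraction(fake_truth(4, c(1L, 2L))), 0.5)
  expect_equal(aggregating_fraction(fake_truth(3, c(1L, 2L, 3L))), 1)
  expect_error(aggregating_fraction(fake_truth(0, integer(0))), "empty")
})

test_that("identical config and seed give identical assay truth", {
  cfg <- sim_config(density = 31, duration = 5, mode = "directed", seed = 123)
  t1 <- run_assay(cfg)
  t2 <- run_assay(cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$merges, t2$merges)
  expect_identical(t1$final_state$clusters, t2$final_state$clusters)
})

test_that("crossing_time interpolates the half-count time", {
  s <- data.frame(time_days = 0:4, count = c(40, 40, 30, 18, 10))
  # crosses 20 between t=2 (30) and t=3 (18)
  expect_equal(crossing_time(s), 2 + (30 - 20) / (30 - 18))
  expect_true(is.na(crossing_time(data.frame(time_days = 0:4,
                                             count = rep(10, 5)))))
})
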