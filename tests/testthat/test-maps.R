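test_that("occupancy heat maps are normalized histograms", {
  pts <- data.frame(x = rep(0.225, 40), y = rep(0.125, 40))
  hm <- heat_map(pts, bin_size = 0.05)
  expect_equal(sum(hm$grid), 1, tolerance = 1e-12)
  expect_equal(max(hm$grid), 1)
  expect_equal(sum(hm$grid > 0), 1L)

  # uniform points: no bin deviates more than 5 Poisson SEs from uniform
  pts_u <- uniform_std_points(10000, seed = 5)
  hm_u <- heat_map(pts_u, bin_size = 0.1)
  expected <- 10000 / (30 * 10)
  dev <- abs(hm_u$counts - expected) / sqrt(expected)
  expect_lt(max(dev), 5)
  expect_equal(sum(hm_u$grid), 1, tolerance = 1e-12)
})

test_that("mirrored maps are exactly four-fold symmetric", {
  pts <- uniform_std_points(3000, seed = 11)
  hm <- heat_map(pts, bin_size = 0.1, mirrored = TRUE)
  expect_equal(sum(hm$grid), 1, tolerance = 1e-12)
  expect_identical(hm$grid, hm$grid[nrow(hm$grid):1, ])
  expect_identical(hm$grid, hm$grid[, ncol(hm$grid):1])

  cfg <- simulation_config(states = data.frame(D = 0.15, fraction = 1),
                           n_tracks = 100, bleach_prob = 0.06, seed = 2)
  ts <- simulate_tracks(cfg)
  ts$tracks$x <- ts$tracks$x - 1.5   # into standardized coordinates
  ts$tracks$y <- ts$tracks$y - 0.5
  sm <- binned_speed_map(ts, bin_size = 0.1, mirrored = TRUE)
  g <- sm$grid
  expect_identical(g, g[nrow(g):1, ])
  expect_identical(g, g[, ncol(g):1])
})

test_that("speed maps average single-step apparent diffusion per bin", {
  # one step of 0.2 um at dt 0.04: d_app = 0.25 um^2/s at the midpoint
  ts <- make_ts(list(cbind(c(-0.1, 0.1), c(0, 0))), dt = 0.04)
  sm <- binned_speed_map(ts, bin_size = 0.1)
  expect_equal(sum(sm$counts), 1)
  expect_equal(sm$grid[!is.na(sm$grid)], 0.2^2 / (4 * 0.04))
  # empty bins are missing, never zero
  expect_true(anyNA(sm$grid))
  expect_false(any(sm$grid == 0, na.rm = TRUE))

  # weighting consistency: global mean equals plain mean of step d_app
  cfg <- simulation_config(states = data.frame(D = 0.1, fraction = 1),
                           n_tracks = 150, bleach_prob = 0.06, seed = 3)
  ts2 <- simulate_tracks(cfg)
  ts2$tracks$x <- ts2$tracks$x - 1.5
  ts2$tracks$y <- ts2$tracks$y - 0.5
  sm2 <- binned_speed_map(ts2, bin_size = 0.1)
  wmean <- sum(sm2$grid * sm2$counts, na.rm = TRUE) / sum(sm2$counts)
  expect_equal(wmean, attr(sm2, "global_mean"), tolerance = 1e-9)
})

test_that("uniform-mobility simulations give flat speed maps", {
  cfg <- simulation_config(states = data.frame(D = 0.1, fraction = 1),
                           n_tracks = 600, bleach_prob = 0.05, seed = 19,
                           boundary = "none")
  ts <- simulate_tracks(cfg)
  ts$tracks$x <- ts$tracks$x - 1.5
  ts$tracks$y <- ts$tracks$y - 0.5
  sm <- binned_speed_map(ts, bin_size = 0.1)
  ok <- !is.na(sm$grid) & sm$counts >= 20
  # per-bin mean of r^2/(4dt) has SE ~ mean/sqrt(n); allow 4 SE
  dev <- abs(sm$grid[ok] - attr(sm, "global_mean")) /
    (attr(sm, "global_mean") / sqrt(sm$counts[ok]))
  expect_lt(stats::quantile(dev, 0.99), 4)
})

test_that("membrane-shell simulations show slower boundary bins", {
  ok_runs <- vapply(1:10, function(s) {
    cfg <- simulation_config(states = data.frame(D = 0.3, fraction = 1),
                             shell = list(thickness = 0.15, D = 0.03),
                             n_tracks = 250, bleach_prob = 0.05, seed = s)
    ts <- simulate_tracks(cfg)
    ts$tracks$x <- ts$tracks$x - 1.5
    ts$tracks$y <- ts$tracks$y - 0.5
    sm <- binned_speed_map(ts, bin_size = 0.1)
    shell_bin <- abs(row(sm$grid) - (nrow(sm$grid) + 1) / 2) >
      (nrow(sm$grid) / 2 - 1) |
      abs(col(sm$grid) - (ncol(sm$grid) + 1) / 2) > (ncol(sm$grid) / 2 - 1)
    mean(sm$grid[shell_bin], na.rm = TRUE) <
      mean(sm$grid[!shell_bin], na.rm = TRUE)
  }, logical(1))
  expect_true(all(ok_runs))
})

test_that("distances to reference presets match closed forms and brute force", {
  pts <- data.frame(x = c(0, 1.5, -1.5, 0.7), y = c(0, 0, 0, 0.2))
  expect_equal(distance_to_references(pts, "midcell")$distances[1], 0)
  expect_equal(distance_to_references(pts, "poles")$distances[2:3], c(0, 0))

  # membrane preset vs brute-force distance over dense boundary points
  set.seed(7)
  q <- data.frame(x = runif(4000, -1.5, 1.5), y = runif(4000, -0.5, 0.5))
  res <- distance_to_references(q, "membrane")
  tb <- rbind(cbind(seq(-1.5, 1.5, by = 0.002), -0.5),
              cbind(seq(-1.5, 1.5, by = 0.002), 0.5),
              cbind(-1.5, seq(-0.5, 0.5, by = 0.002)),
              cbind(1.5, seq(-0.5, 0.5, by = 0.002)))
  brute <- vapply(seq_len(200), function(i)
    min(sqrt((tb[, 1] - q$x[i])^2 + (tb[, 2] - q$y[i])^2)), numeric(1))
  expect_equal(res$distances[1:200], brute, tolerance = 0.02)
  expect_lt(abs(median(res$distances[1:200]) - median(brute)) /
              median(brute), 0.02)

  custom <- distance_to_references(pts, refs = cbind(c(0, 1), c(0, 0)))
  expect_equal(custom$distances[1], 0)
  expect_error(distance_to_references(pts, refs = matrix(0, 0, 2)),
               "non-empty")
})
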