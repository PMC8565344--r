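test_that("trajectory simulation obeys the step-variance law", {
  # zero-mobility state without noise: all steps vanish
  cfg0 <- simulation_config(states = data.frame(D = 0, fraction = 1),
                            n_tracks = 30, bleach_prob = 0.1, seed = 1)
  d0 <- compute_displacements(simulate_tracks(cfg0))
  expect_equal(max(abs(c(d0$dx, d0$dy))), 0)

  # free diffusion: mean r^2/(4 dt) within 2 SE of D
  cfg <- simulation_config(states = data.frame(D = 0.1, fraction = 1),
                           n_tracks = 1200, bleach_prob = 0.1,
                           boundary = "none", seed = 2)
  d <- compute_displacements(simulate_tracks(cfg))
  est <- d$r^2 / (4 * 0.04)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.1), 2 * se)

  # per-axis variance = 2 D dt + 2 sigma_loc^2 within 3 SE, per state
  cfg2 <- simulation_config(states = data.frame(D = c(0.05, 0.4),
                                                fraction = c(0.5, 0.5)),
                            sigma_loc = 0.02, n_tracks = 900,
                            bleach_prob = 0.1, boundary = "none", seed = 3)
  ts2 <- simulate_tracks(cfg2)
  truth <- attr(ts2, "truth")
  for (st in 1:2) {
    per <- split(ts2$tracks, ts2$tracks$track_id)
    steps <- unlist(lapply(per, function(tr) {
      s <- truth$state[truth$track_id == tr$track_id[1]]
      dx <- diff(tr$x)
      dx[s[-length(s)] == st]
    }))
    v_exp <- 2 * cfg2$states$D[st] * 0.04 + 2 * 0.02^2
    se_v <- sd(steps^2) / sqrt(length(steps))
    expect_lt(abs(mean(steps^2) - v_exp), 3 * se_v)
  }
})

test_that("simulation is reproducible and respects geometry and filters", {
  cfg <- simulation_config(n_tracks = 50, seed = 42)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(attr(a, "truth"), attr(b, "truth"))

  # reflecting boundary keeps true positions inside the rod box
  truth <- attr(a, "truth")
  expect_true(all(truth$x_true >= 0 & truth$x_true <= 3))
  expect_true(all(truth$y_true >= 0 & truth$y_true <= 1))

  # every retained track has at least min_steps displacements
  n_by <- table(a$tracks$track_id)
  expect_true(all(n_by >= cfg$min_steps + 1))

  expect_error(simulation_config(cell_length = 0.5, cell_width = 1),
               "impossible geometry")
  expect_error(simulation_config(states = data.frame(D = 0.1,
                                                     fraction = 0.7)),
               "sum to 1")
})

test_that("Markov switching converges to the stationary occupancy", {
  Q <- matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE)  # rates 1<->2 per second
  # stationary distribution of the embedded per-frame chain
  P <- Q * 0.04; diag(P) <- 1 - rowSums(P)
  pi_st <- Re(eigen(t(P))$vectors[, 1]); pi_st <- pi_st / sum(pi_st)
  cfg <- simulation_config(states = data.frame(D = c(0.02, 0.3),
                                               fraction = pi_st),
                           switch_rates = Q, n_tracks = 500,
                           bleach_prob = 0.02, max_steps = 200, seed = 8)
  truth <- attr(simulate_tracks(cfg), "truth")
  occ <- mean(truth$state == 1)
  se <- sqrt(pi_st[1] * (1 - pi_st[1]) / length(unique(truth$track_id)))
  expect_lt(abs(occ - pi_st[1]), 3 * se)
})

test_that("rendered movies conserve photons and honour bleaching", {
  # single molecule, no noise, flat field: frame-0 integral = photons
  cfg <- movie_config(n_molecules = 1, n_frames = 3, noise = FALSE,
                      background = 0, autofluor = 0, bleach_prob = 1e-9,
                      seed = 5)
  mv <- simulate_movie(cfg)
  expect_equal(sum(mv$data[, , 1]), cfg$photons, tolerance = 1e-6)

  # no molecules: constant background field
  cfg0 <- movie_config(n_molecules = 0, n_frames = 2, noise = FALSE,
                       autofluor = 0, seed = 1)
  mv0 <- simulate_movie(cfg0, cells = list())
  expect_true(all(mv0$data == cfg0$background))

  # bleach_prob = 1: all fluorophores emit only in frame 0
  cfg1 <- movie_config(n_molecules = 20, n_frames = 3, noise = FALSE,
                       background = 0, autofluor = 0, bleach_prob = 1,
                       seed = 2)
  mv1 <- simulate_movie(cfg1)
  expect_gt(sum(mv1$data[, , 1]), 0)
  expect_equal(sum(mv1$data[, , 2]), 0)

  # photon conservation before noise across many molecules
  cfgN <- movie_config(n_molecules = 50, n_frames = 1, noise = FALSE,
                       background = 10, autofluor = 0, bleach_prob = 1e-9,
                       seed = 3)
  mvN <- simulate_movie(cfgN)
  expect_equal(sum(mvN$data[, , 1]),
               50 * cfgN$photons + 10 * 48 * 48, tolerance = 1e-6)
})

test_that("movies round-trip through 16-bit TIFF", {
  cfg <- movie_config(n_molecules = 3, n_frames = 4, seed = 6)
  mv <- simulate_movie(cfg)
  f <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mv, f)
  back <- read_movie_tiff(f, pixel_size = cfg$pixel_size)
  expect_equal(dim(back$data), dim(mv$data))
  expect_lt(max(abs(back$data - pmin(pmax(round(mv$data), 0), 65535))), 0.51)
})

test_that("dwell-duration generator matches its mixture moments", {
  d <- simulate_dwell_durations(20000, taus = c(0.18, 0.43),
                                fractions = c(0.824, 0.176), cutoff = 0.16,
                                seed = 2)
  m_exp <- 0.16 + 0.824 * 0.18 + 0.176 * 0.43
  expect_lt(abs(mean(d) - m_exp), 3 * sd(d) / sqrt(length(d)))
  expect_true(all(d >= 0.16))
})
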