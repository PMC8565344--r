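test_that("illumination profiles are recovered from blank movies", {
  # spatially flat blank: profile identically 1
  flat <- array(100, c(32, 32, 12))
  prof <- estimate_illumination(flat, smooth_sigma = 5)
  expect_equal(as.numeric(prof), rep(1, 32 * 32), tolerance = 1e-12)

  # synthetic vignette: recovered profile correlates with the truth
  cx <- (seq_len(48) - 24.5)
  g <- exp(-outer(cx^2, cx^2, "+") / (2 * 30^2))
  truth <- g / mean(g)
  cfg <- movie_config(n_molecules = 0, n_frames = 30, illumination = g,
                      autofluor = 0, seed = 4)
  blank <- simulate_movie(cfg, cells = list())
  est <- estimate_illumination(blank)
  expect_gt(stats::cor(as.numeric(est), as.numeric(truth)), 0.99)
  expect_equal(mean(est), 1, tolerance = 1e-9)

  # division then multiplication restores the image
  img <- matrix(runif(48 * 48, 50, 200), 48)
  expect_equal(as.numeric(img / est * est), as.numeric(img),
               tolerance = 1e-9)

  expect_error(estimate_illumination(array(1, c(8, 8, 5))), ">= 10")
})

test_that("autofluorescence is measured as in-cell excess per pixel", {
  cell <- rect_cell(cx = 2.54, cy = 2.54)
  prof <- flat_profile(48)

  # in-cell equals background: excess 0
  same <- array(80, c(48, 48, 12))
  af0 <- estimate_autofluorescence(same, list(cell), prof, 0.106)
  expect_equal(af0$per_px, 0, tolerance = 1e-12)

  # synthetic cells at background + 50 per px
  cfg <- movie_config(n_molecules = 0, n_frames = 25, autofluor = 50,
                      background = 100, seed = 9)
  nofp <- simulate_movie(cfg)
  af <- estimate_autofluorescence(nofp, nofp$cells, prof, 0.106)
  expect_lt(abs(af$per_px - 50), 2)
  expect_lt(abs(af$background_px - 100), 1)

  expect_error(estimate_autofluorescence(same, list(), prof, 0.106),
               "empty cell list")
})

test_that("spot photometry integrates fluxes and clamps negatives", {
  cfg <- movie_config(n_molecules = 1, n_frames = 2, noise = FALSE,
                      background = 0, autofluor = 0, photons = 1000,
                      bleach_prob = 1e-9, seed = 3)
  mv <- simulate_movie(cfg)
  pos <- data.frame(x_px = mv$truth$x_px, y_px = mv$truth$y_px)
  i1 <- integrate_spot_intensities(mv$data, pos, radius_px = 3,
                                   profile = flat_profile(48),
                                   background_px = 0)
  expect_gt(i1 / 1000, 0.95)    # enclosed energy of the 3-px disc

  # uniform background is removed by the background term
  cfgb <- movie_config(n_molecules = 1, n_frames = 2, background = 40,
                       autofluor = 0, photons = 1000, bleach_prob = 1e-9,
                       seed = 5)
  mvb <- simulate_movie(cfgb)
  ib <- integrate_spot_intensities(mvb$data,
    data.frame(x_px = mvb$truth$x_px, y_px = mvb$truth$y_px),
    3, flat_profile(48), 40)
  expect_lt(abs(ib - i1), 4 * sqrt(29 * 2 * (40 + 35)))

  # zero-flux position on empty background: exactly 0 after clamping
  zero <- integrate_spot_intensities(array(0, c(48, 48, 1)),
    data.frame(x_px = 24, y_px = 24), 3, flat_profile(48), 0)
  expect_equal(as.numeric(zero), 0)

  expect_warning(integrate_spot_intensities(mv$data,
    data.frame(x_px = 1, y_px = 1), 3, flat_profile(48), 0),
    "out-of-bounds")
})

test_that("unit-intensity mixtures recover the reference dimer calibration", {
  set.seed(12)
  n <- 2000
  comp <- rbinom(n, 1, 0.32)
  ints <- ifelse(comp == 1, rnorm(n, 11326, 1500), rnorm(n, 5284, 900))
  fit <- fit_unit_intensity(ints, k = 2)
  expect_lt(abs(fit$I1 - 5284) / 5284, 0.05)
  expect_lt(abs(fit$I2 - 11326) / 11326, 0.05)
  expect_lt(abs(fit$prop2 - 0.32), 0.05)
  expect_true(fit$dimer_consistent)
  expect_equal(fit$ratio, 11326 / 5284, tolerance = 0.1)

  # single-population data: BIC prefers one component
  ints1 <- rnorm(1500, 5000, 600)
  f1 <- fit_unit_intensity(ints1, k = 1)
  f2 <- fit_unit_intensity(ints1, k = 2)
  expect_lt(f1$bic, f2$bic)

  expect_warning(fid <- fit_unit_intensity(rep(1000, 200), k = 1),
                 "zero-variance")
  expect_equal(fid$I1, 1000)
  expect_error(fit_unit_intensity(rnorm(50, 100, 5), k = 2,
                                  min_spots = 100), ">= 100")
})

test_that("noiseless non-overlapping movies count exactly up to ten molecules", {
  prof <- flat_profile(48)
  for (seed in 1:6) {
    N <- 2 + (seed %% 3) * 4   # 2, 6, 10
    cell <- rect_cell(cx = 2.54, cy = 2.54)
    con <- interior_constellation(N, seed)
    xs <- con$x; ys <- con$y
    cfg <- movie_config(n_molecules = 0, n_frames = 60, noise = FALSE,
                        background = 0, autofluor = 0, photons = 1000,
                        bleach_prob = 1e-9, seed = seed)
    mv <- simulate_movie(cfg)
    for (m in seq_len(N)) {   # render the chosen constellation by hand
      p <- sptkit:::.psf_patch(xs[m] / 0.106, ys[m] / 0.106, 1, 48, 48)
      for (f in seq_len(60)) mv$data[p$i, p$j, f] <-
          mv$data[p$i, p$j, f] + 1000 * p$patch
    }
    res <- count_molecules(mv, cell, prof, 0, unit = 1000,
                           pixel_size = 0.106,
                           positions = data.frame(x_px = xs / 0.106,
                                                  y_px = ys / 0.106))
    expect_equal(round(res$raw), N)
    expect_equal(res$corrected, res$raw)  # below the bias threshold
  }
})

test_that("the bias correction applies the +15% rule above the threshold", {
  # raw 400 -> corrected 460, raw below 20 untouched
  cfg <- movie_config(n_molecules = 0, n_frames = 25, noise = FALSE,
                      background = 0, autofluor = 0, seed = 1)
  mv <- simulate_movie(cfg)
  mv$data[20:29, 20:29, ] <- 4e5 / 100  # flat block of intensity
  cellpx <- cell_geometry(cbind(c(1.9, 3.2, 3.2, 1.9),
                                c(1.9, 1.9, 3.2, 3.2)))
  res <- count_molecules(mv, cellpx, flat_profile(48), 0, unit = 1000,
                         pixel_size = 0.106, method = "intensity")
  expect_equal(res$raw, 400, tolerance = 1e-6)
  expect_equal(res$corrected, 460, tolerance = 1e-6)

  # counting is linear: doubling brightness and I1 leaves counts unchanged
  mv2 <- mv; mv2$data <- mv$data * 2
  res2 <- count_molecules(mv2, cellpx, flat_profile(48), 0, unit = 2000,
                          pixel_size = 0.106, method = "intensity")
  expect_equal(res2$raw, res$raw, tolerance = 1e-9)
})

test_that("bleaching curves estimate the decay rate and the regime index", {
  cfg <- movie_config(n_molecules = 50, n_frames = 250, bleach_prob = 0.02,
                      seed = 21)
  mv <- simulate_movie(cfg)
  bg <- cfg$background + cfg$autofluor *
    sptkit:::cell_mask(mv$cells, 48, 48, 0.106)
  bc <- bleaching_curve(mv, mv$cells[[1]], flat_profile(48), bg, 0.106,
                        I1 = 500 * 0.987)
  expect_lt(abs(attr(bc, "rate") - 0.02) / 0.02, 0.15)
  expect_true(is.finite(attr(bc, "regime_index")))
  # fitted remaining molecules at the regime index is near the threshold
  expect_lt(abs(bc$fitted[attr(bc, "regime_index") + 1] / (500 * 0.987)
                - 1.5), 0.5)

  # constant series: warning and no regime index
  flatm <- array(100, c(48, 48, 120))
  expect_warning(bc0 <- bleaching_curve(flatm, mv$cells[[1]],
    flat_profile(48), 0, 0.106, I1 = 500), "does not decay")
  expect_true(is.na(attr(bc0, "regime_index")))

  # zero movie: flat zero curve
  z <- array(0, c(48, 48, 120))
  bcz <- suppressWarnings(bleaching_curve(z, mv$cells[[1]],
    flat_profile(48), 0, 0.106))
  expect_true(all(bcz$intensity == 0))
})

test_that("high-density counting underestimates and the correction compensates", {
  # compact density sweep with the calibration pooled across movies (as
  # spots are pooled across cells in practice): spot photometry is
  # near-exact at low N, where spots stay resolvable, and systematically
  # low at high N, where merged and missed spots lose flux
  run_sweep <- function(N, seeds) {
    movs <- lapply(seeds, function(s)
      simulate_movie(movie_config(n_molecules = N, n_frames = 400,
                                  seed = 1000 * s + N)))
    blank <- simulate_movie(movie_config(n_molecules = 0, autofluor = 0,
             n_frames = 15, seed = N + 11), cells = list())
    nofp <- simulate_movie(movie_config(n_molecules = 0, n_frames = 15,
            seed = N + 13))
    profile <- estimate_illumination(blank)
    af <- estimate_autofluorescence(nofp, movs[[1]]$cells, profile, 0.106)
    mask <- sptkit:::cell_mask(movs[[1]]$cells, 48, 48, 0.106)
    bg <- matrix(af$background_px, 48, 48) + max(af$per_px, 0) * mask
    ints <- unlist(lapply(movs, function(mv) suppressWarnings(
      collect_unit_intensities(mv, mv$cells, profile, bg, 0.106))))
    unit <- fit_unit_intensity(sptkit:::.trim_to_monomer_peak(ints),
                               k = 1, min_spots = 20)
    vapply(movs, function(mv) {
      res <- suppressWarnings(count_molecules(mv, mv$cells, profile, bg,
                                              unit, 0.106))
      c(raw = (N - res$raw) / N, corr = (N - res$corrected) / N)
    }, numeric(2))
  }
  low <- run_sweep(5, 1:4)
  high <- run_sweep(60, 1:4)
  expect_lt(abs(mean(low["raw", ])), 0.08)
  expect_gt(mean(high["raw", ]), 0.05)      # systematic underestimation
  expect_gt(mean(high["raw", ]) - mean(low["raw", ]), 0.03)
  # the +15% adjustment moves high-density counts toward the truth
  expect_lt(abs(mean(high["corr", ])), abs(mean(high["raw", ])))
})
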