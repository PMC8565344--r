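## Fluorescence-based molecule counting.
##
## Pipeline: divide out the illumination profile (from a blank movie),
## subtract extracellular background and cell autofluorescence (from a
## no-fluorophore movie), calibrate the integrated intensity of a single
## fluorophore from late-movie single-molecule spots, then convert the
## bleaching-corrected initial in-cell fluorescence of each cell into a
## molecule number.

# accept an sm_movie, a [ny, nx, frames] array, or a TIFF path
as_movie_array <- function(movie) {
  if (inherits(movie, "sm_movie")) return(movie$data)
  if (is.character(movie)) return(read_movie_tiff(movie)$data)
  if (is.array(movie) && length(dim(movie)) == 3L) return(movie)
  if (is.matrix(movie)) return(array(movie, c(dim(movie), 1L)))
  stop("cannot interpret movie input", call. = FALSE)
}

# separable Gaussian blur with edge renormalization (matrix-operator form)
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  op <- function(n) {
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma)
    K / rowSums(K)
  }
  op(nrow(img)) %*% img %*% t(op(ncol(img)))
}

#' Estimate the illumination profile from a blank movie
#'
#' Temporal median of a movie acquired without cells, heavily smoothed and
#' normalized to mean 1.  Dividing a data movie by this profile flattens
#' uneven (e.g. slim-field) illumination.
#'
#' @param blank_movie movie with no cells (`sm_movie`, array or TIFF path),
#'   at least 10 frames.
#' @param smooth_sigma Gaussian smoothing scale in pixels (default 10).
#' @param saturation pixel value treated as saturated (flagged, default
#'   65535).
#' @return an `illumination_profile`: positive matrix with mean 1;
#'   attribute `"n_saturated"` counts flagged pixels.
#' @export
estimate_illumination <- function(blank_movie, smooth_sigma = 10,
                                  saturation = 65535) {
  a <- as_movie_array(blank_movie)
  if (dim(a)[3L] < 10L)
    stop("need >= 10 blank frames (got ", dim(a)[3L], ")", call. = FALSE)
  n_sat <- sum(a >= saturation)
  med <- apply(a, c(1L, 2L), stats::median)
  sm <- .gauss_blur(med, smooth_sigma)
  if (any(sm <= 0))
    stop("illumination profile has non-positive values", call. = FALSE)
  prof <- sm / mean(sm)
  structure(prof, n_saturated = n_sat, class = c("illumination_profile",
                                                 class(prof)))
}

# logical in-cell mask on the pixel grid; pixel (i, j) center is at
# ((j - 0.5) * pixel_size, (i - 0.5) * pixel_size) in micrometre
cell_mask <- function(cells, ny, nx, pixel_size) {
  if (inherits(cells, "cell_geometry")) cells <- list(cells)
  cx <- (rep(seq_len(nx), each = ny) - 0.5) * pixel_size
  cy <- (rep(seq_len(ny), times = nx) - 0.5) * pixel_size
  m <- rep(FALSE, nx * ny)
  for (cg in cells) m <- m | points_in_cell(cx, cy, cg)
  matrix(m, ny, nx)
}

#' Estimate cell autofluorescence from a no-fluorophore movie
#'
#' After illumination division, compares the mean in-cell intensity of
#' cells expressing no fluorescent protein with the extracellular
#' background, yielding the autofluorescence excess per pixel (difference
#' model) and the in/out ratio.
#'
#' @param nofp_movie movie of cells without any fluorescent-protein fusion.
#' @param cells list of `cell_geometry` (micrometre frame of the field).
#' @param profile an `illumination_profile`.
#' @param pixel_size micrometre per pixel.
#' @param n_frames_avg frames averaged (default first 10).
#' @return list with `per_px` (autofluorescence per in-cell pixel),
#'   `background_px` (extracellular level), `ratio` (in/out), `n_cell_px`.
#' @export
estimate_autofluorescence <- function(nofp_movie, cells, profile,
                                      pixel_size, n_frames_avg = 10L) {
  a <- as_movie_array(nofp_movie)
  if (length(cells) == 0L) stop("empty cell list", call. = FALSE)
  nf <- min(dim(a)[3L], n_frames_avg)
  mimg <- apply(a[, , seq_len(nf), drop = FALSE], c(1L, 2L), mean) / profile
  mask <- cell_mask(cells, nrow(mimg), ncol(mimg), pixel_size)
  if (!any(mask)) stop("no cell pixel in the field", call. = FALSE)
  inside <- mean(mimg[mask])
  outside <- mean(mimg[!mask])
  list(per_px = inside - outside, background_px = outside,
       ratio = inside / outside, n_cell_px = sum(mask))
}

#' Extracellular background of a data movie
#'
#' Mean corrected intensity over all non-cell pixels of the first frames.
#'
#' @inheritParams estimate_autofluorescence
#' @param movie the fluorescence movie to measure.
#' @return background level per pixel (corrected units).
#' @export
estimate_background <- function(movie, cells, profile, pixel_size,
                                n_frames_avg = 10L) {
  a <- as_movie_array(movie)
  nf <- min(dim(a)[3L], n_frames_avg)
  mimg <- apply(a[, , seq_len(nf), drop = FALSE], c(1L, 2L), mean) / profile
  mask <- cell_mask(cells, nrow(mimg), ncol(mimg), pixel_size)
  if (all(mask)) stop("no extracellular pixel in the field", call. = FALSE)
  mean(mimg[!mask])
}

# disc pixel offsets: pixels whose center lies within radius of the spot
.disc_pixels <- function(x_px, y_px, radius_px, ny, nx) {
  j0 <- floor(x_px - radius_px):ceiling(x_px + radius_px)
  i0 <- floor(y_px - radius_px):ceiling(y_px + radius_px)
  g <- expand.grid(i = i0 + 1L, j = j0 + 1L)
  cx <- g$j - 0.5; cy <- g$i - 0.5
  keep <- (cx - x_px)^2 + (cy - y_px)^2 <= radius_px^2 &
    g$i >= 1L & g$i <= ny & g$j >= 1L & g$j <= nx
  g[keep, , drop = FALSE]
}

#' Integrate spot intensities in a fixed-radius disc
#'
#' For each spot position, sums the illumination-corrected, background-
#' subtracted pixel values within a disc of `radius_px` pixels centred on
#' the position (in the spot's frame).  Negative integrals are clamped to 0
#' and counted; spots whose disc would leave the image are skipped with a
#' warning.
#'
#' @param movie movie input.
#' @param positions data.frame with `x_px`, `y_px` (pixel units, origin at
#'   the image corner) and optionally `frame` (0-based; default 0).
#' @param radius_px disc radius in pixels (default 3).
#' @param profile an `illumination_profile`.
#' @param background_px background to subtract: a scalar level, or a
#'   per-pixel matrix (extracellular background plus the in-cell
#'   autofluorescence excess).
#' @return numeric vector of integrated intensities; attributes
#'   `"n_clamped"` and `"skipped"` (row indices).
#' @export
integrate_spot_intensities <- function(movie, positions, radius_px = 3L,
                                       profile, background_px = 0) {
  a <- as_movie_array(movie)
  ny <- dim(a)[1L]; nx <- dim(a)[2L]
  if (is.null(positions$frame)) positions$frame <- 0L
  out <- numeric(nrow(positions))
  skipped <- integer(0)
  n_clamped <- 0L
  for (s in seq_len(nrow(positions))) {
    xp <- positions$x_px[s]; yp <- positions$y_px[s]
    if (xp - radius_px < 0 || xp + radius_px > nx ||
        yp - radius_px < 0 || yp + radius_px > ny) {
      skipped <- c(skipped, s)
      out[s] <- NA_real_
      next
    }
    px <- .disc_pixels(xp, yp, radius_px, ny, nx)
    f <- positions$frame[s] + 1L
    vals <- a[cbind(px$i, px$j, f)] / profile[cbind(px$i, px$j)]
    bg <- if (is.matrix(background_px)) background_px[cbind(px$i, px$j)]
          else background_px
    v <- sum(vals - bg)
    if (v < 0) { v <- 0; n_clamped <- n_clamped + 1L }
    out[s] <- v
  }
  if (length(skipped) > 0L)
    warning(length(skipped), " out-of-bounds spot(s) skipped")
  structure(out[setdiff(seq_along(out), skipped)],
            n_clamped = n_clamped, skipped = skipped)
}

#' Simple difference-of-Gaussians spot detector
#'
#' Plumbing detector for movies without upstream tracking positions: a
#' band-pass (difference of Gaussians) image is thresholded at
#' `threshold_sd` robust standard deviations and 3x3 local maxima are
#' returned.  Deliberately simple; a dedicated tracker's detections are
#' preferable when available.
#'
#' @param img single frame (matrix, already illumination-corrected).
#' @param sigma_small,sigma_large DoG scales in pixels.
#' @param threshold_sd detection threshold in robust SD units of the DoG
#'   image.
#' @return data.frame with `x_px`, `y_px` (pixel-center coordinates) and
#'   `dog` (band-pass amplitude).
#' @export
detect_spots <- function(img, sigma_small = 1, sigma_large = 2,
                         threshold_sd = 5) {
  dog <- .gauss_blur(img, sigma_small) - .gauss_blur(img, sigma_large)
  # noise floor from the band-pass image; tiny guard for noiseless input
  thr <- threshold_sd * max(stats::mad(dog), 1e-6 * max(abs(dog), 1e-12))
  ny <- nrow(dog); nx <- ncol(dog)
  keep <- matrix(FALSE, ny, nx)
  core_i <- 2:(ny - 1L); core_j <- 2:(nx - 1L)
  m <- dog[core_i, core_j]
  is_max <- m > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max & (m >= dog[core_i + di, core_j + dj])
  }
  keep[core_i, core_j] <- is_max
  idx <- which(keep, arr.ind = TRUE)
  data.frame(x_px = idx[, 2L] - 0.5, y_px = idx[, 1L] - 0.5,
             dog = dog[idx])
}

#' Fit the unit (single-fluorophore) intensity
#'
#' 1- or 2-component Gaussian mixture on integrated spot intensities.  With
#' two components the ratio `I2/I1` is reported and flagged
#' dimer-consistent when it falls in \[1.7, 2.3\] (a second population at
#' about twice the monomer intensity indicates two-molecule spots).
#'
#' @param intensities integrated spot intensities (camera units).
#' @param k 1 or 2 components.
#' @param min_spots minimum sample size (default 100).
#' @return a `unit_intensity_fit`: `I1`, `I2`, `prop1`, `prop2`, `ratio`,
#'   `dimer_consistent`, `n_spots`, `bic` (smaller is better), `k`.
#' @export
fit_unit_intensity <- function(intensities, k = 2L, min_spots = 100L) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  if (length(x) < min_spots)
    stop("need >= ", min_spots, " spots (got ", length(x), ")", call. = FALSE)
  k <- as.integer(k)
  if (!k %in% 1:2) stop("k must be 1 or 2", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("zero-variance intensity sample")
    return(structure(list(I1 = x[1L], I2 = NA_real_, prop1 = 1,
                          prop2 = NA_real_, ratio = NA_real_,
                          dimer_consistent = FALSE, n_spots = length(x),
                          bic = NA_real_, k = 1L),
                     class = "unit_intensity_fit"))
  }
  mc <- mclust::Mclust(x, G = k, modelNames = if (k == 1L) "E" else "V",
                       verbose = FALSE)
  if (is.null(mc)) stop("unit-intensity fit did not converge", call. = FALSE)
  mu <- as.numeric(mc$parameters$mean)
  pro <- as.numeric(mc$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; pro <- pro[ord]
  I1 <- mu[1L]
  I2 <- if (k == 2L) mu[2L] else NA_real_
  ratio <- if (k == 2L) I2 / I1 else NA_real_
  structure(list(I1 = I1, I2 = I2, prop1 = pro[1L],
                 prop2 = if (k == 2L) pro[2L] else NA_real_,
                 ratio = ratio,
                 dimer_consistent = isTRUE(ratio >= 1.7 && ratio <= 2.3),
                 n_spots = length(x), bic = -as.numeric(mc$bic), k = k),
            class = "unit_intensity_fit")
}

#' @export
print.unit_intensity_fit <- function(x, ...) {
  cat(sprintf("Unit-intensity fit (%d spots, k = %d)\n", x$n_spots, x$k))
  cat(sprintf("  I1 = %.4g (%.0f%%)", x$I1, 100 * x$prop1))
  if (x$k == 2L)
    cat(sprintf("  I2 = %.4g (%.0f%%)  ratio = %.2f%s", x$I2,
                100 * x$prop2, x$ratio,
                if (x$dimer_consistent) " [dimer-consistent]" else ""))
  cat("\n")
  invisible(x)
}

# background-subtracted in-cell intensity per frame over a pixel set
.series_over_pixels <- function(a, profile, pix, background_px, frames) {
  bg <- if (is.matrix(background_px)) background_px[cbind(pix$i, pix$j)]
        else background_px
  vapply(frames, function(f) {
    vals <- a[cbind(pix$i, pix$j, f + 1L)] / profile[cbind(pix$i, pix$j)]
    sum(vals - bg)
  }, numeric(1))
}

.fit_exp_decay <- function(frames, s) {
  pos <- s > 0
  if (sum(pos) < 3L) return(NULL)
  lf <- stats::lm(log(s[pos]) ~ frames[pos])
  start <- c(log(max(exp(stats::coef(lf)[1L]), 1e-9)),
             min(max(-stats::coef(lf)[2L], 1e-6), 2))
  resid_fn <- function(p) s - exp(p[1L]) * exp(-p[2L] * frames)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  rate <- fit$par[2L]
  if (abs(rate) < 1e-8) rate <- 0   # constant series: no decay, no failure
  list(A = exp(fit$par[1L]), rate = rate)
}

#' Bleaching curve of one cell
#'
#' Background-subtracted, illumination-corrected total in-cell intensity
#' per frame, with a single-exponential decay fit.  When the unit intensity
#' `I1` is supplied, the single-molecule-regime index is the first frame
#' where the fitted expected number of remaining fluorophores drops to
#' `regime_threshold` (default 1.5).
#'
#' @param movie movie input.
#' @param cell a `cell_geometry`.
#' @param profile an `illumination_profile`.
#' @param background_px per-pixel non-fluorophore level inside the cell
#'   (extracellular background + autofluorescence excess).
#' @param pixel_size micrometre per pixel.
#' @param I1 unit intensity (optional).
#' @param regime_threshold expected remaining fluorophores defining the
#'   single-molecule regime.
#' @return a `bleaching_curve`: data.frame `frame`, `intensity`, `fitted`;
#'   attributes `rate` (per frame), `A` (fitted frame-0 intensity),
#'   `regime_index` (NA without `I1` or for a non-decaying series).
#' @export
bleaching_curve <- function(movie, cell, profile, background_px,
                            pixel_size, I1 = NULL, regime_threshold = 1.5) {
  a <- as_movie_array(movie)
  nfr <- dim(a)[3L]
  if (nfr < 100L) stop("need >= 100 frames (got ", nfr, ")", call. = FALSE)
  mask <- cell_mask(cell, dim(a)[1L], dim(a)[2L], pixel_size)
  if (!any(mask)) stop("cell outside the field", call. = FALSE)
  pix <- which(mask, arr.ind = TRUE)
  pix <- data.frame(i = pix[, 1L], j = pix[, 2L])
  frames <- 0:(nfr - 1L)
  s <- .series_over_pixels(a, profile, pix, background_px, frames)
  fit <- .fit_exp_decay(frames, s)
  decaying <- !is.null(fit) && fit$rate > 0
  if (!decaying)
    warning("intensity series does not decay; no single-molecule regime")
  fitted <- if (is.null(fit)) rep(NA_real_, nfr)
            else fit$A * exp(-fit$rate * frames)
  regime <- NA_integer_
  if (decaying && !is.null(I1) && is.finite(I1) && I1 > 0) {
    hit <- which(fitted / I1 <= regime_threshold)
    if (length(hit) > 0L) regime <- frames[hit[1L]]
  }
  structure(data.frame(frame = frames, intensity = s, fitted = fitted),
            rate = if (is.null(fit)) NA_real_ else fit$rate,
            A = if (is.null(fit)) NA_real_ else fit$A,
            regime_index = regime,
            class = c("bleaching_curve", "data.frame"))
}

#' Harvest single-molecule spot intensities from a movie tail
#'
#' Collects the integrated intensities used for unit-intensity
#' calibration.  The single-molecule tail is located operationally by
#' scanning frames backwards from the movie end and keeping the maximal
#' suffix with at most three in-cell detections per frame; spots in that
#' tail are integrated, and same-frame neighbours closer than two aperture
#' radii are dropped (their discs would share flux).  Samples from several
#' movies of the same acquisition can be pooled before fitting.
#'
#' @inheritParams bleaching_curve
#' @param cells list of `cell_geometry`.
#' @param radius_px integration disc radius.
#' @param threshold_sd spot-detection threshold.
#' @return numeric vector of integrated intensities, with the first tail
#'   frame as attribute `"tail_start"`.
#' @export
collect_unit_intensities <- function(movie, cells, profile, background_px,
                                     pixel_size, radius_px = 3L,
                                     threshold_sd = 5) {
  a <- as_movie_array(movie)
  nfr <- dim(a)[3L]
  if (inherits(cells, "cell_geometry")) cells <- list(cells)
  mask <- cell_mask(cells, dim(a)[1L], dim(a)[2L], pixel_size)

  collect_spots <- function(frames) {
    rows <- lapply(frames, function(f) {
      img <- a[, , f + 1L] / profile
      sp <- detect_spots(img, threshold_sd = threshold_sd)
      if (nrow(sp) == 0L) return(NULL)
      # keep spots whose center pixel is inside a cell
      ci <- ceiling(sp$y_px + 0.5); cj <- ceiling(sp$x_px + 0.5)
      inside <- mask[cbind(ci, cj)]
      sp <- sp[inside, , drop = FALSE]
      if (nrow(sp) == 0L) return(NULL)
      sp$frame <- f
      sp
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0L) NULL else do.call(rbind, rows)
  }

  # provisional single-molecule tail: scan backwards from the movie end,
  # keeping the maximal suffix of frames with few in-cell detections
  sp_by_frame <- vector("list", nfr)
  tail_start <- nfr
  violations <- 0L
  for (f in rev(seq_len(nfr) - 1L)) {
    sp_f <- collect_spots(f)
    n_f <- if (is.null(sp_f)) 0L else nrow(sp_f)
    if (n_f > 3L) {   # tolerate isolated busy frames, stop when persistent
      violations <- violations + 1L
      if (violations >= 3L || n_f > 8L) break
      next
    }
    sp_by_frame[[f + 1L]] <- sp_f
    tail_start <- f
  }
  sp <- do.call(rbind, Filter(Negate(is.null), sp_by_frame))
  if (is.null(sp) || nrow(sp) == 0L)
    stop("no spot detected in the single-molecule tail", call. = FALSE)
  if (nrow(sp) > 1L) {
    # isolation criterion: drop spots with a same-frame neighbour closer
    # than two aperture radii (their discs would share flux)
    iso <- vapply(seq_len(nrow(sp)), function(s) {
      same <- setdiff(which(sp$frame == sp$frame[s]), s)
      if (length(same) == 0L) return(TRUE)
      min(sqrt((sp$x_px[same] - sp$x_px[s])^2 +
                 (sp$y_px[same] - sp$y_px[s])^2)) > 2 * radius_px
    }, logical(1))
    if (sum(iso) >= 10L) sp <- sp[iso, , drop = FALSE]
  }
  ints <- suppressWarnings(integrate_spot_intensities(
    a, sp, radius_px, profile, background_px))
  ints <- ints[is.finite(ints) & ints > 0]
  structure(ints, tail_start = tail_start)
}

# monomer-peak trim: keep intensities around the leftmost prominent mode,
# so that coincident two-molecule spots cannot drag the calibration upward
.trim_to_monomer_peak <- function(ints) {
  if (length(ints) < 10L) return(ints)
  dens <- stats::density(ints, n = 512)
  y <- dens$y
  is_peak <- which(diff(sign(diff(y))) == -2) + 1L
  is_peak <- is_peak[y[is_peak] >= 0.25 * max(y)]
  peak <- if (length(is_peak) > 0L) dens$x[min(is_peak)]
          else dens$x[which.max(y)]
  ints[ints > 0.5 * peak & ints < 1.5 * peak]
}

#' Self-calibration of the unit intensity from a movie
#'
#' Harvests single-molecule tail intensities
#' ([collect_unit_intensities()]), trims them around the monomer peak of
#' the intensity distribution (only for `k = 1`; with `k = 2` the second,
#' two-molecule component is itself of interest), and fits the
#' unit-intensity mixture.
#'
#' @inheritParams collect_unit_intensities
#' @param k components for the final [fit_unit_intensity()].
#' @param min_spots floor passed to [fit_unit_intensity()].
#' @return list with `unit` (a `unit_intensity_fit`), `regime_index`
#'   (first tail frame), `intensities`, `curves` (per-cell bleaching
#'   curves).
#' @export
calibrate_unit_intensity <- function(movie, cells, profile, background_px,
                                     pixel_size, k = 1L, radius_px = 3L,
                                     min_spots = 20L, threshold_sd = 5) {
  if (inherits(cells, "cell_geometry")) cells <- list(cells)
  ints <- collect_unit_intensities(movie, cells, profile, background_px,
                                   pixel_size, radius_px, threshold_sd)
  tail_start <- attr(ints, "tail_start")
  if (k == 1L) ints <- .trim_to_monomer_peak(as.numeric(ints))
  unit <- fit_unit_intensity(ints, k = k, min_spots = min_spots)
  curves <- lapply(cells, function(cg)
    bleaching_curve(movie, cg, profile, background_px, pixel_size,
                    I1 = unit$I1))
  list(unit = unit, regime_index = tail_start, intensities = ints,
       curves = curves)
}

#' Count molecules per cell from a fluorescence movie
#'
#' The initial (frame-0) fluorophore-derived intensity of each cell is
#' estimated by fitting an exponential bleaching decay over the first
#' `t0_window` frames and extrapolating to frame 0; dividing by the
#' calibrated monomer intensity `I1` gives the raw fluorophore count.  Raw
#' counts at or above `bias_threshold` are adjusted upward by
#' `bias_factor` (default +15%), compensating the systematic
#' underestimation of spot photometry at high copy numbers.
#'
#' Routes: `"aperture"` (default) is spot photometry, summing the union of
#' fixed-radius discs centred on the frame-0 spot positions (supplied from
#' upstream tracking via `positions`, or detected in-package).  It is
#' near-exact at low copy numbers, because the discs recover the PSF tails
#' that spill across the cell outline, but at high density merged and
#' undetected spots lose flux, producing the systematic underestimation
#' that the bias correction compensates.  `"intensity"` sums the whole
#' cell mask instead (insensitive to crowding, but it forfeits the
#' boundary spill); `"auto"` uses aperture photometry only while the
#' whole-cell estimate is at most `aperture_max_spots` molecules.
#'
#' @inheritParams bleaching_curve
#' @param cells list of `cell_geometry`.
#' @param unit a `unit_intensity_fit` (or a bare number taken as `I1`).
#' @param bias_threshold raw count from which the bias correction applies.
#' @param bias_factor fractional upward correction (default 0.15).
#' @param t0_window frames used for the frame-0 extrapolation.
#' @param method counting route per cell.
#' @param positions optional data.frame (`x_px`, `y_px`) of frame-0 spot
#'   centres from an upstream tracker; when absent, [detect_spots()] is
#'   used.
#' @param aperture_max_spots largest whole-cell estimate for which the
#'   aperture route is kept in `"auto"` mode.
#' @param radius_px aperture disc radius.
#' @param threshold_sd spot-detection threshold.
#' @return a `count_result`: data.frame `cell_id`, `route`, `n_spots_t0`,
#'   `raw`, `corrected`; attributes `mean_raw`, `mean_corrected`, `unit`.
#' @export
count_molecules <- function(movie, cells, profile, background_px, unit,
                            pixel_size, bias_threshold = 20,
                            bias_factor = 0.15, t0_window = 20L,
                            method = c("aperture", "intensity", "auto"),
                            positions = NULL,
                            aperture_max_spots = 10L, radius_px = 3L,
                            threshold_sd = 5) {
  method <- match.arg(method)
  a <- as_movie_array(movie)
  if (inherits(cells, "cell_geometry")) cells <- list(cells)
  I1 <- if (inherits(unit, "unit_intensity_fit")) unit$I1 else as.numeric(unit)
  if (!is.finite(I1) || I1 <= 0) stop("invalid unit intensity", call. = FALSE)
  ny <- dim(a)[1L]; nx <- dim(a)[2L]
  frames <- seq_len(min(t0_window, dim(a)[3L])) - 1L

  rows <- lapply(cells, function(cg) {
    mask <- cell_mask(cg, ny, nx, pixel_size)
    sp <- if (is.null(positions)) {
      detect_spots(a[, , 1L] / profile, threshold_sd = threshold_sd)
    } else positions
    if (nrow(sp) > 0L) {
      ci <- pmin(pmax(ceiling(sp$y_px + 0.5), 1L), ny)
      cj <- pmin(pmax(ceiling(sp$x_px + 0.5), 1L), nx)
      sp <- sp[mask[cbind(ci, cj)], , drop = FALSE]
    }
    n_spots <- nrow(sp)

    estimate_over <- function(pix, what) {
      s <- .series_over_pixels(a, profile, pix, background_px, frames)
      fit <- .fit_exp_decay(frames, s)
      if (is.null(fit) || fit$rate < 0) {
        warning("bleaching fit failed for cell '", cg$cell_id, "' (", what,
                " route); using first-frame intensity")
        s[1L]
      } else fit$A
    }
    mask_pix <- { w <- which(mask, arr.ind = TRUE)
                  data.frame(i = w[, 1L], j = w[, 2L]) }
    aperture_pix <- function() {
      keep <- matrix(FALSE, ny, nx)
      for (s in seq_len(n_spots)) {
        d <- .disc_pixels(sp$x_px[s], sp$y_px[s], radius_px, ny, nx)
        keep[cbind(d$i, d$j)] <- TRUE
      }
      w <- which(keep, arr.ind = TRUE)
      data.frame(i = w[, 1L], j = w[, 2L])
    }

    if (method == "aperture" && n_spots == 0L)
      return(data.frame(cell_id = cg$cell_id, route = "aperture",
                        n_spots_t0 = 0L, raw = 0, corrected = 0))
    raw_mask <- if (method != "aperture")
      max(estimate_over(mask_pix, "intensity") / I1, 0) else NA_real_
    # the aperture route is only trustworthy at low density, where the
    # discs tile the cell loosely; gate it on the cell's own estimate
    use_aperture <- switch(method,
      intensity = FALSE,
      aperture = TRUE,
      auto = n_spots >= 1L && raw_mask <= aperture_max_spots)
    if (use_aperture) {
      raw <- max(estimate_over(aperture_pix(), "aperture") / I1, 0)
      route <- "aperture"
    } else {
      raw <- raw_mask
      route <- "intensity"
    }
    corrected <- if (raw >= bias_threshold) raw * (1 + bias_factor) else raw
    data.frame(cell_id = cg$cell_id, route = route, n_spots_t0 = n_spots,
               raw = raw, corrected = corrected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, mean_raw = mean(out$raw),
            mean_corrected = mean(out$corrected), unit = unit,
            class = c("count_result", "data.frame"))
}

#' Full counting pipeline on one field
#'
#' Convenience orchestration: illumination profile from the blank movie,
#' autofluorescence from the no-fluorophore movie, extracellular background
#' from the data movie, unit-intensity self-calibration, then per-cell
#' molecule counts.
#'
#' @param fp_movie data movie (cells expressing the fluorophore fusion).
#' @param blank_movie movie without cells.
#' @param nofp_movie movie of cells without fluorophore.
#' @param cells list of `cell_geometry`.
#' @param pixel_size micrometre per pixel.
#' @param unit_k components for the unit-intensity fit.
#' @param unit optional precomputed `unit_intensity_fit` (e.g. pooled over
#'   several movies); skips self-calibration.
#' @param ... passed to [count_molecules()].
#' @return list with `counts` (a `count_result`), `unit`, `profile`,
#'   `background_px`, `autofluorescence`.
#' @export
count_pipeline <- function(fp_movie, blank_movie, nofp_movie, cells,
                           pixel_size, unit_k = 1L, unit = NULL, ...) {
  profile <- estimate_illumination(blank_movie)
  af <- estimate_autofluorescence(nofp_movie, cells, profile, pixel_size)
  # background from the no-fluorophore field: the data movie's own
  # extracellular pixels carry PSF spill from in-cell fluorophores, which
  # would bias the background upward in proportion to the copy number
  bg_out <- af$background_px
  a <- as_movie_array(fp_movie)
  mask <- cell_mask(cells, dim(a)[1L], dim(a)[2L], pixel_size)
  # per-pixel non-fluorophore level: extracellular background everywhere,
  # plus the autofluorescence excess inside cells
  bg_map <- matrix(bg_out, dim(a)[1L], dim(a)[2L]) + max(af$per_px, 0) * mask
  if (is.null(unit)) {
    cal <- calibrate_unit_intensity(fp_movie, cells, profile, bg_map,
                                    pixel_size, k = unit_k)
    unit <- cal$unit
    regime <- cal$regime_index
  } else regime <- NA_integer_
  counts <- count_molecules(fp_movie, cells, profile, bg_map, unit,
                            pixel_size, ...)
  list(counts = counts, unit = unit, profile = profile,
       background_px = bg_out, autofluorescence = af,
       regime_index = regime, background_map = bg_map)
}
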