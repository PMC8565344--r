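## Ground-truthed synthetic data: multi-state Brownian trajectories in a
## rod-cell box, and rendered single-molecule movies with uneven
## illumination, autofluorescence and stepwise bleaching.

#' Trajectory simulation configuration
#'
#' Defines the conditions of a tracking simulation: rod-cell size, the
#' diffusive states (coefficient and occupancy), optional Markov switching,
#' localization noise, frame interval, bleaching-limited track lengths and
#' the boundary rule.
#'
#' @param states data.frame with columns `D` (micrometre^2/s) and
#'   `fraction` (summing to 1).
#' @param cell_length,cell_width rod-cell box in micrometre.
#' @param switch_rates optional k x k matrix of per-second transition rates
#'   (off-diagonal; diagonal ignored).  `NULL` for static states.
#' @param sigma_loc localization error SD per axis (micrometre).
#' @param dt frame interval (seconds, default 0.04).
#' @param bleach_prob per-frame bleaching probability, setting the
#'   geometric track-length distribution.
#' @param n_tracks number of tracks to generate (before length filtering).
#' @param min_steps minimum steps per retained track (default 5).
#' @param max_steps cap on track length in steps.
#' @param boundary `"reflect"` for specular reflection at the cell wall,
#'   `"none"` for free (unconfined) diffusion.
#' @param shell optional two-zone override: `list(thickness =, D =)` uses
#'   `D` whenever the current true position lies within `thickness` of the
#'   cell wall (membrane shell), regardless of state.
#' @param seed RNG seed.
#' @param condition condition label for the output `track_set`.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(states = data.frame(D = c(0.031, 0.3),
                                                  fraction = c(0.482, 0.518)),
                              cell_length = 3, cell_width = 1,
                              switch_rates = NULL, sigma_loc = 0,
                              dt = 0.04, bleach_prob = 0.02,
                              n_tracks = 200L, min_steps = 5L,
                              max_steps = 500L,
                              boundary = c("reflect", "none"),
                              shell = NULL, seed = 1L,
                              condition = "simulated") {
  boundary <- match.arg(boundary)
  stopifnot(is.data.frame(states), all(c("D", "fraction") %in% names(states)))
  if (any(states$D < 0) || any(states$fraction < 0))
    stop("states must have D >= 0 and fraction >= 0", call. = FALSE)
  if (abs(sum(states$fraction) - 1) > 1e-9)
    stop("state fractions must sum to 1", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (bleach_prob <= 0 || bleach_prob > 1)
    stop("bleach_prob must be in (0, 1]", call. = FALSE)
  if (cell_width > cell_length)
    stop("impossible geometry: width > length", call. = FALSE)
  if (!is.null(switch_rates)) {
    switch_rates <- as.matrix(switch_rates)
    k <- nrow(states)
    if (!all(dim(switch_rates) == k) || any(switch_rates[row(switch_rates) !=
                                                         col(switch_rates)] < 0))
      stop("switch_rates must be a k x k nonnegative rate matrix",
           call. = FALSE)
    if (any(rowSums(switch_rates * (1 - diag(k))) * dt > 1))
      stop("switching rates too large for dt", call. = FALSE)
  }
  structure(list(states = states, cell_length = cell_length,
                 cell_width = cell_width, switch_rates = switch_rates,
                 sigma_loc = sigma_loc, dt = dt, bleach_prob = bleach_prob,
                 n_tracks = as.integer(n_tracks),
                 min_steps = as.integer(min_steps),
                 max_steps = as.integer(max_steps), boundary = boundary,
                 shell = shell, seed = as.integer(seed),
                 condition = condition),
            class = "simulation_config")
}

# specular fold of coordinate z into [0, L]
.reflect_into <- function(z, L) {
  m <- abs(z) %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

#' Simulate multi-state Brownian trajectories
#'
#' Each track starts uniformly in the rod-cell box, in a state drawn from
#' the configured fractions; steps are Gaussian with per-axis variance
#' `2 D dt` (per the current state, or the shell override), reflected
#' specularly at the cell wall; the observed positions add Gaussian
#' localization noise; track length is geometric (bleaching-limited),
#' capped at `max_steps`, and tracks shorter than `min_steps` steps are
#' dropped.  Fully reproducible from the seed.
#'
#' @param cfg a [simulation_config()].
#' @return a `track_set` with attributes `truth` (data.frame `track_id`,
#'   `frame`, `state`, `x_true`, `y_true`) and `config`.
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  k <- nrow(cfg$states)
  P <- if (is.null(cfg$switch_rates)) NULL else {
    Q <- cfg$switch_rates
    diag(Q) <- 0
    P <- Q * cfg$dt
    diag(P) <- 1 - rowSums(P)
    P
  }
  L <- cfg$cell_length; W <- cfg$cell_width
  lens <- pmin(stats::rgeom(cfg$n_tracks, cfg$bleach_prob) + 1L,
               cfg$max_steps)
  keep <- lens >= cfg$min_steps
  pieces <- vector("list", cfg$n_tracks)
  truth <- vector("list", cfg$n_tracks)
  # dropped tracks are still simulated so that the RNG stream (and thus
  # every retained track) is independent of the retention pattern
  for (t in seq_len(cfg$n_tracks)) {
    n_steps <- lens[t]
    n_pts <- n_steps + 1L
    state <- integer(n_pts)
    state[1L] <- sample.int(k, 1L, prob = cfg$states$fraction)
    x <- numeric(n_pts); y <- numeric(n_pts)
    x[1L] <- stats::runif(1L, 0, L)
    y[1L] <- stats::runif(1L, 0, W)
    for (i in seq_len(n_steps)) {
      D <- cfg$states$D[state[i]]
      if (!is.null(cfg$shell)) {
        d_wall <- min(x[i], L - x[i], y[i], W - y[i])
        if (d_wall <= cfg$shell$thickness) D <- cfg$shell$D
      }
      s <- sqrt(2 * D * cfg$dt)
      nx <- x[i] + stats::rnorm(1L, 0, s)
      ny <- y[i] + stats::rnorm(1L, 0, s)
      if (cfg$boundary == "reflect") {
        nx <- .reflect_into(nx, L)
        ny <- .reflect_into(ny, W)
      }
      x[i + 1L] <- nx; y[i + 1L] <- ny
      state[i + 1L] <- if (is.null(P)) state[i]
                       else sample.int(k, 1L, prob = P[state[i], ])
    }
    if (!keep[t]) next
    id <- sprintf("sim%05d", t)
    xo <- x + stats::rnorm(n_pts, 0, cfg$sigma_loc)
    yo <- y + stats::rnorm(n_pts, 0, cfg$sigma_loc)
    pieces[[t]] <- data.frame(track_id = id, frame = 0:(n_pts - 1L),
                              x = xo, y = yo, stringsAsFactors = FALSE)
    truth[[t]] <- data.frame(track_id = id, frame = 0:(n_pts - 1L),
                             state = state, x_true = x, y_true = y,
                             stringsAsFactors = FALSE)
  }
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L)
    stop("no track survived the length filter", call. = FALSE)
  ts <- track_set(do.call(rbind, pieces), dt = cfg$dt,
                  condition = cfg$condition,
                  source = sprintf("simulate_tracks(seed=%d)", cfg$seed))
  attr(ts, "truth") <- do.call(rbind, Filter(Negate(is.null), truth))
  attr(ts, "config") <- cfg
  ts
}

#' Movie simulation configuration
#'
#' Conditions for rendering a synthetic single-molecule movie: field and
#' pixel geometry, Gaussian PSF width, per-fluorophore photon flux,
#' extracellular background and in-cell autofluorescence, illumination
#' profile, stepwise bleaching and the camera noise model (Poisson photon
#' noise with the EM-CCD excess factor approximated by doubling the Poisson
#' variance, plus Gaussian read noise).
#'
#' @param n_molecules fluorophores per cell.
#' @param nx,ny image size in pixels.
#' @param pixel_size micrometre per pixel.
#' @param psf_sigma_px Gaussian PSF sigma in pixels (>= 0.5).
#' @param photons expected photons per fluorophore per frame.
#' @param background extracellular background photons per pixel per frame.
#' @param autofluor additional in-cell autofluorescence photons per pixel.
#' @param read_noise Gaussian read noise SD (counts).
#' @param bleach_prob per-frame bleaching probability.
#' @param n_frames frames to render.
#' @param illumination `"flat"`, `"gaussian"` (centered vignette), or a
#'   `ny x nx` matrix (mean 1).
#' @param emccd double the Poisson variance (EM-CCD excess noise).
#' @param noise apply photon/read noise at all (off for analytic
#'   fixtures).
#' @param seed RNG seed.
#' @return a `movie_config`.
#' @export
movie_config <- function(n_molecules = 50L, nx = 48L, ny = 48L,
                         pixel_size = 0.106, psf_sigma_px = 1,
                         photons = 500, background = 20, autofluor = 5,
                         read_noise = 2, bleach_prob = 0.02,
                         n_frames = 600L, illumination = "flat",
                         emccd = TRUE, noise = TRUE, seed = 1L) {
  if (psf_sigma_px < 0.5) stop("psf_sigma_px must be >= 0.5", call. = FALSE)
  stopifnot(nx > 0, ny > 0, pixel_size > 0, photons >= 0, background >= 0,
            autofluor >= 0, read_noise >= 0, n_frames >= 1,
            bleach_prob > 0, bleach_prob <= 1)
  structure(list(n_molecules = as.integer(n_molecules), nx = as.integer(nx),
                 ny = as.integer(ny), pixel_size = pixel_size,
                 psf_sigma_px = psf_sigma_px, photons = photons,
                 background = background, autofluor = autofluor,
                 read_noise = read_noise, bleach_prob = bleach_prob,
                 n_frames = as.integer(n_frames),
                 illumination = illumination, emccd = emccd, noise = noise,
                 seed = as.integer(seed)),
            class = "movie_config")
}

#' Default centered rod cell for a movie field
#'
#' A 3 x 1 micrometre rectangle centered in the field.
#'
#' @param cfg a `movie_config`.
#' @param length,width cell dimensions in micrometre.
#' @param cell_id identifier.
#' @return a `cell_geometry`.
#' @export
centered_cell <- function(cfg, length = 3, width = 1, cell_id = "cell1") {
  cx <- cfg$nx * cfg$pixel_size / 2
  cy <- cfg$ny * cfg$pixel_size / 2
  cell_geometry(cbind(cx + c(-1, 1, 1, -1) * length / 2,
                      cy + c(-1, -1, 1, 1) * width / 2),
                cell_id = cell_id)
}

# pixel-integrated Gaussian PSF patch for a molecule at (x_px, y_px)
.psf_patch <- function(x_px, y_px, sigma, nx, ny, half = NULL) {
  if (is.null(half)) half <- ceiling(5 * sigma)
  jc <- round(x_px); ic <- round(y_px)
  js <- max(1L, jc - half):min(nx, jc + half + 1L)
  is <- max(1L, ic - half):min(ny, ic + half + 1L)
  fx <- stats::pnorm(js, x_px, sigma) - stats::pnorm(js - 1, x_px, sigma)
  fy <- stats::pnorm(is, y_px, sigma) - stats::pnorm(is - 1, y_px, sigma)
  list(i = is, j = js, patch = outer(fy, fx))
}

#' Render a synthetic single-molecule movie
#'
#' Places `n_molecules` fluorophores uniformly inside each cell, renders
#' them as pixel-integrated Gaussian PSFs scaled by the photon flux,
#' bleaches each in a single step at a geometric frame, multiplies the
#' illumination profile, adds in-cell autofluorescence and extracellular
#' background, and applies the camera noise model.
#'
#' @param cfg a [movie_config()].
#' @param cells list of `cell_geometry` (default one [centered_cell()]).
#' @return an `sm_movie`: list with `data` (`ny x nx x n_frames` array),
#'   `pixel_size`, `cells`, `config`, and `truth` (data.frame `mol_id`,
#'   `cell_id`, `x_um`, `y_um`, `x_px`, `y_px`, `bleach_frame`; a molecule
#'   emits in frames `0..bleach_frame`).
#' @export
simulate_movie <- function(cfg, cells = NULL) {
  stopifnot(inherits(cfg, "movie_config"))
  set.seed(cfg$seed)
  if (is.null(cells)) cells <- list(centered_cell(cfg))
  if (inherits(cells, "cell_geometry")) cells <- list(cells)
  nx <- cfg$nx; ny <- cfg$ny; ps <- cfg$pixel_size

  illum <- if (is.matrix(cfg$illumination)) {
    cfg$illumination / mean(cfg$illumination)
  } else if (identical(cfg$illumination, "gaussian")) {
    cx <- (seq_len(nx) - 0.5 - nx / 2); cy <- (seq_len(ny) - 0.5 - ny / 2)
    g <- exp(-outer(cy^2, cx^2, "+") / (2 * (0.6 * max(nx, ny))^2))
    g / mean(g)
  } else matrix(1, ny, nx)

  mask <- cell_mask(cells, ny, nx, ps)

  # uniform placement inside each cell polygon (rejection in the bbox)
  truth <- do.call(rbind, lapply(cells, function(cg) {
    if (cfg$n_molecules == 0L) return(NULL)
    bb <- apply(cg$polygon, 2L, range)
    pts <- matrix(numeric(0), 0L, 2L)
    while (nrow(pts) < cfg$n_molecules) {
      m <- 4L * cfg$n_molecules
      cand <- cbind(stats::runif(m, bb[1L, 1L], bb[2L, 1L]),
                    stats::runif(m, bb[1L, 2L], bb[2L, 2L]))
      cand <- cand[points_in_cell(cand[, 1L], cand[, 2L], cg), , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts <- pts[seq_len(cfg$n_molecules), , drop = FALSE]
    data.frame(cell_id = cg$cell_id, x_um = pts[, 1L], y_um = pts[, 2L])
  }))
  n_mol <- if (is.null(truth)) 0L else nrow(truth)
  if (n_mol > 0L) {
    truth$mol_id <- seq_len(n_mol)
    truth$x_px <- truth$x_um / ps
    truth$y_px <- truth$y_um / ps
    truth$bleach_frame <- stats::rgeom(n_mol, cfg$bleach_prob)
  }

  base <- cfg$background + cfg$autofluor * mask
  movie <- array(0, c(ny, nx, cfg$n_frames))

  # start from the full signal image and subtract molecules as they bleach
  signal <- matrix(0, ny, nx)
  patches <- vector("list", n_mol)
  if (n_mol > 0L) {
    for (m in seq_len(n_mol)) {
      p <- .psf_patch(truth$x_px[m], truth$y_px[m], cfg$psf_sigma_px, nx, ny)
      patches[[m]] <- p
      signal[p$i, p$j] <- signal[p$i, p$j] + cfg$photons * p$patch
    }
  }
  bleach_at <- if (n_mol > 0L) split(seq_len(n_mol), truth$bleach_frame + 1L)
               else list()
  for (f in seq_len(cfg$n_frames)) {
    lam <- illum * (base + signal)
    frame <- if (cfg$noise) {
      counts <- if (cfg$emccd) 2 * stats::rpois(length(lam), lam / 2)
                else stats::rpois(length(lam), lam)
      matrix(counts, ny, nx) +
        stats::rnorm(length(lam), 0, cfg$read_noise)
    } else lam
    movie[, , f] <- frame
    gone <- bleach_at[[as.character(f)]]
    if (!is.null(gone)) {
      for (m in gone) {
        p <- patches[[m]]
        signal[p$i, p$j] <- signal[p$i, p$j] - cfg$photons * p$patch
      }
    }
  }
  structure(list(data = movie, pixel_size = ps, cells = cells,
                 config = cfg, truth = truth, illumination = illum),
            class = "sm_movie")
}

#' @export
print.sm_movie <- function(x, ...) {
  cat(sprintf("Synthetic movie: %d x %d px, %d frames, %d molecule(s)\n",
              dim(x$data)[2L], dim(x$data)[1L], dim(x$data)[3L],
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Write a movie as a 16-bit multi-page TIFF
#' @param movie an `sm_movie` or array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  a <- as_movie_array(movie)
  a <- pmin(pmax(round(a), 0), 65535)
  pages <- lapply(seq_len(dim(a)[3L]), function(f) a[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#' @param path TIFF file.
#' @param pixel_size micrometre per pixel to attach.
#' @return an `sm_movie` (data in camera counts, truth unknown).
#' @export
read_movie_tiff <- function(path, pixel_size = 0.106) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, c(dim(pages[[1L]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    p <- pages[[f]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    a[, , f] <- p * 65535
  }
  structure(list(data = a, pixel_size = pixel_size, cells = NULL,
                 config = NULL, truth = NULL),
            class = "sm_movie")
}

#' Reference simulation scenarios
#'
#' Named trajectory-simulation configurations mirroring the mRNA-decay
#' (degradosome) application: a two-population endoribonuclease with a
#' slow/static complex-bound fraction and a mobile fraction, before and
#' after transcription arrest (which empties the slow fraction), and the
#' matching two-component dwell-time mixture.
#'
#' @param name scenario: `"degradosome"` (f1 = 0.482), `"degradosome_rif"`
#'   (f1 = 0.0984), both with D = (0.031, 0.3) micrometre^2/s at dt = 40 ms.
#' @param n_tracks tracks to generate.
#' @param seed RNG seed.
#' @return a `simulation_config`.
#' @export
scenario_config <- function(name = c("degradosome", "degradosome_rif"),
                            n_tracks = 400L, seed = 1L) {
  name <- match.arg(name)
  f1 <- switch(name, degradosome = 0.482, degradosome_rif = 0.0984)
  simulation_config(
    states = data.frame(D = c(0.031, 0.3), fraction = c(f1, 1 - f1)),
    cell_length = 3, cell_width = 1, sigma_loc = 0, dt = 0.04,
    bleach_prob = 0.1, n_tracks = n_tracks, min_steps = 5L,
    boundary = "none", seed = seed, condition = name)
}

#' Sample dwell durations from a two-component exponential mixture
#'
#' Reference dwell-time generator (residence times of a molecule that rests
#' either stochastically or through binding): durations are
#' `cutoff + Exp(tau_i)` with component `i` drawn from `fractions`,
#' mimicking events scored above a minimum-step cutoff.
#'
#' @param n number of events.
#' @param taus component time constants (seconds).
#' @param fractions component weights (sum 1).
#' @param cutoff minimum duration offset (seconds).
#' @param seed RNG seed.
#' @return numeric vector of durations.
#' @export
simulate_dwell_durations <- function(n, taus = c(0.18, 0.43),
                                     fractions = c(0.824, 0.176),
                                     cutoff = 0.16, seed = 1L) {
  stopifnot(length(taus) == length(fractions),
            abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  comp <- sample.int(length(taus), n, replace = TRUE, prob = fractions)
  cutoff + stats::rexp(n, rate = 1 / taus[comp])
}
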