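## Population-level maps over the standardized 1 x 3 um cell.

.grid_breaks <- function(bin_size, std_length = 3, std_width = 1) {
  nx <- round(std_length / bin_size)
  ny <- round(std_width / bin_size)
  if (abs(nx * bin_size - std_length) > 1e-9 ||
      abs(ny * bin_size - std_width) > 1e-9)
    stop("bin_size must divide the standardized cell dimensions",
         call. = FALSE)
  if (nx %% 2L != 0L || ny %% 2L != 0L)
    stop("bin_size must give an even bin count per axis (no bin may ",
         "straddle the cell axes)", call. = FALSE)
  list(x = seq(-std_length / 2, std_length / 2, by = bin_size),
       y = seq(-std_width / 2, std_width / 2, by = bin_size),
       nx = nx, ny = ny)
}

.bin_index <- function(v, breaks) {
  i <- findInterval(v, breaks, rightmost.closed = TRUE)
  i[i < 1L | i > length(breaks) - 1L] <- NA_integer_
  i
}

.new_grid_map <- function(grid, counts, bin_size, kind, mirrored, br) {
  structure(list(grid = grid, counts = counts, bin_size = bin_size,
                 kind = kind, mirrored = mirrored,
                 xbreaks = br$x, ybreaks = br$y),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("Grid map (%s): %d x %d bins of %g um%s\n", x$kind,
              nrow(x$grid), ncol(x$grid), x$bin_size,
              if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}

# reflect a first-quadrant grid to the full standardized cell
.mirror_expand <- function(q, divide) {
  nyq <- nrow(q); nxq <- ncol(q)
  full <- matrix(NA_real_, 2L * nyq, 2L * nxq)
  qq <- if (divide) q / 4 else q
  full[(nyq + 1L):(2L * nyq), (nxq + 1L):(2L * nxq)] <- qq
  full[(nyq + 1L):(2L * nyq), nxq:1L] <- qq
  full[nyq:1L, (nxq + 1L):(2L * nxq)] <- qq
  full[nyq:1L, nxq:1L] <- qq
  full
}

#' Occupancy heat map over the standardized cell
#'
#' 2D histogram of standardized localizations over the 3 x 1 micrometre
#' cell, normalized to total mass 1 (likeliness of presence).  With
#' `mirrored = TRUE` the coordinates are folded into one quadrant and the
#' quadrant map is reflected back for display, making the map exactly
#' symmetric under both axis reflections (appropriate when the cell has no
#' intrinsic polarity).
#'
#' @param points data.frame of standardized localizations (`x`, `y`), e.g.
#'   the `tracks` table of [standardize_tracks()] output.
#' @param bin_size bin edge length in micrometre (default 0.05).
#' @param mirrored fold and reflect the map.
#' @return a `grid_map` of kind `"occupancy"` (rows = y bins, columns = x
#'   bins, grid sums to 1); points outside the standardized frame are
#'   dropped with a count kept in attribute `"n_outside"`.
#' @export
heat_map <- function(points, bin_size = 0.05, mirrored = FALSE) {
  br <- .grid_breaks(bin_size)
  x <- points$x; y <- points$y
  if (mirrored) { x <- abs(x); y <- abs(y) }
  ix <- .bin_index(x, br$x)
  iy <- .bin_index(y, br$y)
  ok <- !is.na(ix) & !is.na(iy)
  n_outside <- sum(!ok)
  if (sum(ok) == 0L) stop("no point inside the standardized cell",
                          call. = FALSE)
  counts <- matrix(0, br$ny, br$nx)
  tab <- table(factor(iy[ok], levels = seq_len(br$ny)),
               factor(ix[ok], levels = seq_len(br$nx)))
  counts[] <- as.numeric(tab)
  if (mirrored) {
    # folded points all land in the first quadrant; reflect for display
    q <- counts[(br$ny / 2L + 1L):br$ny, (br$nx / 2L + 1L):br$nx, drop = FALSE]
    grid <- .mirror_expand(q / sum(q), divide = TRUE)
    counts_full <- .mirror_expand(q, divide = TRUE)
    out <- .new_grid_map(grid, counts_full, bin_size, "occupancy", TRUE, br)
  } else {
    out <- .new_grid_map(counts / sum(counts), counts, bin_size,
                         "occupancy", FALSE, br)
  }
  attr(out, "n_outside") <- n_outside
  out
}

#' Binned speed map over the standardized cell
#'
#' Every consecutive-frame step of every (standardized) track contributes
#' one single-step apparent diffusion estimate `r^2 / (4 dt)` at the step
#' midpoint; bins hold the mean over contributing steps.  Bins without a
#' contributing step are `NA` (missing), never zero.  Mirroring folds the
#' midpoints into one quadrant and reflects the per-quadrant means.
#'
#' @param ts a standardized `track_set`.
#' @param bin_size bin edge length in micrometre (default 0.1, i.e. 100 nm).
#' @param mirrored fold and reflect the map.
#' @return a `grid_map` of kind `"mean_speed"` (micrometre^2/s per bin) with
#'   the per-bin step counts in `$counts`.
#' @export
binned_speed_map <- function(ts, bin_size = 0.1, mirrored = FALSE) {
  stopifnot(inherits(ts, "track_set"))
  br <- .grid_breaks(bin_size)
  per <- split_tracks(ts)
  pieces <- lapply(per, function(tr) {
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    i <- which(diff(tr$frame) == 1L)
    if (length(i) == 0L) return(NULL)
    data.frame(
      mx = (tr$x[i] + tr$x[i + 1L]) / 2,
      my = (tr$y[i] + tr$y[i + 1L]) / 2,
      d_app = ((tr$x[i + 1L] - tr$x[i])^2 + (tr$y[i + 1L] - tr$y[i])^2) /
        (4 * ts$dt))
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) stop("no consecutive-frame step", call. = FALSE)
  st <- do.call(rbind, pieces)
  mx <- st$mx; my <- st$my
  if (mirrored) { mx <- abs(mx); my <- abs(my) }
  ix <- .bin_index(mx, br$x)
  iy <- .bin_index(my, br$y)
  ok <- !is.na(ix) & !is.na(iy)
  cell <- (ix[ok] - 1L) * br$ny + iy[ok]
  sums <- rowsum(st$d_app[ok], cell)
  cnts <- rowsum(rep(1, sum(ok)), cell)
  counts <- matrix(0, br$ny, br$nx)
  total <- matrix(0, br$ny, br$nx)
  idx <- as.integer(rownames(sums))
  counts[idx] <- cnts
  total[idx] <- sums
  means <- ifelse(counts > 0, total / counts, NA_real_)
  if (mirrored) {
    q_m <- means[(br$ny / 2L + 1L):br$ny, (br$nx / 2L + 1L):br$nx, drop = FALSE]
    q_c <- counts[(br$ny / 2L + 1L):br$ny, (br$nx / 2L + 1L):br$nx, drop = FALSE]
    out <- .new_grid_map(.mirror_expand(q_m, divide = FALSE),
                         .mirror_expand(q_c, divide = TRUE),
                         bin_size, "mean_speed", TRUE, br)
  } else {
    out <- .new_grid_map(means, counts, bin_size, "mean_speed", FALSE, br)
  }
  attr(out, "n_steps") <- sum(ok)
  attr(out, "global_mean") <- mean(st$d_app[ok])
  out
}

#' Distances of localizations to reference points
#'
#' Per-localization minimum distance to a reference set in the standardized
#' cell, with a trend summary (median and interquartile range) and a
#' histogram.  Named presets: `"poles"` (the two cell tips at (+-1.5, 0)),
#' `"midcell"` (the origin) and `"membrane"` (the standardized cell
#' boundary; distances are to the nearest boundary edge).
#'
#' @param points data.frame of standardized localizations (`x`, `y`).
#' @param refs two-column matrix/data.frame of reference points, or one of
#'   the preset names.
#' @param breaks histogram bin count.
#' @param std_length,std_width standardized cell dimensions.
#' @return list with `distances`, `median`, `iqr`, `quartiles`, `histogram`
#'   (a [graphics::hist()] object, not plotted), `refs`.
#' @export
distance_to_references <- function(points, refs = "membrane", breaks = 30L,
                                   std_length = 3, std_width = 1) {
  x <- points$x; y <- points$y
  if (length(x) == 0L) stop("no localization", call. = FALSE)
  if (is.character(refs)) {
    preset <- match.arg(refs, c("poles", "midcell", "membrane"))
    d <- switch(preset,
      poles = pmin(sqrt((x - std_length / 2)^2 + y^2),
                   sqrt((x + std_length / 2)^2 + y^2)),
      midcell = sqrt(x^2 + y^2),
      membrane = .rect_boundary_distance(x, y, std_length, std_width))
    ref_out <- preset
  } else {
    R <- as.matrix(refs)
    if (ncol(R) != 2L || nrow(R) == 0L)
      stop("refs must be a non-empty two-column matrix", call. = FALSE)
    d <- rep(Inf, length(x))
    for (i in seq_len(nrow(R)))
      d <- pmin(d, sqrt((x - R[i, 1L])^2 + (y - R[i, 2L])^2))
    ref_out <- R
  }
  qs <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(distances = d, median = qs[2L], iqr = qs[3L] - qs[1L],
       quartiles = qs, histogram = graphics::hist(d, breaks = breaks,
                                                  plot = FALSE),
       refs = ref_out)
}

# unsigned distance to the boundary of the axis-aligned standardized cell
.rect_boundary_distance <- function(x, y, std_length, std_width) {
  hx <- std_length / 2; hy <- std_width / 2
  inside <- abs(x) <= hx & abs(y) <= hy
  d <- numeric(length(x))
  d[inside] <- pmin(hx - abs(x[inside]), hy - abs(y[inside]))
  if (any(!inside)) {
    ox <- pmax(abs(x[!inside]) - hx, 0)
    oy <- pmax(abs(y[!inside]) - hy, 0)
    d[!inside] <- sqrt(ox^2 + oy^2)
  }
  d
}

#' Export a grid map as a CSV matrix
#' @param map a `grid_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_map <- function(map, path) {
  stopifnot(inherits(map, "grid_map"))
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Plot a grid map with the standardized cell outline
#' @param x a `grid_map`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.grid_map <- function(x, main = NULL, ...) {
  g <- x$grid
  graphics::image(x = x$xbreaks, y = x$ybreaks,
                  z = t(g), asp = 1, xlab = "x (um)", ylab = "y (um)",
                  main = main %||% sprintf("%s map", x$kind),
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  ...)
  graphics::rect(min(x$xbreaks), min(x$ybreaks), max(x$xbreaks),
                 max(x$ybreaks), border = "black")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
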