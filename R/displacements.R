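#' Pool displacements at a fixed lag
#'
#' Collects, over all tracks, every ordered pair of localizations separated
#' by `lag` frames (overlapping windows) into one displacement sample.  The
#' lag time is `tau = lag * dt`.
#'
#' @param ts a `track_set`.
#' @param lag frame lag (>= 1).
#' @return an object of class `displacement_sample`: data.frame with `dx`,
#'   `dy`, `r` (micrometre) and `track_id`, plus attributes `tau` (seconds)
#'   and `dt`.
#' @export
compute_displacements <- function(ts, lag = 1L) {
  stopifnot(inherits(ts, "track_set"))
  if (lag < 1L) stop("lag must be >= 1", call. = FALSE)
  per <- split_tracks(ts)
  pieces <- lapply(per, function(tr) {
    n <- nrow(tr)
    if (n < lag + 1L) return(NULL)
    # pair points exactly `lag` frames apart (tracks may contain gaps)
    idx <- match(tr$frame + lag, tr$frame)
    ok <- which(!is.na(idx))
    if (length(ok) == 0L) return(NULL)
    data.frame(track_id = tr$track_id[ok],
               dx = tr$x[idx[ok]] - tr$x[ok],
               dy = tr$y[idx[ok]] - tr$y[ok],
               stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L)
    stop("no displacement at lag ", lag, call. = FALSE)
  d <- do.call(rbind, pieces)
  rownames(d) <- NULL
  d$r <- sqrt(d$dx^2 + d$dy^2)
  structure(d, tau = lag * ts$dt, dt = ts$dt, lag = as.integer(lag),
            class = c("displacement_sample", "data.frame"))
}

#' Displacement sample from raw vectors
#'
#' Builds a `displacement_sample` directly from per-axis displacements, e.g.
#' for analytic fixtures or externally pooled data.
#'
#' @param dx,dy per-axis displacements (micrometre).
#' @param tau lag time in seconds.
#' @return a `displacement_sample`.
#' @export
displacement_sample <- function(dx, dy, tau) {
  stopifnot(length(dx) == length(dy), tau > 0)
  d <- data.frame(track_id = NA_character_, dx = dx, dy = dy,
                  r = sqrt(dx^2 + dy^2))
  structure(d, tau = tau, dt = tau, lag = 1L,
            class = c("displacement_sample", "data.frame"))
}

# significance-star ladder
p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare two jump-distance distributions (two-sample KS test)
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the Euclidean jump
#' distances, with the conventional significance stars
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `ns`).
#'
#' @param a,b `displacement_sample` objects or numeric vectors of jump
#'   distances.
#' @return list with `statistic`, `p_value`, `stars`.
#' @export
ks_compare <- function(a, b) {
  ra <- if (inherits(a, "displacement_sample")) a$r else as.numeric(a)
  rb <- if (inherits(b, "displacement_sample")) b$r else as.numeric(b)
  if (length(ra) == 0L || length(rb) == 0L)
    stop("empty sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(ra, rb))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       stars = p_stars(unname(kt$p.value)))
}
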