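#' Ensemble-averaged mean squared displacement
#'
#' `MSD(l * dt)` is the mean of `r^2` over all tracks and all overlapping
#' point pairs `l` frames apart, with the per-lag standard error of the
#' mean.  Lags with no samples truncate the curve.
#'
#' @param ts a `track_set`.
#' @param max_lag largest frame lag (>= 2).
#' @return an `msd_curve`: data.frame with `lag` (frames), `tau` (seconds),
#'   `msd`, `sem` (micrometre^2) and `n`.
#' @export
ensemble_msd <- function(ts, max_lag = 10L) {
  stopifnot(inherits(ts, "track_set"))
  if (max_lag < 2L) stop("max_lag must be >= 2", call. = FALSE)
  rows <- vector("list", max_lag)
  for (l in seq_len(max_lag)) {
    d <- tryCatch(compute_displacements(ts, lag = l), error = function(e) NULL)
    if (is.null(d)) break
    r2 <- d$r^2
    rows[[l]] <- data.frame(lag = l, tau = l * ts$dt, msd = mean(r2),
                            sem = stats::sd(r2) / sqrt(length(r2)),
                            n = length(r2))
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no displacements for MSD", call. = FALSE)
  out <- do.call(rbind, rows)
  structure(out, dt = ts$dt, class = c("msd_curve", "data.frame"))
}

#' Linear MSD fit: diffusion coefficient and localization error
#'
#' Weighted least squares of `MSD = 4 D tau + b` on the first `n_points`
#' lags (weights `1/sem^2` where available).  The intercept estimates the
#' localization-error floor: `sigma_loc = sqrt(max(b, 0) / 4)`; a negative
#' intercept clamps `sigma_loc` to 0 with a warning.
#'
#' @param msd an `msd_curve`.
#' @param n_points number of initial lags to use (>= 2).
#' @return list with `D` (micrometre^2/s), `sigma_loc` (micrometre),
#'   `intercept`, `slope`.
#' @export
fit_msd_linear <- function(msd, n_points = 4L) {
  stopifnot(inherits(msd, "msd_curve"))
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  n_points <- min(n_points, nrow(msd))
  sub <- msd[seq_len(n_points), ]
  w <- if (all(is.finite(sub$sem)) && all(sub$sem > 0)) 1 / sub$sem^2
       else rep(1, n_points)
  fit <- stats::lm(msd ~ tau, data = sub, weights = w)
  b <- unname(stats::coef(fit)[1L])
  slope <- unname(stats::coef(fit)[2L])
  if (b < -1e-12) {
    warning("negative MSD intercept; sigma_loc clamped to 0")
    sig <- 0
  } else sig <- sqrt(max(b, 0) / 4)
  list(D = slope / 4, sigma_loc = sig, intercept = b, slope = slope)
}

#' Classify anomalous diffusion from the MSD power law
#'
#' Linear regression of `log(MSD)` on `log(tau)` yields the anomalous
#' exponent `alpha` (`MSD ~ tau^alpha`): subdiffusive below the lower band,
#' Brownian inside the bands, superdiffusive above.
#'
#' @param msd an `msd_curve` with at least 4 usable lags.
#' @param bands `(low, high)` interval treated as Brownian.
#' @return list with `alpha`, `D_alpha` (generalized coefficient,
#'   `MSD = 4 D_alpha tau^alpha`), `label`, `r_squared`.
#' @export
fit_anomalous <- function(msd, bands = c(0.9, 1.1)) {
  stopifnot(inherits(msd, "msd_curve"), length(bands) == 2L,
            bands[1L] <= bands[2L])
  ok <- msd$msd > 0 & msd$tau > 0
  if (!any(ok)) stop("no positive MSD values", call. = FALSE)
  sub <- msd[ok, ]
  if (nrow(sub) < 4L) stop("need >= 4 lags with positive MSD", call. = FALSE)
  fit <- stats::lm(log(msd) ~ log(tau), data = sub)
  alpha <- unname(stats::coef(fit)[2L])
  lab <- if (alpha < bands[1L]) "subdiffusive"
         else if (alpha > bands[2L]) "superdiffusive" else "Brownian"
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine here
  list(alpha = alpha, D_alpha = exp(unname(stats::coef(fit)[1L])) / 4,
       label = lab, r_squared = r2)
}

# time-averaged MSD of one track at the requested frame lags
track_tamsd <- function(tr, lags) {
  vapply(lags, function(l) {
    idx <- match(tr$frame + l, tr$frame)
    ok <- which(!is.na(idx))
    if (length(ok) == 0L) return(NA_real_)
    mean((tr$x[idx[ok]] - tr$x[ok])^2 + (tr$y[idx[ok]] - tr$y[ok])^2)
  }, numeric(1))
}

#' Per-track apparent diffusion coefficients
#'
#' For each track, the first `n_points` lags of its time-averaged MSD are
#' fitted through the origin (`TAMSD = 4 D_app tau`); the slope gives the
#' apparent diffusion coefficient of that track.
#'
#' @param ts a `track_set`.
#' @param n_points number of TAMSD lags per track (>= 1).
#' @return data.frame with `track_id` and `D_app` (micrometre^2/s); tracks
#'   shorter than `n_points + 1` localizations are skipped.
#' @export
apparent_diffusion <- function(ts, n_points = 4L) {
  stopifnot(inherits(ts, "track_set"))
  if (n_points < 1L) stop("n_points must be >= 1", call. = FALSE)
  per <- split_tracks(ts)
  rows <- lapply(per, function(tr) {
    if (nrow(tr) < n_points + 1L) return(NULL)
    tam <- track_tamsd(tr, seq_len(n_points))
    ok <- !is.na(tam)
    if (!any(ok)) return(NULL)
    tau <- seq_len(n_points)[ok] * ts$dt
    y <- tam[ok]
    slope <- sum(y * tau) / sum(tau^2)     # through-origin least squares
    data.frame(track_id = tr$track_id[1L], D_app = slope / 4,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no track long enough", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unsupervised trajectory classification on TAMSD features
#'
#' K-means clustering of tracks on standardized log time-averaged MSD
#' feature vectors (default lags 1-4).  Labels are reordered so cluster 1 is
#' the least mobile (ascending centroid mobility); the run is reproducible
#' through `seed`.
#'
#' @param ts a `track_set`.
#' @param K number of clusters.
#' @param seed RNG seed for the k-means initialization.
#' @param feature_lags frame lags used as features.
#' @return list with `labels` (named by track, ordered by mobility),
#'   `centroids` (in log10-TAMSD feature space), `sizes`, `features`.
#' @export
cluster_tamsd <- function(ts, K = 2L, seed = 1L, feature_lags = 1:4) {
  stopifnot(inherits(ts, "track_set"))
  per <- split_tracks(ts)
  feats <- lapply(per, function(tr) {
    if (nrow(tr) < max(feature_lags) + 1L) return(NULL)
    tam <- track_tamsd(tr, feature_lags)
    if (any(is.na(tam)) || any(tam <= 0)) return(NULL)
    log10(tam)
  })
  keep <- !vapply(feats, is.null, logical(1))
  X <- do.call(rbind, feats[keep])
  rownames(X) <- names(per)[keep]
  if (nrow(X) < K)
    stop("K (", K, ") exceeds the number of usable tracks (", nrow(X), ")",
         call. = FALSE)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  if (anyNA(Xs)) Xs[is.na(Xs)] <- 0
  if (nrow(unique(Xs)) < K) {
    warning("degenerate clustering: fewer than K distinct feature vectors",
            call. = FALSE)
    labels <- rep(1L, nrow(X))
    names(labels) <- rownames(X)
    cent <- matrix(colMeans(X), 1L, ncol(X),
                   dimnames = list(NULL, paste0("lag", feature_lags)))
    return(list(labels = labels, centroids = cent,
                sizes = c(nrow(X), rep(0L, K - 1L)), features = X))
  }
  set.seed(seed)
  km <- tryCatch(stats::kmeans(Xs, centers = K, nstart = 10, iter.max = 100),
                 warning = function(w) {
                   warning("degenerate clustering: ", conditionMessage(w),
                           call. = FALSE)
                   suppressWarnings(stats::kmeans(Xs, centers = K, nstart = 10,
                                                  iter.max = 100))
                 })
  # order clusters by mobility (mean log-TAMSD of members)
  mob <- vapply(seq_len(K), function(g) mean(X[km$cluster == g, , drop = FALSE]),
                numeric(1))
  remap <- match(seq_len(K), order(mob))
  labels <- remap[km$cluster]
  names(labels) <- rownames(X)
  cent <- vapply(seq_len(K), function(g)
    colMeans(X[labels == g, , drop = FALSE]), numeric(ncol(X)))
  cent <- t(matrix(cent, ncol = K))
  colnames(cent) <- paste0("lag", feature_lags)
  list(labels = labels, centroids = cent,
       sizes = as.integer(table(factor(labels, levels = seq_len(K)))),
       features = X)
}
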