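#' Score dwell events over a track set
#'
#' An event starts at a localization (the anchor), persists while subsequent
#' localizations of the same track remain within `radius` of the anchor, and
#' ends at the first exit or at the track end.  Events spanning fewer than
#' `min_steps` steps are discarded; events truncated by the track end are
#' flagged censored (the underlying dwell is at least as long).  Durations
#' are `steps * dt` seconds.
#'
#' With `radius = "auto"` the radius is set to three times the localization
#' error estimated from the intercept of the ensemble MSD curve.
#'
#' @param ts a `track_set`.
#' @param radius dwell radius in micrometre, or `"auto"`.
#' @param min_steps minimum steps per event (default 4).
#' @param msd_points lags used for the automatic radius.
#' @return data.frame `track_id`, `start_idx`, `steps`, `duration` (s),
#'   `censored`; the radius used is attached as attribute `"radius"`.
#' @export
dwell_events <- function(ts, radius = "auto", min_steps = 4L,
                         msd_points = 4L) {
  stopifnot(inherits(ts, "track_set"))
  if (min_steps < 1L) stop("min_steps must be >= 1", call. = FALSE)
  if (identical(radius, "auto")) {
    msd <- tryCatch(ensemble_msd(ts, max_lag = max(4L, msd_points)),
                    error = function(e)
                      stop("auto radius unavailable: ", conditionMessage(e),
                           call. = FALSE))
    lin <- suppressWarnings(fit_msd_linear(msd, n_points = msd_points))
    radius <- 3 * lin$sigma_loc
    if (!is.finite(radius) || radius <= 0)
      stop("auto radius unavailable: MSD intercept gives sigma_loc = ",
           lin$sigma_loc, call. = FALSE)
  }
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be > 0 or \"auto\"", call. = FALSE)

  per <- split_tracks(ts)
  rows <- lapply(per, function(tr) {
    n <- nrow(tr)
    ev <- list()
    a <- 1L
    while (a < n) {
      d2 <- (tr$x - tr$x[a])^2 + (tr$y - tr$y[a])^2
      exit <- NA_integer_
      j <- a + 1L
      while (j <= n) {
        if (d2[j] > radius^2) { exit <- j; break }
        j <- j + 1L
      }
      last_in <- if (is.na(exit)) n else exit - 1L
      steps <- last_in - a
      censored <- is.na(exit)
      if (steps >= min_steps)
        ev[[length(ev) + 1L]] <- data.frame(
          track_id = tr$track_id[1L], start_idx = a, steps = steps,
          duration = steps * ts$dt, censored = censored,
          stringsAsFactors = FALSE)
      if (is.na(exit)) break
      a <- exit
    }
    if (length(ev) == 0L) NULL else do.call(rbind, ev)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) == 0L)
    data.frame(track_id = character(0), start_idx = integer(0),
               steps = integer(0), duration = numeric(0),
               censored = logical(0))
  else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "radius") <- radius
  attr(out, "dt") <- ts$dt
  out
}

#' Fit exponential decay components to dwell durations
#'
#' Fits a 1- or 2-component exponential decay to the empirical survival
#' curve of event durations by nonlinear least squares.  The minimum-
#' duration cutoff is handled by shifting the time origin to the shortest
#' duration in the sample, so the fitted components describe the decay
#' beyond the detection threshold.  Censored events are excluded from the
#' curve fit by default but included in the sample mean.
#'
#' @param durations numeric vector of durations (seconds), or the
#'   data.frame from [dwell_events()].
#' @param n_components 1 or 2.
#' @param min_events minimum number of events required.
#' @param include_censored also use censored events in the decay fit.
#' @return a `dwell_fit`: `mean_residence`, `tau_1comp` (+ error), and for
#'   two components `tau1 <= tau2` with percentages `frac1 + frac2 = 100`
#'   and errors on each; `bic` compares the component counts.
#' @export
fit_dwell <- function(durations, n_components = 2L, min_events = 30L,
                      include_censored = FALSE) {
  cens <- NULL
  if (is.data.frame(durations)) {
    cens <- durations$censored
    dur <- durations$duration
  } else dur <- as.numeric(durations)
  if (length(dur) < min_events)
    stop("need >= ", min_events, " dwell events (got ", length(dur), ")",
         call. = FALSE)
  n_components <- as.integer(n_components)
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2", call. = FALSE)

  mean_residence <- mean(dur)

  fit_dur <- if (!is.null(cens) && !include_censored) dur[!cens] else dur
  if (length(fit_dur) < min_events)
    stop("need >= ", min_events, " uncensored dwell events", call. = FALSE)

  t0 <- min(fit_dur)
  n <- length(fit_dur)

  if (stats::sd(fit_dur) == 0) {
    warning("degenerate dwell sample: all durations equal")
    out <- list(mean_residence = mean_residence, tau_1comp = NA_real_,
                err_tau_1comp = NA_real_, tau1 = NA_real_, tau2 = NA_real_,
                frac1 = NA_real_, frac2 = NA_real_, err_tau1 = NA_real_,
                err_tau2 = NA_real_, err_frac = NA_real_, bic = NA_real_,
                n_components = n_components, n_events = length(dur), t0 = t0)
    return(structure(out, class = "dwell_fit"))
  }

  # survival curve on a uniform grid (the extreme tail, where the empirical
  # survival rests on < 5 events, is excluded from the curve objective)
  g_max <- stats::quantile(fit_dur, 1 - min(5 / n, 0.1), names = FALSE) - t0
  grid_t <- seq(0, max(g_max, stats::sd(fit_dur)), length.out = 200L)
  s_grid <- vapply(grid_t + t0, function(t) mean(fit_dur >= t), numeric(1))
  tsh <- fit_dur - t0

  fit_k <- function(k) {
    unpack <- function(raw)
      list(tau = exp(raw[seq_len(k)]),
           w = .softmax_w(raw[k + seq_len(k - 1L)], k))
    surv <- function(th, t) {
      S <- 0
      for (i in seq_len(k)) S <- S + th$w[i] * exp(-t / th$tau[i])
      S
    }
    # stage 1: decay-curve fit (log-survival residuals, multi-start)
    resid_fn <- function(raw) {
      th <- unpack(raw)
      log(pmax(s_grid, 1e-9)) - log(pmax(surv(th, grid_t), 1e-12))
    }
    m_guess <- max(mean(tsh), 1e-6)
    starts <- if (k == 1L) list(log(m_guess), log(m_guess / 3),
                                log(m_guess * 3))
      else list(c(log(m_guess / 3), log(m_guess * 2), 0),
                c(log(m_guess / 2), log(m_guess * 4), 1),
                c(log(m_guess), log(m_guess * 8), -1),
                c(log(m_guess / 5), log(m_guess), 2))
    cands <- list()
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = st, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 400, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit)) cands[[length(cands) + 1L]] <- fit$par
    }
    if (length(cands) == 0L) cands <- starts
    # stage 2: likelihood refinement (efficient for the minority component)
    nll <- function(raw) {
      th <- unpack(raw)
      dens <- 0
      for (i in seq_len(k))
        dens <- dens + th$w[i] / th$tau[i] * exp(-tsh / th$tau[i])
      -sum(log(pmax(dens, 1e-300)))
    }
    best <- NULL
    for (st in cands) {
      op <- tryCatch(stats::optim(st, nll, method = "BFGS",
                                  control = list(maxit = 400,
                                                 reltol = 1e-12)),
                     error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) stop("fit error: dwell fit did not converge",
                            call. = FALSE)
    raw <- best$par
    th <- unpack(raw)
    ll <- -best$value
    bic <- -2 * ll + (2L * k - 1L) * log(n)
    sse <- sum((s_grid - surv(th, grid_t))^2)
    # delta-method errors from the observed information
    H <- tryCatch(stats::optimHess(raw, nll), error = function(e) NULL)
    C <- if (is.null(H)) matrix(NA_real_, length(raw), length(raw)) else
      tryCatch(solve(H + diag(1e-10, length(raw))),
               error = function(e) matrix(NA_real_, length(raw), length(raw)))
    G <- .num_jacobian(function(r) { t2 <- unpack(r); c(t2$tau, t2$w) }, raw)
    ci <- 1.96 * sqrt(pmax(rowSums((G %*% C) * G), 0))
    list(tau = th$tau, w = th$w, sse = sse, bic = bic, ci = ci)
  }

  f1 <- fit_k(1L)
  out <- list(mean_residence = mean_residence,
              tau_1comp = f1$tau, err_tau_1comp = f1$ci[1L],
              bic_1comp = f1$bic, n_components = n_components,
              n_events = length(dur), n_fitted = n, t0 = t0)
  if (n_components == 2L) {
    f2 <- fit_k(2L)
    ord <- order(f2$tau)
    out$tau1 <- f2$tau[ord][1L]; out$tau2 <- f2$tau[ord][2L]
    out$frac1 <- 100 * f2$w[ord][1L]; out$frac2 <- 100 * f2$w[ord][2L]
    out$err_tau1 <- f2$ci[seq_len(2L)][ord][1L]
    out$err_tau2 <- f2$ci[seq_len(2L)][ord][2L]
    out$err_frac <- 100 * f2$ci[3L]
    out$bic_2comp <- f2$bic
    out$bic <- f2$bic
  } else {
    out$tau1 <- f1$tau; out$frac1 <- 100
    out$tau2 <- NA_real_; out$frac2 <- NA_real_
    out$bic <- f1$bic
  }
  structure(out, class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Dwell-time fit (%d events, origin shift %.3g s)\n",
              x$n_events, x$t0))
  cat(sprintf("  mean residence = %.3g s\n", x$mean_residence))
  cat(sprintf("  tau (1-comp.) = %.3g +- %.2g s\n", x$tau_1comp,
              x$err_tau_1comp))
  if (x$n_components == 2L && is.finite(x$tau2))
    cat(sprintf("  tau1 = %.3g s (%.1f%%), tau2 = %.3g s (%.1f%%)\n",
                x$tau1, x$frac1, x$tau2, x$frac2))
  invisible(x)
}
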