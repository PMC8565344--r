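## Multi-population diffusion fits from pooled displacements.
##
## Two routes onto the same `mixture_fit` contract:
##  * SQD: nonlinear least squares of the mixture CDF
##      F(u) = sum_i f_i (1 - exp(-u / (4 D_i tau + 4 sigma^2)))
##    against the empirical CDF of squared displacements u = r^2.
##  * GMM: maximum likelihood of a zero-mean Gaussian mixture on pooled
##    per-axis displacements with component variances 2 D_i tau + 2 sigma^2.
## In both, BIC is computed from the mixture log-likelihood of the pooled
## displacements so that values are comparable across k.

# weights from k-1 free logits (last component pinned at 0)
.softmax_w <- function(a, k) {
  z <- exp(c(a, 0) - max(c(a, 0)))
  z / sum(z)
}

.logit_from_w <- function(w) log(w[-length(w)] / w[length(w)])

# Hazen plotting positions on (optionally thinned) order statistics
.ecdf_grid <- function(u, n_grid = 4000L) {
  n <- length(u)
  us <- sort(u)
  if (n > n_grid) {
    idx <- unique(round(seq(1L, n, length.out = n_grid)))
    list(u = us[idx], p = (idx - 0.5) / n)
  } else {
    list(u = us, p = (seq_len(n) - 0.5) / n)
  }
}

# raw parameter vector: c(log D_1..k, logit w_1..k-1, [log sigma])
.sqd_unpack <- function(raw, k, tau, model_sigma, sigma_fixed) {
  D <- exp(raw[seq_len(k)])
  w <- .softmax_w(raw[k + seq_len(k - 1L)], k)
  sigma <- if (model_sigma) exp(raw[2L * k]) else sigma_fixed
  list(D = D, w = w, sigma = sigma, s = 4 * D * tau + 4 * sigma^2)
}

.sqd_cdf <- function(u, s, w) {
  F <- 0
  for (i in seq_along(s)) F <- F + w[i] * (1 - exp(-u / s[i]))
  F
}

.sqd_loglik <- function(u, s, w) {
  dens <- 0
  for (i in seq_along(s)) dens <- dens + w[i] / s[i] * exp(-u / s[i])
  sum(log(pmax(dens, 1e-300)))
}

# deterministic multi-start grid: k scales log-spaced between shifted
# quantile anchors of u
.sqd_starts <- function(u, k, tau, n_starts = 8L) {
  qs <- stats::quantile(u, c(0.15, 0.5, 0.85), names = FALSE, type = 7)
  qs <- pmax(qs, 1e-12) / log(2)   # median of Exp(s) = s log 2
  combos <- expand.grid(lo = c(0.1, 0.35, 1), hi = c(1, 3, 10))
  combos <- combos[seq_len(min(n_starts, nrow(combos))), , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(j) {
    s0 <- if (k == 1L) qs[2L] * combos$hi[j] * combos$lo[j]
          else exp(seq(log(qs[1L] * combos$lo[j]),
                       log(qs[3L] * combos$hi[j]), length.out = k))
    logD <- log(pmax(s0 / (4 * tau), 1e-9))
    c(logD, rep(0, k - 1L))
  })
}

.fit_sqd_core <- function(u, k, tau, model_sigma, sigma_fixed, n_grid,
                          sigma_start = 0.02) {
  grid <- .ecdf_grid(u, n_grid)
  resid_fn <- function(raw) {
    th <- .sqd_unpack(raw, k, tau, model_sigma, sigma_fixed)
    grid$p - .sqd_cdf(grid$u, th$s, th$w)
  }
  starts <- .sqd_starts(u, k, tau)
  if (model_sigma) starts <- lapply(starts, function(s) c(s, log(sigma_start)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-14)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("fit error: no start converged (k = ", k, ", n = ", length(u), ")",
         call. = FALSE)
  list(raw = best$fit$par, sse = best$sse, grid = grid, resid_fn = resid_fn)
}

# covariance of raw parameters from the residual Jacobian, then delta method
.mixture_ci <- function(raw, resid_fn, natural_fn, sse, m) {
  p <- length(raw)
  J <- .num_jacobian(resid_fn, raw)
  JtJ <- crossprod(J)
  C <- tryCatch(solve(JtJ + diag(1e-12, p)) * sse / max(m - p, 1L),
                error = function(e) matrix(NA_real_, p, p))
  G <- .num_jacobian(natural_fn, raw)
  v <- rowSums((G %*% C) * G)
  1.96 * sqrt(pmax(v, 0))
}

.num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

.new_mixture_fit <- function(k, D, f, sigma_loc, ci95_D, ci95_f, sse, loglik,
                             bic, n, tau, method, model_sigma, residuals) {
  ord <- order(D)
  structure(list(k = k, D = D[ord], f = f[ord], sigma_loc = sigma_loc,
                 ci95_D = ci95_D[ord], ci95_f = ci95_f[ord],
                 sse = sse, loglik = loglik, bic = bic, n = n, tau = tau,
                 method = method, model_sigma = model_sigma,
                 residuals = residuals),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%s mixture fit: k = %d populations (n = %d, tau = %g s)\n",
              toupper(x$method), x$k, x$n, x$tau))
  for (i in seq_len(x$k))
    cat(sprintf("  D%d = %.4g +- %.2g um^2/s   f%d = %.3f +- %.2g\n",
                i, x$D[i], x$ci95_D[i], i, x$f[i], x$ci95_f[i]))
  if (!is.null(x$sigma_loc) && !is.na(x$sigma_loc))
    cat(sprintf("  sigma_loc = %.4g um\n", x$sigma_loc))
  cat(sprintf("  SSE = %.4g, BIC = %.2f\n", x$sse, x$bic))
  invisible(x)
}

#' Fit a squared-displacement (jump-distance) mixture
#'
#' Fits the empirical cumulative distribution of squared displacements
#' `u = r^2` with a mixture of `k` Brownian populations,
#' `F(u) = sum_i f_i (1 - exp(-u / (4 D_i tau + 4 sigma^2)))`,
#' by Levenberg-Marquardt nonlinear least squares with a deterministic
#' multi-start grid.  With `model_sigma = TRUE` a shared localization-error
#' term `sigma` is fitted; otherwise the reported `D` are apparent
#' coefficients (localization error folded in).
#'
#' 95% confidence half-widths come from the fit covariance (delta method);
#' BIC is computed from the exponential-mixture log-likelihood of all pooled
#' squared displacements with `2k - 1` (+1 if `sigma` fitted) parameters, so
#' fits with different `k` are directly comparable.
#'
#' @param d a `displacement_sample`.
#' @param k number of populations (1-3).
#' @param model_sigma fit a shared localization-error term.
#' @param sigma_fixed known localization error (micrometre) used when
#'   `model_sigma = FALSE`; default 0.
#' @param min_per_comp minimum displacements required per population.
#' @param n_grid maximum number of CDF evaluation points.
#' @return a `mixture_fit` with `D` ascending, fractions summing to 1,
#'   `ci95_D`/`ci95_f`, `sse`, `bic` and a `residuals` diagnostic table
#'   (`u`, `ecdf`, `fitted`, `residual`).
#' @export
fit_sqd_mixture <- function(d, k = 2L, model_sigma = FALSE, sigma_fixed = 0,
                            min_per_comp = 50L, n_grid = 4000L) {
  stopifnot(inherits(d, "displacement_sample"))
  k <- as.integer(k)
  if (k < 1L || k > 3L) stop("k must be 1, 2 or 3", call. = FALSE)
  u <- d$r^2
  n <- length(u)
  if (n < min_per_comp * k)
    stop("too few displacements (", n, ") for k = ", k, call. = FALSE)
  tau <- attr(d, "tau")
  core <- .fit_sqd_core(u, k, tau, model_sigma, sigma_fixed, n_grid)
  th <- .sqd_unpack(core$raw, k, tau, model_sigma, sigma_fixed)
  loglik <- .sqd_loglik(u, th$s, th$w)
  p_count <- 2L * k - 1L + as.integer(model_sigma)
  bic <- -2 * loglik + p_count * log(n)

  natural <- function(raw) {
    t2 <- .sqd_unpack(raw, k, tau, model_sigma, sigma_fixed)
    c(t2$D, t2$w)
  }
  ci <- .mixture_ci(core$raw, core$resid_fn, natural, core$sse,
                    length(core$grid$u))
  fitted <- .sqd_cdf(core$grid$u, th$s, th$w)
  res_tab <- data.frame(u = core$grid$u, ecdf = core$grid$p, fitted = fitted,
                        residual = core$grid$p - fitted)
  .new_mixture_fit(k, th$D, th$w,
                   sigma_loc = if (model_sigma) th$sigma else sigma_fixed,
                   ci95_D = ci[seq_len(k)], ci95_f = ci[k + seq_len(k)],
                   sse = core$sse, loglik = loglik, bic = bic, n = n,
                   tau = tau, method = "sqd", model_sigma = model_sigma,
                   residuals = res_tab)
}

#' Fit a zero-mean Gaussian mixture to per-axis displacements
#'
#' Pools x- and y-displacements and fits a `k`-component zero-mean Gaussian
#' mixture with per-component variance `v_i = 2 D_i tau + 2 sigma^2` by
#' direct maximum likelihood (BFGS, deterministic multi-start).  Variances
#' are mapped back to diffusion coefficients; output follows the same
#' `mixture_fit` contract as [fit_sqd_mixture()].
#'
#' @inheritParams fit_sqd_mixture
#' @return a `mixture_fit` (method `"gmm"`).
#' @export
fit_gmm_displacements <- function(d, k = 2L, model_sigma = FALSE,
                                  sigma_fixed = 0, min_per_comp = 50L,
                                  n_grid = 4000L) {
  stopifnot(inherits(d, "displacement_sample"))
  k <- as.integer(k)
  if (k < 1L || k > 3L) stop("k must be 1, 2 or 3", call. = FALSE)
  if (is.null(d$dx) || is.null(d$dy))
    stop("dx and dy are required for the GMM route", call. = FALSE)
  v <- c(d$dx, d$dy)
  if (length(d$dx) < min_per_comp * k)
    stop("too few displacements for k = ", k, call. = FALSE)
  tau <- attr(d, "tau")
  m <- length(v)

  unpack <- function(raw) {
    D <- exp(raw[seq_len(k)])
    w <- .softmax_w(raw[k + seq_len(k - 1L)], k)
    sigma <- if (model_sigma) exp(raw[2L * k]) else sigma_fixed
    list(D = D, w = w, sigma = sigma, var = 2 * D * tau + 2 * sigma^2)
  }
  nll <- function(raw) {
    th <- unpack(raw)
    dens <- 0
    for (i in seq_len(k))
      dens <- dens + th$w[i] * stats::dnorm(v, 0, sqrt(th$var[i]))
    -sum(log(pmax(dens, 1e-300)))
  }

  # exact closed form for a single component without sigma
  if (k == 1L && !model_sigma) {
    vhat <- mean(v^2)
    raw <- log(vhat / (2 * tau))
    th <- unpack(raw)
    ll <- -nll(raw)
  } else {
    starts <- .sqd_starts(v^2 * 2, k, tau)  # reuse scale anchors
    if (model_sigma) starts <- lapply(starts, function(s) c(s, log(0.02)))
    best <- NULL
    for (st in starts) {
      op <- tryCatch(stats::optim(st, nll, method = "BFGS",
                                  control = list(maxit = 500, reltol = 1e-12)),
                     error = function(e) NULL)
      if (is.null(op)) next
      if (is.null(best) || op$value < best$value) best <- op
    }
    if (is.null(best)) stop("fit error: GMM did not converge", call. = FALSE)
    raw <- best$par
    th <- unpack(raw)
    ll <- -best$value
  }

  p_count <- 2L * k - 1L + as.integer(model_sigma)
  bic <- -2 * ll + p_count * log(m)

  # CDF-residual diagnostics (and SSE) against the pooled-axis ECDF
  grid <- .ecdf_grid(v, n_grid)
  mix_cdf <- function(x, th) {
    F <- 0
    for (i in seq_len(k)) F <- F + th$w[i] * stats::pnorm(x, 0, sqrt(th$var[i]))
    F
  }
  fitted <- mix_cdf(grid$u, th)
  sse <- sum((grid$p - fitted)^2)

  # delta-method CIs from the inverse observed information
  H <- tryCatch(stats::optimHess(raw, nll), error = function(e) NULL)
  p <- length(raw)
  C <- if (is.null(H)) matrix(NA_real_, p, p) else
    tryCatch(solve(H + diag(1e-10, p)), error = function(e) matrix(NA_real_, p, p))
  G <- .num_jacobian(function(r) { t2 <- unpack(r); c(t2$D, t2$w) }, raw)
  ci <- 1.96 * sqrt(pmax(rowSums((G %*% C) * G), 0))

  res_tab <- data.frame(u = grid$u, ecdf = grid$p, fitted = fitted,
                        residual = grid$p - fitted)
  .new_mixture_fit(k, th$D, th$w,
                   sigma_loc = if (model_sigma) th$sigma else sigma_fixed,
                   ci95_D = ci[seq_len(k)], ci95_f = ci[k + seq_len(k)],
                   sse = sse, loglik = ll, bic = bic, n = length(d$dx),
                   tau = tau, method = "gmm", model_sigma = model_sigma,
                   residuals = res_tab)
}

#' Pick the number of populations by BIC
#'
#' Returns the fit with the smallest BIC; exact ties go to the smaller `k`
#' (the more parsimonious model).
#'
#' @param fits list of `mixture_fit` objects fitted to the same data.
#' @return the selected `mixture_fit`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) stop("empty fit list", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "mixture_fit")))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  kk <- vapply(fits, `[[`, numeric(1), "k")
  ord <- order(bic, kk)
  fits[[ord[1L]]]
}

#' Joint multi-condition fit with shared diffusion coefficients
#'
#' Fits all conditions simultaneously with one shared set of `D` values and
#' condition-specific fractions, the standard device for comparing fraction
#' sizes between e.g. treated and untreated cells without conflating changes
#' in `D` and changes in occupancy.  The objective concatenates the
#' per-condition squared-displacement ECDF residuals.
#'
#' @param samples named list of `displacement_sample` objects (one per
#'   condition), all at the same lag time.
#' @param k number of shared populations (1-3).
#' @param n_grid maximum CDF evaluation points per condition.
#' @return object of class `shared_d_fit`: shared `D` (+ `ci95_D`), matrix
#'   `f` (conditions x populations, rows sum to 1), `ci95_f`, per-condition
#'   `sse`, total `sse`, `bic`, `n`.
#' @export
joint_fit_shared_D <- function(samples, k = 2L, n_grid = 2000L) {
  if (length(samples) < 2L) stop("need >= 2 conditions", call. = FALSE)
  stopifnot(all(vapply(samples, inherits, logical(1), "displacement_sample")))
  k <- as.integer(k)
  if (k < 1L || k > 3L) stop("k must be 1, 2 or 3", call. = FALSE)
  taus <- vapply(samples, attr, numeric(1), "tau")
  if (max(taus) - min(taus) > 1e-12)
    stop("incompatible lag times across conditions", call. = FALSE)
  tau <- taus[1L]
  C <- length(samples)
  if (is.null(names(samples)))
    names(samples) <- paste0("condition", seq_len(C))

  us <- lapply(samples, function(d) d$r^2)
  grids <- lapply(us, .ecdf_grid, n_grid = n_grid)

  # raw: c(log D_1..k, logits cond1 (k-1), logits cond2 (k-1), ...)
  unpack <- function(raw) {
    D <- exp(raw[seq_len(k)])
    W <- matrix(0, C, k)
    for (c in seq_len(C)) {
      a <- raw[k + (c - 1L) * (k - 1L) + seq_len(k - 1L)]
      W[c, ] <- .softmax_w(a, k)
    }
    list(D = D, W = W, s = 4 * D * tau)
  }
  resid_fn <- function(raw) {
    th <- unpack(raw)
    unlist(lapply(seq_len(C), function(c)
      grids[[c]]$p - .sqd_cdf(grids[[c]]$u, th$s, th$W[c, ])))
  }
  starts <- .sqd_starts(unlist(us), k, tau)
  starts <- lapply(starts, function(s)
    c(s[seq_len(k)], rep(0, C * (k - 1L))))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-14) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("fit error: joint fit did not converge", call. = FALSE)
  raw <- best$fit$par
  th <- unpack(raw)

  ord <- order(th$D)
  natural <- function(r) {
    t2 <- unpack(r)
    c(t2$D[ord], as.numeric(t(t2$W[, ord, drop = FALSE])))
  }
  m_tot <- sum(vapply(grids, function(g) length(g$u), integer(1)))
  ci <- .mixture_ci(raw, resid_fn, natural, best$sse, m_tot)

  n_vec <- vapply(us, length, integer(1))
  ll <- sum(vapply(seq_len(C), function(c)
    .sqd_loglik(us[[c]], th$s, th$W[c, ]), numeric(1)))
  p_count <- k + C * (k - 1L)
  bic <- -2 * ll + p_count * log(sum(n_vec))

  sse_c <- vapply(seq_len(C), function(c)
    sum((grids[[c]]$p - .sqd_cdf(grids[[c]]$u, th$s, th$W[c, ]))^2), numeric(1))

  f_mat <- th$W[, ord, drop = FALSE]
  dimnames(f_mat) <- list(names(samples), paste0("pop", seq_len(k)))
  ci_f <- matrix(ci[-seq_len(k)], C, k, byrow = TRUE,
                 dimnames = dimnames(f_mat))
  structure(list(k = k, D = th$D[ord], ci95_D = ci[seq_len(k)],
                 f = f_mat, ci95_f = ci_f, tau = tau,
                 sse = best$sse, sse_by_condition = sse_c, bic = bic,
                 n = n_vec),
            class = "shared_d_fit")
}

#' @export
print.shared_d_fit <- function(x, ...) {
  cat(sprintf("Shared-D fit: k = %d, conditions = %d\n", x$k, nrow(x$f)))
  cat("  D:", paste(sprintf("%.4g", x$D), collapse = ", "), "um^2/s\n")
  for (c in rownames(x$f))
    cat(sprintf("  %s: f = %s\n", c,
                paste(sprintf("%.3f", x$f[c, ]), collapse = ", ")))
  invisible(x)
}

#' Cross-validated mixture fit
#'
#' Error estimation by the train/test + folds protocol: the displacement
#' pool is split at random into a training part (`split`, default 70%) and a
#' held-out test part; the training part is divided into `n_folds` random
#' folds and the mixture is fitted on each fold.  The reported value per
#' parameter is the fold mean; the reported error is the standard error of
#' the fold mean plus the mean per-fold 95% CI half-width.  The test-set SSE
#' of the fold-mean model is returned as a generalization diagnostic.
#'
#' @param d a `displacement_sample`.
#' @param k number of populations.
#' @param split training fraction of the data.
#' @param n_folds number of training folds (>= 2).
#' @param seed RNG seed controlling the split and fold assignment.
#' @param ... passed to [fit_sqd_mixture()].
#' @return object of class `crossval_result` with `mean_D`, `mean_f`,
#'   `err_D`, `err_f` (SEM + mean CI half-width), `sem_D`, `sem_f`,
#'   `test_sse`, `n_folds`, and the per-fold parameter table `folds`.
#' @export
crossval_fit <- function(d, k = 2L, split = 0.7, n_folds = 10L, seed = 1L,
                         ...) {
  stopifnot(inherits(d, "displacement_sample"))
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  n <- nrow(d)
  tau <- attr(d, "tau")
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(split * n)
  train <- idx[seq_len(n_train)]
  test <- idx[-seq_len(n_train)]
  fold_id <- rep_len(seq_len(n_folds), n_train)  # idx already shuffled

  fits <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sel <- train[fold_id == f]
    sub <- displacement_sample(d$dx[sel], d$dy[sel], tau)
    fits[[f]] <- fit_sqd_mixture(sub, k = k, ...)
  }
  Dm <- t(vapply(fits, `[[`, numeric(k), "D"))
  Fm <- t(vapply(fits, `[[`, numeric(k), "f"))
  ciD <- t(vapply(fits, `[[`, numeric(k), "ci95_D"))
  ciF <- t(vapply(fits, `[[`, numeric(k), "ci95_f"))
  sem <- function(M) apply(M, 2L, stats::sd) / sqrt(n_folds)

  mean_D <- colMeans(Dm); mean_f <- colMeans(Fm)
  # test-set SSE of the fold-mean model
  ut <- (d$r[test])^2
  grid <- .ecdf_grid(ut, 2000L)
  test_sse <- sum((grid$p - .sqd_cdf(grid$u, 4 * mean_D * tau, mean_f))^2)

  structure(list(k = k, mean_D = mean_D, mean_f = mean_f,
                 sem_D = sem(Dm), sem_f = sem(Fm),
                 err_D = sem(Dm) + colMeans(ciD),
                 err_f = sem(Fm) + colMeans(ciF),
                 n_folds = n_folds, split = split, seed = seed,
                 test_sse = test_sse, n_train = n_train, n_test = length(test),
                 folds = list(D = Dm, f = Fm),
                 fold_assignment = list(train = train, test = test,
                                        fold_id = fold_id)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("Cross-validated fit (k = %d, %d folds, %d%%/%d%% split)\n",
              x$k, x$n_folds, round(100 * x$split), round(100 * (1 - x$split))))
  for (i in seq_len(x$k))
    cat(sprintf("  D%d = %.4g +- %.2g um^2/s   f%d = %.3f +- %.3f\n",
                i, x$mean_D[i], x$err_D[i], i, x$mean_f[i], x$err_f[i]))
  cat(sprintf("  held-out test SSE = %.4g (n_test = %d)\n", x$test_sse,
              x$n_test))
  invisible(x)
}
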