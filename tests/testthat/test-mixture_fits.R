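test_that("single-population SQD fit matches the closed-form Rayleigh CDF", {
  D <- 0.1; tau <- 0.04
  d <- rayleigh_sample(4000, D, tau)
  fit <- fit_sqd_mixture(d, k = 1)
  expect_equal(fit$D, D, tolerance = 1e-3)
  expect_equal(fit$f, 1)
  # fitted CDF at the analytic median of squared jumps (4 D tau log 2)
  u_med <- 4 * D * tau * log(2)
  expect_equal(u_med, 0.016 * log(2), tolerance = 1e-12)
  F_hat <- 1 - exp(-u_med / (4 * fit$D * tau))
  expect_equal(F_hat, 0.5, tolerance = 2e-3)
  # whole-quantile agreement with the analytic CDF
  qs <- stats::quantile(d$r^2, seq(0.05, 0.95, by = 0.05))
  expect_lt(max(abs((1 - exp(-qs / (4 * fit$D * tau))) -
                      (1 - exp(-qs / (4 * D * tau))))), 5e-3)
})

test_that("two-population fits recover Table-style parameters from simulation", {
  D_true <- c(0.031, 0.3); f1 <- 0.482; tau <- 0.04
  d <- mixture_sample(10000, D_true, c(f1, 1 - f1), tau, seed = 11)
  fit <- fit_sqd_mixture(d, k = 2)
  expect_lt(abs(fit$D[1] - D_true[1]) / D_true[1], 0.10)
  expect_lt(abs(fit$D[2] - D_true[2]) / D_true[2], 0.10)
  expect_lt(abs(fit$f[1] - f1), 0.03)
  # nested models: k = 1 cannot fit two populations as well
  fit1 <- fit_sqd_mixture(d, k = 1)
  expect_gt(fit1$sse, fit$sse)
  # contract invariants
  expect_equal(sum(fit$f), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$D) > 0))
})

test_that("GMM route agrees with SQD and has exact closed forms", {
  # variance map: v = 2 D tau + 2 sigma^2
  expect_equal(2 * 0.3 * 0.04 + 2 * 0.02^2, 0.0248)
  # one-component ML variance is the mean square -> D = v / (2 tau), exactly
  d1 <- mixture_sample(2000, 0.2, 1, 0.04, seed = 4)
  g1 <- fit_gmm_displacements(d1, k = 1)
  v_hat <- mean(c(d1$dx, d1$dy)^2)
  expect_equal(g1$D, v_hat / (2 * 0.04), tolerance = 1e-9)

  d <- mixture_sample(10000, c(0.031, 0.3), c(0.482, 0.518), 0.04, seed = 12)
  gs <- fit_gmm_displacements(d, k = 2)
  sq <- fit_sqd_mixture(d, k = 2)
  expect_lt(max(abs(gs$D - sq$D) / sq$D), 0.15)
  expect_lt(abs(gs$f[1] - sq$f[1]), 0.05)
})

test_that("modelling a shared localization-error term recovers sigma", {
  sigma <- 0.03
  d <- mixture_sample(20000, c(0.031, 0.3), c(0.5, 0.5), 0.04, seed = 5,
                      sigma = sigma)
  fit <- fit_sqd_mixture(d, k = 2, model_sigma = TRUE)
  expect_lt(abs(fit$sigma_loc - sigma), 0.4 * sigma)
  # without the term, apparent D absorbs the noise: D1_app = D1 + sigma^2/tau
  fit0 <- fit_sqd_mixture(d, k = 2)
  expect_gt(fit0$D[1], 0.031)
})

test_that("increasing localization noise never decreases apparent D", {
  Ds <- vapply(c(0, 0.02, 0.04), function(sig) {
    d <- mixture_sample(6000, 0.1, 1, 0.04, seed = 21, sigma = sig)
    fit_sqd_mixture(d, k = 1)$D
  }, numeric(1))
  expect_true(all(diff(Ds) > 0))
})

test_that("fit preconditions are enforced", {
  small <- mixture_sample(80, 0.1, 1, 0.04, seed = 1)
  expect_error(fit_sqd_mixture(small, k = 2), "too few")
  expect_error(fit_sqd_mixture(small, k = 4), "k must be")
  no_axes <- displacement_sample(rnorm(200), rnorm(200), 0.04)
  no_axes$dx <- NULL
  expect_error(fit_gmm_displacements(no_axes, k = 1), "dx and dy")
})

test_that("BIC model selection picks the true k and breaks ties to smaller k", {
  d1 <- mixture_sample(8000, 0.1, 1, 0.04, seed = 31)
  fits1 <- lapply(1:3, function(k) fit_sqd_mixture(d1, k = k))
  expect_equal(select_model(fits1)$k, 1L)

  d2 <- mixture_sample(10000, c(0.03, 0.3), c(0.5, 0.5), 0.04, seed = 32)
  fits2 <- lapply(1:3, function(k) fit_sqd_mixture(d2, k = k))
  expect_equal(select_model(fits2)$k, 2L)

  tie_a <- fits2[[2]]; tie_b <- fits2[[3]]
  tie_b$bic <- tie_a$bic
  expect_equal(select_model(list(tie_b, tie_a))$k, 2L)
  expect_error(select_model(list()), "empty")
})

test_that("shared-D joint fit recovers per-condition fractions", {
  D <- c(0.031, 0.3); tau <- 0.04
  sA <- mixture_sample(10000, D, c(0.482, 0.518), tau, seed = 41)
  sB <- mixture_sample(10000, D, c(0.0984, 0.9016), tau, seed = 42)
  jf <- joint_fit_shared_D(list(untreated = sA, treated = sB), k = 2)
  expect_lt(max(abs(jf$D - D) / D), 0.10)
  expect_lt(abs(jf$f["untreated", 1] - 0.482), 0.04)
  expect_lt(abs(jf$f["treated", 1] - 0.0984), 0.04)
  expect_equal(unname(rowSums(jf$f)), c(1, 1), tolerance = 1e-9)

  # identical data in both conditions -> identical fractions
  j2 <- joint_fit_shared_D(list(a = sA, b = sA), k = 2)
  expect_equal(j2$f["a", ], j2$f["b", ], tolerance = 1e-6)

  # three conditions, k = 3: every fraction vector sums to 1
  sC <- mixture_sample(6000, c(0.01, 0.1, 0.6), c(0.3, 0.4, 0.3), tau,
                       seed = 43)
  j3 <- joint_fit_shared_D(list(a = sA, b = sB, c = sC), k = 3)
  expect_equal(unname(rowSums(j3$f)), rep(1, 3), tolerance = 1e-9)

  bad <- mixture_sample(1000, 0.1, 1, 0.08, seed = 44)
  expect_error(joint_fit_shared_D(list(a = sA, b = bad)), "incompatible")
  expect_error(joint_fit_shared_D(list(a = sA)), ">= 2 conditions")
})

test_that("cross-validation follows the split/fold protocol deterministically", {
  d <- mixture_sample(6000, c(0.03, 0.3), c(0.5, 0.5), 0.04, seed = 51)
  cv1 <- crossval_fit(d, k = 2, split = 0.7, n_folds = 5, seed = 9)
  cv2 <- crossval_fit(d, k = 2, split = 0.7, n_folds = 5, seed = 9)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$mean_D, cv2$mean_D)
  expect_equal(cv1$n_train, floor(0.7 * 6000))
  expect_equal(cv1$n_test, 6000 - floor(0.7 * 6000))
  # errors are SEM + mean CI half-width, hence at least the SEM
  expect_true(all(cv1$err_D >= cv1$sem_D))
  expect_lt(max(abs(cv1$mean_D - c(0.03, 0.3)) / c(0.03, 0.3)), 0.15)
})
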