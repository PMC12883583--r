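test_that("FIML equals the complete-data Gaussian likelihood when complete", {
  tr <- identity_truth()
  p <- simulate_panel(tr, n = 60, seed = 41)
  Y <- panel_matrix(p)
  im <- implied_moments(tr$params)
  expect_equal(fiml_loglik(tr$params, Y), complete_loglik(Y, im$mu, im$sigma),
               tolerance = 1e-10)
})

test_that("pattern-grouped likelihood equals brute-force row-by-row", {
  tr <- identity_truth()
  p <- simulate_panel(tr, n = 50, seed = 42)
  Y <- panel_matrix(p)
  set.seed(43)
  Y[matrix(runif(length(Y)) < 0.35, nrow(Y))] <- NA
  Y <- Y[rowSums(!is.na(Y)) > 0, ]
  im <- implied_moments(tr$params)
  ll_pkg <- fiml_loglik(tr$params, Y)
  ll_oracle <- rowwise_fiml(Y, im$mu, im$sigma)
  expect_equal(ll_pkg, ll_oracle, tolerance = 1e-10)
})

test_that("a row observing one variable contributes a univariate density", {
  tr <- identity_truth()
  im <- implied_moments(tr$params)
  Y <- matrix(NA_real_, 1, 12)
  Y[1, 5] <- 0.3
  expect_equal(fiml_loglik(tr$params, Y),
               dnorm(0.3, im$mu[5], sqrt(im$sigma[5, 5]), log = TRUE),
               tolerance = 1e-12)
})

test_that("the analytic-plus-Jacobian gradient matches numeric differences", {
  tr <- identity_truth()
  p <- simulate_panel(tr, n = 120, seed = 44)
  Y <- panel_matrix(p)
  set.seed(45)
  Y[matrix(runif(length(Y)) < 0.2, nrow(Y))] <- NA
  pg <- riclpm:::pattern_groups(Y)
  idx <- riclpm_index(6)
  th <- riclpm:::start_values(idx, pg$Y)
  g <- riclpm:::fiml_gradient(th, idx, pg)
  negll <- function(v) {
    im <- implied_moments(unpack_params(idx, v, validate = FALSE))
    riclpm:::loglik_mvn(im$mu, im$sigma, pg)
  }
  h <- 1e-5
  for (j in sample(idx$n_free, 8)) {
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    expect_equal(g[j], (negll(tp) - negll(tm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("fitting the truth's own implied moments recovers it", {
  tr <- default_truth()
  idx <- riclpm_index(6)
  im <- implied_moments(tr$params)
  fm <- fit_moments(idx, im$mu, im$sigma, n = 10000)
  expect_true(fm$convergence$converged)
  tru <- riclpm:::std_quantities(tr$params)
  expect_equal(fm$standardized$estimate, tru, tolerance = 1e-6)
  expect_equal(fm$params$psi_ri, tr$params$psi_ri, tolerance = 1e-5)
})

test_that("parameters are recovered from simulated data", {
  tr <- default_truth()
  p <- simulate_panel(tr, n = 2000, seed = 46)
  mp <- preprocess_panel(p, normalize = "per_construct")
  fit <- fit_riclpm(mp, options = fit_options(restarts = 0, se = "none"))
  expect_true(fit$convergence$converged)
  tru <- riclpm:::std_quantities(tr$params)
  paths <- riclpm_paths(tru)
  expect_lt(max(abs(fit$standardized$estimate[paths] - tru[paths])), 0.1)
  expect_equal(unname(fit$standardized$estimate["r_intercept"]), 0.11,
               tolerance = 0.12)
})

test_that("standardization: unit variances give beta = b, zero stays zero", {
  # the default truth is built on a unit within-variance scale before
  # rescaling; reconstruct that unit-scale version directly
  tr <- default_truth()
  s <- c(0.775, 0.35)
  Dinv <- diag(1 / s)
  p <- tr$params
  p$B <- lapply(p$B, function(b) Dinv %*% b %*% diag(s))
  p$theta <- lapply(p$theta, function(m) Dinv %*% m %*% Dinv)
  std <- riclpm:::std_quantities(p)
  for (t in 1:5) {
    expect_equal(unname(std[paste0("AR_dep_", t)]), p$B[[t]][1, 1],
                 tolerance = 1e-9)
    expect_equal(unname(std[paste0("CL_cm_dep_", t)]), p$B[[t]][1, 2],
                 tolerance = 1e-9)
  }
  p$B[[2]][1, 2] <- 0
  expect_equal(unname(riclpm:::std_quantities(p)["CL_cm_dep_2"]), 0)
})

test_that("standardized estimates are invariant to common-scale rescaling", {
  tr <- identity_truth()
  p <- simulate_panel(tr, n = 1500, seed = 47)
  Y <- panel_matrix(p)
  # rescale each construct by its own constant factor (affine closure)
  Y2 <- Y
  Y2[, seq(1, 12, 2)] <- Y[, seq(1, 12, 2)] / 3.7 + 2
  Y2[, seq(2, 12, 2)] <- Y[, seq(2, 12, 2)] * 5.1 - 1
  f1 <- fit_riclpm(Y, options = fit_options(restarts = 0, se = "none"))
  f2 <- fit_riclpm(Y2, options = fit_options(restarts = 0, se = "none"))
  expect_lt(max(abs(f1$standardized$estimate - f2$standardized$estimate)),
            1e-6)
})

test_that("robust and observed-information SEs agree under correct
           specification, and CIs are estimate +/- 1.96 SE", {
  tr <- identity_truth()
  p <- simulate_panel(tr, n = 10000, seed = 48)
  mp <- preprocess_panel(p, transforms = c(dep = "identity", cm = "identity"),
                         normalize = "per_construct")
  fit <- fit_riclpm(mp, options = fit_options(restarts = 0, se = "robust"))
  fo <- robust_se(fit, mp, type = "observed")
  paths <- riclpm_paths(fit$standardized$estimate)
  rel <- abs(fit$standardized$se[paths] / fo$standardized$se[paths] - 1)
  expect_lt(max(rel), 0.15)
  z <- qnorm(0.975)
  expect_equal(fit$standardized$hi - fit$standardized$estimate,
               z * fit$standardized$se, tolerance = 1e-10)
  expect_equal(fit$standardized$estimate - fit$standardized$lo,
               z * fit$standardized$se, tolerance = 1e-10)
})

test_that("standard errors scale roughly as 1/sqrt(n)", {
  tr <- identity_truth()
  p <- simulate_panel(tr, n = 8000, seed = 49)
  Y <- panel_matrix(p)
  f1 <- fit_riclpm(Y[1:2000, ], options = fit_options(restarts = 0))
  f2 <- fit_riclpm(Y, options = fit_options(restarts = 0))
  paths <- riclpm_paths(f1$standardized$estimate)
  ratio <- median(f1$standardized$se[paths] / f2$standardized$se[paths])
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("saturated and baseline likelihoods behave as closed forms imply", {
  tr <- identity_truth()
  p <- simulate_panel(tr, n = 300, seed = 50)
  Y <- panel_matrix(p)
  sb <- saturated_and_baseline_loglik(Y)
  # complete data: saturated solution is the sample mean and ML covariance
  mu_hat <- colMeans(Y)
  sig_hat <- crossprod(sweep(Y, 2, mu_hat)) / nrow(Y)
  expect_equal(sb$mu, mu_hat, ignore_attr = TRUE)
  expect_equal(sb$sigma, sig_hat, ignore_attr = TRUE)
  expect_equal(sb$loglik_saturated, complete_loglik(Y, mu_hat, sig_hat),
               tolerance = 1e-8)
  expect_lte(sb$loglik_baseline, sb$loglik_saturated)
  expect_identical(sb$df_baseline, 66L)
  # with missing data the EM solution still dominates the baseline and the
  # model fit
  set.seed(51)
  Y[matrix(runif(length(Y)) < 0.3, nrow(Y))] <- NA
  Y <- Y[rowSums(!is.na(Y)) > 0, ]
  sbm <- saturated_and_baseline_loglik(Y)
  expect_lte(sbm$loglik_baseline, sbm$loglik_saturated)
  expect_gte(sbm$loglik_saturated, fiml_loglik(tr$params, Y))
})

test_that("ALT-SR fitted to RI-CLPM data shrinks its slope variances", {
  tr <- default_truth()
  p <- simulate_panel(tr, n = 1500, seed = 52)
  mp <- preprocess_panel(p, normalize = "per_construct")
  fa <- suppressWarnings(
    fit_riclpm(mp, variant = "altsr", schedule = default_schedule(),
               options = fit_options(restarts = 0, se = "none"))
  )
  expect_lt(fa$params$phi[3, 3], 0.005)
  expect_lt(fa$params$phi[4, 4], 0.005)
})
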