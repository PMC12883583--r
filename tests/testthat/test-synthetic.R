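test_that("the default truth matches its calibration targets", {
  tr <- default_truth()
  expect_identical(tr$params$n_waves, 6L)
  expect_length(tr$params$B, 5L)
  std <- riclpm:::std_quantities(tr$params)
  ref <- reference_estimates()
  # standardized AR/CL of the generating truth equal the reference betas
  for (pth in unique(ref$path)) {
    expect_equal(unname(std[paste0(pth, "_", 1:5)]),
                 ref$beta[ref$path == pth], tolerance = 1e-10)
  }
  expect_equal(unname(std["r_intercept"]), 0.11, tolerance = 1e-10)
  # implied covariance is symmetric positive definite
  im <- implied_moments(tr$params)
  expect_equal(im$sigma, t(im$sigma))
  expect_gt(min(eigen(im$sigma, symmetric = TRUE)$values), 0)
})

test_that("simulation is reproducible and complete without missingness", {
  tr <- default_truth()
  p1 <- simulate_panel(tr, n = 200, seed = 11)
  p2 <- simulate_panel(tr, n = 200, seed = 11)
  expect_identical(p1$data, p2$data)
  expect_identical(nrow(p1$data), 200L)
  expect_false(anyNA(p1$data))
  p3 <- simulate_panel(tr, n = 200, seed = 12)
  expect_false(identical(p1$data, p3$data))
  # raw-scale behaviour: integer symptom scores in 0..26, positive marker
  dep <- as.matrix(p1$data[, paste0("dep_", 1:6)])
  expect_true(all(dep == round(dep) & dep >= 0 & dep <= 26))
  expect_true(all(p1$data$cm_1 > 0))
})

test_that("realized missingness converges to the specification", {
  tr <- default_truth()
  ms <- missing_spec(list(dep = c(0, 0, 0.3, 0, 0, 0), cm = rep(0, 6)),
                     mechanism = "MCAR")
  p <- simulate_panel(tr, n = 50000, missing = ms, seed = 3)
  expect_equal(mean(is.na(p$data$dep_3)), 0.30, tolerance = 0.01)
  expect_false(anyNA(p$data$dep_1))
  # MAR: marginal rates calibrated, and missingness depends on the previous
  # wave (higher marker values more likely missing at the next wave)
  p2 <- simulate_panel(tr, n = 50000, missing = default_missing_spec(),
                       seed = 4)
  rates <- colMeans(is.na(p2$data[, paste0("dep_", 1:6)]))
  expect_equal(unname(rates), c(0.15, 0.19, 0.24, 0.43, 0.45, 0.54),
               tolerance = 0.012)
  p3 <- simulate_panel(tr, n = 50000, missing = default_missing_spec(),
                       seed = 5, keep_latent = TRUE)
  cm3 <- attr(p3, "latent")$transformed[[2]][, 3]
  expect_gt(mean(cm3[is.na(p3$data$cm_4)]), mean(cm3[!is.na(p3$data$cm_4)]))
})

test_that("lagged dynamics are recoverable from the latent debug channel", {
  tr <- default_truth()
  p <- simulate_panel(tr, n = 50000, seed = 21, keep_latent = TRUE)
  w <- attr(p, "latent")$within
  # regress wave-4 within-components on wave-3 (true B[[3]] on model scale)
  B3 <- tr$params$B[[3]]
  for (i in 1:2) {
    b <- coef(lm(w[, i, 4] ~ w[, 1, 3] + w[, 2, 3]))
    expect_equal(unname(b[2]), B3[i, 1], tolerance = 0.02)
    expect_equal(unname(b[3]), B3[i, 2], tolerance = 0.02)
  }
})

test_that("zero dynamics and zero intercepts give independent waves", {
  tr <- default_truth()
  T <- 6L
  tr$params$psi_ri <- matrix(0, 2, 2)
  tr$params$B <- lapply(1:(T - 1), function(t) matrix(0, 2, 2))
  tr$links <- list(dep = list(kind = "identity"), cm = list(kind = "identity"))
  p <- simulate_panel(tr, n = 20000, seed = 31)
  m <- panel_matrix(p)
  for (t in 1:(T - 1)) {
    expect_lt(abs(cor(m[, 2 * t - 1], m[, 2 * t + 1])), 0.025)
    expect_lt(abs(cor(m[, 2 * t], m[, 2 * t + 2])), 0.025)
  }
})

test_that("adding intercept variance raises same-construct covariances by tau", {
  tr0 <- identity_truth()
  tr0$params$psi_ri <- matrix(0, 2, 2)
  tau <- 0.3
  tr1 <- tr0
  tr1$params$psi_ri <- diag(c(tau, tau))
  p0 <- simulate_panel(tr0, n = 60000, seed = 8)
  p1 <- simulate_panel(tr1, n = 60000, seed = 8)
  c0 <- cov(panel_matrix(p0))
  c1 <- cov(panel_matrix(p1))
  dep_cols <- seq(1, 12, 2)
  d <- (c1 - c0)[dep_cols, dep_cols]
  expect_equal(mean(d[upper.tri(d)]), tau, tolerance = 0.02)
})

test_that("invalid generator arguments raise argument errors", {
  tr <- default_truth()
  expect_error(simulate_panel(tr, n = -3), "positive")
  tr$params$theta[[2]] <- matrix(c(1, 2, 2, 1), 2, 2)  # not PD
  expect_error(simulate_panel(tr, n = 10, seed = 1), "positive definite")
  expect_error(missing_spec(list(a = c(0.5), b = c(1.2)), "MCAR"), "\\[0, 1\\]")
})
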