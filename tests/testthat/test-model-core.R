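test_that("free-parameter counts follow the wave-specific enumeration", {
  expect_identical(riclpm_index(6)$n_free, 53L)
  expect_identical(riclpm_index(3)$n_free, 26L)
  expect_identical(altsr_index(default_schedule())$n_free, 60L)
})

test_that("model degrees of freedom match the moment count arithmetic", {
  expect_identical(model_df(riclpm_index(6)), 37L)
  expect_identical(model_df(riclpm_index(3)), 1L)   # 27 moments - 26 params
  expect_error(riclpm_index(2), "not identified")
  expect_identical(model_df(altsr_index(default_schedule())), 30L)
  expect_error(altsr_index(wave_schedule(list(dep = c(1, 2, 3),
                                              cm = c(1, 2, 3)))),
               "not identified")
})

test_that("pack/unpack is a bijection on valid parameter vectors", {
  for (idx in list(riclpm_index(4), riclpm_index(6),
                   altsr_index(default_schedule()))) {
    set.seed(17)
    for (r in 1:5) {
      v <- rnorm(idx$n_free, 0, 0.7)
      p <- unpack_params(idx, v)
      expect_equal(pack_params(idx, p), v, tolerance = 1e-9)
      expect_s3_class(p, "riclpm_params")
    }
  }
})

test_that("implied moments: independence case is block diagonal", {
  T <- 3
  thetas <- list(diag(c(1, 2)), diag(c(0.5, 0.7)), diag(c(0.9, 1.1)))
  params <- riclpm_params(
    psi_ri = matrix(0, 2, 2),
    B = list(matrix(0, 2, 2), matrix(0, 2, 2)),
    theta = thetas, mu = rep(0, 6)
  )
  im <- implied_moments(params)
  expected <- matrix(0, 6, 6)
  for (t in 1:3) expected[(2 * t - 1):(2 * t), (2 * t - 1):(2 * t)] <-
    thetas[[t]]
  expect_equal(im$sigma, expected, ignore_attr = TRUE)
})

test_that("implied moments reproduce the univariate AR recursion by hand", {
  # one construct carries an AR(1) with a = 0.5, stationary variance 1
  # (innovations 0.75); the other is shut off
  eps <- 1e-12
  a <- 0.5
  params <- riclpm_params(
    psi_ri = matrix(0, 2, 2),
    B = list(matrix(c(0, 0, 0, a), 2, 2), matrix(c(0, 0, 0, a), 2, 2)),
    theta = list(diag(c(eps, 1)), diag(c(eps, 0.75)), diag(c(eps, 0.75))),
    mu = rep(0, 6)
  )
  s <- implied_moments(params)$sigma
  cm_idx <- c(2, 4, 6)
  expect_equal(diag(s[cm_idx, cm_idx]), rep(1, 3), tolerance = 1e-9)
  expect_equal(s[2, 4], 0.5, tolerance = 1e-9)
  expect_equal(s[4, 6], 0.5, tolerance = 1e-9)
  expect_equal(s[2, 6], 0.25, tolerance = 1e-9)
})

test_that("intercept variance adds a constant to same-construct covariances", {
  tr <- default_truth()
  tau <- 0.37
  p0 <- tr$params
  p1 <- p0
  p1$psi_ri <- p0$psi_ri + matrix(c(tau, 0, 0, 0), 2, 2)
  d <- implied_moments(p1)$sigma - implied_moments(p0)$sigma
  dep_cols <- seq(1, 12, 2)
  expect_equal(d[dep_cols, dep_cols], matrix(tau, 6, 6), ignore_attr = TRUE)
  expect_equal(d[seq(2, 12, 2), seq(2, 12, 2)], matrix(0, 6, 6),
               ignore_attr = TRUE)
})

test_that("implied moments are symmetric PD across random valid parameters", {
  idx <- riclpm_index(5)
  set.seed(23)
  for (r in 1:20) {
    p <- unpack_params(idx, rnorm(idx$n_free, 0, 0.5))
    im <- implied_moments(p)
    expect_equal(im$sigma, t(im$sigma))
    expect_gt(min(eigen(im$sigma, symmetric = TRUE)$values), 0)
  }
})

test_that("Monte-Carlo covariance of simulated data matches implied moments", {
  tr <- identity_truth()
  n <- 100000
  p <- simulate_panel(tr, n = n, seed = 77)
  Y <- panel_matrix(p)
  emp <- cov(Y)
  im <- implied_moments(tr$params)
  se <- sqrt((tcrossprod(diag(im$sigma)) + im$sigma^2) / n)
  expect_true(all(abs(emp - im$sigma) < 3.5 * se))
  expect_true(all(abs(colMeans(Y) - im$mu) < 3.5 * sqrt(diag(im$sigma) / n)))
})

test_that("ALT-SR slope loadings are years since each construct's first wave", {
  lam <- riclpm:::slope_loadings(default_schedule())
  expect_equal(lam[[1]], c(0, 2.2, 3.2, 6.0, 7.2, 13.2))
  expect_equal(lam[[2]], c(0, 2.0, 4.0, 5.6, 8.0, 14.7))
})

test_that("ALT-SR with zero slope block reduces to the RI-CLPM exactly", {
  tr <- default_truth()
  sch <- default_schedule()
  phi <- matrix(0, 4, 4)
  phi[1:2, 1:2] <- tr$params$psi_ri
  ap <- altsr_params(phi, tr$params$B, tr$params$theta, tr$params$mu, sch)
  im_a <- implied_moments(ap)
  im_r <- implied_moments(tr$params)
  expect_equal(im_a$sigma, im_r$sigma)
  expect_equal(im_a$mu, im_r$mu)
  # non-zero slope variance changes the far-apart covariances most
  phi2 <- phi
  phi2[3, 3] <- 0.001
  ap2 <- altsr_params(phi2, tr$params$B, tr$params$theta, tr$params$mu, sch)
  d <- implied_moments(ap2)$sigma - im_r$sigma
  lam <- riclpm:::slope_loadings(sch)[[1]]
  expect_equal(d[11, 11], 0.001 * lam[6]^2, tolerance = 1e-12)
})

test_that("invalid covariance blocks are rejected", {
  tr <- default_truth()
  bad <- tr$params
  bad$theta[[3]] <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(validate_params <- riclpm:::validate_params(bad),
               "positive definite")
  bad2 <- tr$params
  bad2$psi_ri <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
  expect_error(riclpm:::validate_params(bad2), "symmetric")
})
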