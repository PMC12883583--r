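#' @title Full-information maximum likelihood estimation
#' @description
#' The model is fitted by maximising the Gaussian likelihood evaluated on
#' each participant's observed sub-vector (full-information maximum
#' likelihood, valid under MAR missingness). Rows are grouped by missingness
#' pattern; each pattern contributes through its sufficient statistics
#' (count, sub-mean, sub-scatter), so a likelihood evaluation costs
#' O(patterns), not O(rows). The score of the likelihood with respect to the
#' implied mean and covariance is analytic; the Jacobian of the implied
#' moments with respect to the free parameters is obtained by central finite
#' differences on the (cheap, data-free) moment map, with the saturated mean
#' parameters handled exactly.
#' @name estimation
NULL

LOGLIK_SENTINEL <- -1e12  # optimizer-safe stand-in for -Inf

# ---- pattern groups ---------------------------------------------------------

# Group the rows of an observed-data matrix by missingness pattern.
# Each group carries sufficient statistics and the raw centered rows are
# recoverable via $rows for per-row score computations.
pattern_groups <- function(Y) {
  obs <- !is.na(Y)
  nobs <- rowSums(obs)
  dropped <- sum(nobs == 0)
  keep <- nobs > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(m) paste(as.integer(m), collapse = ""))
  idx <- split(seq_len(nrow(Y)), key)
  groups <- lapply(idx, function(rows) {
    v <- which(obs[rows[1], ])
    Yg <- Y[rows, v, drop = FALSE]
    ybar <- colMeans(Yg)
    Z <- sweep(Yg, 2, ybar)
    list(vars = v, rows = rows, n = length(rows), k = length(v),
         ybar = ybar, S = crossprod(Z) / length(rows), Y = Yg)
  })
  structure(list(groups = unname(groups), n = nrow(Y), p = ncol(Y),
                 n_dropped_empty = dropped, Y = Y),
            class = "pattern_groups")
}

# Coerce panel-like inputs to the interleaved observed-variable matrix.
as_model_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, c("model_panel", "raw_panel"))) return(panel_matrix(x))
  stop("expected a model_panel, raw_panel or numeric matrix", call. = FALSE)
}

# ---- likelihood -------------------------------------------------------------

# Total multivariate-normal log-likelihood over pattern groups for given
# moments. Returns LOGLIK_SENTINEL when a pattern's implied sub-covariance
# is not numerically PD.
loglik_mvn <- function(mu, sigma, pg) {
  ll <- 0
  log2pi <- log(2 * pi)
  for (g in pg$groups) {
    v <- g$vars
    ch <- tryCatch(chol(sigma[v, v, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(ch)) return(LOGLIK_SENTINEL)
    iS <- chol2inv(ch)
    d <- g$ybar - mu[v]
    ll <- ll - 0.5 * g$n *
      (g$k * log2pi + 2 * sum(log(diag(ch))) +
         sum(iS * g$S) + sum(d * (iS %*% d)))
  }
  ll
}

# Gradient of the total log-likelihood with respect to (mu, sigma):
# per pattern, dl/dmu = n * S^-1 (ybar - mu) on the observed coordinates and
# dl/dSigma = n/2 * (S^-1 (Sg + dd') S^-1 - S^-1), accumulated into the full
# 2T positions.
moment_gradient <- function(mu, sigma, pg) {
  p <- pg$p
  G_mu <- numeric(p)
  G_sig <- matrix(0, p, p)
  for (g in pg$groups) {
    v <- g$vars
    iS <- chol2inv(chol(sigma[v, v, drop = FALSE]))
    d <- g$ybar - mu[v]
    u <- iS %*% d
    G_mu[v] <- G_mu[v] + g$n * u
    M <- g$S + tcrossprod(d)
    G_sig[v, v] <- G_sig[v, v] + 0.5 * g$n * (iS %*% M %*% iS - iS)
  }
  list(mu = G_mu, sigma = G_sig)
}

#' FIML log-likelihood of a parameter set on a panel
#'
#' Sums, over missingness-pattern groups, the multivariate-normal log-density
#' of each participant's observed sub-vector under the corresponding sub-mean
#' and sub-covariance of the model-implied moments. Rows with no observed
#' values contribute nothing. With complete data this equals the standard
#' complete-data Gaussian log-likelihood.
#'
#' @param params A `riclpm_params` or `altsr_params`.
#' @param panel A `model_panel` (or an observed-data matrix in interleaved
#'   variable order).
#' @return Scalar log-likelihood (a large negative sentinel if an implied
#'   sub-covariance is singular).
#' @export
fiml_loglik <- function(params, panel) {
  im <- implied_moments(params)
  loglik_mvn(im$mu, im$sigma, pattern_groups(as_model_matrix(panel)))
}

# ---- moment Jacobians -------------------------------------------------------

# d(mu, vec sigma)/d(theta). The last 2T entries of theta are the saturated
# means (exact identity block, zero effect on sigma); all other parameters
# are differentiated centrally on the implied-moment map.
moment_jacobian <- function(index, theta, h = 1e-6) {
  p <- 2L * index$n_waves
  q <- index$n_free
  n_mu <- 2L * index$n_waves
  q_cov <- q - n_mu
  dmu <- matrix(0, p, q)
  dsig <- matrix(0, p * p, q)
  for (j in seq_len(q_cov)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    sp <- implied_moments(unpack_params(index, tp, validate = FALSE))$sigma
    sm <- implied_moments(unpack_params(index, tm, validate = FALSE))$sigma
    dsig[, j] <- (sp - sm) / (2 * h)
  }
  dmu[cbind(seq_len(n_mu), q_cov + seq_len(n_mu))] <- 1
  list(dmu = dmu, dsig = dsig)
}

# Gradient of the total FIML log-likelihood wrt the packed parameter vector.
fiml_gradient <- function(theta, index, pg) {
  params <- unpack_params(index, theta, validate = FALSE)
  im <- implied_moments(params)
  ok <- tryCatch({chol(im$sigma); TRUE}, error = function(e) FALSE)
  if (!ok) return(numeric(index$n_free))
  G <- moment_gradient(im$mu, im$sigma, pg)
  J <- moment_jacobian(index, theta)
  as.numeric(crossprod(J$dsig, as.numeric(G$sigma))) +
    as.numeric(crossprod(J$dmu, G$mu))
}

# ---- starting values --------------------------------------------------------

# Moment-based starting values: observed means; intercept covariance from the
# between-person covariance of per-person construct means (halved); within
# blocks from the residual variance split; lagged matrices from lag-1
# regressions on pairwise-complete covariance estimates.
start_values <- function(index, Y) {
  T <- index$n_waves
  p <- 2L * T
  mu0 <- colMeans(Y, na.rm = TRUE)
  mu0[!is.finite(mu0)] <- 0
  pm <- cbind(
    rowMeans(Y[, seq(1, p, 2), drop = FALSE], na.rm = TRUE),
    rowMeans(Y[, seq(2, p, 2), drop = FALSE], na.rm = TRUE)
  )
  pm[!is.finite(pm)] <- NA
  psi0 <- 0.5 * stats::cov(pm, use = "pairwise.complete.obs")
  psi0[!is.finite(psi0)] <- 0
  tot <- apply(Y, 2, stats::var, na.rm = TRUE)
  tot[!is.finite(tot) | tot <= 0] <- 1
  wvar <- pmax(tot - rep(diag(psi0), T), 0.25 * tot)
  diag(psi0) <- pmax(diag(psi0), 0.05 * tot[1:2])
  if (abs(psi0[1, 2]) >= 0.95 * sqrt(prod(diag(psi0)))) {
    psi0[1, 2] <- psi0[2, 1] <- 0
  }
  Cw <- stats::cov(Y, use = "pairwise.complete.obs")
  Cw[!is.finite(Cw)] <- 0
  Bs <- vector("list", T - 1)
  for (t in seq_len(T - 1)) {
    it <- (2 * t - 1):(2 * t)
    it1 <- (2 * t + 1):(2 * t + 2)
    Ct <- Cw[it, it]
    b <- tryCatch(Cw[it1, it] %*% solve(Ct + diag(1e-8, 2)),
                  error = function(e) matrix(0, 2, 2))
    b[!is.finite(b)] <- 0
    b[abs(b) > 0.95] <- sign(b[abs(b) > 0.95]) * 0.5
    Bs[[t]] <- 0.8 * b
  }
  thetas <- lapply(seq_len(T), function(t) {
    diag(wvar[(2 * t - 1):(2 * t)], 2)
  })
  params <- if (index$variant == "altsr") {
    phi0 <- diag(c(diag(psi0), 1e-4 * diag(psi0)))
    phi0[1, 2] <- phi0[2, 1] <- psi0[1, 2]
    altsr_params(phi0, Bs, thetas, mu0, index$schedule)
  } else {
    riclpm_params(psi0, Bs, thetas, mu0, labels = index$labels)
  }
  pack_params(index, params)
}

# ---- fitting ----------------------------------------------------------------

#' Fitting options
#'
#' @param maxit Maximum BFGS iterations per optimization run.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param gtol Convergence threshold on the sup-norm of the per-observation
#'   mean gradient.
#' @param restarts Number of additional optimizations from perturbed starting
#'   values (guards against local optima; 0 disables).
#' @param restart_sd Standard deviation of the perturbation on the packed
#'   scale.
#' @param seed Seed controlling the restart perturbations.
#' @param se `"robust"` (Huber-White sandwich, default), `"observed"`
#'   (observed-information), or `"none"` (no standard errors; fastest, for
#'   simulation loops).
#' @param ci_level Confidence level for reported intervals.
#' @return A list of options for [fit_riclpm()].
#' @export
fit_options <- function(maxit = 1000L, reltol = 1e-12, gtol = 1e-5,
                        restarts = 3L, restart_sd = 0.05, seed = 1L,
                        se = c("robust", "observed", "none"),
                        ci_level = 0.95) {
  list(maxit = maxit, reltol = reltol, gtol = gtol, restarts = restarts,
       restart_sd = restart_sd, seed = seed, se = match.arg(se),
       ci_level = ci_level)
}

optimize_from <- function(start, index, pg, opts) {
  negll <- function(th) {
    params <- unpack_params(index, th, validate = FALSE)
    im <- implied_moments(params)
    -loglik_mvn(im$mu, im$sigma, pg)
  }
  neggr <- function(th) -fiml_gradient(th, index, pg)
  res <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = opts$maxit,
                                     reltol = opts$reltol))
  iters <- res$counts[1]
  # polish until the mean gradient passes the tolerance or stops improving
  for (round in 1:2) {
    g <- max(abs(neggr(res$par))) / pg$n
    if (g < opts$gtol) break
    res2 <- stats::optim(res$par, negll, neggr, method = "BFGS",
                         control = list(maxit = opts$maxit,
                                        reltol = opts$reltol))
    iters <- iters + res2$counts[1]
    if (res2$value >= res$value - abs(res$value) * 1e-12) {
      res <- res2
      break
    }
    res <- res2
  }
  gnorm <- max(abs(neggr(res$par))) / pg$n
  list(par = res$par, loglik = -res$value, gnorm = gnorm, iterations = iters,
       code = res$convergence)
}

#' Fit an RI-CLPM or ALT-SR model by FIML
#'
#' Maximises the pattern-grouped FIML log-likelihood by quasi-Newton (BFGS)
#' iteration from moment-based starting values, optionally repeating from
#' perturbed starts, then populates standardized estimates and (by default)
#' Huber-White robust standard errors with delta-method intervals for the
#' standardized quantities.
#'
#' @param panel A `model_panel` (from [preprocess_panel()]) or an
#'   observed-data matrix in interleaved variable order.
#' @param variant `"riclpm"` or `"altsr"`.
#' @param schedule Required for `variant = "altsr"` when `panel` is a bare
#'   matrix; otherwise taken from the panel.
#' @param options A [fit_options()] list.
#' @return An object of class `riclpm_fit`: structured parameter estimates,
#'   packed vector, standardized quantities with SEs and CIs, log-likelihood,
#'   convergence metadata and the model degrees of freedom.
#' @export
fit_riclpm <- function(panel, variant = c("riclpm", "altsr"),
                       schedule = NULL, options = fit_options()) {
  variant <- match.arg(variant)
  if (is.null(schedule) && !is.matrix(panel)) schedule <- panel$schedule
  Y <- as_model_matrix(panel)
  T <- ncol(Y) %/% 2L
  index <- if (variant == "altsr") {
    if (is.null(schedule)) stop("ALT-SR needs a wave schedule", call. = FALSE)
    altsr_index(schedule)
  } else if (!is.null(schedule)) {
    riclpm_index(T, labels = schedule$labels)
  } else {
    riclpm_index(T)
  }
  df <- model_df(index)  # errors when not identified
  pg <- pattern_groups(Y)
  start <- start_values(index, pg$Y)
  best <- optimize_from(start, index, pg, options)
  if (options$restarts > 0) {
    rng_state <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(as.integer(options$seed))
    for (r in seq_len(options$restarts)) {
      cand <- optimize_from(
        start + stats::rnorm(length(start), 0, options$restart_sd),
        index, pg, options
      )
      if (cand$loglik > best$loglik) best <- cand
    }
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv)
  }
  params <- unpack_params(index, best$par)
  boundary <- any(best$par[log_diag_positions(index)] < -25)  # variance floor
  fit <- structure(
    list(index = index, params = params, theta = best$par,
         loglik = best$loglik, n = pg$n, df = df,
         convergence = list(converged = best$gnorm < options$gtol &&
                              best$code %in% c(0L, 1L),
                            iterations = best$iterations,
                            gradient_norm = best$gnorm,
                            boundary = boundary),
         options = options),
    class = "riclpm_fit"
  )
  if (!fit$convergence$converged) {
    warning("fit did not meet convergence tolerances (gradient norm ",
            signif(best$gnorm, 3), "); partial output retained")
  }
  fit$standardized <- standardize_fit(fit)
  if (options$se != "none") {
    fit <- robust_se(fit, pg, type = options$se)
  }
  fit
}

#' @export
print.riclpm_fit <- function(x, ...) {
  cat(toupper(x$index$variant), "fit:", x$n, "participants,",
      x$index$n_free, "free parameters, df =", x$df, "\n")
  cat("  log-likelihood:", format(x$loglik, nsmall = 2), "\n")
  cat("  converged:", x$convergence$converged,
      "( iterations:", x$convergence$iterations,
      ", gradient norm:", signif(x$convergence$gradient_norm, 3), ")\n")
  if (!is.null(x$standardized)) {
    est <- x$standardized$estimate
    cat("  standardized paths (first lags):",
        paste(names(est)[1:4], round(est[1:4], 3), collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- standardization --------------------------------------------------------

# Standardized quantities implied by a parameter set: lagged paths scaled by
# the model-implied within-component SDs (predictor over outcome), residual
# covariances as correlations, intercept covariance as a correlation.
std_quantities <- function(params) {
  T <- params$n_waves
  labs <- params$labels
  C <- vector("list", T)
  C[[1]] <- params$theta[[1]]
  for (t in seq_len(T - 1)) {
    C[[t + 1]] <- params$B[[t]] %*% C[[t]] %*% t(params$B[[t]]) +
      params$theta[[t + 1]]
  }
  sds <- vapply(C, function(m) sqrt(pmax(diag(m), 0)), numeric(2))
  out <- c()
  for (t in seq_len(T - 1)) {
    b <- params$B[[t]]
    s_t <- sds[, t]
    s_t1 <- sds[, t + 1]
    vals <- c(
      b[1, 1] * s_t[1] / s_t1[1],  # AR construct 1
      b[2, 2] * s_t[2] / s_t1[2],  # AR construct 2
      b[1, 2] * s_t[2] / s_t1[1],  # construct2 -> construct1
      b[2, 1] * s_t[1] / s_t1[2]   # construct1 -> construct2
    )
    names(vals) <- paste0(
      c(paste0("AR_", labs[1]), paste0("AR_", labs[2]),
        paste0("CL_", labs[2], "_", labs[1]),
        paste0("CL_", labs[1], "_", labs[2])), "_", t
    )
    out <- c(out, vals)
  }
  rc <- vapply(seq_len(T), function(t) {
    th <- params$theta[[t]]
    den <- sqrt(prod(diag(th)))
    if (den <= 0) NA_real_ else th[1, 2] / den
  }, numeric(1))
  names(rc) <- paste0("rcross_", seq_len(T))
  psi <- params$psi_ri
  den <- sqrt(prod(diag(psi)))
  ri <- if (den <= 0) NA_real_ else psi[1, 2] / den
  c(out, rc, r_intercept = ri)
}

# Populate the standardized block of a fit (estimates only; SEs are added by
# robust_se via the delta method).
standardize_fit <- function(fit) {
  est <- std_quantities(fit$params)
  if (anyNA(est)) {
    warning("zero variance encountered; some standardized values undefined")
  }
  list(estimate = est)
}

# ---- robust standard errors -------------------------------------------------

#' Robust (sandwich) standard errors and confidence intervals
#'
#' Computes the Huber-White sandwich covariance `A^-1 B A^-1 / n` of the free
#' parameters, with `A` the mean per-row Hessian contribution (by central
#' finite differences of the analytic gradient) and `B` the mean outer
#' product of per-row score contributions, then propagates to the
#' standardized quantities by the delta method (central differences with step
#' 1e-6 on the packed vector). With `type = "observed"` the
#' observed-information covariance `(-H)^-1` is used instead.
#'
#' @param fit A `riclpm_fit`.
#' @param pg Pattern groups of the fitted data (recomputed from `panel` if a
#'   panel is supplied).
#' @param type `"robust"` or `"observed"`.
#' @return The fit with `vcov`, and `standardized` extended by `se`, `lo`,
#'   `hi`.
#' @export
robust_se <- function(fit, pg, type = c("robust", "observed")) {
  type <- match.arg(type)
  if (!inherits(pg, "pattern_groups")) pg <- pattern_groups(as_model_matrix(pg))
  index <- fit$index
  theta <- fit$theta
  q <- index$n_free
  H <- hessian_fd(theta, index, pg)
  A <- -H / pg$n
  Ainv <- tryCatch(solve(A), error = function(e) {
    warning("singular Hessian; using pseudo-inverse")
    pseudo_inverse(A)
  })
  V <- if (type == "robust") {
    S <- score_rows(theta, index, pg)
    B <- crossprod(S) / pg$n
    Ainv %*% B %*% Ainv / pg$n
  } else {
    Ainv / pg$n
  }
  V <- (V + t(V)) / 2
  # delta method for the standardized quantities
  h <- 1e-6
  g0 <- std_quantities(fit$params)
  Jg <- matrix(0, length(g0), q)
  for (j in seq_len(q)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    Jg[, j] <- (std_quantities(unpack_params(index, tp, validate = FALSE)) -
                  std_quantities(unpack_params(index, tm, validate = FALSE))) / (2 * h)
  }
  Vstd <- Jg %*% V %*% t(Jg)
  se <- sqrt(pmax(diag(Vstd), 0))
  z <- stats::qnorm(1 - (1 - fit$options$ci_level) / 2)
  fit$vcov <- V
  fit$se_type <- type
  fit$standardized <- list(
    estimate = g0, se = stats::setNames(se, names(g0)),
    lo = g0 - z * se, hi = g0 + z * se
  )
  fit
}

pseudo_inverse <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  pos <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*%
    t(e$vectors[, pos, drop = FALSE])
}

# Central-difference Hessian of the total log-likelihood.
hessian_fd <- function(theta, index, pg, h = 1e-5) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (fiml_gradient(tp, index, pg) -
                 fiml_gradient(tm, index, pg)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Per-row score contributions (n x q).
score_rows <- function(theta, index, pg) {
  params <- unpack_params(index, theta, validate = FALSE)
  im <- implied_moments(params)
  J <- moment_jacobian(index, theta)
  q <- index$n_free
  p <- pg$p
  scores <- matrix(0, pg$n, q)
  for (g in pg$groups) {
    v <- g$vars
    iS <- chol2inv(chol(im$sigma[v, v, drop = FALSE]))
    Z <- sweep(g$Y, 2, im$mu[v])
    U <- Z %*% iS
    full_idx <- as.numeric(outer(v, (v - 1) * p, `+`))
    for (j in seq_len(q)) {
      mv <- J$dmu[v, j]
      dcol <- J$dsig[full_idx, j]
      sc <- numeric(g$n)
      if (any(mv != 0)) sc <- sc + as.numeric(U %*% mv)
      if (any(dcol != 0)) {
        Dv <- matrix(dcol, g$k, g$k)
        sc <- sc + 0.5 * (rowSums((U %*% Dv) * U) - sum(iS * Dv))
      }
      scores[g$rows, j] <- sc
    }
  }
  scores
}

# ---- moment-based fitting (n -> infinity self-consistency) ------------------

#' Fit a model directly to target moments
#'
#' Maximises the complete-data Gaussian log-likelihood implied by a target
#' mean vector and covariance matrix treated as sufficient statistics of a
#' pseudo-sample of size `n` (equivalently, minimises the ML discrepancy to
#' those moments). When the target moments lie in the model class the
#' generating parameters are recovered exactly (up to optimizer tolerance).
#'
#' @param index A `param_index`.
#' @param mu Target mean vector (length 2T).
#' @param sigma Target covariance (2T x 2T, ML scaling).
#' @param n Pseudo-sample size (only scales the objective).
#' @param options A [fit_options()] list (`se` forced to `"none"`).
#' @return A `riclpm_fit` (no standard errors).
#' @export
fit_moments <- function(index, mu, sigma, n = 1e4, options = fit_options()) {
  p <- 2L * index$n_waves
  stopifnot(length(mu) == p, all(dim(sigma) == c(p, p)))
  pg <- structure(
    list(groups = list(list(vars = seq_len(p), rows = 1L, n = n, k = p,
                            ybar = mu, S = sigma,
                            Y = matrix(mu, 1, p))),
         n = n, p = p, n_dropped_empty = 0L, Y = matrix(mu, 1, p)),
    class = "pattern_groups"
  )
  start <- tryCatch(
    start_values(index, mvn_pseudo_sample(mu, sigma)),
    error = function(e) rep(0, index$n_free)
  )
  best <- optimize_from(start, index, pg, options)
  params <- unpack_params(index, best$par)
  structure(
    list(index = index, params = params, theta = best$par,
         loglik = best$loglik, n = n, df = model_df(index),
         convergence = list(converged = best$gnorm < options$gtol,
                            iterations = best$iterations,
                            gradient_norm = best$gnorm, boundary = FALSE),
         options = options,
         standardized = list(estimate = std_quantities(params))),
    class = "riclpm_fit"
  )
}

# Small deterministic pseudo-sample matching given moments (for starts only).
mvn_pseudo_sample <- function(mu, sigma) {
  p <- length(mu)
  L <- t(chol(sigma + diag(1e-10, p)))
  X <- rbind(diag(sqrt(p), p), -diag(sqrt(p), p))  # mean 0, cov = I (ML)
  sweep(X %*% t(L), 2, mu, `+`)
}

# ---- saturated and baseline models ------------------------------------------

#' Saturated and baseline FIML log-likelihoods
#'
#' The saturated model (unstructured mean and covariance) is fitted by
#' expectation-maximisation over missingness patterns (closed form with
#' complete data); the baseline (independence) model frees only means and
#' variances, whose FIML solution separates into per-variable univariate
#' problems and is closed-form. The baseline degrees of freedom are
#' `p(p+3)/2 - 2p`.
#'
#' @param panel A `model_panel` or observed-data matrix.
#' @param tol Absolute EM log-likelihood convergence tolerance.
#' @param maxit Maximum EM iterations.
#' @return A list: `loglik_saturated`, `loglik_baseline`, `df_baseline`,
#'   `mu`, `sigma` (saturated estimates), `em_iterations`.
#' @export
saturated_and_baseline_loglik <- function(panel, tol = 1e-7, maxit = 5000L) {
  Y <- as_model_matrix(panel)
  pg <- pattern_groups(Y)
  p <- pg$p
  n <- pg$n
  complete <- length(pg$groups) == 1L && pg$groups[[1]]$k == p

  # --- baseline: diagonal covariance, closed form per variable
  ll_base <- 0
  for (v in seq_len(p)) {
    x <- Y[!is.na(Y[, v]), v]
    s2 <- mean((x - mean(x))^2)
    ll_base <- ll_base - 0.5 * length(x) * (log(2 * pi * s2) + 1)
  }

  # --- saturated
  if (complete) {
    mu <- colMeans(pg$Y)
    Z <- sweep(pg$Y, 2, mu)
    sigma <- crossprod(Z) / n
    ll_sat <- loglik_mvn(mu, sigma, pg)
    iter <- 0L
  } else {
    mu <- colMeans(Y, na.rm = TRUE)
    sigma <- stats::cov(Y, use = "pairwise.complete.obs")
    sigma[!is.finite(sigma)] <- 0
    diag(sigma)[diag(sigma) <= 0] <- 1
    ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
    sigma <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
    ll_sat <- loglik_mvn(mu, sigma, pg)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      sum_y <- numeric(p)
      sum_yy <- matrix(0, p, p)
      for (g in pg$groups) {
        o <- g$vars
        m <- setdiff(seq_len(p), o)
        Yg <- g$Y
        if (length(m) == 0) {
          sum_y <- sum_y + colSums(Yg)
          sum_yy <- sum_yy + crossprod(Yg)
          next
        }
        iSo <- chol2inv(chol(sigma[o, o, drop = FALSE]))
        W <- sigma[m, o, drop = FALSE] %*% iSo
        Em <- matrix(mu[m], g$n, length(m), byrow = TRUE) +
          sweep(Yg, 2, mu[o]) %*% t(W)
        Cmm <- sigma[m, m, drop = FALSE] -
          W %*% sigma[o, m, drop = FALSE]
        full <- matrix(0, g$n, p)
        full[, o] <- Yg
        full[, m] <- Em
        sum_y <- sum_y + colSums(full)
        cp <- crossprod(full)
        cp[m, m] <- cp[m, m] + g$n * Cmm
        sum_yy <- sum_yy + cp
      }
      mu_new <- sum_y / n
      sigma_new <- sum_yy / n - tcrossprod(mu_new)
      sigma_new <- (sigma_new + t(sigma_new)) / 2
      ll_new <- loglik_mvn(mu_new, sigma_new, pg)
      done <- is.finite(ll_new) && abs(ll_new - ll_sat) < tol
      mu <- mu_new
      sigma <- sigma_new
      ll_sat <- ll_new
      if (done || iter >= maxit) break
    }
  }
  list(loglik_saturated = ll_sat, loglik_baseline = ll_base,
       df_baseline = as.integer(p * (p + 3) / 2 - 2 * p),
       mu = mu, sigma = sigma, em_iterations = iter)
}
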