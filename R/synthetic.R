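#' @title Synthetic two-construct panel generator
#' @description
#' Generates raw-scale panel datasets with the statistical structure the
#' analysis pipeline assumes: stable between-person intercepts with a small
#' positive correlation, lag-1 within-person AR/CL dynamics with wave-specific
#' coefficients, wave-specific residual correlations, right-skewed raw score
#' distributions, and per-wave missingness rising over follow-up. Everything
#' downstream is testable against known generating values without any data
#' download.
#' @name synthetic_data
NULL

#' Per-wave missingness specification
#'
#' @param prop Named list of two numeric vectors (one per construct, names
#'   matching the schedule labels) of per-wave missing proportions in
#'   \[0, 1\].
#' @param mechanism One of `"none"`, `"MCAR"`, `"MAR"`. Under `"MAR"`,
#'   missingness at wave t is logistic in the participant's wave t-1 value of
#'   the same construct (standardized), with wave 1 MCAR; intercepts are
#'   calibrated so the marginal per-wave rates match `prop`.
#' @param mar_slope Log-odds slope per standard deviation of the previous
#'   wave's raw value.
#' @return An object of class `missing_spec`.
#' @export
missing_spec <- function(prop, mechanism = c("MAR", "MCAR", "none"),
                         mar_slope = 0.5) {
  mechanism <- match.arg(mechanism)
  if (mechanism != "none") {
    stopifnot(is.list(prop), length(prop) == 2L)
    for (p in prop) {
      if (any(p < 0 | p > 1)) {
        stop("missing proportions must be in [0, 1]", call. = FALSE)
      }
    }
    if (mechanism == "MAR" && length(prop[[1]]) < 2) {
      stop("MAR mechanism requires at least 2 waves", call. = FALSE)
    }
  }
  structure(list(prop = prop, mechanism = mechanism, mar_slope = mar_slope),
            class = "missing_spec")
}

#' Default missingness: birth-cohort-like attrition
#'
#' Per-wave missing proportions emulating a long-running cohort: symptom
#' scores 15--54% missing, the cardio-metabolic marker 24--53% (highest at
#' the clinic-visit waves in early childhood and at the final follow-up),
#' with a mild MAR dependence on the previous wave.
#'
#' @param labels Construct labels.
#' @inheritParams missing_spec
#' @return A `missing_spec`.
#' @export
default_missing_spec <- function(labels = c("dep", "cm"),
                                 mechanism = "MAR", mar_slope = 0.5) {
  prop <- list(
    c(0.15, 0.19, 0.24, 0.43, 0.45, 0.54),
    c(0.50, 0.51, 0.24, 0.36, 0.40, 0.53)
  )
  names(prop) <- labels
  missing_spec(prop, mechanism = mechanism, mar_slope = mar_slope)
}

#' Default generating truth calibrated to the reference cohort analysis
#'
#' Returns a generating truth whose standardized AR and CL coefficients,
#' wave-specific residual correlations and intercept correlation equal the
#' published reference estimates for depressive symptoms and fat mass index
#' (see [reference_estimates()]), with T = 6 waves. The parameters live on
#' the transformed scale (square-root scale for the symptom score, natural
#' log scale for the marker); the raw-scale link inverts those transforms,
#' so the generator exercises both preprocessing branches. Within-person
#' variances are constant over waves, so the generating coefficient matrices
#' coincide with their standardized values.
#'
#' @param schedule A [wave_schedule()] (defaults to [default_schedule()]).
#' @return An object of class `generating_truth`: list with `params`
#'   (a [riclpm_params()]), `links` (per-construct raw-scale link), and
#'   `schedule`.
#' @export
default_truth <- function(schedule = default_schedule()) {
  T <- schedule$n_waves
  stopifnot(T == 6L)
  ref <- reference_estimates()
  ar1 <- ref$beta[ref$path == "AR_dep"]
  ar2 <- ref$beta[ref$path == "AR_cm"]
  cl21 <- ref$beta[ref$path == "CL_cm_dep"]  # construct 2 -> construct 1
  cl12 <- ref$beta[ref$path == "CL_dep_cm"]
  rho <- c(-0.08, 0.02, 0.10, 0.11, -0.02, 0.10)  # residual correlations
  B_unit <- lapply(seq_len(T - 1), function(t) {
    matrix(c(ar1[t], cl21[t], cl12[t], ar2[t]), 2, 2, byrow = TRUE)
  })
  # Unit within-variance construction: choose innovation variances so every
  # wave's within-component variance is 1; then B is its own standardization.
  theta_unit <- vector("list", T)
  theta_unit[[1]] <- matrix(c(1, rho[1], rho[1], 1), 2, 2)
  C <- theta_unit[[1]]
  for (t in seq_len(T - 1)) {
    M <- B_unit[[t]] %*% C %*% t(B_unit[[t]])
    v <- 1 - diag(M)
    if (any(v <= 0)) stop("generating dynamics leave no innovation variance")
    off <- rho[t + 1] * sqrt(prod(v))
    theta_unit[[t + 1]] <- matrix(c(v[1], off, off, v[2]), 2, 2)
    C <- M + theta_unit[[t + 1]]
  }
  # Rescale to realistic transformed-scale spreads: sqrt-score within-sd
  # ~0.77, ln-marker within-sd ~0.35; intercept variances sized for modest
  # (symptoms) and higher (adiposity, on top of strong AR) trait stability.
  s <- c(0.775, 0.35)
  D <- diag(s)
  Dinv <- diag(1 / s)
  B <- lapply(B_unit, function(b) D %*% b %*% Dinv)
  theta <- lapply(theta_unit, function(m) D %*% m %*% D)
  tau <- c(0.20, 0.08)
  r_ri <- 0.11
  psi <- matrix(c(tau[1], r_ri * sqrt(prod(tau)),
                  r_ri * sqrt(prod(tau)), tau[2]), 2, 2)
  # Means on the transformed scale: sqrt of typical symptom medians
  # (3,3,4,4,5,5) and log of typical marker medians (3.8 ... 7.2 kg/m^2).
  mu1 <- sqrt(c(3, 3, 4, 4, 5, 5))
  mu2 <- log(c(3.8, 4.4, 4.6, 5.0, 5.8, 7.2))
  mu <- as.vector(rbind(mu1, mu2))
  params <- riclpm_params(psi, B, theta, mu, labels = schedule$labels)
  links <- list(
    list(kind = "square", max = 26),   # integer score 0..26
    list(kind = "exp")                 # positive, right-skewed
  )
  names(links) <- schedule$labels
  structure(list(params = params, links = links, schedule = schedule),
            class = "generating_truth")
}

#' @export
print.generating_truth <- function(x, ...) {
  cat("Generating truth:", x$params$n_waves, "waves; links:",
      paste(vapply(x$links, `[[`, "", "kind"), collapse = ", "), "\n")
  invisible(x)
}

# Map a transformed-scale matrix (n x T) to the raw scale.
apply_link <- function(y, link) {
  switch(link$kind,
    square = {
      out <- round(y * abs(y))           # signed square, then integer scores
      out[out < 0] <- 0
      if (!is.null(link$max)) out[out > link$max] <- link$max
      out
    },
    exp = exp(y),
    identity = y,
    stop("unknown link kind '", link$kind, "'", call. = FALSE)
  )
}

#' Simulate a raw-scale panel from a generating truth
#'
#' Per participant: random intercepts are drawn from their 2x2 covariance,
#' wave-1 within-components from the wave-1 covariance, later
#' within-components by the lag-1 recursion with wave-specific innovations;
#' intercept + within-component + mean is mapped through the construct's
#' raw-scale link, and missingness is applied last. A single seed governs
#' all draws, in a fixed order (intercepts, wave-1 components, innovations
#' wave by wave, then missingness uniforms construct by construct and wave
#' by wave), so identical seeds give identical output.
#'
#' @param truth A `generating_truth` (see [default_truth()]).
#' @param n Number of participants (>= 1).
#' @param missing A [missing_spec()]; default none.
#' @param seed Integer seed.
#' @param keep_latent If `TRUE`, attach the latent intercepts and
#'   within-components as attribute `"latent"` (a debug channel used by
#'   oracle tests; never written to CSV fixtures).
#' @return A [raw_panel()].
#' @export
simulate_panel <- function(truth, n, missing = missing_spec(NULL, "none"),
                           seed = 1L, keep_latent = FALSE) {
  stopifnot(inherits(truth, "generating_truth"))
  if (!is.numeric(n) || n < 1) stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  params <- truth$params
  validate_params(params)
  sch <- truth$schedule
  T <- params$n_waves
  labels <- sch$labels
  set.seed(as.integer(seed))

  rmvn2 <- function(n, sigma) {
    L <- t(chol(sigma + diag(1e-12, nrow(sigma))))
    matrix(stats::rnorm(n * nrow(sigma)), n) %*% t(L)
  }
  eta <- rmvn2(n, params$psi_ri)                     # n x 2 intercepts
  w <- array(0, dim = c(n, 2, T))
  w[, , 1] <- rmvn2(n, params$theta[[1]])
  for (t in seq_len(T - 1)) {
    w[, , t + 1] <- w[, , t] %*% t(params$B[[t]]) +
      rmvn2(n, params$theta[[t + 1]])
  }

  data <- data.frame(id = seq_len(n))
  trans <- vector("list", 2)                          # transformed-scale values
  for (ci in 1:2) {
    mu_c <- params$mu[seq(ci, 2 * T, by = 2)]
    y <- sweep(eta[, ci] + matrix(w[, ci, ], n, T), 2, mu_c, `+`)
    trans[[ci]] <- y
    raw <- apply_link(y, truth$links[[labels[ci]]])
    for (t in seq_len(T)) data[[paste0(labels[ci], "_", t)]] <- raw[, t]
  }

  # Missingness, applied on the raw scale.
  if (missing$mechanism != "none") {
    for (ci in 1:2) {
      prop <- missing$prop[[labels[ci]]]
      if (is.null(prop)) prop <- missing$prop[[ci]]
      stopifnot(length(prop) == T)
      raw_prev <- NULL
      for (t in seq_len(T)) {
        col <- paste0(labels[ci], "_", t)
        u <- stats::runif(n)
        if (missing$mechanism == "MCAR" || t == 1L) {
          drop <- u < prop[t]
        } else {
          z <- scale(raw_prev)[, 1]
          z[!is.finite(z)] <- 0
          b <- missing$mar_slope
          # calibrate the intercept so the marginal rate matches prop[t]
          a <- if (prop[t] <= 0) -Inf else if (prop[t] >= 1) Inf else
            stats::uniroot(function(a) mean(stats::plogis(a + b * z)) - prop[t],
                           c(-30, 30))$root
          drop <- u < stats::plogis(a + b * z)
        }
        raw_prev <- data[[col]]                       # pre-missingness value
        data[[col]][drop] <- NA_real_
      }
    }
  }

  panel <- raw_panel(data, sch)
  if (keep_latent) {
    attr(panel, "latent") <- list(eta = eta, within = w, transformed = trans)
  }
  panel
}
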