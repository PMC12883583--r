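#' @title RI-CLPM parameter structures and model-implied moments
#' @description
#' The lag-1 random-intercept cross-lagged panel model decomposes each of the
#' 2T observed variables (two constructs, T waves) into (i) a person-specific
#' random intercept with unit loading on every wave of its construct, (ii) a
#' wave-specific within-person fluctuation, and (iii) an observed-variable
#' mean. Within-person components follow a lag-1 vector autoregression with
#' wave-specific coefficient matrices and innovation covariances; the two
#' random intercepts covary freely. Loadings are fixed to 1 and measurement
#' error variances to 0 throughout, so these are not free parameters.
#' @name model_core
NULL

# ---- parameter containers ---------------------------------------------------

#' Construct an RI-CLPM parameter set
#'
#' @param psi_ri 2x2 covariance matrix of the random intercepts
#'   (construct order: first, second).
#' @param B List of length T-1 of 2x2 lagged coefficient matrices; `B[[t]]`
#'   maps the within-component at wave t to wave t+1. Diagonal entries are the
#'   autoregressive (AR) paths; `B[[t]][1,2]` is the cross-lagged path from
#'   construct 2 to construct 1, `B[[t]][2,1]` the reverse.
#' @param theta List of length T of 2x2 within-part covariances: `theta[[1]]`
#'   is the covariance of the wave-1 within-components, `theta[[t]]` (t >= 2)
#'   the innovation (residual) covariance at wave t.
#' @param mu Numeric vector of length 2T of observed-variable means, in
#'   interleaved order (construct1_wave1, construct2_wave1, construct1_wave2,
#'   ...).
#' @param labels Construct labels (length 2).
#' @return An object of class `riclpm_params`.
#' @export
riclpm_params <- function(psi_ri, B, theta, mu, labels = c("dep", "cm")) {
  n_waves <- length(theta)
  p <- structure(
    list(n_waves = n_waves, psi_ri = psi_ri, B = B, theta = theta,
         mu = as.numeric(mu), labels = labels),
    class = "riclpm_params"
  )
  validate_params(p)
  p
}

#' Construct an ALT-SR parameter set
#'
#' The autoregressive latent trajectory model with structured residuals
#' extends the RI-CLPM by per-construct latent linear slopes whose loadings
#' are fixed to years elapsed since that construct's first wave. The observed
#' means remain saturated, so slope means are fixed at 0 (they are absorbed
#' by the free occasion means and would otherwise not be identified); the
#' slopes contribute through the joint 4x4 covariance of
#' (intercept_1, intercept_2, slope_1, slope_2).
#'
#' @param phi 4x4 covariance of intercepts and slopes; its top-left 2x2 block
#'   plays the role of `psi_ri`.
#' @param schedule A [wave_schedule()] (fixes the slope loadings).
#' @inheritParams riclpm_params
#' @return An object of class `altsr_params`.
#' @export
altsr_params <- function(phi, B, theta, mu, schedule) {
  n_waves <- length(theta)
  stopifnot(inherits(schedule, "wave_schedule"),
            schedule$n_waves == n_waves)
  p <- structure(
    list(n_waves = n_waves, phi = phi, psi_ri = phi[1:2, 1:2, drop = FALSE],
         B = B, theta = theta, mu = as.numeric(mu),
         labels = schedule$labels, schedule = schedule),
    class = c("altsr_params", "riclpm_params")
  )
  validate_params(p)
  p
}

# Slope loadings: years since each construct's first wave.
slope_loadings <- function(schedule) {
  lapply(schedule$ages, function(a) a - a[1])
}

validate_params <- function(p) {
  T <- p$n_waves
  if (T < 2) stop("at least 2 waves required", call. = FALSE)
  if (length(p$B) != T - 1) stop("need T-1 lagged coefficient matrices",
                                 call. = FALSE)
  if (length(p$mu) != 2 * T) stop("mu must have length 2T", call. = FALSE)
  check_cov <- function(m, nm, strict, d = 2L) {
    if (!is.matrix(m) || any(dim(m) != c(d, d))) {
      stop(nm, " must be a ", d, "x", d, " matrix", call. = FALSE)
    }
    if (max(abs(m - t(m))) > 1e-8) {
      stop(nm, " must be symmetric", call. = FALSE)
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    lim <- if (strict) 1e-12 else -1e-10
    if (min(ev) < lim) {
      stop("invalid parameter: ", nm,
           if (strict) " must be positive definite"
           else " must be positive semidefinite", call. = FALSE)
    }
  }
  if (!is.null(p$phi)) check_cov(p$phi, "phi", strict = FALSE, d = 4L)
  else check_cov(p$psi_ri, "psi_ri", strict = FALSE)
  check_cov(p$theta[[1]], "theta[[1]]", strict = FALSE)
  for (t in 2:T) check_cov(p$theta[[t]], paste0("theta[[", t, "]]"),
                           strict = TRUE)
  invisible(p)
}

# ---- free-parameter indexing ------------------------------------------------

#' Build the free-parameter index of a lag-1 RI-CLPM
#'
#' Enumerates the packing of the structured parameters into one unconstrained
#' optimizer vector: covariance blocks via Cholesky factors with
#' log-diagonals, lagged coefficients and means as-is. The free parameters
#' are 3 (intercept covariance) + 3 (wave-1 within covariance) + 4(T-1)
#' (lagged matrices) + 3(T-1) (innovation covariances) + 2T (means).
#'
#' @param n_waves Number of waves T (>= 3 for identification).
#' @param labels Construct labels.
#' @return An object of class `param_index`.
#' @export
riclpm_index <- function(n_waves, labels = c("dep", "cm")) {
  n_waves <- as.integer(n_waves)
  if (n_waves < 3) {
    stop("RI-CLPM with T = ", n_waves, " waves is not identified ",
         "(model_df would be negative); need T >= 3", call. = FALSE)
  }
  n_free <- 3L + 3L + 4L * (n_waves - 1L) + 3L * (n_waves - 1L) + 2L * n_waves
  structure(
    list(variant = "riclpm", n_waves = n_waves, labels = labels,
         n_free = n_free),
    class = "param_index"
  )
}

#' Build the free-parameter index of an ALT-SR model
#'
#' Extends [riclpm_index()] with the 4x4 intercept/slope covariance (10
#' Cholesky parameters replacing the 3 of the intercept block: 7 extra free
#' parameters). Slope loadings are fixed from the schedule; slope means are
#' fixed to 0 under the saturated mean structure (see [altsr_params()]).
#'
#' @param schedule A [wave_schedule()].
#' @return An object of class `param_index`.
#' @export
altsr_index <- function(schedule) {
  stopifnot(inherits(schedule, "wave_schedule"))
  n_waves <- schedule$n_waves
  if (n_waves < 4) {
    stop("ALT-SR with T = ", n_waves, " waves is not identified ",
         "(model_df would be negative); need T >= 4", call. = FALSE)
  }
  base <- 3L + 4L * (n_waves - 1L) + 3L * (n_waves - 1L) + 2L * n_waves
  structure(
    list(variant = "altsr", n_waves = n_waves, labels = schedule$labels,
         n_free = 10L + base, schedule = schedule),
    class = "param_index"
  )
}

#' @export
print.param_index <- function(x, ...) {
  cat(toupper(x$variant), "parameter index:", x$n_waves, "waves,",
      x$n_free, "free parameters, df =", model_df(x), "\n")
  invisible(x)
}

#' Model degrees of freedom
#'
#' With p = 2T observed variables there are p(p+3)/2 observed moments
#' (means plus the covariance lower triangle); the model degrees of freedom
#' are the moments minus the free parameters. A negative value means the
#' model is not identified and raises an error.
#'
#' @param index A `param_index` (or an integer wave count, interpreted as a
#'   RI-CLPM).
#' @return Integer degrees of freedom.
#' @examples
#' model_df(riclpm_index(6))  # 37
#' @export
model_df <- function(index) {
  if (is.numeric(index)) index <- riclpm_index(index)
  p <- 2L * index$n_waves
  df <- (p * (p + 3L)) %/% 2L - index$n_free
  if (df < 0) {
    stop("model is not identified: ", index$n_free, " free parameters but ",
         (p * (p + 3L)) %/% 2L, " observed moments", call. = FALSE)
  }
  as.integer(df)
}

# ---- packing ---------------------------------------------------------------

# Lower-triangular Cholesky with log-diagonal <-> covariance matrix.
# Diagonal entries are floored at exp(-30): the intercept block may sit on
# the zero-variance boundary without breaking the optimizer.
chol_pack <- function(m) {
  L <- tryCatch(t(chol(m)), error = function(e) {
    t(chol(m + diag(1e-10, nrow(m))))
  })
  d <- nrow(m)
  out <- numeric(d * (d + 1) / 2)
  k <- 1L
  for (j in seq_len(d)) {
    for (i in j:d) {
      out[k] <- if (i == j) log(max(L[i, j], exp(-30))) else L[i, j]
      k <- k + 1L
    }
  }
  out
}

chol_unpack <- function(v, d) {
  if (d == 2L) {
    # closed form for the common 2x2 case (hot path)
    a <- exp(min(max(v[1], -30), 30))
    b <- v[2]
    c <- exp(min(max(v[3], -30), 30))
    return(matrix(c(a * a, a * b, a * b, b * b + c * c), 2, 2))
  }
  L <- matrix(0, d, d)
  k <- 1L
  for (j in seq_len(d)) {
    for (i in j:d) {
      L[i, j] <- if (i == j) exp(min(max(v[k], -30), 30)) else v[k]
      k <- k + 1L
    }
  }
  L %*% t(L)
}

#' Pack structured parameters into the free-parameter vector
#'
#' @param index A `param_index`.
#' @param params A `riclpm_params` or `altsr_params` matching the index.
#' @return Numeric vector of length `index$n_free`.
#' @export
pack_params <- function(index, params) {
  T <- index$n_waves
  stopifnot(params$n_waves == T)
  head_block <- if (index$variant == "altsr") chol_pack(params$phi)
                else chol_pack(params$psi_ri)
  c(
    head_block,
    chol_pack(params$theta[[1]]),
    unlist(lapply(params$B, function(b) as.vector(t(b)))),
    unlist(lapply(params$theta[-1], chol_pack)),
    params$mu
  )
}

#' Unpack a free-parameter vector into structured parameters
#'
#' Inverse of [pack_params()]; `unpack_params(index, pack_params(index, p))`
#' returns `p` up to machine precision for any valid `p`.
#'
#' @param index A `param_index`.
#' @param theta Numeric vector of length `index$n_free`.
#' @param validate Run the full invariant checks on the result (disabled on
#'   the optimizer's hot path, where the Cholesky parameterization already
#'   guarantees valid covariance blocks).
#' @return A `riclpm_params` or `altsr_params`.
#' @export
unpack_params <- function(index, theta, validate = TRUE) {
  T <- index$n_waves
  stopifnot(length(theta) == index$n_free)
  k <- if (index$variant == "altsr") 10L else 3L
  head_block <- chol_unpack(theta[seq_len(k)],
                            if (index$variant == "altsr") 4L else 2L)
  theta1 <- chol_unpack(theta[(k + 1L):(k + 3L)], 2L)
  k <- k + 3L
  B <- vector("list", T - 1L)
  for (t in seq_len(T - 1L)) {
    B[[t]] <- matrix(theta[(k + 1L):(k + 4L)], 2, 2, byrow = TRUE)
    k <- k + 4L
  }
  thetas <- vector("list", T)
  thetas[[1L]] <- theta1
  for (t in 2:T) {
    thetas[[t]] <- chol_unpack(theta[(k + 1L):(k + 3L)], 2L)
    k <- k + 3L
  }
  mu <- theta[(k + 1L):(k + 2L * T)]
  p <- if (index$variant == "altsr") {
    structure(
      list(n_waves = T, phi = head_block,
           psi_ri = head_block[1:2, 1:2, drop = FALSE], B = B,
           theta = thetas, mu = mu, labels = index$labels,
           schedule = index$schedule),
      class = c("altsr_params", "riclpm_params")
    )
  } else {
    structure(
      list(n_waves = T, psi_ri = head_block, B = B, theta = thetas, mu = mu,
           labels = index$labels),
      class = "riclpm_params"
    )
  }
  if (validate) validate_params(p)
  p
}

# Packed-vector positions holding log-diagonal Cholesky entries (used to
# detect variance-floor boundary solutions). Within a lower-triangular
# column-major packing of a d x d factor, column j's diagonal entry sits
# after the d-j+1 entries of the previous columns.
log_diag_positions <- function(index) {
  T <- index$n_waves
  ld <- function(offset, d) {
    offset + cumsum(c(1L, if (d > 1) (d - seq_len(d - 1) + 1L)))[seq_len(d)]
  }
  head_d <- if (index$variant == "altsr") 4L else 2L
  head_n <- (head_d * (head_d + 1L)) %/% 2L
  pos <- ld(0L, head_d)                      # intercept/slope block
  pos <- c(pos, ld(head_n, 2L))              # wave-1 within block
  off <- head_n + 3L + 4L * (T - 1L)
  for (t in seq_len(T - 1L)) {
    pos <- c(pos, ld(off + 3L * (t - 1L), 2L))
  }
  pos
}

# ---- implied moments --------------------------------------------------------

#' Model-implied mean vector and covariance matrix
#'
#' Computes the first and second moments of the 2T observed variables implied
#' by a parameter set. The within-process covariance follows the lag-1
#' recursion `C[1] = theta[[1]]`, `C[t+1] = B[t] C[t] B[t]' + theta[[t+1]]`,
#' with cross-wave blocks obtained by propagating through the intervening
#' coefficient matrices; the between part adds the intercept (and, for
#' ALT-SR, slope) covariance through the fixed unit/slope loadings.
#'
#' @param params A `riclpm_params` or `altsr_params`.
#' @return A list with `mu` (length 2T) and `sigma` (2T x 2T, symmetric).
#' @export
implied_moments <- function(params) {
  UseMethod("implied_moments")
}

# Within-process covariance blocks shared by both variants.
within_covariance <- function(params) {
  T <- params$n_waves
  W <- matrix(0, 2 * T, 2 * T)
  C <- vector("list", T)
  C[[1]] <- params$theta[[1]]
  for (t in seq_len(T - 1)) {
    C[[t + 1]] <- params$B[[t]] %*% C[[t]] %*% t(params$B[[t]]) +
      params$theta[[t + 1]]
  }
  for (t in seq_len(T)) {
    it <- (2 * t - 1):(2 * t)
    W[it, it] <- C[[t]]
    X <- C[[t]]
    if (t < T) {
      for (s in (t + 1):T) {
        X <- params$B[[s - 1]] %*% X
        is <- (2 * s - 1):(2 * s)
        W[is, it] <- X
        W[it, is] <- t(X)
      }
    }
  }
  W
}

#' @export
implied_moments.riclpm_params <- function(params) {
  T <- params$n_waves
  sigma <- within_covariance(params) +
    matrix(1, T, T) %x% params$psi_ri
  list(mu = params$mu, sigma = (sigma + t(sigma)) / 2)
}

#' @export
implied_moments.altsr_params <- function(params) {
  T <- params$n_waves
  lam <- slope_loadings(params$schedule)
  L <- matrix(0, 2 * T, 4)
  rows1 <- seq(1, 2 * T, by = 2)
  rows2 <- seq(2, 2 * T, by = 2)
  L[rows1, 1] <- 1
  L[rows2, 2] <- 1
  L[rows1, 3] <- lam[[1]]
  L[rows2, 4] <- lam[[2]]
  sigma <- within_covariance(params) + L %*% params$phi %*% t(L)
  list(mu = params$mu, sigma = (sigma + t(sigma)) / 2)
}
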