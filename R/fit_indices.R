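#' @title Global fit indices
#' @description
#' Likelihood-ratio chi-square against the saturated model, RMSEA with a
#' noncentrality-inversion confidence interval, CFI/TLI against the
#' independence baseline, SRMR on correlation-metric covariance residuals,
#' and the adequacy thresholds RMSEA <= 0.05, CFI >= 0.95, TLI >= 0.95,
#' SRMR < 0.08 (note the strict inequality for SRMR).
#' @name fit_indices
NULL

#' Likelihood-ratio chi-square
#'
#' @param ll_model Maximised model log-likelihood.
#' @param ll_saturated Maximised saturated log-likelihood (must be >= model).
#' @param df Model degrees of freedom.
#' @return List with `chi2` and `p`.
#' @export
chi_square <- function(ll_model, ll_saturated, df) {
  chi2 <- 2 * (ll_saturated - ll_model)
  if (chi2 < -1e-8) {
    stop("internal inconsistency: saturated log-likelihood below model ",
         "log-likelihood (chi2 = ", chi2, ")", call. = FALSE)
  }
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Root mean square error of approximation with confidence interval
#'
#' Point estimate `sqrt(max(chi2 - df, 0) / (df (n - 1)))`; interval bounds
#' by inverting the noncentral chi-square distribution in its noncentrality
#' parameter at the requested coverage and mapping `sqrt(lambda / (df (n -
#' 1)))`.
#'
#' @param chi2 Chi-square statistic.
#' @param df Degrees of freedom (>= 1).
#' @param n Sample size (> 1).
#' @param conf Interval coverage (default 0.95).
#' @param denominator `"n-1"` (default) or `"n"`; the two agree to three
#'   decimals at cohort-scale n.
#' @return List with `rmsea`, `lo`, `hi`, `conf`.
#' @export
rmsea <- function(chi2, df, n, conf = 0.95, denominator = c("n-1", "n")) {
  stopifnot(n > 1, df >= 1)
  denominator <- match.arg(denominator)
  den <- df * (if (denominator == "n-1") n - 1 else n)
  point <- sqrt(max(chi2 - df, 0) / den)
  a <- (1 - conf) / 2
  # lambda_lo solves P(X_{df,lambda} <= chi2) = 1 - a ; 0 if impossible
  ncp_root <- function(target) {
    # pchisq is decreasing in the ncp; its maximum is at ncp = 0
    if (stats::pchisq(chi2, df, ncp = 0) <= target) return(0)
    hi <- max(2 * chi2, df + 10)
    while (stats::pchisq(chi2, df, ncp = hi) > target && hi < 1e7) hi <- hi * 2
    stats::uniroot(function(l) stats::pchisq(chi2, df, ncp = l) - target,
                   c(0, hi), tol = 1e-8)$root
  }
  lo <- sqrt(ncp_root(1 - a) / den)
  hi <- sqrt(ncp_root(a) / den)
  list(rmsea = point, lo = lo, hi = hi, conf = conf)
}

#' Comparative fit index and Tucker-Lewis index
#'
#' `cfi = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`;
#' `tli = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`. TLI may exceed
#' 1; by default it is clamped at 1 (configurable).
#'
#' @param chi2,df Model statistic and degrees of freedom.
#' @param chi2_baseline,df_baseline Baseline (independence) model statistic
#'   and degrees of freedom.
#' @param clamp_tli Clamp TLI at 1 (default TRUE).
#' @return List with `cfi` and `tli`.
#' @export
cfi_tli <- function(chi2, df, chi2_baseline, df_baseline, clamp_tli = TRUE) {
  if (df_baseline == 0) stop("baseline degrees of freedom must be positive",
                             call. = FALSE)
  num <- max(chi2 - df, 0)
  den <- max(chi2_baseline - df_baseline, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- chi2_baseline / df_baseline
  rm <- chi2 / df
  tli <- (rb - rm) / (rb - 1)
  if (clamp_tli) tli <- min(tli, 1)
  list(cfi = cfi, tli = tli)
}

#' Standardized root mean square residual
#'
#' Root mean square of the standardized covariance residuals
#' `s_ij / sqrt(s_ii s_jj) - sigma_ij / sqrt(sigma_ii sigma_jj)` over the
#' lower triangle including the diagonal (p(p+1)/2 terms; mean residuals
#' excluded). Under missingness the sample moments should be the
#' saturated-model FIML estimates (see [saturated_and_baseline_loglik()]).
#'
#' @param sample_sigma Sample (or saturated-FIML) covariance.
#' @param implied_sigma Model-implied covariance in the same variable order.
#' @return Scalar SRMR.
#' @export
srmr <- function(sample_sigma, implied_sigma) {
  ds <- diag(sample_sigma)
  if (any(ds <= 0)) stop("sample covariance has non-positive diagonal",
                         call. = FALSE)
  di <- diag(implied_sigma)
  Rs <- sample_sigma / sqrt(tcrossprod(ds))
  Ri <- implied_sigma / sqrt(tcrossprod(di))
  res <- (Rs - Ri)[lower.tri(Rs, diag = TRUE)]
  sqrt(mean(res^2))
}

#' Adequacy flags for a set of fit indices
#'
#' RMSEA <= 0.05 (inclusive), CFI >= 0.95, TLI >= 0.95, SRMR < 0.08
#' (strict).
#'
#' @param rmsea,cfi,tli,srmr Index values.
#' @return Named logical vector with an `all` summary.
#' @export
adequacy <- function(rmsea, cfi, tli, srmr) {
  flags <- c(rmsea = rmsea <= 0.05, cfi = cfi >= 0.95,
             tli = tli >= 0.95, srmr = srmr < 0.08)
  c(flags, all = all(flags))
}

#' Full fit-index set for a fitted model
#'
#' Computes chi-square, RMSEA (with CI), CFI, TLI and SRMR for a
#' `riclpm_fit`, fitting the saturated and baseline models on the same data.
#'
#' @param fit A `riclpm_fit`.
#' @param panel The panel (or matrix) the model was fitted to.
#' @param conf RMSEA interval coverage.
#' @return An object of class `fit_index_set`.
#' @export
fit_index_set <- function(fit, panel, conf = 0.95) {
  sb <- saturated_and_baseline_loglik(panel)
  cs <- chi_square(fit$loglik, sb$loglik_saturated, fit$df)
  csb <- chi_square(sb$loglik_baseline, sb$loglik_saturated, sb$df_baseline)
  rm <- rmsea(cs$chi2, fit$df, fit$n, conf = conf)
  ct <- cfi_tli(cs$chi2, fit$df, csb$chi2, sb$df_baseline)
  sr <- srmr(sb$sigma, implied_moments(fit$params)$sigma)
  structure(
    list(chi2 = cs$chi2, df = fit$df, p_value = cs$p,
         rmsea = rm$rmsea, rmsea_lo = rm$lo, rmsea_hi = rm$hi,
         rmsea_conf = conf, cfi = ct$cfi, tli = ct$tli, srmr = sr,
         chi2_baseline = csb$chi2, df_baseline = sb$df_baseline,
         adequate = adequacy(rm$rmsea, ct$cfi, ct$tli, sr),
         thresholds = c(rmsea = 0.05, cfi = 0.95, tli = 0.95, srmr = 0.08)),
    class = "fit_index_set"
  )
}

#' @export
print.fit_index_set <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.2f, p %s\n", x$df, x$chi2,
              ifelse(x$p_value < 0.001, "< .001",
                     paste0("= ", signif(x$p_value, 3)))))
  cat(sprintf("RMSEA [%d%% CI] = %.3f [%.3f, %.3f]; CFI = %.3f; TLI = %.3f; SRMR = %.3f\n",
              round(100 * x$rmsea_conf), x$rmsea, x$rmsea_lo, x$rmsea_hi,
              x$cfi, x$tli, x$srmr))
  cat("adequate:", paste(names(x$adequate), unname(x$adequate),
                         collapse = ", "), "\n")
  invisible(x)
}
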