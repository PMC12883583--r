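#' Published reference estimates for the depressive-symptoms / fat-mass-index
#' co-development analysis
#'
#' Standardized lag-1 RI-CLPM estimates from a large UK birth-cohort analysis
#' of self-reported depressive symptom scores (6 waves, ages 10.6--23.8) and
#' fat mass index (6 waves, ages 9.8--24.5), as printed: per-lag standardized
#' coefficients with 95% CIs, predictor/outcome median ages, lag durations and
#' yearly (time-adjusted) estimates. These serve as calibration targets for
#' [default_truth()] and as inputs to the reporting arithmetic; the underlying
#' individual-level cohort data are access-restricted and are not part of this
#' package.
#'
#' Path labels: `AR_dep`, `AR_cm` (autoregressive), `CL_cm_dep` (marker to
#' later symptoms), `CL_dep_cm` (symptoms to later marker).
#'
#' @return A data.frame with one row per path and lag: `path`, `lag`, `beta`,
#'   `lo`, `hi`, `age_from`, `age_to`, `dt`, `yearly`, `yearly_lo`,
#'   `yearly_hi`.
#' @seealso [reference_fit_stats()], [reference_correlations()]
#' @export
reference_estimates <- function() {
  tab <- rbind(
    data.frame(path = "AR_cm", lag = 1:5,
               beta = c(0.84, 0.73, 0.84, 0.82, 0.54),
               lo   = c(0.82, 0.71, 0.82, 0.80, 0.47),
               hi   = c(0.85, 0.76, 0.85, 0.84, 0.60),
               age_from = c(9.8, 11.8, 13.8, 15.4, 17.8),
               age_to   = c(11.8, 13.8, 15.4, 17.8, 24.5),
               dt       = c(2.0, 2.0, 1.6, 2.4, 6.7),
               yearly    = c(0.42, 0.37, 0.52, 0.34, 0.08),
               yearly_lo = c(0.41, 0.36, 0.51, 0.33, 0.07),
               yearly_hi = c(0.43, 0.38, 0.53, 0.35, 0.09)),
    data.frame(path = "AR_dep", lag = 1:5,
               beta = c(0.12, 0.32, 0.21, 0.38, 0.26),
               lo   = c(0.08, 0.28, 0.18, 0.34, 0.21),
               hi   = c(0.16, 0.35, 0.25, 0.42, 0.30),
               age_from = c(10.6, 12.8, 13.8, 16.6, 17.8),
               age_to   = c(12.8, 13.8, 16.6, 17.8, 23.8),
               dt       = c(2.2, 1.0, 2.8, 1.2, 6.0),
               yearly    = c(0.05, 0.32, 0.08, 0.31, 0.04),
               yearly_lo = c(0.04, 0.28, 0.06, 0.28, 0.03),
               yearly_hi = c(0.07, 0.35, 0.09, 0.35, 0.05)),
    data.frame(path = "CL_cm_dep", lag = 1:5,
               beta = c(0.04, 0.03, 0.13, 0.08, 0.08),
               lo   = c(0.00, -0.01, 0.09, 0.03, 0.03),
               hi   = c(0.09, 0.06, 0.17, 0.12, 0.13),
               age_from = c(9.8, 11.8, 13.8, 15.4, 17.8),
               age_to   = c(12.8, 13.8, 16.6, 17.8, 23.8),
               dt       = c(3.0, 2.0, 2.8, 2.4, 6.0),
               yearly    = c(0.01, 0.01, 0.05, 0.03, 0.01),
               yearly_lo = c(0.00, -0.01, 0.03, 0.01, 0.01),
               yearly_hi = c(0.03, 0.03, 0.06, 0.05, 0.02)),
    data.frame(path = "CL_dep_cm", lag = 1:5,
               beta = c(0.03, 0.04, 0.05, 0.03, 0.06),
               lo   = c(0.01, 0.01, 0.03, 0.00, 0.00),
               hi   = c(0.05, 0.06, 0.07, 0.05, 0.12),
               age_from = c(10.6, 12.8, 13.8, 16.6, 17.8),
               age_to   = c(11.8, 13.8, 15.4, 17.8, 24.5),
               dt       = c(1.2, 1.0, 1.6, 1.2, 6.7),
               yearly    = c(0.03, 0.04, 0.03, 0.02, 0.01),
               yearly_lo = c(0.01, 0.01, 0.02, 0.00, 0.00),
               yearly_hi = c(0.05, 0.06, 0.04, 0.04, 0.02))
  )
  rownames(tab) <- NULL
  tab
}

#' Published fit statistics of the reference analysis
#'
#' @return A list: `chi2`, `df`, `n`, `rmsea`, `rmsea_ci`, `cfi`, `tli`,
#'   `srmr`.
#' @export
reference_fit_stats <- function() {
  list(chi2 = 356.77, df = 37L, n = 7970L,
       rmsea = 0.033, rmsea_ci = c(0.030, 0.036),
       cfi = 0.991, tli = 0.983, srmr = 0.027)
}

#' Published cross-sectional residual correlations and intercept correlation
#'
#' @return A list with `residual` (data.frame: wave, r, lo, hi) and
#'   `intercept` (vector: r, lo, hi).
#' @export
reference_correlations <- function() {
  list(
    residual = data.frame(
      wave = 1:6,
      r  = c(-0.08, 0.02, 0.10, 0.11, -0.02, 0.10),
      lo = c(-0.12, -0.02, 0.07, 0.07, -0.06, 0.03),
      hi = c(-0.04, 0.06, 0.13, 0.14, 0.01, 0.17)
    ),
    intercept = c(r = 0.11, lo = 0.06, hi = 0.16)
  )
}
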