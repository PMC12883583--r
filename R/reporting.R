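#' @title Time-adjusted reporting of lagged estimates
#' @description
#' Because assessment waves are unevenly spaced (1 to 6.7 years apart) and
#' the two constructs are measured at different ages, per-lag coefficients
#' are not directly comparable. The reporting layer attaches each path's
#' predictor and outcome median ages, the lag duration in years, and a
#' yearly (time-adjusted) estimate obtained by dividing the standardized
#' coefficient by the lag duration, assuming linear additivity of effects
#' over time. Display rounding is half-away-from-zero; full precision is
#' retained in CSV output.
#' @name reporting
NULL

#' Round half away from zero
#'
#' Display rounding used in the tables (0.075 -> 0.08, -0.075 -> -0.08),
#' unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Lag durations for every path
#'
#' Autoregressive paths span the same construct's consecutive median ages;
#' cross-lagged paths span the predictor construct's age at wave t to the
#' outcome construct's age at wave t+1 (so the two directions of a lag have
#' different durations when the constructs' schedules differ).
#'
#' @param schedule A [wave_schedule()].
#' @return A data.frame: `path`, `lag`, `age_from`, `age_to`, `dt`.
#' @export
lag_durations <- function(schedule) {
  stopifnot(inherits(schedule, "wave_schedule"))
  labs <- schedule$labels
  a1 <- schedule$ages[[1]]
  a2 <- schedule$ages[[2]]
  T <- schedule$n_waves
  t <- seq_len(T - 1)
  out <- rbind(
    data.frame(path = paste0("AR_", labs[1]), lag = t,
               age_from = a1[t], age_to = a1[t + 1]),
    data.frame(path = paste0("AR_", labs[2]), lag = t,
               age_from = a2[t], age_to = a2[t + 1]),
    data.frame(path = paste0("CL_", labs[2], "_", labs[1]), lag = t,
               age_from = a2[t], age_to = a1[t + 1]),
    data.frame(path = paste0("CL_", labs[1], "_", labs[2]), lag = t,
               age_from = a1[t], age_to = a2[t + 1])
  )
  out$dt <- out$age_to - out$age_from
  if (any(out$dt <= 0)) {
    stop("non-positive lag duration: outcome age must exceed predictor age",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Yearly (time-adjusted) estimate
#'
#' @param beta Standardized estimate (or CI bound).
#' @param dt Lag duration in years (> 0).
#' @return `beta / dt` (unrounded; use [round_half_away()] for display).
#' @export
yearly_estimate <- function(beta, dt) {
  if (any(dt <= 0)) stop("lag duration must be positive", call. = FALSE)
  beta / dt
}

#' Summaries of one path's per-lag estimates
#'
#' Arithmetic mean and range of the standardized estimates across lags, plus
#' the mean standard error, as used in text summaries such as
#' "mean beta \[range\] = 0.75 \[0.54; 0.84\], SE = 0.016".
#'
#' @param beta Numeric vector of per-lag standardized estimates.
#' @param se Optional vector of their standard errors.
#' @return List with `mean`, `min`, `max`, `mean_se`.
#' @export
summarize_paths <- function(beta, se = NULL) {
  stopifnot(length(beta) >= 1)
  list(mean = mean(beta), min = min(beta), max = max(beta),
       mean_se = if (is.null(se)) NA_real_ else mean(se))
}

#' Render the lagged-estimates table of a fitted model
#'
#' Produces the standard report: four path blocks (two autoregressive, two
#' cross-lagged) with per-lag standardized estimates, 95% CIs, median-age
#' pairs, lag durations and yearly estimates, followed by the per-wave
#' cross-sectional residual correlations and the random-intercept
#' correlation. Estimates whose CI excludes zero are flagged significant.
#'
#' @param fit A `riclpm_fit` with standard errors.
#' @param schedule A [wave_schedule()] (defaults to the index schedule for
#'   ALT-SR fits).
#' @return A data.frame of class `lag_table`; attribute `"summaries"` holds
#'   the per-path mean/range summaries.
#' @export
render_lag_table <- function(fit, schedule) {
  stopifnot(inherits(fit, "riclpm_fit"))
  std <- fit$standardized
  if (is.null(std$se)) {
    stop("fit has no standard errors; refit with se != 'none'", call. = FALSE)
  }
  T <- fit$index$n_waves
  durations <- lag_durations(schedule)
  nm <- names(std$estimate)
  pick <- function(name) {
    i <- match(name, nm)
    c(est = unname(std$estimate[i]), se = unname(std$se[i]),
      lo = unname(std$lo[i]), hi = unname(std$hi[i]))
  }
  rows <- lapply(seq_len(nrow(durations)), function(r) {
    d <- durations[r, ]
    v <- pick(paste0(d$path, "_", d$lag))
    data.frame(
      path = d$path, lag = d$lag, estimate = v["est"], se = v["se"],
      lo = v["lo"], hi = v["hi"], age_from = d$age_from, age_to = d$age_to,
      dt = d$dt,
      yearly = yearly_estimate(v["est"], d$dt),
      yearly_lo = yearly_estimate(v["lo"], d$dt),
      yearly_hi = yearly_estimate(v["hi"], d$dt),
      significant = v["lo"] > 0 | v["hi"] < 0,
      row.names = NULL
    )
  })
  tab <- do.call(rbind, rows)
  # cross-sectional residual correlations and the intercept correlation
  labs <- schedule$labels
  extra <- lapply(seq_len(T), function(t) {
    v <- pick(paste0("rcross_", t))
    data.frame(path = paste0("COR_", labs[2], "_", labs[1]), lag = t,
               estimate = v["est"], se = v["se"], lo = v["lo"], hi = v["hi"],
               age_from = schedule$ages[[2]][t],
               age_to = schedule$ages[[1]][t],
               dt = NA_real_, yearly = NA_real_, yearly_lo = NA_real_,
               yearly_hi = NA_real_,
               significant = v["lo"] > 0 | v["hi"] < 0, row.names = NULL)
  })
  ri <- pick("r_intercept")
  extra <- c(extra, list(data.frame(
    path = "COR_intercepts", lag = NA_integer_, estimate = ri["est"],
    se = ri["se"], lo = ri["lo"], hi = ri["hi"], age_from = NA_real_,
    age_to = NA_real_, dt = NA_real_, yearly = NA_real_,
    yearly_lo = NA_real_, yearly_hi = NA_real_,
    significant = ri["lo"] > 0 | ri["hi"] < 0, row.names = NULL)))
  tab <- rbind(tab, do.call(rbind, extra))
  rownames(tab) <- NULL
  paths <- unique(durations$path)
  summaries <- lapply(stats::setNames(paths, paths), function(pth) {
    sel <- tab$path == pth
    summarize_paths(tab$estimate[sel], tab$se[sel])
  })
  structure(tab, summaries = summaries, class = c("lag_table", "data.frame"))
}

#' @export
print.lag_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  fmt <- function(b, lo, hi) {
    ifelse(is.na(b), "", sprintf("%.2f [%.2f; %.2f]",
                                 round_half_away(b, digits),
                                 round_half_away(lo, digits),
                                 round_half_away(hi, digits)))
  }
  out <- data.frame(
    path = df$path, lag = df$lag,
    estimate = paste0(fmt(df$estimate, df$lo, df$hi),
                      ifelse(!is.na(df$significant) & df$significant, " *", "")),
    ages = ifelse(is.na(df$age_from), "",
                  sprintf("%.1f → %.1f", df$age_from, df$age_to)),
    dt = ifelse(is.na(df$dt), "", sprintf("%.1f", df$dt)),
    yearly = fmt(df$yearly, df$yearly_lo, df$yearly_hi)
  )
  print(out, row.names = FALSE, right = FALSE)
  s <- attr(x, "summaries")
  if (!is.null(s)) {
    cat("\nPath summaries (mean [range], mean SE):\n")
    for (nm in names(s)) {
      cat(sprintf("  %-14s %.2f [%.2f; %.2f], SE = %.3f\n", nm,
                  round_half_away(s[[nm]]$mean, 2),
                  round_half_away(s[[nm]]$min, 2),
                  round_half_away(s[[nm]]$max, 2), s[[nm]]$mean_se))
    }
  }
  invisible(x)
}

#' Write a lag table to CSV (full precision)
#'
#' @param tab A `lag_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lag_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}
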