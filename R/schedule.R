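#' Wave schedule for a two-construct panel
#'
#' A wave schedule records, for each of the two constructs, the ordered median
#' ages (in years) at which the repeated measures were taken. The two
#' constructs must share the same number of waves, but their ages may differ
#' wave by wave (uneven, construct-specific assessment schedules), which is
#' what makes time-adjusted reporting necessary.
#'
#' @param ages A named list of two strictly increasing numeric vectors of
#'   equal length: the per-construct median ages in years. Names are the
#'   construct labels (first element is the "first" construct, conventionally
#'   the symptom score).
#' @return An object of class `wave_schedule` with fields `labels`, `ages`
#'   (named list) and `n_waves`.
#' @examples
#' wave_schedule(list(dep = c(10.6, 12.8, 13.8), cm = c(9.8, 11.8, 13.8)))
#' @export
wave_schedule <- function(ages) {
  if (!is.list(ages) || length(ages) != 2L || is.null(names(ages)) ||
      any(!nzchar(names(ages)))) {
    stop("`ages` must be a named list of two numeric vectors", call. = FALSE)
  }
  labels <- names(ages)
  ages <- lapply(ages, as.numeric)
  n <- lengths(ages)
  if (n[1] != n[2]) {
    stop("both constructs must have the same number of waves", call. = FALSE)
  }
  for (lab in labels) {
    a <- ages[[lab]]
    if (any(!is.finite(a)) || any(a <= 0)) {
      stop("ages for '", lab, "' must be finite and positive", call. = FALSE)
    }
    if (any(diff(a) <= 0)) {
      stop("ages for '", lab, "' must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(labels = labels, ages = ages, n_waves = as.integer(n[1])),
    class = "wave_schedule"
  )
}

#' Default six-wave schedule
#'
#' The median ages used throughout the package's worked examples: self-reported
#' depressive symptom scores at 10.6, 12.8, 13.8, 16.6, 17.8 and 23.8 years and
#' a DXA-derived fat mass index at 9.8, 11.8, 13.8, 15.4, 17.8 and 24.5 years.
#'
#' @param labels Character vector of length 2 giving the construct labels.
#' @return A [wave_schedule()].
#' @export
default_schedule <- function(labels = c("dep", "cm")) {
  ages <- list(
    c(10.6, 12.8, 13.8, 16.6, 17.8, 23.8),
    c(9.8, 11.8, 13.8, 15.4, 17.8, 24.5)
  )
  names(ages) <- labels
  wave_schedule(ages)
}

#' @export
print.wave_schedule <- function(x, ...) {
  cat("Wave schedule:", x$n_waves, "waves\n")
  for (lab in x$labels) {
    cat(sprintf("  %-8s %s\n", lab, paste(x$ages[[lab]], collapse = ", ")))
  }
  invisible(x)
}

# Serialize / parse the sidecar format: one "label: a1, a2, ..." line per
# construct. Plain text so fixtures remain human-readable.
schedule_to_text <- function(schedule) {
  vapply(
    schedule$labels,
    function(lab) {
      paste0(lab, ": ", paste(schedule$ages[[lab]], collapse = ", "))
    },
    character(1)
  )
}

schedule_from_text <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  labs <- vapply(parts, function(p) trimws(p[1]), character(1))
  ages <- lapply(parts, function(p) {
    as.numeric(trimws(strsplit(p[2], ",", fixed = TRUE)[[1]]))
  })
  names(ages) <- labs
  wave_schedule(ages)
}
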