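#' Construct a raw panel
#'
#' A raw panel is a wide participant-by-wave table of scores for two
#' constructs, on their original measurement scale, together with the wave
#' schedule. Missing cells are `NA`. Columns follow the `<label>_<wave>`
#' convention, e.g. `dep_1 .. dep_6, cm_1 .. cm_6`.
#'
#' @param data A data.frame with an `id` column and one `<label>_<wave>`
#'   column per construct and wave.
#' @param schedule A [wave_schedule()].
#' @return An object of class `raw_panel`: a list with `data`, `schedule`.
#' @export
raw_panel <- function(data, schedule) {
  stopifnot(inherits(schedule, "wave_schedule"))
  data <- as.data.frame(data)
  if (!"id" %in% names(data)) {
    data <- cbind(id = seq_len(nrow(data)), data)
  }
  needed <- panel_columns(schedule)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[, c("id", needed)]
  structure(list(data = data, schedule = schedule), class = "raw_panel")
}

panel_columns <- function(schedule) {
  unlist(lapply(schedule$labels, function(lab) {
    paste0(lab, "_", seq_len(schedule$n_waves))
  }))
}

# Columns of one construct, in wave order.
construct_columns <- function(schedule, label) {
  paste0(label, "_", seq_len(schedule$n_waves))
}

#' Observed-variable matrix of a panel in model order
#'
#' Returns the participant-by-variable matrix with columns interleaved as
#' (construct1_wave1, construct2_wave1, construct1_wave2, ...): waves vary
#' slowest, constructs fastest. This is the variable order used by all
#' model-implied moments and fitted objects.
#'
#' @param panel A `raw_panel` or `model_panel`.
#' @return Numeric matrix (missing cells `NA`), row names = participant ids.
#' @export
panel_matrix <- function(panel) {
  sch <- panel$schedule
  cols <- as.vector(rbind(
    construct_columns(sch, sch$labels[1]),
    construct_columns(sch, sch$labels[2])
  ))
  m <- as.matrix(panel$data[, cols])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(panel$data$id)
  m
}

# Names of the interleaved model variables.
model_variable_names <- function(schedule) {
  as.vector(rbind(
    construct_columns(schedule, schedule$labels[1]),
    construct_columns(schedule, schedule$labels[2])
  ))
}

#' Number of participants in a panel
#' @param panel A `raw_panel` or `model_panel`.
#' @return Integer row count.
#' @export
n_participants <- function(panel) nrow(panel$data)

#' @export
print.raw_panel <- function(x, ...) {
  cat("Raw panel:", nrow(x$data), "participants x",
      x$schedule$n_waves, "waves x 2 constructs (",
      paste(x$schedule$labels, collapse = ", "), ")\n")
  invisible(x)
}

#' Write a panel to a wide CSV fixture with a schedule sidecar
#'
#' Writes `<path>` as a wide CSV (one row per participant, empty fields for
#' missing cells) and `<path>.schedule` as a key-value text file holding the
#' per-construct median ages, so that the panel round-trips losslessly
#' through [read_panel()].
#'
#' @param panel A `raw_panel` (or `model_panel`; values written as-is).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  ok <- tryCatch({
    utils::write.csv(panel$data, path, row.names = FALSE, na = "")
    writeLines(schedule_to_text(panel$schedule), paste0(path, ".schedule"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write panel fixture at '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read a panel from a wide CSV fixture
#'
#' @param path CSV path previously written by [write_panel()], or any CSV in
#'   the same wide layout.
#' @param schedule Optional [wave_schedule()]; when `NULL` the sidecar file
#'   `<path>.schedule` is read.
#' @return A `raw_panel`.
#' @export
read_panel <- function(path, schedule = NULL) {
  if (is.null(schedule)) {
    sidecar <- paste0(path, ".schedule")
    if (!file.exists(sidecar)) {
      stop("no schedule given and sidecar '", sidecar, "' not found",
           call. = FALSE)
    }
    schedule <- schedule_from_text(readLines(sidecar))
  }
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw_panel(data, schedule)
}

#' Convert between long and wide panel layouts
#'
#' The long layout has columns `id`, `construct`, `wave`, `value`; the wide
#' layout is the package's native `<label>_<wave>` form.
#'
#' @param data Long-format data.frame.
#' @param schedule A [wave_schedule()] naming the constructs.
#' @return A `raw_panel`.
#' @export
long_to_wide <- function(data, schedule) {
  stopifnot(all(c("id", "construct", "wave", "value") %in% names(data)))
  ids <- sort(unique(data$id))
  out <- data.frame(id = ids)
  for (lab in schedule$labels) {
    for (w in seq_len(schedule$n_waves)) {
      sel <- data$construct == lab & data$wave == w
      col <- rep(NA_real_, length(ids))
      col[match(data$id[sel], ids)] <- data$value[sel]
      out[[paste0(lab, "_", w)]] <- col
    }
  }
  raw_panel(out, schedule)
}
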