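#' @title End-to-end pipeline orchestration
#' @description
#' Runs simulate (or load) -> preprocess -> fit -> fit indices -> lag table
#' as one reproducible unit: a config fully determines the run, every stage's
#' counts are logged, and the output bundle carries a manifest with the seed
#' and a config hash so identical configs reproduce identical numbers.
#' @name pipeline
NULL

#' Build a run configuration
#'
#' Exactly one of simulation mode (`n` given) or data mode (`input` path
#' given) must be active.
#'
#' @param schedule A [wave_schedule()].
#' @param transforms Named per-construct transform kinds.
#' @param variant `"riclpm"` or `"altsr"`.
#' @param n Simulation-mode sample size.
#' @param seed Seed for simulation and fitting restarts.
#' @param missing A [missing_spec()] (simulation mode).
#' @param input Data-mode CSV path (wide layout, schedule sidecar honoured).
#' @param out Output directory.
#' @param k Outlier fence multiplier.
#' @param options A [fit_options()] list.
#' @return A list of class `run_config`.
#' @export
run_config <- function(schedule = default_schedule(),
                       transforms = stats::setNames(c("sqrt", "ln"),
                                                    schedule$labels),
                       variant = c("riclpm", "altsr"),
                       n = NULL, seed = 1L,
                       missing = default_missing_spec(schedule$labels),
                       input = NULL, out = tempfile("riclpm_run_"),
                       k = 5, options = fit_options(seed = seed)) {
  variant <- match.arg(variant)
  if (is.null(n) == is.null(input)) {
    stop("exactly one of `n` (simulation mode) or `input` (data mode) ",
         "must be given", call. = FALSE)
  }
  structure(
    list(schedule = schedule, transforms = transforms, variant = variant,
         n = n, seed = as.integer(seed), missing = missing, input = input,
         out = out, k = k, options = options),
    class = "run_config"
  )
}

# Deterministic polynomial hash of the config's serialized form (8-hex-digit
# string); a manifest fingerprint, not a cryptographic digest.
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
               collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `panel`, `model_panel`, `fit`, `indices`,
#'   `table`, and `files` (the artifact paths). Artifacts written: the
#'   simulated fixture (simulation mode), preprocessing log, fit summary
#'   (JSON + CSV), fit-index JSON, lag-table CSV and a manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out, ...)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name, "\n",
                        conditionMessage(e)), out("FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  panel <- stage("simulate/load", {
    if (!is.null(config$n)) {
      truth <- default_truth(config$schedule)
      p <- simulate_panel(truth, n = config$n, missing = config$missing,
                          seed = config$seed)
      write_panel(p, out("panel.csv"))
      files <- c(files, out("panel.csv"))
      p
    } else {
      read_panel(config$input, schedule = config$schedule)
    }
  })

  mp <- stage("preprocess", preprocess_panel(panel, config$transforms,
                                             k = config$k))
  jsonlite::write_json(mp$log, out("preprocess_log.json"), auto_unbox = TRUE,
                       digits = NA)

  fit <- stage("fit", fit_riclpm(mp, variant = config$variant,
                                 schedule = config$schedule,
                                 options = config$options))
  indices <- stage("fit_indices", fit_index_set(fit, mp))
  tab <- stage("report", render_lag_table(fit, config$schedule))

  std <- fit$standardized
  jsonlite::write_json(
    list(variant = config$variant, n = fit$n, df = fit$df,
         loglik = fit$loglik, convergence = fit$convergence,
         estimates = as.list(std$estimate), se = as.list(std$se),
         ci_lo = as.list(std$lo), ci_hi = as.list(std$hi)),
    out("fit.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(
    data.frame(quantity = names(std$estimate), estimate = std$estimate,
               se = std$se, lo = std$lo, hi = std$hi, row.names = NULL),
    out("fit.csv"), row.names = FALSE
  )
  jsonlite::write_json(
    unclass(indices)[c("chi2", "df", "p_value", "rmsea", "rmsea_lo",
                       "rmsea_hi", "cfi", "tli", "srmr", "chi2_baseline",
                       "df_baseline")] |>
      c(list(adequate = as.list(indices$adequate),
             thresholds = as.list(indices$thresholds))),
    out("fit_indices.json"), auto_unbox = TRUE, digits = NA
  )
  write_lag_table(tab, out("lag_table.csv"))
  jsonlite::write_json(
    list(seed = config$seed, variant = config$variant,
         n = if (!is.null(config$n)) config$n else NA,
         input = if (!is.null(config$input)) config$input else NA,
         config_hash = config_hash(config),
         version = as.character(utils::packageVersion("riclpm")),
         n_retained = mp$log$n_retained, cells_masked = mp$log$n_cells_masked),
    out("manifest.json"), auto_unbox = TRUE, digits = NA
  )

  invisible(list(panel = panel, model_panel = mp, fit = fit,
                 indices = indices, table = tab,
                 files = list.files(config$out, full.names = TRUE)))
}

#' Fit several model variants on the same panel
#'
#' Fits each requested variant to the same (simulated or loaded,
#' preprocessed) panel and returns side-by-side standardized cross-lagged
#' paths and fit indices, in the order given.
#'
#' @param config A [run_config()].
#' @param variants Character vector of variants (length >= 2, duplicates
#'   allowed).
#' @return A data.frame: one row per quantity, one column per variant.
#' @export
compare_models <- function(config, variants = c("riclpm", "altsr")) {
  stopifnot(length(variants) >= 2)
  panel <- if (!is.null(config$n)) {
    simulate_panel(default_truth(config$schedule), n = config$n,
                   missing = config$missing, seed = config$seed)
  } else {
    read_panel(config$input, schedule = config$schedule)
  }
  mp <- preprocess_panel(panel, config$transforms, k = config$k)
  cols <- lapply(variants, function(v) {
    fit <- fit_riclpm(mp, variant = v, schedule = config$schedule,
                      options = config$options)
    idx <- fit_index_set(fit, mp)
    std <- fit$standardized$estimate
    keep <- grepl("^CL_|^r_intercept$", names(std))
    c(std[keep],
      chi2 = idx$chi2, df = idx$df, rmsea = idx$rmsea, cfi = idx$cfi,
      tli = idx$tli, srmr = idx$srmr,
      slope_var_1 = if (v == "altsr") fit$params$phi[3, 3] else NA_real_,
      slope_var_2 = if (v == "altsr") fit$params$phi[4, 4] else NA_real_)
  })
  out <- data.frame(quantity = names(cols[[1]]))
  for (i in seq_along(variants)) {
    out[[paste0(variants[i], "_", i)]] <- unname(cols[[i]])
  }
  out
}
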