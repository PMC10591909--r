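#' Full synergy analysis of a study
#'
#' The whole pipeline in one call: read (or accept) a study dataset,
#' validate it, compute per-mouse and per-group eGRs, run the stratified
#' BCa bootstrap for the requested synergy models, and optionally the
#' single-day log-ratio Bliss baseline. The returned report carries a
#' provenance block (seed, n_boot, t_eval, package version) sufficient to
#' reproduce every number in it.
#'
#' @param x a `study_dataset` or a path to a study CSV.
#' @param models character vector from `c("bliss", "hsa")`.
#' @param t_eval evaluation time in days (default 21).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param max_day optional truncation of curves before eGR.
#' @param baseline if `TRUE`, also compute [global_ci()].
#' @param column_map passed to [read_study()] when `x` is a path.
#' @return an `analysis_report`: list with `input` (summary), `validation`,
#'   `egr` (an `egr_table`), `inference` (named list of
#'   `synergy_inference`), `baseline` (or `NULL`) and `provenance`.
#' @export
analyze_study <- function(x, models = c("bliss", "hsa"), t_eval = 21,
                          n_boot = 1000, seed = 1, max_day = NULL,
                          baseline = FALSE, column_map = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  ds <- if (inherits(x, "study_dataset")) x else read_study(x, column_map)
  issues <- validate_study(ds)
  if (any(issues$severity == "fatal")) {
    stop("study fails validation: ",
         paste(issues$message[issues$severity == "fatal"], collapse = "; "),
         call. = FALSE)
  }
  egrs <- suppressWarnings(group_egr(ds, max_day = max_day))
  inference <- list()
  for (i in seq_along(models)) {
    inference[[models[i]]] <- bootstrap_synergy(
      ds, model = models[i], t_eval = t_eval, n_boot = n_boot,
      seed = seed + i - 1L, max_day = max_day
    )
  }
  base <- if (baseline) global_ci(ds) else NULL
  mice <- study_mice(ds)
  structure(
    list(
      input = list(
        n_mice = nrow(mice), group_sizes = as.list(group_sizes(ds)),
        day_span = range(ds$day), n_measurements = nrow(ds),
        n_not_analyzable = sum(!mice$analyzable)
      ),
      validation = issues,
      egr = egrs,
      inference = inference,
      baseline = base,
      provenance = list(seed = seed, n_boot = n_boot, t_eval = t_eval,
                        max_day = max_day, models = models,
                        package_version = as.character(
                          utils::packageVersion("egrsyn")))
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  input:", x$input$n_mice, "mice,", x$input$n_measurements,
      "measurements, days", x$input$day_span[1], "-", x$input$day_span[2], "\n")
  for (m in names(x$inference)) print(x$inference[[m]])
  if (!is.null(x$baseline)) print(x$baseline)
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serializes the point estimates, intervals, P values, group eGRs, optional
#' baseline table and provenance block. The bootstrap distributions can be
#' dumped alongside as CSV for histogram plots.
#'
#' @param report an [analyze_study()] report.
#' @param path output JSON path.
#' @param boot_csv optional path for a CSV dump of the bootstrap
#'   distributions (columns: model, replicate, ci, ss).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, boot_csv = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  inf <- lapply(report$inference, function(z) {
    list(
      model = z$observed$model,
      t_eval = z$observed$t_eval,
      egr = as.list(z$observed$egr),
      relative_survival = as.list(z$observed$survival),
      expected_survival = z$observed$expected_survival,
      ci = z$observed$ci,
      ss = z$observed$ss,
      verdict = z$observed$verdict,
      intervals = z$intervals,
      p_ci = z$p[["ci"]],
      p_ss = z$p[["ss"]],
      degenerate = as.list(z$degenerate),
      n_boot = z$config$n_boot,
      seed = z$config$seed,
      level = z$config$level
    )
  })
  out <- list(
    input = report$input,
    validation = report$validation,
    group_egr = report$egr$group,
    inference = inf,
    provenance = report$provenance
  )
  if (!is.null(report$baseline)) {
    out$baseline <- list(gci = report$baseline$gci,
                         days_used = report$baseline$days_used,
                         per_day = report$baseline$per_day)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(boot_csv)) {
    dump <- dplyr::bind_rows(lapply(names(report$inference), function(m) {
      b <- report$inference[[m]]$boot
      tibble(model = m, replicate = seq_len(nrow(b)), ci = b$ci, ss = b$ss)
    }))
    readr::write_csv(dump, boot_csv, progress = FALSE)
  }
  invisible(path)
}
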