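# End-to-end analysis pipeline: describe -> correlations -> optional term
# screen -> constant-dispersion GLM -> joint GLM -> comparison ->
# diagnostics, with a JSON report. Logging goes to standard error via
# message(); the report goes to a file (or is only returned).

log_info <- function(fmt, ...) message(sprintf(paste0("INFO  ", fmt), ...))

#' Construct a pipeline configuration
#'
#' Exactly one data source must be given: a cohort (a [cohort_table()] or a
#' CSV path) or a [generator_config()] for a synthetic cohort.
#'
#' @param data a [cohort_table()] or CSV path, or `NULL`.
#' @param generator a [generator_config()], or `NULL`.
#' @param mean_terms,disp_terms term lists for the two submodels.
#' @param method `"REML"` or `"ML"`.
#' @param screen if `TRUE`, run [backward_eliminate()] on the mean terms
#'   before fitting.
#' @param screen_threshold retention p-value for the screen, in (0, 1).
#' @param out optional path for the JSON report.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, generator = NULL,
                            mean_terms = default_terms(),
                            disp_terms = default_terms(),
                            method = c("REML", "ML"),
                            screen = FALSE, screen_threshold = 0.2,
                            out = NULL) {
  method <- match.arg(method)
  if (is.null(data) == is.null(generator)) {
    stop("pipeline_config: give exactly one of `data` or `generator`",
         call. = FALSE)
  }
  if (screen_threshold <= 0 || screen_threshold >= 1) {
    stop("pipeline_config: screen_threshold must be in (0, 1)", call. = FALSE)
  }
  structure(list(data = data, generator = generator,
                 mean_terms = mean_terms, disp_terms = disp_terms,
                 method = method, screen = isTRUE(screen),
                 screen_threshold = screen_threshold, out = out),
            class = "pipeline_config")
}

run_stage <- function(stage, report, out, expr) {
  tryCatch(expr, error = function(e) {
    partial <- NULL
    if (!is.null(out)) {
      partial <- paste0(out, ".partial")
      try(write_report(report, partial), silent = TRUE)
    }
    stop(errorCondition(
      paste0("run_pipeline: stage '", stage, "' failed: ",
             conditionMessage(e),
             if (!is.null(partial)) paste0(" (partial report: ", partial, ")")),
      stage = stage,
      class = c("muacjglm_stage_error", "error", "condition")))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort ingestion (or generation), descriptive
#' statistics, correlations, an optional backward-elimination screen of the
#' mean terms, the constant-dispersion Gaussian GLM, the joint
#' mean-dispersion GLM, the criteria comparison, and diagnostics for both
#' fits. Each stage logs row counts / convergence at INFO level on standard
#' error. The assembled report (analogues of the six published tables plus
#' the two diagnostics bundles) is returned and, when `config$out` is set,
#' written as JSON at full precision.
#'
#' @param config a [pipeline_config()].
#' @return the report, an object of class `muac_report` (a named list),
#'   invisibly when written to file.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  out <- config$out

  tab <- run_stage("ingest", report, out, {
    if (!is.null(config$generator)) {
      t0 <- generate_cohort(config$generator)
      log_info("generated synthetic cohort: n = %d (seed %d)", nrow(t0),
               config$generator$seed)
      t0
    } else if (inherits(config$data, "cohort_table")) {
      log_info("using in-memory cohort: n = %d", nrow(config$data))
      config$data
    } else {
      t0 <- read_cohort(config$data)
      log_info("read cohort from %s: n = %d", config$data, nrow(t0))
      t0
    }
  })

  report$descriptives <- run_stage("describe", report, out, {
    d <- describe_cohort(tab)
    log_info("descriptive statistics: %d variables", nrow(d))
    d
  })

  report$correlations <- run_stage("correlations", report, out, {
    cc <- cohort_correlations(tab)
    log_info("correlation matrix: %d x %d", nrow(cc$r), ncol(cc$r))
    list(labels = cc$labels, r = cc$r, p = cc$p, flags = cc$flags)
  })

  mean_terms <- config$mean_terms
  if (config$screen) {
    mean_terms <- run_stage("screen", report, out, {
      kept <- backward_eliminate(tab, config$mean_terms,
                                 threshold = config$screen_threshold)
      log_info("backward elimination: kept %d of %d terms", length(kept),
               length(config$mean_terms))
      kept
    })
  }
  report$screen <- list(applied = config$screen,
                        threshold = config$screen_threshold,
                        mean_terms = mean_terms)

  glm_fit <- run_stage("glm_fit", report, out, {
    f <- fit_joint(tab, mean_terms, character(0), method = "ML")
    log_info("constant-dispersion GLM: converged = %s, -2h = %.4f",
             f$converged, f$criteria$minus2h)
    f
  })
  joint_fit <- run_stage("joint_fit", report, out, {
    f <- fit_joint(tab, mean_terms, config$disp_terms,
                   method = config$method)
    log_info("joint GLM (%s): converged = %s in %d iterations, -2h = %.4f",
             config$method, f$converged, f$n_iter, f$criteria$minus2h)
    f
  })

  fit_block <- function(f) {
    list(mean_coefficients = wald_table(f$mean_fit$beta, f$mean_fit$se),
         dispersion_coefficients = wald_table(f$disp_fit$gamma_coef,
                                              f$disp_fit$se),
         criteria = unclass(f$criteria),
         converged = f$converged, n_iter = f$n_iter, method = f$method)
  }
  report$glm <- fit_block(glm_fit)
  report$joint <- fit_block(joint_fit)

  report$comparison <- run_stage("compare", report, out, {
    cmp <- compare_models(list(glm_fit, joint_fit),
                          labels = c("gaussian_glm", "joint_glm"))
    log_info("model comparison: overall winner = %s",
             ifelse(is.na(cmp$overall), "tie", cmp$overall))
    list(table = cmp$table, best = cmp$best, overall = cmp$overall)
  })

  report$diagnostics <- run_stage("diagnostics", report, out, {
    log_info("diagnostics bundles for both fits")
    list(glm = unclass(diagnostics_bundle(glm_fit)),
         joint = unclass(diagnostics_bundle(joint_fit)))
  })

  class(report) <- c("muac_report", "list")
  if (!is.null(out)) {
    write_report(report, out)
    log_info("report written to %s", out)
    return(invisible(report))
  }
  report
}

#' Write a pipeline report as JSON
#'
#' Full-precision serialization (no digit rounding); rounding for display is
#' left to the text renderers (the print methods).
#'
#' @param report a `muac_report` from [run_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE,
                           na = "null", pretty = TRUE, force = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Validate the structure of a pipeline report
#'
#' Checks the report (in memory or a JSON file) against the shipped report
#' schema (`inst/schema/report-schema.json`): required top-level blocks and
#' the required fields inside each.
#'
#' @param report a `muac_report`, or a path to a report JSON file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::fromJSON(report, simplifyVector = TRUE)
  }
  need <- c("descriptives", "correlations", "screen", "glm", "joint",
            "comparison", "diagnostics")
  miss <- setdiff(need, names(report))
  if (length(miss) > 0) {
    stop("validate_report: missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (blk in c("glm", "joint")) {
    fields <- c("mean_coefficients", "dispersion_coefficients", "criteria",
                "converged")
    miss <- setdiff(fields, names(report[[blk]]))
    if (length(miss) > 0) {
      stop("validate_report: block '", blk, "' missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  for (blk in c("glm", "joint")) {
    fields <- c("fitted", "std_resid", "abs_resid", "running_mean", "qq",
                "hist")
    miss <- setdiff(fields, names(report$diagnostics[[blk]]))
    if (length(miss) > 0) {
      stop("validate_report: diagnostics '", blk, "' missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}
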