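#' Recommended end-to-end association workflow
#'
#' Runs the full analysis with recommended defaults: mean imputation,
#' single-marker scan with genomic-control check, pre-screening at
#' p <= 0.01, penalized multiple-regression fitting (grid search with 100
#' update-order reorderings for the non-convex penalties), AIC model
#' selection under the model-size bound, post-hoc refit with correlation
#' pruning and minimum-p scoring, and a residual-QQ overfitting
#' diagnostic.
#'
#' @param g a [genotype_dataset()].
#' @param y a [phenotype_vector()].
#' @param C covariate matrix with intercept (principal components etc. are
#'   supplied here, not computed); intercept-only when `NULL`.
#' @param penalty one of `"mcp"`, `"log"`, `"neg"`, `"lasso"`,
#'   `"adaptive_lasso"`.
#' @param mode `"2D"` or `"1D"` grid for the non-convex penalties.
#' @param prescreen_cutoff single-marker p-value cutoff (default 0.01).
#' @param n_orders update-order reorderings (default 100).
#' @param seed RNG seed controlling the reorderings (end-to-end
#'   determinism given data and seed).
#' @param report_threshold significance threshold for the reported-hit
#'   count; default 1e-7 for 2D MCP-style reports and 1e-5 otherwise.
#' @param out_dir optional directory; when given, every stage artifact is
#'   written as tab-separated text plus a JSON run log.
#' @param k_max optional model-size cap override.
#' @return List of class `pmr_run`: `report` (association report),
#'   `scan`, `lambda_gc`, `screened` (indices), `selected_fit`,
#'   `path_models` / `path_unique_models` counts, `diagnostic`,
#'   `significant` (ids at the reporting threshold), `config`.
#' @export
run_pipeline <- function(g, y, C = NULL, penalty = "mcp", mode = "2D",
                         prescreen_cutoff = 0.01, n_orders = 100,
                         seed = NULL, report_threshold = NULL,
                         out_dir = NULL, k_max = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  n <- nrow(g$dosages)
  if (is.null(C)) C <- covariate_matrix(n)
  if (is.null(report_threshold)) {
    report_threshold <- if (penalty == "mcp" && identical(mode, "2D"))
      1e-7 else 1e-5
  }
  if (is.null(k_max)) k_max <- model_size_bound(n)

  g <- stage("impute", impute_missing_mean(g))
  scan <- stage("scan", single_marker_scan(g, y, C))
  lambda_gc <- genomic_inflation(scan)
  keep <- stage("prescreen", prescreen(scan, prescreen_cutoff))
  g_s <- subset_markers(g, keep)

  path <- stage("pmr", {
    if (penalty %in% c("lasso", "adaptive_lasso")) {
      convex_path(g_s, y, C, penalty, k_max = k_max)
    } else {
      nonconvex_grid(g_s, y, C, penalty, k_max = k_max, n_orders = n_orders,
                     mode = mode, seed = seed)
    }
  })
  fit <- stage("select", select_model(path, n, bound = k_max))
  sel <- selected_markers(fit)

  report <- if (length(sel)) {
    stage("report", prune_and_score(sel, g, y, C))
  } else {
    structure(data.frame(id = character(0), chrom = character(0),
                         bp = integer(0), coefficient = numeric(0),
                         score = numeric(0), iteration = integer(0),
                         retained = logical(0)),
              class = c("association_report", "data.frame"))
  }
  diagnostic <- stage("diagnostic",
                      residual_qq_diagnostic(report$id[report$retained], g, y, C))
  significant <- report$id[report$score <= report_threshold]

  out <- structure(list(report = report, scan = scan, lambda_gc = lambda_gc,
                        screened = keep, selected_fit = fit,
                        path_models = nrow(path$table),
                        path_unique_models = n_unique_models(path),
                        diagnostic = diagnostic, significant = significant,
                        config = list(penalty = penalty, mode = mode,
                                      prescreen_cutoff = prescreen_cutoff,
                                      n_orders = n_orders, seed = seed,
                                      report_threshold = report_threshold,
                                      k_max = k_max)),
                   class = "pmr_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.pmr_run <- function(x, ...) {
  cat(sprintf(paste0("pmr_run (%s %s): lambda_gc %.3f, %d screened, ",
                     "%d selected, %d significant at %.1e\n",
                     "%d models examined (%d unique); diagnostic lambda %.3f\n"),
              x$config$penalty, x$config$mode, x$lambda_gc,
              length(x$screened), x$selected_fit$k, length(x$significant),
              x$config$report_threshold, x$path_models,
              x$path_unique_models, x$diagnostic$lambda))
  invisible(x)
}

# tab-separated stage artifacts + JSON log, "readable by R"
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(run$scan, "scan.tsv")
  wt(run$report, "report.tsv")
  sel <- run$selected_fit
  wt(data.frame(id = selected_markers(sel),
                beta = sel$beta[sel$beta != 0]), "selected.tsv")
  wt(data.frame(id = names(run$diagnostic$p), p = run$diagnostic$p),
     "diagnostic.tsv")
  log <- c(run$config,
           list(lambda_gc = run$lambda_gc,
                n_screened = length(run$screened),
                k_selected = sel$k, aic = sel$aic,
                models = run$path_models,
                unique_models = run$path_unique_models,
                diagnostic_lambda = run$diagnostic$lambda))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    writeLines(paste(names(log), vapply(log, function(v)
      paste(format(v), collapse = ","), character(1)), sep = "="),
      file.path(out_dir, "run_log.txt"))
  }
  invisible(out_dir)
}
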