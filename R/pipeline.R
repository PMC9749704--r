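#' Run the full stage-two analysis (optionally preceded by stage one)
#'
#' Orchestrates the whole workflow: (optionally) create stratified
#' summarised data from individual-level data, compute LACE estimates and
#' the instrument-homogeneity diagnostics, search the fractional-polynomial
#' family at degrees 1 and 2, compute the four non-linearity tests, build
#' the piecewise-linear curve, and attach parametric-bootstrap confidence
#' intervals. The "selected" model is the best degree-2 fit when the
#' fp_d1_d2 test rejects at the 5% level, and the best degree-1 fit
#' otherwise.
#'
#' All randomness flows from `seed`. When `outdir` is given, the report is
#' written as JSON alongside CSVs of the summary, LACE table and curves (and
#' plots if `plot = TRUE`); a failure in any stage removes partial outputs
#' and aborts with a stage-named message.
#'
#' @param summary An [stratified_summary()] object, or path to its CSV.
#' @param data Alternatively, an [individual_data()] object (stage one is
#'   then run with `K` strata).
#' @param K Number of strata for stage one (default 10).
#' @param powers Fractional-polynomial power set.
#' @param n_boot Parametric-bootstrap draws (default 1000).
#' @param seed Integer seed (default 1).
#' @param ci_level Confidence level (default 0.95).
#' @param x_ref Reference exposure; default as in [build_piecewise()].
#' @param outcome_type Used when `summary` is a path.
#' @param se_method LACE standard-error method (see [compute_lace()]).
#' @param outdir Optional output directory.
#' @param plot Also write curve plots (requires `outdir`).
#' @param plot_style,plot_scale Passed to [plot_curve()].
#' @return Object of class `mr_report`: list with elements `summary`,
#'   `lace`, `homogeneity`, `best_d1`, `best_d2`, `selected`, `tests`,
#'   `piecewise`, `boot_fracpoly`, `boot_piecewise`, `config`.
#' @examples
#' rep <- run_pipeline(summary = ldl_cad_example(), n_boot = 200, seed = 1)
#' @export
run_pipeline <- function(summary = NULL, data = NULL, K = 10L,
                         powers = fp_default_powers, n_boot = 1000L,
                         seed = 1L, ci_level = 0.95, x_ref = NULL,
                         outcome_type = "continuous",
                         se_method = "first_order",
                         outdir = NULL, plot = FALSE,
                         plot_style = "band", plot_scale = "identity") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir)) unlink(written, force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  written <- character()

  if (is.null(summary) && is.null(data))
    stop("provide either 'summary' or 'data'", call. = FALSE)
  if (is.null(summary)) {
    summary <- stage("create-summary",
                     create_summary_data(data, K = K, quiet = TRUE))
  } else if (is.character(summary)) {
    summary <- stage("read-summary",
                     read_summary(summary, outcome_type = outcome_type))
  }

  lace <- stage("lace", compute_lace(summary, se_method = se_method))
  homog <- stage("homogeneity", assess_homogeneity(summary))
  best_d1 <- stage("fracpoly-d1", select_best(lace, powers, degree = 1L))
  best_d2 <- stage("fracpoly-d2", select_best(lace, powers, degree = 2L))
  tests <- stage("nonlinearity-tests",
                 nonlinearity_tests(lace, best_d1, best_d2, powers = powers))
  selected <- if (tests$p_fp_d1_d2 < 0.05) best_d2 else best_d1
  if (is.null(x_ref)) x_ref <- default_x_ref(lace)
  pw <- stage("piecewise", build_piecewise(lace, x_ref = x_ref))
  boot_fp <- stage("bootstrap-fracpoly",
                   parametric_bootstrap(lace, selected, n_boot = n_boot,
                                        seed = seed, ci_level = ci_level,
                                        x_ref = x_ref))
  boot_pw <- stage("bootstrap-piecewise",
                   parametric_bootstrap(lace, pw, n_boot = n_boot,
                                        seed = seed + 1L,
                                        ci_level = ci_level, x_ref = x_ref))

  config <- list(K = nrow(summary), powers = powers, n_boot = n_boot,
                 seed = seed, ci_level = ci_level, x_ref = x_ref,
                 se_method = se_method,
                 outcome_type = attr(summary, "outcome_type"),
                 package_version = as.character(utils::packageVersion("strataMR")))
  report <- structure(list(summary = summary, lace = lace,
                           homogeneity = homog, best_d1 = best_d1,
                           best_d2 = best_d2, selected = selected,
                           tests = tests, piecewise = pw,
                           boot_fracpoly = boot_fp, boot_piecewise = boot_pw,
                           config = config),
                      class = "mr_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(outdir, c("summary.csv", "lace.csv",
                                 "curve_fracpoly.csv", "curve_piecewise.csv",
                                 "report.json"))
    written <- paths
    stage("write-outputs", {
      write_summary(summary, paths[1])
      write_lace(lace, paths[2])
      write_curve(boot_fp$curve, paths[3])
      write_curve(boot_pw$curve, paths[4])
      jsonlite::write_json(report_as_list(report), paths[5],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (plot) {
        plot_curve(boot_fp$curve, style = plot_style, scale = plot_scale,
                   x_ref = x_ref,
                   outcome_type = attr(summary, "outcome_type"),
                   file = file.path(outdir, "curve_fracpoly.pdf"))
        plot_curve(boot_pw$curve, style = plot_style, scale = plot_scale,
                   x_ref = x_ref,
                   outcome_type = attr(summary, "outcome_type"),
                   file = file.path(outdir, "curve_piecewise.pdf"))
      }
    })
  }
  report
}

# flatten an mr_report into plain lists for JSON serialisation
report_as_list <- function(report) {
  fit_info <- function(fit) list(degree = fit$degree, powers = fit$powers,
                                 coefficients = fit$coefficients,
                                 loglik = fit$loglik)
  list(
    config = report$config,
    homogeneity = unclass(report$homogeneity),
    lace = as.data.frame(report$lace),
    best_d1 = fit_info(report$best_d1),
    best_d2 = fit_info(report$best_d2),
    selected = fit_info(report$selected),
    candidates_d1 = report$best_d1$candidates,
    candidates_d2 = report$best_d2$candidates,
    nonlinearity_tests = unclass(report$tests),
    coefficient_ci = report$boot_fracpoly$coef_ci,
    piecewise = list(knots = report$piecewise$knots,
                     slopes = report$piecewise$slopes,
                     x_ref = report$piecewise$x_ref,
                     values_at_knots = report$piecewise$values_at_knots),
    bootstrap = list(n_boot = report$boot_fracpoly$n_boot,
                     seed = report$boot_fracpoly$seed,
                     n_discarded = report$boot_fracpoly$n_discarded))
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Non-linear MR analysis report\n")
  cat("=============================\n")
  print(x$homogeneity)
  print(x$tests)
  cat("Selected model:\n")
  print(x$selected)
  if (!is.null(x$boot_fracpoly$coef_ci)) {
    ci <- x$boot_fracpoly$coef_ci
    for (j in seq_along(x$selected$coefficients))
      cat(sprintf("  coefficient %d: %.4g (%.0f%% CI %.4g, %.4g)\n",
                  j, x$selected$coefficients[j], 100 * x$config$ci_level,
                  ci[j, 1], ci[j, 2]))
  }
  invisible(x)
}
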