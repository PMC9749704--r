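#' Individual-level data for non-linear Mendelian randomisation
#'
#' Bundles the per-person genetic instrument, exposure and outcome (plus
#' optional covariates) into a validated container. The instrument `g` is a
#' single continuous score; if multiple variants are available a weighted
#' allele score should be computed upstream. Rows with a missing value in any
#' used column are dropped (complete-case) and the count is recorded in the
#' `n_dropped` attribute.
#'
#' @param g Numeric vector, instrument / genetic score per person.
#' @param x Numeric vector, exposure per person (must be continuous; a
#'   coarsened exposure biases the stratification).
#' @param y Numeric vector, outcome per person. Continuous, or strictly 0/1
#'   when `outcome_type = "binary"`.
#' @param covariates Optional data frame of covariate columns (numeric or
#'   factor) entering the within-stratum association regressions.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return An object of class `mr_individual`: a data frame with columns
#'   `g`, `x`, `y` and any covariates, with attributes `outcome_type`,
#'   `covariate_names` and `n_dropped`.
#' @examples
#' d <- individual_data(g = rbinom(200, 2, 0.3), x = rnorm(200, 10),
#'                      y = rnorm(200))
#' @export
individual_data <- function(g, x, y, covariates = NULL,
                            outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  g <- as.numeric(g); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(g)
  if (length(x) != n || length(y) != n)
    stop("g, x and y must have the same length", call. = FALSE)
  df <- data.frame(g = g, x = x, y = y)
  covariate_names <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per person", call. = FALSE)
    covariate_names <- names(covariates)
    if (any(covariate_names %in% names(df)))
      stop("covariate names may not be 'g', 'x' or 'y'", call. = FALSE)
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) < 4L)
    stop("fewer than 4 complete rows", call. = FALSE)
  if (outcome_type == "binary" && !all(df$y %in% c(0, 1)))
    stop("binary outcome column must contain only 0 and 1", call. = FALSE)
  structure(df,
            class = c("mr_individual", "data.frame"),
            outcome_type = outcome_type,
            covariate_names = covariate_names,
            n_dropped = n_dropped)
}

#' @export
print.mr_individual <- function(x, ...) {
  cat(sprintf("Individual-level MR data: n = %d, outcome = %s\n",
              nrow(x), attr(x, "outcome_type")))
  if (length(attr(x, "covariate_names")))
    cat("  covariates:", paste(attr(x, "covariate_names"), collapse = ", "), "\n")
  if (attr(x, "n_dropped") > 0)
    cat(sprintf("  %d incomplete rows dropped\n", attr(x, "n_dropped")))
  invisible(x)
}

# coerce plain data frames with the right columns; used by the CLI
as_individual_data <- function(df, g = "g", x = "x", y = "y",
                               covar = character(),
                               outcome_type = "continuous") {
  missing_cols <- setdiff(c(g, x, y, covar), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  covs <- if (length(covar)) df[covar] else NULL
  individual_data(df[[g]], df[[x]], df[[y]], covariates = covs,
                  outcome_type = outcome_type)
}
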