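#' Stratified summarised data
#'
#' The interchange format between the two analysis stages, one row per
#' stratum: instrument-exposure association `bx` (SE `bxse`),
#' instrument-outcome association `by` (SE `byse`, log-odds per score unit
#' for binary outcomes), and the stratum mean / lower / upper percentiles of
#' the exposure (`xmean`, `xmin`, `xmax`). Strata must be ordered by
#' increasing `xmean`. Any analysis that only needs this object can be run
#' without access to individual-level data.
#'
#' @param df Data frame with columns `stratum, bx, bxse, by, byse, xmean,
#'   xmin, xmax`.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param covariate_names Covariates used when forming the summaries
#'   (metadata only).
#' @param stratum_sizes Optional integer vector of per-stratum sample sizes
#'   (metadata; used for the default reference value).
#' @return Object of class `mr_summary` (a data frame plus attributes).
#' @export
stratified_summary <- function(df, outcome_type = "continuous",
                               covariate_names = character(),
                               stratum_sizes = NULL) {
  required <- c("stratum", "bx", "bxse", "by", "byse", "xmean", "xmin", "xmax")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[required]
  K <- nrow(df)
  if (K < 2L) stop("need at least 2 strata", call. = FALSE)
  if (anyNA(df)) stop("stratified summary contains missing values", call. = FALSE)
  bad_se <- which(df$bxse <= 0 | df$byse <= 0)
  if (length(bad_se))
    stop("non-positive standard error in row ", bad_se[1], call. = FALSE)
  if (any(diff(df$xmean) <= 0))
    stop("xmean must be strictly increasing across strata; sort rows by xmean",
         call. = FALSE)
  bad_rng <- which(!(df$xmin < df$xmean & df$xmean < df$xmax))
  if (length(bad_rng))
    stop("need xmin < xmean < xmax; violated in row ", bad_rng[1],
         call. = FALSE)
  rownames(df) <- NULL
  structure(df,
            class = c("mr_summary", "data.frame"),
            outcome_type = outcome_type,
            covariate_names = covariate_names,
            stratum_sizes = stratum_sizes)
}

#' @export
print.mr_summary <- function(x, ...) {
  cat(sprintf("Stratified summarised data: K = %d strata, outcome = %s\n",
              nrow(x), attr(x, "outcome_type")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Residual exposure
#'
#' Residual from the ordinary least-squares regression of the exposure on the
#' genetic instrument (intercept included). Stratifying on this residual --
#' rather than on the exposure itself, which sits on the causal path -- keeps
#' the instrument distribution uniform across strata and avoids collider
#' bias. Covariates are excluded from this regression by default; set
#' `adjust_covariates = TRUE` for a sensitivity analysis that residualises on
#' them too.
#'
#' @param data An [individual_data()] object.
#' @param adjust_covariates Include the covariate columns in the residual
#'   regression (default `FALSE`).
#' @return Numeric vector of residuals, one per retained person.
#' @export
compute_residual_exposure <- function(data, adjust_covariates = FALSE) {
  stopifnot(inherits(data, "mr_individual"))
  if (stats::var(data$g) == 0)
    stop("instrument has zero variance", call. = FALSE)
  covs <- attr(data, "covariate_names")
  rhs <- "g"
  if (adjust_covariates && length(covs))
    rhs <- paste(c("g", covs), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("x ~", rhs)), data = data)
  as.numeric(stats::residuals(fit))
}

#' Assign residual-exposure strata
#'
#' Ranks the residuals (ties broken stably by input order) and splits the
#' sample into `K` equal-size quantile groups; group sizes differ by at most
#' one, with the larger groups placed first. Lowest residuals go to
#' stratum 1.
#'
#' @param residuals Numeric vector of residual exposures.
#' @param K Number of strata (default 10, i.e. deciles).
#' @return Integer vector of stratum indices in `1:K`, same order as input.
#' @export
assign_strata <- function(residuals, K = 10L) {
  K <- as.integer(K)
  n <- length(residuals)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (K > n / 2) stop("too few observations per stratum", call. = FALSE)
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(residuals)          # stable: ties keep input order
  idx <- integer(n)
  idx[ord] <- rep.int(seq_len(K), sizes)
  idx
}

# type-7 quantiles; the interior strata use the 10th/90th percentiles, the
# extreme strata 20th/80th to avoid excessive extrapolation
stratum_percentiles <- function(x, k, K) {
  p <- if (k == 1L || k == K) c(0.20, 0.80) else c(0.10, 0.90)
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

# simple regression y ~ g (+ covariates) with OLS or logistic ML; returns
# c(beta, se) for the g coefficient
.assoc_fit <- function(df, response, covs, binary, stratum) {
  rhs <- paste(c("g", covs), collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  if (binary) {
    if (length(unique(df[[response]])) < 2L)
      stop("stratum ", stratum, " contains a single outcome class",
           call. = FALSE)
    fit <- stats::glm(f, data = df, family = stats::binomial())
  } else {
    fit <- stats::lm(f, data = df)
  }
  if (anyNA(stats::coef(fit)))
    stop("singular design matrix in stratum ", stratum, call. = FALSE)
  cf <- summary(fit)$coefficients
  cf["g", 1:2]
}

#' Within-stratum genetic associations
#'
#' For each stratum: the instrument-exposure association (`bx`, `bxse`) from
#' OLS of exposure on instrument plus covariates; the instrument-outcome
#' association (`by`, `byse`) from OLS for a continuous outcome or
#' maximum-likelihood logistic regression for a binary one; and the stratum
#' mean and percentile range of the exposure.
#'
#' @param data An [individual_data()] object.
#' @param strata Stratum index per person, as from [assign_strata()].
#' @param K Number of strata.
#' @return An [stratified_summary()] object.
#' @export
stratum_associations <- function(data, strata, K = max(strata)) {
  stopifnot(inherits(data, "mr_individual"))
  K <- as.integer(K)
  binary <- attr(data, "outcome_type") == "binary"
  covs <- attr(data, "covariate_names")
  rows <- vector("list", K)
  sizes <- integer(K)
  for (k in seq_len(K)) {
    sel <- strata == k
    sizes[k] <- sum(sel)
    if (sizes[k] == 0L) stop("stratum ", k, " is empty", call. = FALSE)
    dk <- data[sel, , drop = FALSE]
    bx <- .assoc_fit(dk, "x", covs, binary = FALSE, stratum = k)
    by <- .assoc_fit(dk, "y", covs, binary = binary, stratum = k)
    pr <- stratum_percentiles(dk$x, k, K)
    rows[[k]] <- data.frame(stratum = k,
                            bx = bx[1], bxse = bx[2],
                            by = by[1], byse = by[2],
                            xmean = mean(dk$x), xmin = pr[1], xmax = pr[2])
  }
  stratified_summary(do.call(rbind, rows),
                     outcome_type = attr(data, "outcome_type"),
                     covariate_names = covs,
                     stratum_sizes = sizes)
}

#' Create stratified summarised data from individual-level data
#'
#' Stage-one entry point: residualise the exposure on the instrument, assign
#' equal-size residual-exposure strata, and compute the within-stratum
#' genetic associations. The result is the complete input to every stage-two
#' analysis and can be shared without disclosing individual-level data.
#'
#' @inheritParams compute_residual_exposure
#' @param K Number of strata (default 10).
#' @param quiet Suppress the dropped-row / stratum-size message.
#' @return An [stratified_summary()] object.
#' @examples
#' d <- generate_mr_data(sim_scenario(n = 2000, shape = "null", seed = 7))
#' s <- create_summary_data(d, K = 5)
#' @export
create_summary_data <- function(data, K = 10L, adjust_covariates = FALSE,
                                quiet = FALSE) {
  res <- compute_residual_exposure(data, adjust_covariates = adjust_covariates)
  strata <- assign_strata(res, K)
  out <- stratum_associations(data, strata, K = as.integer(K))
  if (!quiet) {
    message(sprintf("dropped %d incomplete rows; stratum sizes: %s",
                    attr(data, "n_dropped"),
                    paste(attr(out, "stratum_sizes"), collapse = ", ")))
  }
  out
}
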