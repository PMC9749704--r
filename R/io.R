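#' Published LDL-cholesterol / CAD stratified summary excerpt
#'
#' The first four strata of the published stratified summarised data for the
#' LDL-cholesterol and coronary artery disease worked example (binary
#' outcome; `by` is on the log-odds scale). Useful as a small real-data
#' fixture; note the full analysis used ten strata, so model selection on
#' this excerpt does not reproduce the published curve.
#'
#' @return An [stratified_summary()] object with K = 4.
#' @export
ldl_cad_example <- function() {
  stratified_summary(data.frame(
    stratum = 1:4,
    bx   = c(0.253, 0.227, 0.226, 0.234),
    bxse = c(0.006, 0.004, 0.003, 0.002),
    by   = c(0.154, 0.249, 0.205, 0.197),
    byse = c(0.049, 0.050, 0.048, 0.048),
    xmean = c(2.45, 2.75, 2.97, 3.14),
    xmin = c(2.30, 2.53, 2.74, 2.92),
    xmax = c(2.70, 2.93, 3.11, 3.36)),
    outcome_type = "binary")
}

summary_columns <- c("stratum", "bx", "bxse", "by", "byse",
                     "xmean", "xmin", "xmax")

#' Read stratified summarised data from CSV
#'
#' Expects a comma-separated file with header
#' `stratum,bx,bxse,by,byse,xmean,xmin,xmax` ('.' decimal separator, UTF-8).
#' Extra columns are ignored with a warning; all type invariants are
#' enforced at load so any file this accepts is analysable.
#'
#' @param path File path.
#' @param outcome_type `"continuous"` or `"binary"` (how `by` should be
#'   interpreted; not stored in the file).
#' @return An [stratified_summary()] object.
#' @export
read_summary <- function(path, outcome_type = "continuous") {
  df <- utils::read.csv(path, header = TRUE)
  missing_cols <- setdiff(summary_columns, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), summary_columns)
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  stratified_summary(df[summary_columns], outcome_type = outcome_type)
}

#' Write stratified summarised data to CSV
#'
#' Inverse of [read_summary()]; values round-trip to full double precision.
#'
#' @param summary An [stratified_summary()] object.
#' @param path File path.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "mr_summary"))
  df <- as.data.frame(summary)
  df[] <- lapply(df, function(v) if (is.double(v))
    formatC(v, digits = 17, format = "g") else v)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a LACE table to CSV (`stratum,lace,se,xmean,xmin,xmax`)
#' @param lace A [compute_lace()] table.
#' @param path File path.
#' @export
write_lace <- function(lace, path) {
  stopifnot(inherits(lace, "lace_table"))
  utils::write.csv(as.data.frame(lace), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a curve estimate to CSV (`x,estimate,ci_lower,ci_upper`)
#' @param curve A `curve_estimate`.
#' @param path File path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "curve_estimate"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Plot an estimated causal curve with its confidence band
#'
#' @param curve A `curve_estimate` from [parametric_bootstrap()].
#' @param style `"band"` (shaded ribbon) or `"lines"` (dashed CI lines).
#' @param scale `"identity"`, or `"odds-ratio"` to exponentiate the curve
#'   and CI pointwise (meaningful when the curve is on the log-odds scale,
#'   i.e. a binary outcome).
#' @param x_ref Optional reference value to mark.
#' @param outcome_type If `"continuous"` and `scale = "odds-ratio"`, a
#'   warning is issued (the transform is still applied).
#' @param file Optional output path (e.g. `.pdf`, `.png`); written with
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly.
#' @export
plot_curve <- function(curve, style = c("band", "lines"),
                       scale = c("identity", "odds-ratio"),
                       x_ref = NULL, outcome_type = NULL, file = NULL) {
  stopifnot(inherits(curve, "curve_estimate"))
  style <- match.arg(style)
  scale <- match.arg(scale)
  df <- as.data.frame(curve)
  ylab <- "Outcome difference vs reference"
  if (scale == "odds-ratio") {
    if (identical(outcome_type, "continuous"))
      warning("odds-ratio scale requested for a continuous outcome",
              call. = FALSE)
    df$estimate <- exp(df$estimate)
    df$ci_lower <- exp(df$ci_lower)
    df$ci_upper <- exp(df$ci_upper)
    ylab <- "Odds ratio vs reference"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = estimate))
  if (style == "band") {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = ci_lower, ymax = ci_upper),
      fill = "grey70", alpha = 0.6)
  } else {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = ci_lower), linetype = 2) +
      ggplot2::geom_line(ggplot2::aes(y = ci_upper), linetype = 2)
  }
  p <- p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Exposure", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(x_ref))
    p <- p + ggplot2::geom_vline(xintercept = x_ref, linetype = 3)
  if (scale == "odds-ratio")
    p <- p + ggplot2::geom_hline(yintercept = 1, colour = "grey50")
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 4)
  invisible(p)
}
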