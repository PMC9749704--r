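#' Continuous piecewise-linear causal curve
#'
#' Builds the piecewise-linear estimate of the exposure-outcome curve: one
#' linear segment per stratum with slope equal to that stratum's LACE
#' estimate, joined continuously and anchored to zero at the reference
#' exposure `x_ref`.
#'
#' Segment k nominally spans stratum k's reported percentile range
#' `[xmin_k, xmax_k]`. Adjacent reported ranges usually overlap slightly (the
#' 90th percentile of stratum k exceeds the 10th of stratum k+1), so interior
#' knots are placed at the midpoint of `(xmax_k, xmin_(k+1))`, giving a curve
#' defined on the connected interval `[xmin_1, xmax_K]`. No extrapolation
#' beyond that interval is performed.
#'
#' @param lace A [compute_lace()] table with at least 2 strata.
#' @param x_ref Reference exposure at which the curve is zero. Default: the
#'   stratum-size-weighted mean of the stratum mean exposures (equal weights
#'   when sizes are unknown).
#' @param strict Error (instead of repairing with a warning) if the midpoint
#'   knots are not strictly increasing.
#' @return Object of class `piecewise_fit`: list with `knots` (length K+1),
#'   `slopes` (length K), `x_ref`, `values_at_knots`.
#' @examples
#' pw <- build_piecewise(compute_lace(ldl_cad_example()))
#' evaluate_piecewise(pw, pw$x_ref)   # 0 by construction
#' @export
build_piecewise <- function(lace, x_ref = NULL, strict = FALSE) {
  stopifnot(inherits(lace, "lace_table"))
  K <- nrow(lace)
  if (K < 2L) stop("need at least 2 strata", call. = FALSE)
  if (is.null(x_ref)) {
    sizes <- attr(lace, "stratum_sizes")
    x_ref <- if (is.null(sizes)) mean(lace$xmean)
             else stats::weighted.mean(lace$xmean, sizes)
  }
  interior <- (lace$xmax[-K] + lace$xmin[-1]) / 2
  knots <- c(lace$xmin[1], interior, lace$xmax[K])
  if (any(diff(knots) <= 0)) {
    if (strict)
      stop("percentile ranges give non-increasing knots", call. = FALSE)
    warning("non-increasing knots repaired by pooling", call. = FALSE)
    knots <- cummax(knots) + seq_along(knots) * 1e-9 * diff(range(knots))
  }
  if (x_ref < knots[1] || x_ref > knots[K + 1])
    stop("x_ref must lie within [", signif(knots[1], 4), ", ",
         signif(knots[K + 1], 4), "]", call. = FALSE)
  slopes <- lace$lace
  heights_raw <- c(0, cumsum(slopes * diff(knots)))
  seg <- min(findInterval(x_ref, knots, rightmost.closed = TRUE), K)
  ref_val <- heights_raw[seg] + slopes[seg] * (x_ref - knots[seg])
  structure(list(knots = knots, slopes = slopes, x_ref = x_ref,
                 heights_raw = heights_raw, ref_val = ref_val,
                 values_at_knots = heights_raw - ref_val, lace = lace),
            class = "piecewise_fit")
}

#' Evaluate a piecewise-linear curve
#'
#' Linear interpolation within segments; exact at the knots; errors on any
#' grid point outside the knot range (the stratified method deliberately
#' does not extrapolate beyond the reported percentile range).
#'
#' @param model A `piecewise_fit`.
#' @param x_grid Exposure values within `[knots[1], knots[K+1]]`.
#' @return Numeric vector of curve values, zero at `x_ref`.
#' @export
evaluate_piecewise <- function(model, x_grid) {
  stopifnot(inherits(model, "piecewise_fit"))
  kn <- model$knots
  tol <- 1e-8 * max(abs(kn))
  if (any(x_grid < kn[1] - tol | x_grid > kn[length(kn)] + tol))
    stop("grid point outside the knot range; no extrapolation", call. = FALSE)
  x <- pmin(pmax(x_grid, kn[1]), kn[length(kn)])
  seg <- pmin(findInterval(x, kn, rightmost.closed = TRUE), length(kn) - 1L)
  # subtracting ref_val computed through this same expression makes the
  # curve exactly zero at x_ref in floating point
  model$heights_raw[seg] + model$slopes[seg] * (x - kn[seg]) - model$ref_val
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise-linear curve: %d segments, reference %.4g\n",
              length(x$slopes), x$x_ref))
  cat("  knots: ", paste(signif(x$knots, 4), collapse = ", "), "\n")
  cat("  slopes:", paste(signif(x$slopes, 4), collapse = ", "), "\n")
  invisible(x)
}
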