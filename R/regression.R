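#' Validate back-calculated against prepared concentrations
#'
#' Ordinary least squares of the back-calculated concentrations (y) on the
#' prepared ones (x). An accurate reference-free quantification gives a slope
#' near 1, an intercept near 0 and R-squared near 1; a receiver-gain
#' nonlinearity shows up as a slope away from 1. R-squared is the squared
#' Pearson correlation of (x, y), identical to the OLS coefficient of
#' determination for simple regression.
#'
#' @param prepared_mM Prepared (true) concentrations, mM.
#' @param backcalc_mM Back-calculated concentrations, mM; same length.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_regression <- function(prepared_mM, backcalc_mM) {
  if (length(prepared_mM) != length(backcalc_mM))
    stop(sprintf("length mismatch: %d prepared vs %d back-calculated values",
                 length(prepared_mM), length(backcalc_mM)))
  if (length(prepared_mM) < 2)
    stop("need at least 2 points for a regression")
  if (stats::var(prepared_mM) == 0)
    stop("degenerate x: prepared concentrations are all identical")
  fit <- stats::lm(backcalc_mM ~ prepared_mM)
  r <- stats::cor(prepared_mM, backcalc_mM)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r * r, n = length(prepared_mM)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4f x + %.4f   R^2 = %.4f   (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
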