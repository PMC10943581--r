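#' Two-sided -log10 p-value from a t statistic, computed in log space
#'
#' Converts a t statistic into a two-sided p-value on the -log10 scale
#' without ever materializing the raw p-value, so the result stays accurate
#' when p underflows double precision (p-values down to 10^-5000 and beyond
#' arise routinely in large-cohort protein QTL scans).
#'
#' The two-sided p-value for a t statistic with `df` degrees of freedom is
#' the regularized incomplete beta function I_x(df/2, 1/2) evaluated at
#' x = df / (df + t^2); this identity is evaluated on the log scale via
#' [stats::pbeta()] with `log.p = TRUE`.
#'
#' @param t Numeric vector of t statistics. Must be finite.
#' @param df Degrees of freedom (>= 1); scalar or vector recycled against `t`.
#' @return Numeric vector of -log10 two-sided p-values (>= 0). `t = 0` maps
#'   to exactly 0 (p = 1).
#' @examples
#' neglog10_p_from_t(1.96, 10000) # ~ 1.301 (p ~ 0.05)
#' neglog10_p_from_t(130, 40000)  # ~ 3063, far below double-precision p
#' @export
neglog10_p_from_t <- function(t, df) {
  if (length(t) == 0L) return(numeric(0))
  if (any(!is.finite(t))) stop("'t' must be finite")
  if (any(!is.finite(df)) || any(df < 1)) stop("'df' must be finite and >= 1")
  x <- df / (df + t^2)
  # I_x(df/2, 1/2) is the exact two-sided p; log scale keeps tiny p exact
  -stats::pbeta(x, df / 2, 0.5, log.p = TRUE) / log(10)
}

#' Two-sided -log10 p-value from a standard normal deviate, in log space
#'
#' @param z Numeric vector of z statistics (finite).
#' @return -log10 of the two-sided normal p-value.
#' @keywords internal
neglog10_p_from_z <- function(z) {
  if (any(!is.finite(z))) stop("'z' must be finite")
  -(log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
}
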