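#' Saturation vapor pressure of air
#'
#' Tetens-type exponential relation, `SVP = 0.6108 * base^(17.27*T / (T + 237.3))`
#' in kPa. The default exponential base is the four-decimal constant 2.7183
#' commonly printed alongside this formula in the horticultural literature;
#' set `base = exp(1)` for the exact natural base (relative difference is
#' below 1e-4 over 0--50 degrees C).
#'
#' @param temp_c air temperature, degrees C (vector). Must be > -237.3.
#' @param base positive real, base of the exponential. Default `2.7183`.
#' @return saturation vapor pressure in kPa, same length as `temp_c`.
#'   `NA` inputs propagate.
#' @seealso [vpd()]
#' @examples
#' svp(0)            # 0.6108 exactly
#' svp(c(20, 25))
#' @export
svp <- function(temp_c, base = 2.7183) {
  stopifnot(is.numeric(temp_c), is.numeric(base), length(base) == 1L, base > 0)
  if (any(temp_c <= -237.3, na.rm = TRUE)) {
    stop("svp(): temperature must exceed -237.3 degrees C", call. = FALSE)
  }
  0.6108 * base^((17.27 * temp_c) / (temp_c + 237.3))
}

#' Vapor pressure deficit from temperature and relative humidity
#'
#' VPD = SVP - AVP where the actual vapor pressure AVP = SVP * RH / 100.
#' With RH validated to \[0, 100\] the result is nonnegative; classification
#' downstream uses the absolute value regardless, so out-of-convention signs
#' can never leak into categories.
#'
#' @param temp_c air temperature, degrees C (vector).
#' @param rh_pct relative humidity, percent (vector, recycled against
#'   `temp_c` by base rules; normally equal length).
#' @param strict if `TRUE` (default) RH outside \[0, 100\] is an error; if
#'   `FALSE` RH is clamped into range with a warning.
#' @param base exponential base passed to [svp()].
#' @return VPD in kPa. `NA` in either input propagates.
#' @examples
#' vpd(20, 100)  # saturated air: 0
#' vpd(20, 50)   # about 1.169 kPa
#' @export
vpd <- function(temp_c, rh_pct, strict = TRUE, base = 2.7183) {
  stopifnot(is.numeric(rh_pct))
  bad <- !is.na(rh_pct) & (rh_pct < 0 | rh_pct > 100)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("vpd(): %d RH value(s) outside [0, 100]; first offender %.3f",
                   sum(bad), rh_pct[which(bad)[1L]]), call. = FALSE)
    }
    warning("vpd(): RH values outside [0, 100] clamped into range")
    rh_pct <- pmin(pmax(rh_pct, 0), 100)
  }
  s <- svp(temp_c, base = base)
  s * (1 - rh_pct / 100)
}

#' Add a VPD column to a sensor record table
#'
#' @param records data frame with numeric `temp_c` and `rh_pct` columns
#'   (missing values allowed; VPD is `NA` where either is missing).
#' @param strict,base passed to [vpd()].
#' @return `records` with an added/overwritten `vpd_kpa` column.
#' @export
add_vpd <- function(records, strict = TRUE, base = 2.7183) {
  stopifnot(is.data.frame(records), all(c("temp_c", "rh_pct") %in% names(records)))
  records$vpd_kpa <- vpd(records$temp_c, records$rh_pct, strict = strict, base = base)
  records
}
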