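#' Apparent temperature from ambient temperature and relative humidity
#'
#' Steadman-type apparent temperature: the dew point is obtained from the
#' Magnus approximation (constants 17.27 and 237.7 degrees C) and combined
#' with the ambient temperature as
#'
#' \deqn{AT = -2.653 + 0.994\,T_a + 0.0153\,T_d^2}
#'
#' where \eqn{T_a} is the ambient (dry-bulb) temperature in degrees C and
#' \eqn{T_d} the dew point.  The index is monotone increasing in both
#' temperature and humidity over the physiological range.
#'
#' @param temp_ambient Ambient temperature in degrees C (finite; vectorised).
#' @param rel_humidity Relative humidity in percent, in `[0, 100]`
#'   (vectorised; 0 is rejected because the dew point is undefined).
#' @return Apparent temperature in degrees C.
#' @examples
#' apparent_temperature(20, 100)  # dew point 20 C -> 23.347 C
#' @export
apparent_temperature <- function(temp_ambient, rel_humidity) {
  if (!is.numeric(temp_ambient) || any(!is.finite(temp_ambient)))
    stop("'temp_ambient' must be finite numeric", call. = FALSE)
  if (!is.numeric(rel_humidity) || any(!is.finite(rel_humidity)) ||
      any(rel_humidity <= 0) || any(rel_humidity > 100))
    stop("'rel_humidity' must lie in (0, 100] percent", call. = FALSE)
  gamma <- log(rel_humidity / 100) +
    17.27 * temp_ambient / (237.7 + temp_ambient)
  dew_point <- 237.7 * gamma / (17.27 - gamma)
  -2.653 + 0.994 * temp_ambient + 0.0153 * dew_point^2
}
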