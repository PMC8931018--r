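#' Uniformly sampled waveform
#'
#' The basic signal container of the package: a uniformly sampled voltage
#' (or current) time series with its sampling rate and units. Sensor
#' simulation, utterance synthesis and all preprocessing operations consume
#' and produce `waveform` objects.
#'
#' @param samples Numeric vector of sample values; all values must be finite.
#' @param rate Sampling rate in Hz.
#' @param units Unit string, one of `"V"`, `"nA"` or `"normalized"`.
#' @param kind Optional signal kind tag, e.g. `"voc"` (open-circuit voltage)
#'   or `"isc"` (short-circuit current).
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `rate`, `units` and `kind`.
#' @examples
#' w <- waveform(sin(2 * pi * 2 * seq(0, 1, by = 1e-3)), rate = 1000)
#' duration(w)
#' @export
waveform <- function(samples, rate, units = "V", kind = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("`samples` must be finite", call. = FALSE)
  stop_if_not_scalar_num(rate, "rate", lower = .Machine$double.eps)
  units <- match.arg(units, c("V", "nA", "normalized"))
  structure(
    list(samples = samples, rate = as.numeric(rate), units = units, kind = kind),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), units %s%s\n",
              length(x$samples), x$rate, duration(x), x$units,
              if (is.null(x$kind)) "" else paste0(", kind ", x$kind)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds (`n / rate`).
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

#' Time axis of a waveform
#' @param w A [waveform()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
time_axis <- function(w) {
  stopifnot(inherits(w, "waveform"))
  (seq_along(w$samples) - 1) / w$rate
}
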