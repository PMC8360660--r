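#' Uniformly sampled recording trace
#'
#' A trace is a tibble with `time` (ms) and `value` columns plus metadata:
#' sampling interval `dt` (ms), stimulus times (ms) and a unit tag
#' (`"mV"`, `"pA"` or `"dff"`).  All waveform analyses in the package
#' (kinetics, summation, imaging) operate on this container.
#'
#' @param values numeric vector of samples.
#' @param dt sampling interval, ms (> 0).
#' @param t0 time of the first sample, ms.
#' @param stim_times numeric vector of stimulus onset times, ms.
#' @param unit unit tag, one of `"mV"`, `"pA"`, `"dff"`.
#' @return A tibble of class `ngf_trace` with columns `time`, `value`.
#' @export
#' @examples
#' tr <- ngf_trace(sin(seq(0, 1, 0.01)), dt = 0.1)
#' trace_dt(tr)
ngf_trace <- function(values, dt, t0 = 0, stim_times = numeric(), unit = "mV") {
  if (!is.numeric(values) || length(values) < 1)
    abort("`values` must be a non-empty numeric vector.", class = "ngf_error_config")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    abort("`dt` must be a single positive number (ms).", class = "ngf_error_config")
  if (any(!is.finite(values)))
    abort("trace values must be finite.", class = "ngf_error_config")
  out <- tibble(
    time = t0 + dt * (seq_along(values) - 1),
    value = as.double(values)
  )
  attr(out, "dt") <- dt
  attr(out, "t0") <- t0
  attr(out, "stim_times") <- as.double(stim_times)
  attr(out, "unit") <- unit
  class(out) <- c("ngf_trace", class(out))
  out
}

#' @rdname ngf_trace
#' @param x an `ngf_trace`.
#' @export
trace_dt <- function(x) attr(x, "dt")

#' @rdname ngf_trace
#' @export
trace_stim_times <- function(x) attr(x, "stim_times")

#' @rdname ngf_trace
#' @export
trace_unit <- function(x) attr(x, "unit")

same_time_base <- function(a, b) {
  nrow(a) == nrow(b) &&
    isTRUE(all.equal(trace_dt(a), trace_dt(b))) &&
    isTRUE(all.equal(a$time[1], b$time[1]))
}

#' @export
autoplot.ngf_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    labs(x = "time (ms)", y = trace_unit(object))
}
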