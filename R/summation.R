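# Kinetics conventions: rise time is the 10-90% interval of the peak
# amplitude, half-width the full width at 50%, and the decay time the
# interval from the peak to 67.3% decay (i.e. 32.7% of peak remaining),
# matching common practice for evoked IPSC/IPSP analysis.

interp_crossing <- function(t, y, level, from = 1, to = length(y),
                            first = TRUE) {
  idx <- seq(from, to)
  yy <- y[idx]; tt <- t[idx]
  above <- yy >= level
  hits <- which(above[-1] != above[-length(above)])
  if (length(hits) == 0) return(NA_real_)
  i <- if (first) hits[1] else hits[length(hits)]
  t1 <- tt[i]; t2 <- tt[i + 1]; y1 <- yy[i]; y2 <- yy[i + 1]
  t1 + (level - y1) / (y2 - y1) * (t2 - t1)
}

#' Measure IPSP/IPSC kinetics of a trace
#'
#' Finds the response peak after the (first) stimulus, then measures the
#' 10-90% rise time, the half-width (full width at 50% of peak) and the
#' decay time, defined as the interval from the peak until the response has
#' decayed by 67.3% (32.7% of the peak remaining).  The peak is the signed
#' extremum of the baseline-subtracted trace inside `peak_window` after the
#' stimulus, so hyperpolarizing responses yield negative peaks.
#'
#' @param trace an [ngf_trace()] with at least one stimulus time.
#' @param peak_window window after the stimulus searched for the peak, ms.
#'   Use ~50 ms for fast (GABA-A) and ~400 ms for slow (GABA-B) signals.
#' @param baseline_window pre-stimulus interval averaged as baseline, ms.
#' @return One-row tibble: `peak`, `peak_time`, `rise_10_90`, `half_width`,
#'   `decay_time`, `baseline` (times in ms, peak in the trace unit).
#' @export
measure_kinetics <- function(trace, peak_window = 50, baseline_window = 50) {
  stopifnot(inherits(trace, "ngf_trace"))
  stim <- trace_stim_times(trace)
  if (length(stim) < 1)
    abort("trace carries no stimulus time.", class = "ngf_error_config")
  if (peak_window <= 0)
    abort("`peak_window` must be > 0.", class = "ngf_error_config")
  stim <- stim[1]
  t <- trace$time; v <- trace$value
  pre <- v[t < stim & t >= stim - baseline_window]
  baseline <- if (length(pre)) mean(pre) else 0
  d <- v - baseline
  win <- which(t >= stim & t <= stim + peak_window)
  if (length(win) < 3)
    abort("peak window contains too few samples.", class = "ngf_error_config")
  ipk <- win[which.max(abs(d[win]))]
  peak <- d[ipk]
  if (abs(peak) < .Machine$double.eps * 100 || !is.finite(peak))
    abort("flat trace: no measurable peak.", class = "ngf_error_kinetics")
  s <- sign(peak)
  a <- s * d  # rectified deflection, peak positive
  i0 <- win[1]
  t10 <- interp_crossing(t, a, 0.1 * abs(peak), i0, ipk, first = FALSE)
  t90 <- interp_crossing(t, a, 0.9 * abs(peak), i0, ipk, first = FALSE)
  th1 <- interp_crossing(t, a, 0.5 * abs(peak), i0, ipk, first = FALSE)
  th2 <- interp_crossing(t, a, 0.5 * abs(peak), ipk, length(t), first = TRUE)
  tdec <- interp_crossing(t, a, 0.327 * abs(peak), ipk, length(t), first = TRUE)
  tibble(
    peak = peak,
    peak_time = t[ipk] - stim,
    rise_10_90 = t90 - t10,
    half_width = th2 - th1,
    decay_time = tdec - t[ipk],
    baseline = baseline
  )
}

#' Summation nonlinearity of convergent postsynaptic potentials
#'
#' Compares the measured compound response to the calculated (arithmetic)
#' sum of the unitary responses.  The peak nonlinearity is
#' `100 * (measured_peak - calculated_peak) / calculated_peak` (% of the
#' calculated-sum peak; negative = sublinear in magnitude, for either
#' polarity) and the time-resolved nonlinearity is
#' `100 * (measured - calculated) / calculated_peak` (signed peak in the
#' denominator, so a compound response smaller in magnitude than the sum is
#' negative for hyperpolarizing traces too).
#'
#' All traces must be baseline-subtracted and share the same time base.
#'
#' @param unitaries list of unitary [ngf_trace()]s.
#' @param measured measured compound [ngf_trace()].
#' @param peak_window window after the stimulus searched for peaks, ms.
#' @return An object of class `summation_result`; see [tidy.summation_result()]
#'   and [glance.summation_result()].
#' @export
summation_nonlinearity <- function(unitaries, measured, peak_window = 400) {
  stopifnot(is.list(unitaries), length(unitaries) >= 1,
            inherits(measured, "ngf_trace"))
  for (u in unitaries) {
    if (!inherits(u, "ngf_trace") || !same_time_base(u, measured))
      abort("all traces must share one time base.", class = "ngf_error_alignment")
  }
  calc <- rowSums(do.call(cbind, lapply(unitaries, function(u) u$value)))
  stim <- trace_stim_times(measured)
  stim1 <- if (length(stim)) stim[1] else measured$time[1]
  t <- measured$time
  win <- which(t >= stim1 & t <= stim1 + peak_window)
  if (!length(win)) win <- seq_along(t)
  calc_peak <- calc[win][which.max(abs(calc[win]))]
  meas_peak <- measured$value[win][which.max(abs(measured$value[win]))]
  if (abs(calc_peak) < .Machine$double.eps * 100)
    abort("calculated sum is flat; nonlinearity undefined.",
          class = "ngf_error_kinetics")
  diff <- measured$value - calc
  structure(
    list(
      time = t,
      calculated = calc,
      measured = measured$value,
      difference = diff,
      nonlinearity_t = 100 * diff / calc_peak,
      calculated_peak = calc_peak,
      measured_peak = meas_peak,
      max_nonlinearity = 100 * (meas_peak - calc_peak) / calc_peak,
      unit = trace_unit(measured)
    ),
    class = "summation_result"
  )
}

#' @describeIn summation_nonlinearity Per-sample tibble: `time`, `measured`,
#'   `calculated`, `difference`, `nonlinearity_pct`.
#' @param x a `summation_result`.
#' @param ... unused.
#' @export
tidy.summation_result <- function(x, ...) {
  tibble(time = x$time, measured = x$measured, calculated = x$calculated,
         difference = x$difference, nonlinearity_pct = x$nonlinearity_t)
}

#' @describeIn summation_nonlinearity One-row summary: peak amplitudes and
#'   the peak nonlinearity in percent.
#' @export
glance.summation_result <- function(x, ...) {
  tibble(measured_peak = x$measured_peak, calculated_peak = x$calculated_peak,
         max_nonlinearity_pct = x$max_nonlinearity)
}

#' @export
autoplot.summation_result <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("measured", "calculated"), names_to = "trace")
  ggplot(d, aes(x = .data$time, y = .data$value, colour = .data$trace)) +
    geom_line() +
    labs(x = "time (ms)", y = object$unit)
}

#' Normalize burst-evoked response peaks to the single-AP response
#'
#' Postsynaptic peak amplitudes recorded for bursts of 1..k presynaptic
#' action potentials are divided by the 1-AP peak of the same set, so each
#' set reports fold-change relative to its own unitary response.
#'
#' @param peaks numeric vector of peak amplitudes ordered by AP count
#'   (1 AP first), or a tibble with columns `n_ap` and `peak`.
#' @return Tibble with `n_ap`, `peak`, `normalized`.
#' @export
#' @examples
#' normalize_burst(c(-0.63, -1.25, -1.53, -1.61))
normalize_burst <- function(peaks) {
  if (is.data.frame(peaks)) {
    stopifnot(all(c("n_ap", "peak") %in% names(peaks)))
    peaks <- peaks$peak[order(peaks$n_ap)]
  }
  if (length(peaks) < 1 || !is.numeric(peaks))
    abort("`peaks` must be a numeric vector.", class = "ngf_error_config")
  if (peaks[1] == 0)
    abort("1-AP peak is zero; normalization undefined.",
          class = "ngf_error_normalization")
  tibble(n_ap = seq_along(peaks), peak = peaks,
         normalized = peaks / peaks[1])
}
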