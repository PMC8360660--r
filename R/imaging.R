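#' Relative fluorescence change (dF/F) of a calcium trace
#'
#' Computes `R(t) = (F(t) - F0(t)) / F0(t)` where `F0(t)` is a
#' time-dependent baseline estimated as a running percentile of the raw
#' fluorescence in a sliding window, so slow drifts are removed while
#' transients survive.
#'
#' @param trace an [ngf_trace()] of raw fluorescence (arbitrary units,
#'   strictly positive baseline).
#' @param window baseline window width, ms (default 3000).
#' @param percentile baseline percentile in `[0, 1]` (default 0.2).
#' @return An [ngf_trace()] with unit `"dff"`.
#' @export
delta_f_over_f <- function(trace, window = 3000, percentile = 0.2) {
  stopifnot(inherits(trace, "ngf_trace"))
  f <- trace$value
  dt <- trace_dt(trace)
  half <- max(1L, floor(window / dt / 2))
  n <- length(f)
  f0 <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    unname(quantile(f[lo:hi], percentile, names = FALSE))
  }, numeric(1))
  if (any(f0 <= 0))
    abort("baseline F0 reaches zero; dF/F undefined.",
          class = "ngf_error_numeric")
  ngf_trace((f - f0) / f0, dt = dt, t0 = trace$time[1],
            stim_times = trace_stim_times(trace), unit = "dff")
}

#' Classify stimulus responsiveness of a calcium trial set
#'
#' Averages the trials, then calls the cell responsive if the post-stimulus
#' peak dF/F of the averaged trace exceeds three times the standard
#' deviation of its pre-stimulus noise.
#'
#' @param trials a `ca_trial_set` (see [synth_ca_trials()]), or a data frame
#'   with columns `trial`, `time`, `dff` plus a `stim_time` attribute.
#' @param stim_time stimulus time, ms; defaults to the attribute on `trials`.
#' @param noise_window pre-stimulus interval used for the noise SD, ms.
#' @param peak_window post-stimulus interval searched for the peak, ms
#'   (default 300, bracketing the rise of a stimulus-locked calcium
#'   transient; widening it inflates the false-positive rate of the
#'   max-over-window rule).
#' @param threshold multiple of the noise SD (default 3).
#' @return One-row tibble: `responsive`, `evoked_dff` (peak of the averaged
#'   trace, baseline-subtracted), `noise_sd`, `n_trials`.
#' @export
classify_responsive <- function(trials, stim_time = attr(trials, "stim_time"),
                                noise_window = 1000, peak_window = 300,
                                threshold = 3) {
  stopifnot(is.data.frame(trials),
            all(c("trial", "time", "dff") %in% names(trials)))
  if (is.null(stim_time))
    abort("stimulus time missing.", class = "ngf_error_config")
  n_trials <- length(unique(trials$trial))
  if (n_trials < 2)
    abort("need at least 2 trials.", class = "ngf_error_config")
  avg <- trials |>
    group_by(.data$time) |>
    summarise(dff = mean(.data$dff), .groups = "drop") |>
    arrange(.data$time)
  pre <- avg$dff[avg$time < stim_time & avg$time >= stim_time - noise_window]
  if (length(pre) < 2)
    abort("pre-stimulus noise window too short.", class = "ngf_error_config")
  noise_sd <- sd(pre)
  base <- mean(pre)
  post <- avg$dff[avg$time >= stim_time & avg$time <= stim_time + peak_window]
  evoked <- max(post) - base
  responsive <- if (noise_sd > 0) evoked > threshold * noise_sd else evoked > 0
  tibble(responsive = responsive, evoked_dff = evoked,
         noise_sd = noise_sd, n_trials = n_trials)
}

#' Fraction of responsive cells across a population
#'
#' @param results tibble with one row per cell as returned by
#'   [classify_responsive()] (rows bound together).
#' @return One-row tibble: `n_cells`, `n_responsive`, `fraction_pct`.
#' @export
responsive_fraction <- function(results) {
  stopifnot("responsive" %in% names(results))
  tibble(n_cells = nrow(results),
         n_responsive = sum(results$responsive),
         fraction_pct = 100 * mean(results$responsive))
}
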