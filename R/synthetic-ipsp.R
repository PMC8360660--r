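#' Target IPSP kinetics
#'
#' Container for the kinetics of a unitary postsynaptic potential: onset
#' latency, 10-90% rise time, half-width, decay time and (signed) peak
#' amplitude.  Hyperpolarizing responses carry negative amplitudes (mV).
#' Defaults are typical fast (GABA-A) kinetics; see [slow_ipsp_kinetics()]
#' for the metabotropic (GABA-B) counterpart.
#'
#' @param onset_latency ms (> 0).
#' @param rise_time_10_90 ms (> 0).
#' @param half_width ms (> 0).
#' @param decay_time ms (> 0), interval from peak to 67.3% decay.
#' @param amplitude peak amplitude, mV (negative = hyperpolarizing).
#' @return List of class `ipsp_kinetics`.
#' @export
ipsp_kinetics <- function(onset_latency = 2, rise_time_10_90 = 4.66,
                          half_width = 19.29, decay_time = 8.94,
                          amplitude = -2.19) {
  times <- c(onset_latency, rise_time_10_90, half_width, decay_time)
  if (any(!is.finite(times)) || any(times <= 0))
    abort("all kinetic times must be > 0.", class = "ngf_error_config")
  structure(list(onset_latency = onset_latency,
                 rise_time_10_90 = rise_time_10_90,
                 half_width = half_width, decay_time = decay_time,
                 amplitude = amplitude),
            class = "ipsp_kinetics")
}

#' @rdname ipsp_kinetics
#' @export
slow_ipsp_kinetics <- function(onset_latency = 49.42, rise_time_10_90 = 86.95,
                               half_width = 252.27, decay_time = 180,
                               amplitude = -0.94) {
  ipsp_kinetics(onset_latency, rise_time_10_90, half_width, decay_time,
                amplitude)
}

# Waveform family: y(t) = (1 - exp(-t/tau_r))^n * exp(-t/tau_d).
# n = 1 is the classical difference of exponentials (fast, ionotropic
# kinetics); n > 1 adds the sigmoidal onset of metabotropic responses,
# whose 10-90% rise is long relative to the half-width (a plain
# biexponential cannot go below half-width/rise of about 4.3).

ipsp_waveform <- function(t, tau_r, tau_d, n_pow) {
  (1 - exp(-t / tau_r))^n_pow * exp(-t / tau_d)
}

waveform_kinetics <- function(tau_r, tau_d, n_pow, span) {
  n <- 2500L
  t <- seq(0, span, length.out = n)
  y <- ipsp_waveform(t, tau_r, tau_d, n_pow)
  ipk <- which.max(y)
  pk <- y[ipk]
  if (ipk <= 1 || ipk >= n) return(c(NA_real_, NA_real_))
  t10 <- interp_crossing(t, y, 0.1 * pk, 1, ipk, first = FALSE)
  t90 <- interp_crossing(t, y, 0.9 * pk, 1, ipk, first = FALSE)
  h1 <- interp_crossing(t, y, 0.5 * pk, 1, ipk, first = FALSE)
  h2 <- interp_crossing(t, y, 0.5 * pk, ipk, n, first = TRUE)
  c(rise = t90 - t10, half_width = h2 - h1)
}

calibrate_waveform <- function(rise, half_width, tol = 0.05) {
  span <- 12 * half_width
  obj <- function(par) {
    k <- waveform_kinetics(exp(par[1]), exp(par[2]), 1 + exp(par[3]), span)
    if (any(!is.finite(k))) return(1e6)
    ((k[1] - rise) / rise)^2 + ((k[2] - half_width) / half_width)^2
  }
  inits <- list(c(log(rise / 2.2), log(max(half_width / log(2), rise)),
                  log(0.01)),
                c(log(rise / 1.3), log(half_width / 1.8), log(4)),
                c(log(rise), log(half_width / 2), log(10)))
  best <- NULL; best_val <- Inf
  for (init in inits) {
    fit <- optim(init, obj, method = "Nelder-Mead",
                 control = list(maxit = 600, reltol = 1e-12))
    if (fit$value < best_val) { best <- fit$par; best_val <- fit$value }
    if (best_val < (tol / 5)^2) break
  }
  pars <- list(tau_rise = exp(best[1]), tau_decay = exp(best[2]),
               n_pow = 1 + exp(best[3]))
  k <- waveform_kinetics(pars$tau_rise, pars$tau_decay, pars$n_pow, span)
  err <- max(abs(k[1] - rise) / rise, abs(k[2] - half_width) / half_width)
  if (!is.finite(err) || err > tol)
    abort(sprintf(paste0("requested kinetics unreachable",
                         " (best relative error %.1f%%)."), 100 * err),
          class = "ngf_error_calibration")
  pars
}

#' Synthesize a unitary IPSP trace with requested kinetics
#'
#' Builds a difference-of-exponentials waveform whose measured 10-90% rise
#' time, half-width and peak amplitude match the requested kinetics within
#' 5% (the time constants are calibrated numerically), plus optional
#' additive Gaussian noise.  A zero amplitude yields a flat trace.
#'
#' @param kinetics an [ipsp_kinetics()].
#' @param dt sampling interval, ms.
#' @param duration trace duration, ms; must exceed the response support.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param stim_time stimulus time, ms.
#' @param noise_sd additive Gaussian noise SD, mV.
#' @return An [ngf_trace()] in mV with the stimulus time attached.
#' @export
#' @examples
#' tr <- synth_ipsp(ipsp_kinetics(), dt = 0.1, duration = 300, seed = 1)
#' measure_kinetics(tr)
synth_ipsp <- function(kinetics, dt = 0.1, duration = 400, seed = 1,
                       stim_time = 50, noise_sd = 0) {
  stopifnot(inherits(kinetics, "ipsp_kinetics"))
  if (dt <= 0) abort("`dt` must be > 0.", class = "ngf_error_config")
  if (duration <= stim_time + kinetics$onset_latency + kinetics$half_width)
    abort("`duration` too short for the requested response.",
          class = "ngf_error_config")
  n <- floor(duration / dt) + 1L
  t <- dt * (seq_len(n) - 1L)
  v <- numeric(n)
  if (kinetics$amplitude != 0) {
    cal <- calibrate_waveform(kinetics$rise_time_10_90, kinetics$half_width)
    t0 <- stim_time + kinetics$onset_latency
    u <- pmax(t - t0, 0)
    y <- ipsp_waveform(u, cal$tau_rise, cal$tau_decay, cal$n_pow)
    y[t < t0] <- 0
    v <- kinetics$amplitude * y / max(y)
  }
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(n, 0, noise_sd))
  ngf_trace(v, dt = dt, stim_times = stim_time, unit = "mV")
}
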