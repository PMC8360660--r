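#' Synthesize a trial-structured calcium-imaging data set
#'
#' Emulates the input of the responsiveness analysis: `n_trials` repeats of a
#' dF/F trace sampled around a hindlimb-stimulation time.  Responsive sets
#' contain a stimulus-locked calcium transient (fast rise, slow decay) of the
#' configured amplitude in every trial; non-responsive sets contain Gaussian
#' noise only.
#'
#' @param n_trials number of trials (>= 1); the classification rule averages
#'   10 trials by default.
#' @param stim_time stimulus time, ms.
#' @param duration trial duration, ms.
#' @param dt sampling interval, ms (default 50 ms, i.e. ~20 Hz frame rate).
#' @param noise_sd SD of the additive dF/F noise per frame.
#' @param response_amplitude peak dF/F of the evoked transient.
#' @param responsive logical: include the transient?
#' @param seed integer seed.
#' @param tau_on,tau_off rise / decay time constants of the transient, ms.
#' @return A tibble of class `ca_trial_set` with columns `trial`, `time`,
#'   `dff`, and attributes `stim_time`, `dt`, `n_trials`.
#' @export
synth_ca_trials <- function(n_trials = 10, stim_time = 2000, duration = 5000,
                            dt = 50, noise_sd = 0.05,
                            response_amplitude = 0.3, responsive = TRUE,
                            seed = 1, tau_on = 50, tau_off = 500) {
  if (n_trials < 1)
    abort("`n_trials` must be >= 1.", class = "ngf_error_config")
  if (noise_sd < 0)
    abort("`noise_sd` must be >= 0.", class = "ngf_error_config")
  n <- floor(duration / dt) + 1L
  t <- dt * (seq_len(n) - 1L)
  u <- pmax(t - stim_time, 0)
  shape <- (1 - exp(-u / tau_on)) * exp(-u / tau_off)
  shape[t < stim_time] <- 0
  if (max(shape) > 0) shape <- shape / max(shape)
  base <- if (responsive) response_amplitude * shape else numeric(n)
  out <- with_seed(seed, {
    bind_rows(lapply(seq_len(n_trials), function(i) {
      tibble(trial = i, time = t,
             dff = base + rnorm(n, 0, noise_sd))
    }))
  })
  attr(out, "stim_time") <- stim_time
  attr(out, "dt") <- dt
  attr(out, "n_trials") <- n_trials
  class(out) <- c("ca_trial_set", class(out))
  out
}
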