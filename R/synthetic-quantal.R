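#' Binomial-quantal release model
#'
#' Describes a unitary GABAergic connection in the classical binomial-quantal
#' framework: `n_sites` functional release sites, each releasing independently
#' with a condition-specific probability, each released vesicle contributing a
#' gamma-distributed quantal amplitude with mean `q` (pA) and coefficient of
#' variation `quantal_cv`, on top of Gaussian baseline noise.
#'
#' Release probability is varied experimentally through the extracellular
#' Ca2+/Mg2+ ratio, so the model carries one probability per named condition
#' (typically `high_pr` and `low_pr`).
#'
#' @param n_sites number of functional release sites (positive integer).
#' @param q mean quantal amplitude, pA (> 0). IPSCs are analysed as
#'   magnitudes, so `q` is positive.
#' @param p_by_condition named numeric vector of release probabilities in
#'   `[0, 1]`; values 0 and 1 are allowed as degenerate test settings.
#' @param quantal_cv per-site coefficient of variation of the quantal
#'   amplitude (>= 0). Gamma-distributed to keep amplitudes positive.
#' @param noise_sd SD of the Gaussian baseline noise, pA (>= 0).
#' @return A list of class `quantal_model`.
#' @export
#' @examples
#' m <- quantal_model(11, 3.9, c(high_pr = 0.8, low_pr = 0.45))
#' simulate_quantal(m, "high_pr", n_trials = 5, seed = 1)
quantal_model <- function(n_sites, q,
                          p_by_condition = c(high_pr = 0.8, low_pr = 0.45),
                          quantal_cv = 0.3, noise_sd = 2) {
  if (!is.numeric(n_sites) || n_sites < 1 || n_sites != round(n_sites))
    abort("`n_sites` must be a positive integer.", class = "ngf_error_config")
  if (!is.numeric(q) || q <= 0)
    abort("`q` must be a positive quantal amplitude (pA).", class = "ngf_error_config")
  if (is.null(names(p_by_condition)) || any(!nzchar(names(p_by_condition))))
    abort("`p_by_condition` must be a named vector.", class = "ngf_error_config")
  if (any(p_by_condition < 0 | p_by_condition > 1))
    abort("release probabilities must lie in [0, 1].", class = "ngf_error_config")
  if (quantal_cv < 0 || noise_sd < 0)
    abort("`quantal_cv` and `noise_sd` must be >= 0.", class = "ngf_error_config")
  structure(
    list(n_sites = as.integer(n_sites), q = q,
         p_by_condition = p_by_condition,
         quantal_cv = quantal_cv, noise_sd = noise_sd),
    class = "quantal_model"
  )
}

#' Simulate unitary IPSC amplitudes from a binomial-quantal model
#'
#' Each trial draws a released-site count from `Binomial(n_sites, p)`, sums
#' that many independent gamma quantal amplitudes (mean `q`, CV `quantal_cv`)
#' and adds Gaussian baseline noise.  Amplitudes are returned as positive
#' magnitudes (pA) in a tibble, one row per trial, with an elapsed-time
#' column emulating the slow acquisition of paired recordings.
#'
#' @param model a [quantal_model()].
#' @param condition condition name; must be a key of `p_by_condition`.
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; all randomness derives from it.
#' @param inter_trial_s spacing of consecutive trials, seconds (stimulation
#'   of neurogliaform cells must be slow to avoid use-dependent depression).
#' @return Tibble with columns `condition`, `trial_index`, `time_s`,
#'   `amplitude_pA`.
#' @export
simulate_quantal <- function(model, condition, n_trials, seed,
                             inter_trial_s = 60) {
  stopifnot(inherits(model, "quantal_model"))
  if (!condition %in% names(model$p_by_condition))
    abort(paste0("unknown condition '", condition, "'."),
          class = "ngf_error_config")
  if (n_trials < 1)
    abort("`n_trials` must be >= 1.", class = "ngf_error_config")
  p <- unname(model$p_by_condition[[condition]])
  with_seed(seed, {
    k <- rbinom(n_trials, model$n_sites, p)
    cv <- model$quantal_cv
    amp <- if (cv > 0) {
      shape <- 1 / cv^2
      vapply(k, function(ki) {
        if (ki == 0) 0 else sum(rgamma(ki, shape = shape,
                                       scale = model$q * cv^2))
      }, numeric(1))
    } else {
      k * model$q
    }
    amp <- amp + rnorm(n_trials, 0, model$noise_sd)
    tibble(
      condition = condition,
      trial_index = seq_len(n_trials),
      time_s = (seq_len(n_trials) - 1) * inter_trial_s,
      amplitude_pA = amp
    )
  })
}

#' Analytic moments of the binomial-quantal amplitude distribution
#'
#' Mean `n p q` and variance `n p (1 - p) q^2 + n p (q cv)^2 + noise_sd^2`;
#' used as the independent oracle for the simulator and in tests of the
#' Bayesian quantal analysis.
#'
#' @inheritParams simulate_quantal
#' @return Tibble with columns `condition`, `mean`, `variance`.
#' @export
quantal_moments <- function(model, condition = names(model$p_by_condition)) {
  stopifnot(inherits(model, "quantal_model"))
  p <- unname(model$p_by_condition[condition])
  n <- model$n_sites; q <- model$q
  tibble(
    condition = condition,
    mean = n * p * q,
    variance = n * p * (1 - p) * q^2 + n * p * (q * model$quantal_cv)^2 +
      model$noise_sd^2
  )
}
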