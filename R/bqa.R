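# Bayesian quantal analysis: joint posterior over the number of functional
# release sites (Nfrs), quantal size q, per-condition release probability p,
# quantal CV and baseline noise SD, from IPSC amplitude samples recorded
# under two or more release-probability conditions.  Nfrs and q are shared
# across conditions; p is condition-specific.  The likelihood is a binomial
# mixture over the released-site count k; the k-site component density is
# the k-fold gamma convolution (exact, via Gauss-Hermite quadrature over
# the Gaussian noise) when the gamma shape k/cv^2 is small enough to be
# skewed, and the moment-matched normal otherwise.  p, cv and noise are
# marginalized on grids.

#' Default BQA priors
#'
#' Weakly informative defaults: Nfrs uniform on `1..n_max`; q log-uniform
#' on `q_range` (pA); p uniform on (0, 1); small grids over the quantal CV
#' and the baseline noise SD.
#'
#' @param n_max largest Nfrs considered.
#' @param q_range quantal-size range, pA.
#' @param n_q,n_p grid resolutions for q and p.
#' @param cv_grid,noise_grid marginalization grids for quantal CV and
#'   noise SD (pA).
#' @return List of prior settings for [bqa_fit()].
#' @export
bqa_priors <- function(n_max = 30, q_range = c(0.5, 20), n_q = 40, n_p = 39,
                       cv_grid = c(0.15, 0.3, 0.45),
                       noise_grid = c(0.5, 1, 2, 4, 8)) {
  list(n_max = as.integer(n_max), q_range = q_range, n_q = n_q, n_p = n_p,
       cv_grid = cv_grid, noise_grid = noise_grid)
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Bayesian quantal analysis across release-probability conditions
#'
#' @param data tibble with columns `condition` and `amplitude_pA` (IPSC
#'   magnitudes, pA); at least two conditions recorded from the same
#'   connection.  [simulate_quantal()] produces this layout.
#' @param priors see [bqa_priors()].
#' @param seed unused by the deterministic grid inference; kept so the
#'   interface matches the stochastic backends.
#' @return Object of class `bqa_fit`: posterior grid over (Nfrs, q),
#'   marginal posteriors, point estimates (the joint posterior mode, which
#'   on the ridge-shaped quantal likelihood is insensitive to the upper
#'   prior bound on Nfrs; marginal medians are also reported) and
#'   per-condition release-probability estimates.  See [tidy.bqa_fit()],
#'   [glance.bqa_fit()].
#' @export
bqa_fit <- function(data, priors = bqa_priors(), seed = 1) {
  stopifnot(is.data.frame(data),
            all(c("condition", "amplitude_pA") %in% names(data)))
  conds <- unique(data$condition)
  if (length(conds) < 2)
    abort("BQA needs >= 2 release-probability conditions.",
          class = "ngf_error_config")
  amps <- lapply(conds, function(cc)
    abs(data$amplitude_pA[data$condition == cc]))
  n_per <- vapply(amps, length, integer(1))
  if (any(n_per < 20))
    warn("fewer than 20 trials in some condition; estimates will be weak.")
  if (max(unlist(amps)) / priors$n_max < priors$q_range[1] * 0.5)
    NULL  # amplitudes comfortably inside the prior support
  q_grid <- exp(seq(log(priors$q_range[1]), log(priors$q_range[2]),
                    length.out = priors$n_q))
  p_grid <- seq(0.5 / priors$n_p, 1 - 0.5 / priors$n_p,
                length.out = priors$n_p)
  n_grid <- seq_len(priors$n_max)
  dims <- c(length(n_grid), length(q_grid), length(priors$cv_grid),
            length(priors$noise_grid))
  ll <- bqa_loglik_cpp(amps, priors$n_max, q_grid, p_grid,
                       priors$cv_grid, priors$noise_grid,
                       shape_normal_threshold = 30)
  m <- max(ll)
  post <- exp(ll - m)
  post <- post / sum(post)
  # marginals over (N, q)
  post_nq <- apply(post, c(1, 2), sum)
  post_n <- rowSums(post_nq)
  post_q <- colSums(post_nq)
  wmedian <- function(x, w) {
    o <- order(x); cw <- cumsum(w[o]) / sum(w)
    x[o][which(cw >= 0.5)[1]]
  }
  n_med <- wmedian(n_grid, post_n)
  q_med <- wmedian(q_grid, post_q)
  # Point estimates: Nfrs at the joint posterior mode, q as the posterior
  # mean conditional on that Nfrs.  The quantal likelihood is ridge-shaped
  # (N*q nearly constant), so the median of the N marginal inherits the
  # upper prior bound, whereas the mode is invariant to it; conditioning q
  # on the modal N removes the ridge-induced skew (and q-grid
  # quantization) from the q estimate.
  jm <- arrayInd(which.max(post_nq), dim(post_nq))
  n_hat <- n_grid[jm[1]]
  wq_row <- post_nq[jm[1], ]
  q_hat <- sum(q_grid * wq_row) / sum(wq_row)
  # per-condition p: posterior expectation with (N,q,cv,sg) at the joint mode
  mode_idx <- arrayInd(which.max(ll), dims)
  N <- n_grid[mode_idx[1]]; q <- q_grid[mode_idx[2]]
  cv <- priors$cv_grid[mode_idx[3]]; sg <- priors$noise_grid[mode_idx[4]]
  k <- 0:N
  W <- outer(k, p_grid, function(kk, pp) dbinom(kk, N, pp))
  sds <- sqrt(sg^2 + k * (q * cv)^2)
  p_hat <- vapply(seq_along(conds), function(ic) {
    y <- amps[[ic]]
    D <- vapply(seq_along(k), function(j)
      dnorm(y, k[j] * q, sds[j]), numeric(length(y)))
    llp <- colSums(log(pmax(D %*% W, 1e-300)))
    w <- exp(llp - max(llp)); sum(p_grid * w) / sum(w)
  }, numeric(1))
  structure(
    list(
      conditions = conds,
      n_grid = n_grid, q_grid = q_grid,
      posterior_nq = post_nq,
      posterior_n = post_n, posterior_q = post_q,
      nfrs_estimate = n_hat, q_estimate = q_hat,
      nfrs_median = n_med, q_median = q_med,
      p_by_condition = setNames(p_hat, conds),
      log_marginal = m + log(sum(exp(ll - m))) -
        log(length(ll)),  # under uniform grid prior
      n_trials = setNames(n_per, conds),
      priors = priors
    ),
    class = "bqa_fit"
  )
}

#' @describeIn bqa_fit Parameter summary: one row per parameter with the
#'   posterior median and a 90% credible interval (grid quantiles).
#' @param x a `bqa_fit`.
#' @param ... unused.
#' @export
tidy.bqa_fit <- function(x, ...) {
  wq <- function(vals, w, p) {
    o <- order(vals); cw <- cumsum(w[o]) / sum(w)
    vapply(p, function(pp) vals[o][which(cw >= pp)[1]], numeric(1))
  }
  nq <- wq(x$n_grid, x$posterior_n, c(0.05, 0.5, 0.95))
  qq <- wq(x$q_grid, x$posterior_q, c(0.05, 0.5, 0.95))
  bind_rows(
    tibble(term = "n_sites", estimate = x$nfrs_estimate, conf_low = nq[1],
           conf_high = nq[3]),
    tibble(term = "q", estimate = x$q_estimate, conf_low = qq[1],
           conf_high = qq[3]),
    tibble(term = paste0("p_", x$conditions),
           estimate = unname(x$p_by_condition),
           conf_low = NA_real_, conf_high = NA_real_)
  )
}

#' @describeIn bqa_fit One-row model summary.
#' @export
glance.bqa_fit <- function(x, ...) {
  tibble(nfrs_estimate = x$nfrs_estimate, q_estimate = x$q_estimate,
         nfrs_median = x$nfrs_median, q_median = x$q_median,
         log_marginal = x$log_marginal,
         n_conditions = length(x$conditions),
         n_trials_total = sum(x$n_trials))
}

#' @export
print.bqa_fit <- function(x, ...) {
  cat("Bayesian quantal analysis\n")
  cat(sprintf("  Nfrs: %d    q: %.2f pA   (joint posterior mode)\n",
              x$nfrs_estimate, x$q_estimate))
  cat(sprintf("  p: %s\n",
              paste(sprintf("%s = %.2f", names(x$p_by_condition),
                            x$p_by_condition), collapse = ", ")))
  invisible(x)
}

#' @export
autoplot.bqa_fit <- function(object, ...) {
  d <- tibble(n_sites = object$n_grid, posterior = object$posterior_n)
  ggplot(d, aes(x = .data$n_sites, y = .data$posterior)) +
    geom_col() +
    labs(x = "number of functional release sites",
         y = "posterior probability")
}

kmeanspp_init <- function(x, k, seed) {
  with_seed(seed, {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    i <- sample.int(n, 1)
    centers[1, ] <- x[i, ]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in seq_len(k - 1) + 1) {
      if (all(d2 == 0)) i <- which.min(seq_len(n)) else
        i <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
    centers
  })
}

#' Separate uniquantal events by K-means clustering
#'
#' Clusters per-event features (initial slope, peak amplitude, area;
#' standardized internally) into `k = 3` groups and labels them, by
#' increasing amplitude centroid, as `failure`, `uniquantal` and
#' `multiquantal`.  Initialization is a deterministic k-means++ seeded by
#' `seed`.
#'
#' @param features data frame with columns `slope`, `amplitude`, `area`
#'   (one row per event).
#' @param k number of clusters (default 3).
#' @param seed integer seed for the k-means++ initialization.
#' @return List of class `event_separation`: `events` (features plus
#'   `label`), `uniquantal_mean` (mean amplitude of the uniquantal
#'   cluster, pA), `centers`.
#' @export
kmeans_event_separation <- function(features, k = 3, seed = 1) {
  stopifnot(is.data.frame(features),
            all(c("slope", "amplitude", "area") %in% names(features)))
  x <- as.matrix(features[, c("slope", "amplitude", "area")])
  if (nrow(unique(x)) < k)
    abort("fewer distinct events than clusters.", class = "ngf_error_cluster")
  mu <- colMeans(x); s <- apply(x, 2, sd)
  s[s == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  init <- kmeanspp_init(xs, k, seed)
  km <- kmeans(xs, centers = init, iter.max = 100)
  amp_cent <- vapply(seq_len(k), function(j)
    mean(features$amplitude[km$cluster == j]), numeric(1))
  rank <- order(amp_cent)  # ties broken by lowest index (order is stable)
  lab_names <- if (k == 3) c("failure", "uniquantal", "multiquantal")
    else paste0("cluster_", seq_len(k))
  labels <- lab_names[match(km$cluster, rank)]
  uni <- if (k == 3) mean(features$amplitude[labels == "uniquantal"])
    else NA_real_
  structure(
    list(events = mutate(as_tibble(features), label = labels),
         uniquantal_mean = uni,
         centers = tibble(label = lab_names,
                          amplitude = amp_cent[rank])),
    class = "event_separation"
  )
}

#' Stability of IPSC amplitudes over a recording
#'
#' Pearson correlation between IPSC amplitude and elapsed recording time,
#' used to screen epochs for rundown or long-term plasticity (stable
#' connections show |r| well below ~0.5).
#'
#' @param amplitudes numeric amplitudes (>= 3, nonzero variance).
#' @param times elapsed times, s (same length, nonzero variance).
#' @return Tibble with `r` and `p_value` (two-sided).
#' @export
stability_correlation <- function(amplitudes, times) {
  if (length(amplitudes) < 3 || length(amplitudes) != length(times))
    abort("need >= 3 paired points.", class = "ngf_error_stats")
  if (sd(amplitudes) == 0 || sd(times) == 0)
    abort("zero variance.", class = "ngf_error_stats")
  ct <- cor.test(amplitudes, times, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value)
}
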