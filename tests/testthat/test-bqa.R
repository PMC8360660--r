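test_that("degenerate noiseless data concentrate on the N*q ridge", {
  d <- dplyr::bind_rows(
    tibble::tibble(condition = "a", trial_index = 1:25, time_s = 0,
                   amplitude_pA = 40),
    tibble::tibble(condition = "b", trial_index = 1:25, time_s = 0,
                   amplitude_pA = 40))
  f <- bqa_fit(d, priors = bqa_priors(n_max = 20))
  # posterior-weighted ridge deviation |N*q - 40| is small
  ridge <- outer(f$n_grid, f$q_grid)
  dev <- sum(abs(ridge - 40) * f$posterior_nq)
  expect_lt(dev, 3)
  expect_lt(abs(f$nfrs_estimate * f$q_estimate - 40), 5)
  # posterior mass is conserved
  expect_equal(sum(f$posterior_nq), 1, tolerance = 1e-6)
  expect_equal(sum(f$posterior_n), 1, tolerance = 1e-6)
})

test_that("posterior is exchangeable over trial order", {
  m <- quantal_model(6, 4, c(hi = 0.8, lo = 0.4))
  d <- dplyr::bind_rows(simulate_quantal(m, "hi", 30, seed = 1),
                        simulate_quantal(m, "lo", 30, seed = 2))
  f1 <- bqa_fit(d)
  set.seed(3)
  f2 <- bqa_fit(d[sample(nrow(d)), ])
  expect_equal(f1$posterior_nq, f2$posterior_nq, tolerance = 1e-12)
})

test_that("recovery sharpens with ten times the trials", {
  m <- quantal_model(8, 4.5, c(hi = 0.8, lo = 0.45),
                     quantal_cv = 0.3, noise_sd = 2)
  fit_with <- function(n, seed) {
    d <- dplyr::bind_rows(simulate_quantal(m, "hi", n, seed = seed),
                          simulate_quantal(m, "lo", n, seed = seed + 500))
    bqa_fit(d)
  }
  errs <- function(f) c(abs(f$nfrs_estimate - 8), abs(f$q_estimate - 4.5))
  e33 <- rowMeans(vapply(1:4, function(s) errs(fit_with(33, s)),
                         numeric(2)))
  e330 <- rowMeans(vapply(1:4, function(s) errs(fit_with(330, s)),
                          numeric(2)))
  # q error shrinks markedly with more data; Nfrs error does not grow
  expect_lt(e330[2], e33[2] + 0.2)
  expect_lte(e330[1], e33[1] + 1)
})

test_that("BQA input validation", {
  one <- tibble::tibble(condition = "a", trial_index = 1:30, time_s = 0,
                        amplitude_pA = rnorm(30, 20, 4))
  expect_error(bqa_fit(one), class = "ngf_error_config")
  expect_warning(
    bqa_fit(dplyr::bind_rows(
      tibble::tibble(condition = "a", trial_index = 1:10, time_s = 0,
                     amplitude_pA = rnorm(10, 30, 5)),
      tibble::tibble(condition = "b", trial_index = 1:10, time_s = 0,
                     amplitude_pA = rnorm(10, 15, 5)))),
    "fewer than 20")
})

test_that("K-means separation labels failures/uni/multiquantal correctly", {
  ev <- three_cluster_events()
  sep <- kmeans_event_separation(ev[c("slope", "amplitude", "area")],
                                 seed = 1)
  expect_equal(sep$events$label, ev$truth)
  expect_lt(abs(sep$uniquantal_mean - 4.6), 3 * 0.3 / sqrt(20))

  # label semantics invariant under feature-row permutation
  set.seed(2)
  perm <- sample(nrow(ev))
  sep2 <- kmeans_event_separation(ev[perm, c("slope", "amplitude", "area")],
                                  seed = 1)
  expect_equal(sep2$events$label, ev$truth[perm])

  # all-identical events cannot be clustered
  same <- data.frame(slope = rep(1, 10), amplitude = rep(2, 10),
                     area = rep(3, 10))
  expect_error(kmeans_event_separation(same), class = "ngf_error_cluster")
})

test_that("stability correlation: exact line, null, and closed form", {
  t <- 1:50
  expect_equal(stability_correlation(2 + 0.3 * t, t)$r, 1)
  set.seed(7)
  null <- stability_correlation(rnorm(10000), 1:10000)
  expect_lt(abs(null$r), 0.05)
  # 4-point hand case against the direct product-moment formula
  a <- c(1, 3, 2, 5); tt <- c(0, 1, 2, 3)
  r_hand <- sum((a - mean(a)) * (tt - mean(tt))) /
    sqrt(sum((a - mean(a))^2) * sum((tt - mean(tt))^2))
  expect_equal(stability_correlation(a, tt)$r, r_hand)
  expect_error(stability_correlation(c(1, 1, 1), 1:3),
               class = "ngf_error_stats")
})
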