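test_that("dF/F is zero for constant fluorescence and recovers step changes", {
  f <- ngf_trace(rep(100, 200), dt = 50, unit = "dff")
  d <- delta_f_over_f(f)
  expect_true(all(abs(d$value) < 1e-12))

  # multiplicative step on a constant baseline
  v <- rep(100, 200); v[120:140] <- 100 * 1.3
  d2 <- delta_f_over_f(ngf_trace(v, dt = 50), window = 3000)
  expect_lt(abs(max(d2$value) - 0.3), 0.02)
})

test_that("a drifting baseline plus transient is recovered within 10%", {
  t <- seq(0, 10000, 50)
  f0 <- 100 + 15 * sin(t / 3000)
  tran <- 0.35 * exp(-(t - 5000) / 600) * (t >= 5000)
  f <- ngf_trace(f0 * (1 + tran), dt = 50, stim_times = 5000)
  d <- delta_f_over_f(f)
  expect_lt(abs(max(d$value) - 0.35) / 0.35, 0.1)
})

test_that("3xSD responsiveness rule: hits, misses and false-positive rate", {
  strong <- synth_ca_trials(response_amplitude = 10 * 0.05, noise_sd = 0.05,
                            responsive = TRUE, seed = 1)
  expect_true(classify_responsive(strong)$responsive)

  silent0 <- synth_ca_trials(response_amplitude = 0, noise_sd = 0,
                             responsive = FALSE, seed = 1)
  expect_false(classify_responsive(silent0)$responsive)

  fp <- vapply(1:100, function(s)
    classify_responsive(synth_ca_trials(responsive = FALSE, seed = s)
                        )$responsive,
    logical(1))
  expect_lte(mean(fp), 0.05)
})

test_that("classification is invariant to positive scaling of dF/F", {
  set1 <- synth_ca_trials(response_amplitude = 0.2, noise_sd = 0.05, seed = 3)
  scaled <- set1
  scaled$dff <- scaled$dff * 7.3
  expect_identical(classify_responsive(set1)$responsive,
                   classify_responsive(scaled)$responsive)
})

test_that("averaging n trials shrinks the noise SD like 1/sqrt(n)", {
  sd1 <- classify_responsive(
    synth_ca_trials(n_trials = 2, responsive = FALSE, noise_sd = 0.1,
                    seed = 5))$noise_sd
  sd16 <- classify_responsive(
    synth_ca_trials(n_trials = 32, responsive = FALSE, noise_sd = 0.1,
                    seed = 5))$noise_sd
  expect_gt(sd1 / sd16, 4 * 0.5)   # expect ~4, allow wide MC slack
  expect_lt(sd1 / sd16, 4 * 2)
})

test_that("responsive fraction aggregates cells", {
  res <- dplyr::bind_rows(lapply(1:10, function(s)
    classify_responsive(synth_ca_trials(responsive = s <= 4,
                                        response_amplitude = 0.5,
                                        noise_sd = 0.05, seed = s))))
  fr <- responsive_fraction(res)
  expect_equal(fr$n_cells, 10)
  expect_equal(fr$fraction_pct, 10 * fr$n_responsive)
  expect_gte(fr$n_responsive, 4)
})
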