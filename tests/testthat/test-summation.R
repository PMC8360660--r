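test_that("kinetics measurement: closed-form decay and shape invariance", {
  t <- seq(0, 200, 0.05)
  v <- ifelse(t >= 50, -exp(-(t - 50) / 10), 0)
  tr <- ngf_trace(v, dt = 0.05, stim_times = 50)
  k <- measure_kinetics(tr, peak_window = 5)
  expect_equal(k$decay_time, -10 * log(0.327), tolerance = 0.01)

  # amplitude scaling leaves the time measures unchanged
  tr2 <- ngf_trace(2 * v, dt = 0.05, stim_times = 50)
  k2 <- measure_kinetics(tr2, peak_window = 5)
  expect_equal(k2$rise_10_90, k$rise_10_90, tolerance = 1e-9)
  expect_equal(k2$half_width, k$half_width, tolerance = 1e-9)
  expect_equal(k2$decay_time, k$decay_time, tolerance = 1e-9)
  expect_equal(k2$peak, 2 * k$peak)

  expect_error(measure_kinetics(ngf_trace(rep(0, 1000), dt = 0.1,
                                          stim_times = 10)),
               class = "ngf_error_kinetics")
  expect_error(measure_kinetics(ngf_trace(v, dt = 0.05)),
               class = "ngf_error_config")
})

test_that("summation arithmetic: exact sum, scaled sum, and symmetry", {
  u1 <- synth_ipsp(ipsp_kinetics(amplitude = -1.7), dt = 0.2,
                   duration = 400, seed = 1)
  u2 <- synth_ipsp(ipsp_kinetics(amplitude = -2.2, rise_time_10_90 = 6,
                                 half_width = 25), dt = 0.2,
                   duration = 400, seed = 1)
  exact <- ngf_trace(u1$value + u2$value, dt = 0.2, stim_times = 50)
  s0 <- summation_nonlinearity(list(u1, u2), exact)
  expect_equal(s0$max_nonlinearity, 0)
  expect_true(all(tidy(s0)$nonlinearity_pct == 0))

  scaled <- ngf_trace(0.9 * (u1$value + u2$value), dt = 0.2,
                      stim_times = 50)
  s1 <- summation_nonlinearity(list(u1, u2), scaled)
  expect_equal(s1$max_nonlinearity, -10, tolerance = 1e-6)

  # identical linear unitaries k times: exactly 0%
  s2 <- summation_nonlinearity(list(u1, u1, u1),
                               ngf_trace(3 * u1$value, dt = 0.2,
                                         stim_times = 50))
  expect_equal(s2$max_nonlinearity, 0)

  # mismatched time base errors
  short <- ngf_trace(u1$value[1:100], dt = 0.2, stim_times = 50)
  expect_error(summation_nonlinearity(list(u1), short),
               class = "ngf_error_alignment")
})

test_that("driving-force sublinearity matches a conductance-based ODE", {
  skip_if_not_installed("deSolve")
  # passive membrane with two synaptic conductances (alpha kinetics)
  gl <- 0.05; El <- -65; Es <- -80; Cm <- 1
  galpha <- function(t, on, gmax, tau)
    ifelse(t >= on, gmax * (t - on) / tau * exp(1 - (t - on) / tau), 0)
  rhs <- function(t, y, p) {
    g1 <- if (p$use1) galpha(t, 20, 0.02, 15) else 0
    g2 <- if (p$use2) galpha(t, 20, 0.03, 15) else 0
    list((-gl * (y - El) - (g1 + g2) * (y - Es)) / Cm)
  }
  solve_v <- function(use1, use2) {
    out <- deSolve::ode(c(V = El), times = seq(0, 300, 0.1), rhs,
                        list(use1 = use1, use2 = use2))
    out[, "V"] - El
  }
  v1 <- solve_v(TRUE, FALSE); v2 <- solve_v(FALSE, TRUE)
  v12 <- solve_v(TRUE, TRUE)
  tr <- function(v) ngf_trace(v, dt = 0.1, stim_times = 20)
  res <- summation_nonlinearity(list(tr(v1), tr(v2)), tr(v12),
                                peak_window = 200)
  # independent evaluation of the same metric from the ODE solutions
  pk <- function(v) v[which.max(abs(v))]
  oracle <- 100 * (pk(v12) - pk(v1 + v2)) / pk(v1 + v2)
  expect_equal(res$max_nonlinearity, oracle, tolerance = 0.01)
  # driving-force interaction makes the compound response sublinear
  expect_lt(res$max_nonlinearity, 0)
})

test_that("burst normalization divides by the single-AP peak", {
  out <- normalize_burst(c(-1, -2, -3, -4))
  expect_equal(out$normalized, c(1, 2, 3, 4))
  paper_like <- normalize_burst(c(-0.63, -1.25, -1.53, -1.61))
  expect_equal(paper_like$normalized, c(1, 1.98, 2.43, 2.56),
               tolerance = 0.01)
  expect_error(normalize_burst(c(0, -1)), class = "ngf_error_normalization")
  # tibble input with unordered rows
  tb <- tibble::tibble(n_ap = c(2, 1), peak = c(-2, -1))
  expect_equal(normalize_burst(tb)$normalized, c(1, 2))
})
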