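test_that("synthesized IPSPs round-trip their requested kinetics", {
  # fast (ionotropic-like) kinetics
  k_fast <- ipsp_kinetics(rise_time_10_90 = 4.66, half_width = 19.29,
                          amplitude = -2.19)
  tr <- synth_ipsp(k_fast, dt = 0.1, duration = 300, seed = 1)
  meas <- measure_kinetics(tr, peak_window = 50)
  expect_lt(abs(meas$peak - (-2.19)), 0.01 * 2.19)
  expect_lt(abs(meas$rise_10_90 - 4.66), 0.05 * 4.66)
  expect_lt(abs(meas$half_width - 19.29), 0.05 * 19.29)

  # slow (metabotropic-like) kinetics: long rise relative to half-width
  k_slow <- slow_ipsp_kinetics()
  trs <- synth_ipsp(k_slow, dt = 0.5, duration = 2500, seed = 1)
  ms <- measure_kinetics(trs, peak_window = 400)
  expect_lt(abs(ms$rise_10_90 - 86.95), 0.05 * 86.95)
  expect_lt(abs(ms$half_width - 252.27), 0.05 * 252.27)
  expect_lt(abs(ms$peak - (-0.94)), 0.01 * 0.94)
})

test_that("zero amplitude gives a flat trace; bad kinetics are rejected", {
  k0 <- ipsp_kinetics(amplitude = 0)
  tr <- synth_ipsp(k0, dt = 0.1, duration = 200, seed = 1)
  expect_true(all(tr$value == 0))
  # 10-90% rise longer than the half-width is not representable
  expect_error(synth_ipsp(ipsp_kinetics(rise_time_10_90 = 30, half_width = 20,
                                        amplitude = -1),
                          dt = 0.1, duration = 400),
               class = "ngf_error_calibration")
  expect_error(ipsp_kinetics(rise_time_10_90 = -1),
               class = "ngf_error_config")
})

test_that("generator is deterministic given a seed (with noise)", {
  k <- ipsp_kinetics()
  a <- synth_ipsp(k, dt = 0.2, duration = 300, seed = 9, noise_sd = 0.1)
  b <- synth_ipsp(k, dt = 0.2, duration = 300, seed = 9, noise_sd = 0.1)
  expect_identical(a$value, b$value)
})
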