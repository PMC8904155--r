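test_that("spike probability counts at most one spike per period", {
  tr <- pulse_train(100, 0.5, 0, 120, 1000)
  per <- tr$period
  all_periods <- (0:119) * per + 1
  expect_equal(spike_probability(all_periods, tr), 1)
  expect_equal(spike_probability(numeric(0), tr), 0)
  every_other <- (seq(0, 118, by = 2)) * per + 1
  expect_equal(spike_probability(every_other, tr), 0.5)
  # doublets within one period still count once
  doublets <- sort(c(all_periods, all_periods + 1))
  expect_equal(spike_probability(doublets, tr), 1)
})

test_that("threshold search returns a minimal grid amplitude with certificate", {
  pair <- reduced_pair_cached()
  th <- find_threshold(pair$a2, 0.5, 0, 120, duration = 250, resolution = 1)
  expect_gte(th$achieved_probability, 1)
  expect_equal(th$charge, th$current * 0.5)
  below <- th$search_trace$probability[
    abs(th$search_trace$amplitude - (th$current - 1)) < 1e-9]
  if (length(below)) expect_lt(below, 1)
  # strength-duration ordering and interphase-gap relief
  th_long <- find_threshold(pair$a2, 1.2, 0, 120, duration = 250)
  th_short <- find_threshold(pair$a2, 0.1, 0, 120, duration = 250)
  expect_lte(th_long$current, th_short$current)
  th_gap <- find_threshold(pair$a2, 0.5, 1, 120, duration = 250)
  expect_lte(th_gap$current, th$current)
})

test_that("response curves respect the counting cap and grid geometry", {
  pair <- reduced_pair_cached()
  curve <- rate_vs_amplitude(pair$a2, c(10, 40), step = 10, pulse_width = 0.5,
                             frequency = 200, duration = 250)
  expect_identical(nrow(curve), 4L)
  expect_true(all(curve$rate <= 200))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_equal(curve$rate, curve$probability * 200)
  # the tuned 120 Hz threshold has probability 1 when evaluated at 120 Hz
  th <- find_threshold(pair$a2, 0.5, 0, 120, duration = 250)
  c120 <- rate_vs_amplitude(pair$a2, th$current, pulse_width = 0.5,
                            frequency = 120, duration = 250)
  expect_equal(c120$probability, 1)
})

test_that("saturation windows are measured on constructed curves", {
  flat <- data.frame(amplitude = seq(100, 400, by = 50),
                     probability = c(0.1, 0.5, 0.5, 0.5, 0.5, 0.9, 1),
                     rate = NA)
  w <- saturation_window(flat, level = 0.5)
  expect_equal(w$width, 150)
  expect_equal(w$interval, c(150, 300))
  rising <- data.frame(amplitude = seq(0, 100, by = 10),
                       probability = seq(0, 1, by = 0.1), rate = NA)
  expect_equal(saturation_window(rising, level = 0.45, tol = 0.02)$width, 0)
  none <- data.frame(amplitude = 1:3, probability = c(0, 1, 1), rate = NA)
  expect_equal(saturation_window(none)$width, 0)
})

test_that("differential response is antisymmetric and zero for identical curves", {
  a <- data.frame(amplitude = seq(0, 100, by = 10),
                  rate = pmin(200, seq(0, 200, by = 20)))
  b <- a
  d0 <- differential_response(a, b, target_rate = 20)
  expect_true(all(d0$difference$rate_diff == 0))
  expect_equal(d0$gap, 0)
  b$rate <- pmin(200, pmax(0, seq(-40, 160, by = 20)))
  d1 <- differential_response(a, b, target_rate = 20)
  d2 <- differential_response(b, a, target_rate = 20)
  expect_equal(d1$difference$rate_diff, -d2$difference$rate_diff)
  expect_equal(d1$gap, -d2$gap)
  # unreached targets are reported
  low <- data.frame(amplitude = a$amplitude, rate = rep(1, 11))
  d3 <- differential_response(a, low, target_rate = 20)
  expect_false(d3$reached_b)
  expect_true(is.na(d3$gap))
})

test_that("the IPG sweep at zero gap reproduces the strength-duration entry", {
  pair <- reduced_pair_cached()
  sd <- strength_duration_sweep(pair$a2, pair$d1, pulse_widths = 0.5,
                                duration = 250)
  ip <- ipg_sweep(pair$a2, pair$d1, ipgs = 0, pulse_width = 0.5,
                  duration = 250)
  expect_equal(sd$current_a2, ip$current_a2)
  expect_equal(sd$current_d1, ip$current_d1)
  expect_equal(sd$rate_difference, ip$rate_difference)
})

test_that("swapping a channel to its own value reproduces the trace bit for bit", {
  pair <- reduced_pair_cached(1)
  res <- channel_swap_experiment(pair$a2, "g_Ca", 0.137)
  expect_identical(res$base$soma_voltage, res$swapped$soma_voltage)
  expect_equal(res$delta$width, 0)
})

test_that("sag is absent in passive cells, greater in D1, monotone in g_h", {
  expect_lt(abs(measure_sag(passive_soma_cell())), 0.01)
  pair <- reduced_pair_cached(1)
  expect_gt(measure_sag(pair$d1), measure_sag(pair$a2))
  sags <- vapply(c(0, 1e-4, 2e-4),
                 function(gh) measure_sag(passive_soma_cell(g_h = gh)),
                 numeric(1))
  expect_true(all(diff(sags) > 0))
})
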