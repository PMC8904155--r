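test_that("biphasic waveforms are cathodic-first and charge balanced", {
  tr <- pulse_train(100, 0.5, 0.2, 120, 1000)
  expect_equal(waveform_current(0.25, tr), -100)     # mid cathodic phase
  expect_equal(waveform_current(0.6, tr), 0)         # inside the gap
  expect_equal(waveform_current(0.9, tr), 100)       # mid anodic phase
  expect_equal(waveform_current(3, tr), 0)           # inter-pulse
  # analytic charge balance over any whole period
  q <- integrate(function(t) waveform_current(t, tr), 0, tr$period,
                 subdivisions = 2000, rel.tol = 1e-10)$value
  expect_lt(abs(q), 1e-8)
})

test_that("grid-sampled waveforms balance to 1e-12 over whole periods", {
  for (pw in c(0.1, 0.5, 1.2)) {
    for (ipg in c(0, 0.1, 1.0)) {
      for (f in c(120, 200)) {
        if (2 * pw + ipg > 1000 / f) next
        tr <- pulse_train(237, pw, ipg, f, 1000)
        dt <- rgcstim:::snap_dt(0.01, tr)
        nper <- floor(1000 / tr$period)
        nt <- round(nper * tr$period / dt)
        tmid <- (seq_len(nt) - 0.5) * dt
        q <- sum(waveform_current(tmid, tr)) * dt
        expect_lt(abs(q) / charge_per_phase(tr), 1e-12)
      }
    }
  }
})

test_that("per-phase charge follows amplitude x width", {
  expect_equal(charge_per_phase(pulse_train(550, 0.1, 0, 200, 1000)), 55)
  expect_equal(charge_per_phase(pulse_train(75, 1, 0, 200, 1000)), 75)
  expect_equal(charge_per_phase(pulse_train(0, 0.5, 0, 120, 1000)), 0)
})

test_that("invalid trains are rejected at construction", {
  expect_error(pulse_train(100, 3, 0, 200, 1000), "period")
  expect_error(pulse_train(100, 0.5, 0, 120, 4), "duration")
  expect_error(pulse_train(-5, 0.5, 0, 120, 1000))
})

test_that("disk potential matches its closed-form anchors", {
  el <- electrode_model(radius = 100, sigma = 0.1)
  # disk surface value I/(4 sigma a)
  expect_equal(disk_potential(0, 0, 1, el),
               1e-6 / (4 * 0.1 * 100e-6) * 1e3, tolerance = 1e-12)
  # far field approaches the half-space point source I/(2 pi sigma R)
  z <- 100 * 100
  v_far <- disk_potential(0, z, 1, el)
  v_pt <- 1e-6 / (2 * pi * 0.1 * z * 1e-6) * 1e3
  expect_equal(v_far, v_pt, tolerance = 1e-3)
  # strictly decreasing along the axis
  v <- disk_potential(0, seq(10, 500, by = 10), 1, el)
  expect_true(all(diff(v) < 0))
})

test_that("disk potential agrees with quadrature over the disk current density", {
  el <- electrode_model(radius = 100, sigma = 0.1)
  a <- 100e-6
  z <- 50e-6
  # equipotential disk carries surface density I/(2 pi a sqrt(a^2 - rho^2));
  # integrate half-space point sources over the disk
  v_quad <- integrate(function(rho) {
    (1e-6 / (2 * pi * a * sqrt(a^2 - rho^2))) *
      (1 / (2 * pi * 0.1)) * 2 * pi * rho / sqrt(rho^2 + z^2)
  }, 0, a, rel.tol = 1e-10)$value * 1e3
  expect_equal(disk_potential(0, 50, 1, el), v_quad, tolerance = 5e-3)
})

test_that("extracellular coupling is linear, decays with distance, and matches the field", {
  pair <- reduced_pair_cached()
  comp <- discretize_cell(pair$a2)
  el <- electrode_model()
  phi <- map_extracellular(comp, el)
  expect_equal(phi, disk_potential(sqrt(comp$x^2 + comp$y^2), comp$z, 1, el),
               tolerance = 1e-12)
  # linearity: scaling the current scales every potential
  expect_equal(10 * phi, vapply(seq_len(nrow(comp)), function(i) {
    disk_potential(sqrt(comp$x[i]^2 + comp$y[i]^2), comp$z[i], 10, el)
  }, numeric(1)), tolerance = 1e-12)
  # on-axis monotone decay
  on_axis <- data.frame(x = 0, y = 0, z = c(60, 120))
  v2 <- map_extracellular(on_axis, el)
  expect_gt(abs(v2[1]), abs(v2[2]))
  inside <- data.frame(x = 10, y = 0, z = 0)
  expect_error(map_extracellular(inside, el), "inside")
})
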