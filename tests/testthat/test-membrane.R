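test_that("with all maximal conductances zero the total current is the leak", {
  st <- gating_state(-60)
  d <- unlist(zero_densities())
  for (V in c(-80, -65, -40, 0)) {
    cur <- ionic_current(V, st, d, g_leak = 5e-5)
    expect_equal(cur$total, 1e3 * 5e-5 * (V + 65), tolerance = 1e-12)
    expect_true(all(cur$by_channel[setdiff(names(cur$by_channel), "leak")] == 0))
  }
})

test_that("currents vanish at their reversal potentials", {
  st <- gating_state(-60)
  d <- unlist(zero_densities())
  d["g_K"] <- 0.12
  cur <- ionic_current(-75, st, d, g_leak = 0)
  expect_equal(cur$by_channel[["K"]], 0)
  expect_equal(cur$total, 0)
})

test_that("raising intracellular calcium strengthens the K_Ca current", {
  d <- unlist(zero_densities())
  d["g_KCa"] <- 5e-4
  st1 <- gating_state(-60, ca_i = 1e-3)
  st2 <- gating_state(-60, ca_i = 1e-2)
  i1 <- ionic_current(-60, st1, d, g_leak = 0)$by_channel[["KCa"]]
  i2 <- ionic_current(-60, st2, d, g_leak = 0)$by_channel[["KCa"]]
  expect_gt(abs(i2), abs(i1))
})

test_that("the calcium pool has a fixed point at rest and relaxes exponentially", {
  p <- membrane_params()
  expect_equal(step_calcium(0, p$ca_rest, 0.01, p), p$ca_rest)
  # closed-form decay: excess reduced to 1/e after one time constant
  ca <- p$ca_rest + 1e-3
  dt <- p$tau_ca / 1000
  for (k in 1:1000) ca <- step_calcium(0, ca, dt, p)
  expect_equal((ca - p$ca_rest) / 1e-3, exp(-1), tolerance = 0.01)
  # inward (negative) calcium current raises the concentration
  expect_gt(step_calcium(-10, p$ca_rest, 0.01, p), p$ca_rest)
})

test_that("gating variables stay within [0,1] along bounded voltage excursions", {
  gates <- c("m", "h", "n", "a", "ha", "c", "q", "tm", "th")
  set.seed(42)
  for (rep in 1:20) {
    V <- runif(1, -120, 80)
    x <- runif(length(gates))
    for (step in 1:50) {
      V <- min(80, max(-120, V + rnorm(1, 0, 15)))
      for (i in seq_along(gates)) {
        r <- rate_functions(gates[i], V)
        tau <- 1 / (r$alpha + r$beta)
        xinf <- r$alpha * tau
        x[i] <- xinf + (x[i] - xinf) * exp(-0.05 / tau)
      }
      expect_true(all(x >= 0 & x <= 1))
    }
  }
})

test_that("single-compartment presets settle to a quiescent resting potential", {
  pair <- reduced_pair_cached(1)
  st <- solver_settings(settle_ms = 0)
  for (nm in c("a2", "d1")) {
    sim <- simulate_cell(pair[[nm]], train = NULL, electrode = NULL,
                         duration = 700, settings = st)
    late <- sim$soma_voltage[sim$time >= 500]
    expect_equal(length(sim$spike_times), 0, info = nm)
    n <- length(sim$soma_voltage)
    dvdt <- abs(sim$soma_voltage[n] - sim$soma_voltage[n - 1]) / sim$metadata$dt
    expect_lt(dvdt, 0.01)
    expect_gt(sim$soma_voltage[n], -75)
    expect_lt(sim$soma_voltage[n], -55)
    expect_true(all(abs(late - late[length(late)]) < 2))
  }
})

test_that("swapping soma conductances moves spike shape and rest as expected", {
  pair <- reduced_pair_cached(1)
  # lowering the Ca density narrows the action potential
  sw <- channel_swap_experiment(pair$a2, "g_Ca", 0.013)
  expect_lt(sw$metrics_swapped$width_at_half_max,
            sw$metrics_base$width_at_half_max)
  # raising the delayed-rectifier density lowers the resting potential
  rest_of <- function(cell) {
    sim <- simulate_cell(cell, train = NULL, electrode = NULL,
                         duration = 600)
    tail(sim$soma_voltage, 1)
  }
  expect_lt(rest_of(set_density(pair$a2, "g_K", 0.211)), rest_of(pair$a2))
})
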